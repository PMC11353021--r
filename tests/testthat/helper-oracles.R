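# Independent oracles: deliberately naive re-derivations used to check the
# package's optimized paths. They share only the contract, not the code.

# Exhaustive CED: for every anchor exam, filter-and-sum the half-open window
# (anchor - window_days, anchor]; maximum with earliest-anchor tie-break.
brute_force_ced <- function(dates, doses, window_days) {
  dates <- as.numeric(dates)
  ord <- order(dates)
  dates <- dates[ord]; doses <- doses[ord]
  best <- -Inf; best_anchor <- NA_real_
  for (i in seq_along(dates)) {
    inside <- dates > dates[i] - window_days & dates <= dates[i]
    s <- sum(doses[inside])
    if (s > best) {
      best <- s
      best_anchor <- dates[i]
    }
  }
  list(ced = best, anchor = best_anchor)
}

# draw a random single-patient history (integer dates, mixed modalities)
random_history <- function(n_exams, patient_id = "R1",
                           span_days = 4000) {
  dates <- as.Date("2015-01-01") + sample.int(span_days, n_exams,
                                              replace = TRUE)
  modality <- sample(c("CT", "RADIOGRAPH", "NUCLEAR"), n_exams,
                     replace = TRUE, prob = c(0.6, 0.3, 0.1))
  protocol <- ifelse(modality == "CT",
                     sample(ct_protocols(), n_exams, replace = TRUE),
                     ifelse(modality == "RADIOGRAPH", "XRAY_GENERAL", "NM"))
  exam_records(data.frame(
    patient_id = patient_id, study_date = dates, modality = modality,
    protocol = protocol,
    effective_dose_mSv = round(stats::rlnorm(n_exams, log(8), 0.8), 3),
    stringsAsFactors = FALSE))
}

# hand-rolled piecewise-linear interpolation with top clamp, reading a
# coefficient CSV directly (bypasses the package loader and approx())
oracle_lar_coefficient <- function(csv_path, kind, sex, site, age) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  df <- df[df$kind == kind & df$sex == sex & df$site == site, ]
  df <- df[order(df$age), ]
  ages <- df$age; vals <- df$coefficient
  if (age >= max(ages)) return(vals[length(vals)])
  i <- max(which(ages <= age))
  if (ages[i] == age) return(vals[i])
  vals[i] + (vals[i + 1] - vals[i]) * (age - ages[i]) / (ages[i + 1] - ages[i])
}

beir_csv <- function(kind) {
  system.file("extdata",
              if (kind == "incidence") "beir7_12d1.csv" else "beir7_12d2.csv",
              package = "cedlar")
}
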