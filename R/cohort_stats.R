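#' Descriptive summary of a numeric sample
#'
#' The cohort's presentation conventions: median of an even-sized sample is
#' the mean of the two central order statistics; quartiles use linear
#' interpolation between order statistics (`quantile` type 7); standard
#' deviation uses denominator n - 1 and is reported as `NA` for a single
#' value.
#'
#' @param values non-empty numeric vector.
#' @return list `n`, `median`, `sd`, `p25`, `p75`, `min`, `max`.
#' @export
summarize_values <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("summarize_values requires a non-empty sample without NAs",
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(n = length(values),
       median = stats::median(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       p25 = q[1], p75 = q[2],
       min = min(values), max = max(values))
}

#' Grouped CED summary by sex and age band
#'
#' One row per (sex, band) with the group's size, its share of that sex's
#' shortlisted patients and of the whole shortlist, and the CED summary.
#' Empty bands are emitted as explicit `NA` rows (matching the "not
#' available" strata of the printed tables), not dropped.
#'
#' @param shortlisted data.frame with columns `sex`, `age` (integer years,
#'   the banding age) and `ced_mSv`.
#' @param scheme an [age_group_scheme()].
#' @return data.frame with columns `sex`, `age_band`, `n`, `pct_within_sex`,
#'   `pct_overall`, `median`, `sd`, `p25`, `p75`, `min`, `max`.
#' @export
group_ced_summary <- function(shortlisted, scheme = age_group_scheme()) {
  stopifnot(all(c("sex", "age", "ced_mSv") %in% names(shortlisted)))
  shortlisted$age_band <- assign_age_group(shortlisted$age, scheme)
  n_total <- nrow(shortlisted)
  rows <- list()
  for (sx in c("M", "F")) {
    sub <- shortlisted[shortlisted$sex == sx, , drop = FALSE]
    for (b in scheme$band) {
      vals <- sub$ced_mSv[sub$age_band == b]
      if (length(vals) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, age_band = b, n = 0L, pct_within_sex = 0,
          pct_overall = 0, median = NA_real_, sd = NA_real_, p25 = NA_real_,
          p75 = NA_real_, min = NA_real_, max = NA_real_,
          stringsAsFactors = FALSE)
      } else {
        s <- summarize_values(vals)
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, age_band = b, n = s$n,
          pct_within_sex = 100 * s$n / nrow(sub),
          pct_overall = 100 * s$n / n_total,
          median = s$median, sd = s$sd, p25 = s$p25, p75 = s$p75,
          min = s$min, max = s$max, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exam-mix report for a reporting period
#'
#' Per-protocol CT study counts with percentage shares (one decimal), sex
#' split, patient-age summary (median, SD, range over the studies' patient
#' ages) and per-study recurrent counts under the definition of
#' [recurrent_ct_rate()].
#'
#' @param records an [exam_records] data.frame.
#' @param patients data.frame `patient_id`, `sex`, and `age` (years) or
#'   `birth_date`.
#' @param period_start,period_end inclusive `Date` bounds.
#' @return data.frame, one row per protocol present, ordered by descending
#'   study count, plus attributes `total_ct` and `total_recurrent`.
#' @export
build_exam_mix_table <- function(records, patients, period_start,
                                 period_end) {
  records <- exam_records(as.data.frame(records))
  ct <- records[records$modality == "CT" &
                  records$study_date >= as.Date(period_start) &
                  records$study_date <= as.Date(period_end), , drop = FALSE]
  if (nrow(ct) == 0) {
    out <- data.frame(protocol = character(), n_studies = integer(),
                      pct = numeric(), n_male = integer(),
                      n_female = integer(), age_median = numeric(),
                      age_sd = numeric(), age_min = numeric(),
                      age_max = numeric(), n_recurrent = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "total_ct") <- 0L
    attr(out, "total_recurrent") <- 0L
    return(out)
  }
  m <- match(ct$patient_id, patients$patient_id)
  if (anyNA(m)) stop("records reference unknown patient_id(s)",
                     call. = FALSE)
  ct$sex <- patients$sex[m]
  ct$age <- if ("age" %in% names(patients)) patients$age[m] else
    floor(as.numeric(ct$study_date - as.Date(patients$birth_date[m])) /
            365.25)
  total <- nrow(ct)
  rows <- lapply(split(ct, ct$protocol), function(g) {
    per_patient <- table(g$patient_id)
    s <- summarize_values(g$age)
    data.frame(protocol = g$protocol[1], n_studies = nrow(g),
               pct = round(100 * nrow(g) / total, 1),
               n_male = sum(g$sex == "M"), n_female = sum(g$sex == "F"),
               age_median = s$median, age_sd = s$sd, age_min = s$min,
               age_max = s$max,
               n_recurrent = sum(pmax(as.integer(per_patient) - 1L, 0L)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_studies), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_ct") <- total
  attr(out, "total_recurrent") <- sum(out$n_recurrent)
  out
}

#' Grouped LAR report tables
#'
#' Median and IQR, by (sex, age band), of the per-site and total lifetime
#' attributable risks of a set of patient profiles, for incidence and
#' mortality. Single-member groups echo the member's value as the median.
#'
#' @param profiles list of entries `list(sex =, age_band =, profile =)` where
#'   `profile` is a [lar_profile()] result.
#' @param per_100 report risks per 100 patients (the "%LAR" presentation,
#'   per-100,000 values divided by 1000); default `TRUE`.
#' @return data.frame with columns `sex`, `age_band`, `kind`, `site`
#'   (including `"total"`), `n`, `median`, `p25`, `p75`, `min`, `max`.
#' @export
build_lar_tables <- function(profiles, per_100 = TRUE) {
  scale <- if (per_100) 1 / 1000 else 1
  keys <- vapply(profiles, function(p) paste(p$sex, p$age_band), character(1))
  rows <- list()
  for (key in unique(keys)) {
    members <- profiles[keys == key]
    sx <- members[[1]]$sex; band <- members[[1]]$age_band
    for (kind in c("incidence", "mortality")) {
      sites <- c(names(members[[1]]$profile[[kind]]$per_site), "total")
      for (site in sites) {
        vals <- vapply(members, function(m) {
          r <- m$profile[[kind]]
          if (site == "total") r$total else r$per_site[[site]]
        }, numeric(1)) * scale
        s <- summarize_values(vals)
        rows[[length(rows) + 1L]] <- data.frame(
          sex = sx, age_band = band, kind = kind, site = site, n = s$n,
          median = s$median, p25 = s$p25, p75 = s$p75, min = s$min,
          max = s$max, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
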