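#' Path to a packaged reference table
#'
#' @param file file name under the package's `extdata/`.
#' @return absolute path.
#' @keywords internal
cedlar_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cedlar", mustWork = FALSE)
  if (!nzchar(path)) {
    # source-tree fallback so scripts can run before installation
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged file not found: ", file, call. = FALSE)
  path
}

#' Shortlisted-cohort fixture: the 22 patients with CED >= 100 mSv
#'
#' The printed summary of the 22 adult patients whose cumulative effective
#' dose reached 100 mSv over the review's five-year horizon: sex, printed age
#' range (stored as an integer min/max pair), total CED (mSv), average study
#' interval (days), and total/CT/X-ray exam counts plus free-text history.
#' Values are stored exactly as printed. One entry (id 4) counts one more
#' total exam than its CT + X-ray split; its footnote attributes the extra
#' exam to an interventional procedure, and the printed counts are kept
#' verbatim.
#'
#' @return data.frame with 22 rows and columns `id`, `sex`, `age_min`,
#'   `age_max`, `ced_mSv`, `interval_days`, `n_total`, `n_ct`, `n_xray`,
#'   `history`.
#' @export
load_study_fixture <- function() {
  df <- utils::read.csv(cedlar_extdata("table2_patients.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 22, all(df$ced_mSv >= 100),
            all(df$sex %in% c("M", "F")),
            all(df$age_min >= 15), all(df$age_min <= df$age_max))
  # exam-count consistency holds for every entry except the documented one
  split_ok <- df$n_ct + df$n_xray == df$n_total
  stopifnot(all(split_ok | df$id == 4))
  df
}

#' Exam-mix fixture: one year of CT studies by protocol
#'
#' Per-protocol study counts, sex split, patient-age summary and recurrent-CT
#' counts for the one-year review period (4406 adult CT studies in total).
#'
#' @return data.frame with one row per CT protocol.
#' @export
load_exam_mix_fixture <- function() {
  df <- utils::read.csv(cedlar_extdata("table1_exam_mix.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(all(df$protocol %in% ct_protocols()),
            all(df$n_male + df$n_female == df$n_studies),
            all(df$n_recurrent <= df$n_studies))
  df
}

#' Cumulative organ-dose fixture by sex and age band
#'
#' Printed per-(sex, age-band) cumulative quantities for the shortlisted
#' cohort: the CED (mSv; median and min-max) and the nine risk-relevant
#' cumulative organ doses (mGy; median, with 25th/75th percentiles for
#' multi-patient male bands). Single-patient bands carry the single value as
#' the median. Bands with no shortlisted patient are omitted here and emitted
#' as explicit NA rows by the report builders.
#'
#' @return long data.frame with columns `sex`, `age_band`, `pct_cases`,
#'   `quantity` (`CED_mSv` or an organ name), `median`, `p25`, `p75`, `min`,
#'   `max`.
#' @export
load_organ_dose_fixture <- function() {
  df <- utils::read.csv(cedlar_extdata("table4_organ_doses.csv"),
                        stringsAsFactors = FALSE)
  stopifnot(all(df$sex %in% c("M", "F")), all(df$median >= 0, na.rm = TRUE))
  df
}

#' Expand a fixture entry into a per-exam history
#'
#' The cohort fixture prints per-patient totals (CED, exam counts, average
#' interval), not per-exam doses. This synthesizes a per-exam series exactly
#' consistent with the printed totals: `n_total` exams at a constant spacing
#' equal to the printed average interval, with the CED apportioned across
#' modalities by `ct_share` (the fraction of CED attributed to CT; the
#' default reflects the near-total CT dominance of CED in this cohort, where
#' radiography contributes on the order of one percent). The per-exam dose
#' sum is corrected in the last exam so it equals the printed CED exactly.
#'
#' Printed average intervals carry one decimal, so exact reproduction of the
#' mean gap requires sub-day date resolution; expanded histories therefore
#' use fractional `Date` values.
#'
#' @param entry one row of [load_study_fixture()].
#' @param ct_share fraction of CED apportioned to CT exams when non-CT exams
#'   are present (default 0.988).
#' @param start_date date of the first exam.
#' @return a [patient_history].
#' @export
expand_fixture_history <- function(entry, ct_share = 0.988,
                                   start_date = as.Date("2021-01-01")) {
  entry <- as.list(entry)
  n <- as.integer(entry$n_total)
  if (n == 0 && entry$ced_mSv > 0) {
    stop("inconsistent fixture entry: zero exams with positive CED",
         call. = FALSE)
  }
  n_ct <- as.integer(entry$n_ct)
  n_xray <- as.integer(entry$n_xray)
  n_ir <- n - n_ct - n_xray   # the documented interventional extra, if any
  stopifnot(n_ir >= 0, n_ct >= 1)

  n_nonct <- n_xray + n_ir
  share <- if (n_nonct == 0) 1 else ct_share
  doses <- c(rep(entry$ced_mSv * share / n_ct, n_ct),
             rep(if (n_nonct == 0) 0 else
               entry$ced_mSv * (1 - share) / n_nonct, n_nonct))
  doses[n] <- entry$ced_mSv - sum(doses[-n])  # exact printed total

  dates <- start_date + (seq_len(n) - 1) *
    (if (n > 1) entry$interval_days else 0)
  exams <- data.frame(
    patient_id = as.character(entry$id),
    study_date = dates,
    modality = c(rep("CT", n_ct), rep("RADIOGRAPH", n_xray),
                 rep("INTERVENTIONAL", n_ir)),
    protocol = c(rep("OTHER", n_ct), rep("XRAY_GENERAL", n_xray),
                 rep("IR", n_ir)),
    effective_dose_mSv = doses,
    stringsAsFactors = FALSE)
  patient <- list(patient_id = as.character(entry$id), sex = entry$sex,
                  age_min = entry$age_min, age_max = entry$age_max)
  patient_history(patient, exams)
}

#' Expand the whole shortlisted-cohort fixture
#'
#' @inheritParams expand_fixture_history
#' @return named list of 22 [patient_history] objects.
#' @export
expand_all_fixture_histories <- function(ct_share = 0.988,
                                         start_date = as.Date("2021-01-01")) {
  fx <- load_study_fixture()
  out <- lapply(seq_len(nrow(fx)), function(i)
    expand_fixture_history(fx[i, ], ct_share = ct_share,
                           start_date = start_date))
  names(out) <- as.character(fx$id)
  out
}

#' Deterministic registry reproducing a printed exam mix
#'
#' Builds an exam-record registry whose per-protocol study counts and
#' per-study recurrence counts equal a printed exam-mix table exactly: for a
#' protocol with `n_studies` studies of which `n_recurrent` are recurrent,
#' `n_recurrent` patients receive two studies each (the second being the
#' recurrent one under the "an earlier CT by the same patient in the period"
#' definition) and the remainder one study each. Study dates are spread
#' deterministically over the period; sexes are assigned to match the printed
#' sex split. Doses are nominal per-protocol values; this constructor is for
#' count/rate arithmetic, not dosimetry.
#'
#' @param mix data.frame as returned by [load_exam_mix_fixture()].
#' @param period_start,period_end `Date` bounds of the reporting period.
#' @return list with `records` ([exam_records]) and `patients` (data.frame
#'   `patient_id`, `sex`, `age`).
#' @export
registry_from_exam_mix <- function(mix,
                                   period_start = as.Date("2021-01-01"),
                                   period_end = as.Date("2021-12-31")) {
  span <- as.numeric(period_end - period_start)
  recs <- list(); pats <- list(); uid <- 0L
  for (i in seq_len(nrow(mix))) {
    row <- mix[i, ]
    n_pat <- row$n_studies - row$n_recurrent  # one patient per first study
    stopifnot(n_pat >= row$n_recurrent)
    ids <- sprintf("%s_%04d", row$protocol, uid + seq_len(n_pat))
    uid <- uid + n_pat
    sex <- rep(c("M", "F"), times = c(row$n_male, row$n_female))
    # map printed per-study sex counts onto patients: recurrent patients'
    # two studies share one sex, so assign sexes study-wise in patient order
    n_per_pat <- c(rep(2L, row$n_recurrent), rep(1L, n_pat - row$n_recurrent))
    pat_sex <- sex[cumsum(n_per_pat) - n_per_pat + 1L]
    first_day <- period_start + floor(seq(0, span * 0.6, length.out = n_pat))
    age <- round(seq(max(row$age_min, 18), row$age_max, length.out = n_pat))
    pats[[i]] <- data.frame(patient_id = ids, sex = pat_sex, age = age,
                            stringsAsFactors = FALSE)
    rep_idx <- rep(seq_len(n_pat), times = n_per_pat)
    offset <- unlist(lapply(n_per_pat, function(k) seq_len(k) - 1L)) * 30
    recs[[i]] <- data.frame(
      patient_id = ids[rep_idx],
      study_date = pmin(first_day[rep_idx] + offset, period_end),
      modality = "CT", protocol = row$protocol,
      effective_dose_mSv = 10, stringsAsFactors = FALSE)
  }
  list(records = exam_records(do.call(rbind, recs)),
       patients = do.call(rbind, pats))
}
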