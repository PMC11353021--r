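DAYS_PER_YEAR <- 365.25

# Core sliding-window maximum on pre-sorted numeric dates/doses.
# Window of `window_days` anchored at each exam date, half-open at the start:
# exam j contributes to anchor i iff  d_i - window_days < d_j <= d_i.
# Ties on the maximum are broken toward the earliest anchor.
ced_core <- function(dates, doses, window_days) {
  ord <- order(dates)
  dates <- dates[ord]; doses <- doses[ord]
  n <- length(dates)
  csum <- cumsum(doses)
  # first index inside each anchor's window: smallest j with d_j > d_i - W
  lo <- findInterval(dates - window_days, dates) + 1L
  # findInterval counts d_j <= boundary, so +1 lands on the first strictly
  # greater element: the half-open start excludes a boundary exam exactly.
  sums <- csum - c(0, csum)[lo]
  best <- which.max(sums)  # earliest anchor among ties
  list(ced = sums[best],
       start = dates[best] - window_days,
       end = dates[best],
       n = best - lo[best] + 1L)
}

#' Cumulative effective dose over a sliding multi-year window
#'
#' Computes the CED of one patient's history: the maximum, over windows of
#' `window_years` years anchored at each exam date, of the summed effective
#' doses of the patient's non-nuclear-medicine exams falling in the half-open
#' window `(anchor - window, anchor]`. Anchoring at exam dates makes the
#' search exact and finite; an exam lying exactly on a window's start
#' boundary is excluded (it anchors its own window instead), so no exam is
#' double-counted across adjacent windows. Ties are broken toward the
#' earliest window. A window year is 365.25 days.
#'
#' Nuclear-medicine records are retained in the history but never contribute
#' to the CED sum.
#'
#' @param history a [patient_history], or an [exam_records] data.frame for a
#'   single patient.
#' @param window_years positive window length in years (default 5).
#' @return list of class `ced_result`: `patient_id`, `ced_mSv`,
#'   `window_start`, `window_end` (Dates), `contributing_exam_count`,
#'   `window_years`.
#' @export
compute_ced <- function(history, window_years = 5) {
  stopifnot(window_years > 0)
  exams <- if (inherits(history, "patient_history")) history$exams else
    exam_records(as.data.frame(history))
  if (length(unique(exams$patient_id)) > 1) {
    stop("compute_ced expects exams of a single patient", call. = FALSE)
  }
  exams <- exams[exams$modality != "NUCLEAR", , drop = FALSE]
  if (nrow(exams) == 0) {
    stop("no irradiating (non-nuclear-medicine) exams in history",
         call. = FALSE)
  }
  res <- ced_core(as.numeric(exams$study_date), exams$effective_dose_mSv,
                  window_years * DAYS_PER_YEAR)
  structure(list(patient_id = exams$patient_id[1],
                 ced_mSv = res$ced,
                 window_start = as.Date(res$start,
                                        origin = as.Date("1970-01-01")),
                 window_end = as.Date(res$end, origin = as.Date("1970-01-01")),
                 contributing_exam_count = res$n,
                 window_years = window_years),
            class = "ced_result")
}

#' @export
print.ced_result <- function(x, ...) {
  cat(sprintf("<ced_result> patient %s: CED %.2f mSv over %d exam(s), %s .. %s\n",
              x$patient_id, x$ced_mSv, x$contributing_exam_count,
              format(x$window_start), format(x$window_end)))
  invisible(x)
}

#' Shortlist patients whose CED reaches a threshold
#'
#' Applies [compute_ced()] to each history and keeps the patients whose CED
#' is at or above `threshold_mSv`, sorted by descending CED.
#'
#' @param histories list of [patient_history] objects, or an [exam_records]
#'   data.frame covering several patients (split on `patient_id`).
#' @param threshold_mSv positive threshold, default 100 mSv.
#' @param window_years window length passed to [compute_ced()].
#' @return data.frame with one row per shortlisted patient: `patient_id`,
#'   `ced_mSv`, `window_start`, `window_end`, `n_exams` (and `sex` when
#'   available from the histories).
#' @export
shortlist_patients <- function(histories, threshold_mSv = 100,
                               window_years = 5) {
  stopifnot(threshold_mSv >= 0)
  if (inherits(histories, "data.frame")) {
    recs <- exam_records(as.data.frame(histories))
    recs <- recs[recs$modality != "NUCLEAR", , drop = FALSE]
    idx <- split(seq_len(nrow(recs)), recs$patient_id)
    dates <- as.numeric(recs$study_date)
    doses <- recs$effective_dose_mSv
    wdays <- window_years * DAYS_PER_YEAR
    rows <- lapply(idx, function(ii) {
      r <- ced_core(dates[ii], doses[ii], wdays)
      if (r$ced >= threshold_mSv) {
        data.frame(patient_id = recs$patient_id[ii[1]], sex = NA_character_,
                   ced_mSv = r$ced,
                   window_start = as.Date(r$start, origin = "1970-01-01"),
                   window_end = as.Date(r$end, origin = "1970-01-01"),
                   n_exams = r$n, stringsAsFactors = FALSE)
      }
    })
  } else {
    rows <- lapply(histories, function(h) {
      r <- compute_ced(h, window_years = window_years)
      if (r$ced_mSv >= threshold_mSv) {
        data.frame(patient_id = r$patient_id,
                   sex = if (is.null(h$patient$sex)) NA_character_ else
                     h$patient$sex,
                   ced_mSv = r$ced_mSv, window_start = r$window_start,
                   window_end = r$window_end,
                   n_exams = r$contributing_exam_count,
                   stringsAsFactors = FALSE)
      }
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(), sex = character(),
                      ced_mSv = numeric(),
                      window_start = as.Date(character()),
                      window_end = as.Date(character()),
                      n_exams = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$ced_mSv, out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average interval between a patient's studies
#'
#' The printed cohort convention: the date span of the history divided by the
#' number of gaps, `(last - first) / (n - 1)`, in days.
#'
#' @param history a [patient_history] or single-patient [exam_records].
#' @return mean successive gap in days.
#' @export
average_study_interval <- function(history) {
  exams <- if (inherits(history, "patient_history")) history$exams else
    exam_records(as.data.frame(history))
  if (nrow(exams) < 2) {
    stop("average interval undefined for fewer than 2 exams", call. = FALSE)
  }
  as.numeric(max(exams$study_date) - min(exams$study_date)) /
    (nrow(exams) - 1)
}

#' Per-study recurrent-CT rate over a reporting period
#'
#' A CT study is counted as recurrent when the same patient has at least one
#' earlier CT study within the same period; equivalently, every CT after a
#' patient's first one in the period is recurrent. The rate is the recurrent
#' count over all CT studies in the period.
#'
#' @param records an [exam_records] data.frame.
#' @param period_start,period_end inclusive `Date` bounds.
#' @return list `recurrent_count`, `total_ct_count`, `rate`.
#' @export
recurrent_ct_rate <- function(records, period_start, period_end) {
  period_start <- as.Date(period_start); period_end <- as.Date(period_end)
  if (period_end < period_start) stop("empty period", call. = FALSE)
  records <- exam_records(as.data.frame(records))
  ct <- records[records$modality == "CT" &
                  records$study_date >= period_start &
                  records$study_date <= period_end, , drop = FALSE]
  total <- nrow(ct)
  if (total == 0) stop("no CT studies in period: rate undefined",
                       call. = FALSE)
  per_patient <- table(ct$patient_id)
  recurrent <- sum(pmax(as.integer(per_patient) - 1L, 0L))
  list(recurrent_count = recurrent, total_ct_count = total,
       rate = recurrent / total)
}

#' The cohort age-band scheme
#'
#' Eight contiguous adult bands: 15-20, 21-30, 31-40, 41-50, 51-60, 61-70,
#' 71-80, 81-90. Every integer age in \[15, 90\] falls in exactly one band.
#'
#' @return data.frame with `band` (label), `lo`, `hi` (inclusive integer
#'   bounds).
#' @export
age_group_scheme <- function() {
  lo <- c(15L, 21L, 31L, 41L, 51L, 61L, 71L, 81L)
  hi <- c(20L, 30L, 40L, 50L, 60L, 70L, 80L, 90L)
  data.frame(band = paste0(lo, "-", hi), lo = lo, hi = hi,
             stringsAsFactors = FALSE)
}

#' Assign ages to age bands
#'
#' For patients carrying a printed age range rather than a birth date, the
#' banding age is the upper end of the range (the age at the most recent
#' exam); resolve it with [patient_age()] first.
#'
#' @param age integer age(s) in years.
#' @param scheme a scheme as returned by [age_group_scheme()].
#' @return character band label(s).
#' @export
assign_age_group <- function(age, scheme = age_group_scheme()) {
  age <- as.integer(age)
  out_of_scheme <- age < min(scheme$lo) | age > max(scheme$hi)
  if (any(out_of_scheme, na.rm = TRUE)) {
    stop("age(s) outside the banding scheme [",
         min(scheme$lo), ", ", max(scheme$hi), "]: ",
         paste(age[which(out_of_scheme)], collapse = ", "), call. = FALSE)
  }
  idx <- findInterval(age, scheme$lo)
  scheme$band[idx]
}
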