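#' CT protocol and modality vocabularies
#'
#' The registry distinguishes four irradiating modalities and a fixed set of
#' CT protocol codes. The seven named CT protocols are the acquisition
#' protocols of a trauma/emergency CT service (abdomen-pelvis with contrast,
#' polytrauma whole-body, kidney-ureter-bladder, brain stroke with CT
#' angiogram, chest-abdomen-pelvis with contrast, triphasic liver, abdominal
#' angiogram); any other CT acquisition is coded `OTHER`. Non-CT records carry
#' one of the non-CT protocol codes.
#'
#' @return `ct_protocols()` and `nonct_protocols()` return character vectors
#'   of protocol codes; `modalities()` the four modality codes.
#' @export
ct_protocols <- function() {
  c("ABD_PELVIS_C", "POLYTRAUMA", "KUB", "BRAIN_STROKE_CTA",
    "CHEST_ABD_PELVIS_C", "TRIPHASIC_LIVER", "ABD_ANGIO", "OTHER")
}

#' @rdname ct_protocols
#' @export
nonct_protocols <- function() c("XRAY_GENERAL", "IR", "NM")

#' @rdname ct_protocols
#' @export
modalities <- function() c("CT", "RADIOGRAPH", "INTERVENTIONAL", "NUCLEAR")

#' Construct a validated table of exam records
#'
#' An exam record is one irradiating event: patient identifier, study date,
#' modality, protocol code, effective dose in mSv and (optionally) the
#' dose-length product in mGy cm. Validation enforces non-negative doses and
#' the modality/protocol consistency rule: a record has modality `CT` exactly
#' when its protocol is a CT protocol code.
#'
#' @param df data.frame with columns `patient_id`, `study_date` (`Date` or
#'   ISO-8601 string), `modality`, `protocol`, `effective_dose_mSv` and
#'   optionally `dlp_mGycm`.
#' @return the validated data.frame with class `exam_records`, sorted rows
#'   preserved as given.
#' @export
exam_records <- function(df) {
  required <- c("patient_id", "study_date", "modality", "protocol",
                "effective_dose_mSv")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  if (!inherits(df$study_date, "Date")) {
    dates <- as.Date(df$study_date, format = "%Y-%m-%d")
    if (anyNA(dates) && !anyNA(df$study_date)) {
      stop("study_date must be an ISO-8601 calendar date (YYYY-MM-DD)",
           call. = FALSE)
    }
    df$study_date <- dates
  }
  if (!"dlp_mGycm" %in% names(df)) df$dlp_mGycm <- NA_real_
  df$effective_dose_mSv <- as.numeric(df$effective_dose_mSv)
  df$dlp_mGycm <- as.numeric(df$dlp_mGycm)

  bad_modality <- !df$modality %in% modalities()
  if (any(bad_modality)) {
    stop("unknown modality at row(s) ",
         paste(which(bad_modality), collapse = ", "), ": ",
         paste(unique(df$modality[bad_modality]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- !df$protocol %in% c(ct_protocols(), nonct_protocols())
  if (any(unknown)) {
    warning("unknown protocol string(s) mapped to OTHER: ",
            paste(unique(df$protocol[unknown]), collapse = ", "),
            call. = FALSE)
    df$protocol[unknown] <- "OTHER"
  }
  neg <- which(df$effective_dose_mSv < 0)
  if (length(neg) > 0) {
    stop("negative effective_dose_mSv at row(s): ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  neg_dlp <- which(!is.na(df$dlp_mGycm) & df$dlp_mGycm < 0)
  if (length(neg_dlp) > 0) {
    stop("negative dlp_mGycm at row(s): ", paste(neg_dlp, collapse = ", "),
         call. = FALSE)
  }
  is_ct_protocol <- df$protocol %in% ct_protocols()
  inconsistent <- which((df$modality == "CT") != is_ct_protocol)
  if (length(inconsistent) > 0) {
    stop("modality/protocol mismatch at row(s): ",
         paste(inconsistent, collapse = ", "),
         " (modality CT requires a CT protocol code and vice versa)",
         call. = FALSE)
  }
  class(df) <- unique(c("exam_records", class(df)))
  df
}

#' Read exam records from CSV
#'
#' Expects a UTF-8 CSV with header
#' `patient_id,study_date,modality,protocol,effective_dose_mSv,dlp_mGycm`
#' (`dlp_mGycm` optional), dates ISO-8601, dot decimal separator. Unknown
#' protocol strings are mapped to `OTHER` with a warning; unknown modalities
#' and negative doses are rejected with the offending rows named.
#'
#' @param path path to a CSV file (or a connection).
#' @return an [exam_records] data.frame, one row per data row.
#' @export
read_exam_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  exam_records(df)
}

#' Write exam records to CSV
#'
#' Inverse of [read_exam_records()]: round-tripping preserves all fields.
#'
#' @param records an [exam_records] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exam_records <- function(records, path) {
  records <- exam_records(as.data.frame(records))
  out <- records[, c("patient_id", "study_date", "modality", "protocol",
                     "effective_dose_mSv", "dlp_mGycm")]
  out$study_date <- format(out$study_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Bundle a patient with their date-ordered exams
#'
#' @param patient one-row data.frame (or list) with `patient_id`, `sex`
#'   (`"M"`/`"F"`) and either a `birth_date` or a printed age range
#'   (`age_min`, `age_max`, integer years).
#' @param exams an [exam_records] data.frame; all rows must carry the
#'   patient's id. Rows are sorted by `study_date`.
#' @return list of class `patient_history` with elements `patient` and
#'   `exams`.
#' @export
patient_history <- function(patient, exams) {
  patient <- as.list(patient)
  if (!patient$sex %in% c("M", "F")) {
    stop("sex must be exactly one of M, F", call. = FALSE)
  }
  exams <- exam_records(as.data.frame(exams))
  if (!all(exams$patient_id == as.character(patient$patient_id))) {
    stop("all exams must share patient_id with the patient", call. = FALSE)
  }
  exams <- exams[order(exams$study_date), , drop = FALSE]
  rownames(exams) <- NULL
  structure(list(patient = patient, exams = exams),
            class = "patient_history")
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("<patient_history> %s (%s), %d exam(s)\n",
              x$patient$patient_id, x$patient$sex, nrow(x$exams)))
  invisible(x)
}

#' Resolve a patient's age in whole years
#'
#' Uses the birth date when available (age in completed years at `at_date`);
#' otherwise the upper end of the printed age range, which is the convention
#' under which the shortlisted cohort's printed age-band assignments are all
#' reproduced (age at the most recent exam).
#'
#' @param patient list/row with `birth_date` or `age_min`/`age_max`.
#' @param at_date reference `Date` (used only with `birth_date`).
#' @return integer age in years.
#' @export
patient_age <- function(patient, at_date = NULL) {
  patient <- as.list(patient)
  if (!is.null(patient$birth_date) && !is.na(patient$birth_date)) {
    if (is.null(at_date)) {
      stop("at_date required to compute age from birth_date", call. = FALSE)
    }
    return(as.integer(floor(as.numeric(at_date - as.Date(patient$birth_date)) /
                              365.25)))
  }
  if (!is.null(patient$age_max) && !is.na(patient$age_max)) {
    return(as.integer(patient$age_max))
  }
  stop("patient has neither birth_date nor an age range", call. = FALSE)
}
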