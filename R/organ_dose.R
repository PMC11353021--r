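FEMALE_ONLY_ORGANS <- c("breast", "uterus")
MALE_ONLY_ORGANS <- "prostate"

#' The 16-organ set tracked for cumulative dose
#'
#' Bladder, red bone marrow, brain, breast (female only), colon, gonads,
#' liver, lung, esophagus, salivary glands, skin, stomach, thyroid, kidneys,
#' eye lenses, and uterus/cervix (female) or prostate (male).
#'
#' @param sex `"M"` or `"F"`.
#' @return character vector of 16 organ names valid for that sex.
#' @export
organ_set <- function(sex) {
  stopifnot(sex %in% c("M", "F"))
  base <- c("bladder", "bone_marrow", "brain", "colon", "gonads", "liver",
            "lung", "esophagus", "salivary_glands", "skin", "stomach",
            "thyroid", "kidneys", "eye_lens")
  if (sex == "F") c(base, "breast", "uterus") else c(base, "prostate")
}

check_sex_compatible <- function(organs, sex = NULL) {
  has_f <- any(organs %in% FEMALE_ONLY_ORGANS)
  has_m <- any(organs %in% MALE_ONLY_ORGANS)
  if (has_f && has_m) {
    stop("sex-inconsistent organ dose vector: female-only and male-only ",
         "organs both present", call. = FALSE)
  }
  if (!is.null(sex)) {
    if (sex == "M" && has_f) stop("female-only organ in a male dose vector",
                                  call. = FALSE)
    if (sex == "F" && has_m) stop("male-only organ in a female dose vector",
                                  call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a per-protocol organ-dose coefficient table
#'
#' The packaged default is a declarative per-exam table keyed by (protocol,
#' sex): each row gives the absorbed dose (mGy) a typical exam of that
#' protocol deposits in one organ. It stands behind the organ-dose step the
#' way a Monte Carlo dosimetry engine would in a clinical workflow, and is
#' calibrated to the order of magnitude of the cohort's printed per-exam
#' organ doses. Tables in `dlp` mode instead give mGy per mGy cm, to be
#' scaled by each exam's dose-length product.
#'
#' @param path CSV with columns `protocol,sex,organ,coefficient,mode`;
#'   `NULL` for the packaged default.
#' @return data.frame of class `organ_dose_table`.
#' @export
load_organ_dose_coefficients <- function(path = NULL) {
  if (is.null(path)) path <- cedlar_extdata("organ_dose_coefficients.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protocol", "sex", "organ", "coefficient", "mode") %in%
                  names(df)),
            all(df$coefficient >= 0),
            all(df$mode %in% c("per_exam", "dlp")))
  for (p in ct_protocols()) {
    for (s in c("M", "F")) {
      if (!any(df$protocol == p & df$sex == s)) {
        stop("coefficient table lacks protocol ", p, " for sex ", s,
             call. = FALSE)
      }
    }
  }
  class(df) <- unique(c("organ_dose_table", class(df)))
  df
}

#' Load an ICRP tissue-weighting-factor set
#'
#' Both the ICRP 60 and ICRP 103 weight sets ship with the package; ICRP 103
#' is the default. Remainder organs carry their share of the remainder
#' weight; the eye lens carries weight 0 (it does not enter the effective
#' dose sum).
#'
#' @param set `"ICRP103"` (default) or `"ICRP60"`.
#' @param sex `"M"` or `"F"`: restricts to the sex-valid organ set.
#' @return named numeric vector of weights, all in \[0, 1\] and summing to
#'   at most 1 over the represented organs.
#' @export
load_tissue_weights <- function(set = c("ICRP103", "ICRP60"), sex = "F") {
  set <- match.arg(set)
  df <- utils::read.csv(cedlar_extdata("tissue_weights.csv"),
                        stringsAsFactors = FALSE)
  df <- df[df$set == set & df$organ %in% organ_set(sex), ]
  w <- stats::setNames(df$weight, df$organ)
  stopifnot(all(w >= 0), all(w <= 1), sum(w) <= 1)
  w
}

#' Per-exam organ doses from a coefficient table
#'
#' Looks up the (protocol, sex) row set of the table. In `per_exam` mode the
#' coefficients are returned verbatim as the exam's organ doses; in `dlp`
#' mode they are scaled by the exam's dose-length product. Non-CT exams get
#' an all-zero vector with a notice: radiography contributes a negligible
#' share of organ dose in this setting and is not modelled.
#'
#' @param exam one exam record (one-row data.frame or list).
#' @param table an `organ_dose_table` from [load_organ_dose_coefficients()].
#' @param sex `"M"` or `"F"`.
#' @return named numeric vector of absorbed doses (mGy), one per organ.
#' @export
estimate_organ_doses <- function(exam, table, sex) {
  exam <- as.list(exam)
  stopifnot(sex %in% c("M", "F"))
  if (exam$modality != "CT") {
    message("non-CT exam (", exam$modality,
            "): organ doses taken as zero")
    return(stats::setNames(numeric(length(organ_set(sex))), organ_set(sex)))
  }
  rows <- table[table$protocol == exam$protocol & table$sex == sex, ]
  if (nrow(rows) == 0) {
    stop("unknown protocol in coefficient table: ", exam$protocol,
         call. = FALSE)
  }
  doses <- stats::setNames(rows$coefficient, rows$organ)
  if (rows$mode[1] == "dlp") {
    dlp <- exam$dlp_mGycm
    if (is.null(dlp) || is.na(dlp)) {
      stop("DLP-mode coefficient table but exam carries no dlp_mGycm",
           call. = FALSE)
    }
    doses <- doses * dlp
  }
  check_sex_compatible(names(doses), sex)
  doses
}

#' Accumulate per-exam organ doses into a cumulative vector
#'
#' Element-wise sum over a sequence of organ-dose vectors; organs absent
#' from a vector contribute zero. The result is order-invariant. Mixing
#' female-only and male-only organs across vectors is rejected.
#'
#' @param vectors list of named numeric vectors (mGy).
#' @return named numeric vector over the union of organs.
#' @export
accumulate_organ_doses <- function(vectors) {
  if (length(vectors) == 0) return(stats::setNames(numeric(0), character(0)))
  all_organs <- unique(unlist(lapply(vectors, names)))
  check_sex_compatible(all_organs)
  out <- stats::setNames(numeric(length(all_organs)), all_organs)
  for (v in vectors) {
    stopifnot(all(v >= 0))
    out[names(v)] <- out[names(v)] + v
  }
  out
}

#' Tissue-weighted effective dose
#'
#' The effective dose E = sum over organs of w_T x H_T, in mSv for low-LET
#' radiation (radiation weighting factor 1) given absorbed organ doses in
#' mGy.
#'
#' @param organ_doses named numeric vector of organ doses (mGy).
#' @param weights named weight vector as from [load_tissue_weights()]; must
#'   cover every organ present.
#' @return effective dose in mSv.
#' @export
effective_dose <- function(organ_doses, weights) {
  missing_w <- setdiff(names(organ_doses), names(weights))
  if (length(missing_w) > 0) {
    stop("no tissue weight for organ(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  sum(organ_doses * weights[names(organ_doses)])
}
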