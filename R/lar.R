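#' Cancer sites carrying site-specific risk coefficients
#'
#' The nine sites of the risk tables: bladder, breast (female only), colon,
#' liver, lung, stomach, thyroid, uterus (female only), prostate (male
#' only).
#'
#' @param sex `"M"` or `"F"`.
#' @return character vector of site names valid for that sex.
#' @export
cancer_sites <- function(sex) {
  stopifnot(sex %in% c("M", "F"))
  shared <- c("bladder", "colon", "liver", "lung", "stomach", "thyroid")
  if (sex == "F") c(shared, "breast", "uterus") else c(shared, "prostate")
}

#' Age grid of the lifetime-risk coefficient tables
#'
#' @return integer ages at exposure (years) at which coefficients are
#'   tabulated.
#' @export
lar_age_grid <- function() c(0L, 5L, 10L, 15L, 20L, 30L, 40L, 50L, 60L, 70L, 80L)

#' Load a BEIR VII lifetime-attributable-risk coefficient table
#'
#' The packaged grids are the BEIR VII Phase 2 report's lifetime attributable
#' risk of cancer incidence (table 12D-1) and cancer mortality (table 12D-2):
#' expected cases (or deaths) per 100,000 persons exposed to a single organ
#' dose of 0.1 Gy, by sex, cancer site, and age at exposure on the grid of
#' [lar_age_grid()]. The mortality table carries no thyroid row in the
#' source; thyroid mortality coefficients are stored as zero.
#'
#' @param kind `"incidence"` or `"mortality"`.
#' @param path CSV with columns `kind,sex,site,age,coefficient`; `NULL` for
#'   the packaged transcription.
#' @return data.frame of class `lar_table` with attribute `kind`.
#' @export
load_lar_table <- function(kind = c("incidence", "mortality"), path = NULL) {
  kind <- match.arg(kind)
  if (is.null(path)) {
    path <- cedlar_extdata(if (kind == "incidence") "beir7_12d1.csv" else
      "beir7_12d2.csv")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$kind == kind, ]
  stopifnot(nrow(df) > 0, all(df$coefficient >= 0),
            all(df$age %in% lar_age_grid()))
  for (s in c("M", "F")) {
    found <- sort(unique(df$site[df$sex == s]))
    stopifnot(setequal(found, cancer_sites(s)))
  }
  attr(df, "kind") <- kind
  class(df) <- unique(c("lar_table", class(df)))
  df
}

#' Interpolate a risk coefficient at an arbitrary age at exposure
#'
#' Exact grid values at grid ages; linear interpolation between the
#' bracketing grid ages otherwise. Ages above the last grid age (80) clamp
#' to the value at 80: the tables end there and extrapolation beyond the
#' published grid is unjustified, while the cohort extends to age 81.
#'
#' @param table a `lar_table` from [load_lar_table()].
#' @param sex `"M"` or `"F"`.
#' @param site a site from [cancer_sites()].
#' @param age age at exposure in years, `>= 0`.
#' @return coefficient: cases (or deaths) per 100,000 per 0.1 Gy.
#' @export
interpolate_coefficient <- function(table, sex, site, age) {
  stopifnot(age >= 0)
  rows <- table[table$sex == sex & table$site == site, ]
  if (nrow(rows) == 0) {
    stop("no coefficient for sex ", sex, ", site ", site, call. = FALSE)
  }
  rows <- rows[order(rows$age), ]
  stats::approx(rows$age, rows$coefficient, xout = pmin(age, max(rows$age)),
                method = "linear", rule = 2)$y
}

#' Site risk from a cumulative organ dose
#'
#' Scales a per-0.1-Gy coefficient by the cumulative organ dose. Two dose
#' scaling conventions are supported, because the cohort's printed risk
#' tables are internally consistent only under a per-10-mGy reading of the
#' coefficients, one decade above the per-0.1-Gy (100 mGy) scale the source
#' tables define:
#' \describe{
#'   \item{`canonical`}{risk = coefficient x dose / 100 (coefficients per
#'     0.1 Gy, the source definition; default).}
#'   \item{`per_10mGy`}{risk = coefficient x dose / 10 (the scaling the
#'     printed risk tables imply).}
#' }
#'
#' @param dose_mGy cumulative organ dose, mGy, `>= 0`.
#' @param coefficient per-100,000-per-0.1-Gy coefficient, `>= 0`.
#' @param convention `"canonical"` or `"per_10mGy"`.
#' @return risk per 100,000 persons.
#' @export
lar_for_site <- function(dose_mGy, coefficient,
                         convention = c("canonical", "per_10mGy")) {
  convention <- match.arg(convention)
  stopifnot(dose_mGy >= 0, coefficient >= 0)
  divisor <- if (convention == "canonical") 100 else 10
  coefficient * dose_mGy / divisor
}

#' Map dosed organs to risk-table sites
#'
#' Only organs with a site-specific coefficient in scope are mapped; the
#' remaining tracked organs (e.g. red bone marrow) carry no site coefficient
#' here and contribute nothing to the site-summed risk.
#'
#' @return named character vector, organ -> site.
#' @export
organ_site_map <- function() {
  sites <- c("bladder", "breast", "colon", "liver", "lung", "stomach",
             "thyroid", "uterus", "prostate")
  stats::setNames(sites, sites)
}

#' Lifetime attributable risk profile of one patient
#'
#' Per-site incidence and mortality risks from a cumulative organ-dose
#' vector: each dosed organ with a mapped site gets
#' [interpolate_coefficient()] at the patient's age (one age per patient,
#' the age at the most recent exam) times the dose under the chosen
#' convention; sites without a dosed organ contribute zero; totals are sums
#' over sites. Risks are kept per 100,000 internally; divide by 1000 at the
#' reporting boundary for the per-100 ("%LAR") presentation.
#'
#' @param organ_doses named cumulative organ-dose vector (mGy).
#' @param sex `"M"` or `"F"`.
#' @param age age at exposure in years.
#' @param convention see [lar_for_site()].
#' @param incidence_table,mortality_table `lar_table`s; `NULL` loads the
#'   packaged grids.
#' @return list with elements `incidence` and `mortality`, each a list
#'   `kind`, `convention`, `per_site` (named vector per 100,000), `total`.
#' @export
lar_profile <- function(organ_doses, sex, age,
                        convention = c("canonical", "per_10mGy"),
                        incidence_table = NULL, mortality_table = NULL) {
  convention <- match.arg(convention)
  if (convention == "per_10mGy") {
    message("per_10mGy convention: coefficients applied per 10 mGy, ",
            "one decade above the per-0.1-Gy scale of the source tables")
  }
  check_sex_compatible(names(organ_doses), sex)
  if (is.null(incidence_table)) incidence_table <- load_lar_table("incidence")
  if (is.null(mortality_table)) mortality_table <- load_lar_table("mortality")
  map <- organ_site_map()
  sites <- cancer_sites(sex)
  one_kind <- function(table, kind) {
    per_site <- stats::setNames(numeric(length(sites)), sites)
    for (organ in names(organ_doses)) {
      site <- map[organ]
      if (is.na(site) || !site %in% sites) next
      co <- interpolate_coefficient(table, sex, site, age)
      per_site[site] <- per_site[site] +
        lar_for_site(organ_doses[[organ]], co, convention)
    }
    list(kind = kind, convention = convention, per_site = per_site,
         total = sum(per_site))
  }
  list(incidence = one_kind(incidence_table, "incidence"),
       mortality = one_kind(mortality_table, "mortality"))
}
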