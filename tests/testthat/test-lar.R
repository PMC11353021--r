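test_that("coefficient interpolation is exact at grid ages and linear between", {
  inc <- load_lar_table("incidence")
  grid <- lar_age_grid()
  for (age in grid) {
    stored <- inc$coefficient[inc$sex == "F" & inc$site == "colon" &
                                inc$age == age]
    expect_equal(interpolate_coefficient(inc, "F", "colon", age), stored)
  }
  # midway between two grid ages gives their mean
  a <- interpolate_coefficient(inc, "M", "lung", 50)
  b <- interpolate_coefficient(inc, "M", "lung", 60)
  expect_equal(interpolate_coefficient(inc, "M", "lung", 55), (a + b) / 2)
  # ages beyond the grid clamp to the last value
  expect_equal(interpolate_coefficient(inc, "M", "colon", 85),
               interpolate_coefficient(inc, "M", "colon", 80))
  expect_error(interpolate_coefficient(inc, "M", "breast", 40),
               "no coefficient")
})

test_that("interpolated coefficients stay within their bracketing grid values", {
  inc <- load_lar_table("incidence")
  mor <- load_lar_table("mortality")
  grid <- lar_age_grid()
  set.seed(5)
  for (i in 1:300) {
    tab <- if (i %% 2 == 0) inc else mor
    sex <- sample(c("M", "F"), 1)
    site <- sample(cancer_sites(sex), 1)
    age <- runif(1, 0, 95)
    co <- interpolate_coefficient(tab, sex, site, age)
    a_clamped <- min(age, max(grid))
    lo <- max(grid[grid <= a_clamped])
    hi <- min(grid[grid >= a_clamped])
    bracket <- tab$coefficient[tab$sex == sex & tab$site == site &
                                 tab$age %in% c(lo, hi)]
    expect_gte(co, min(bracket) - 1e-12)
    expect_lte(co, max(bracket) + 1e-12)
  }
})

test_that("interpolation agrees with a hand-rolled piecewise-linear oracle", {
  inc <- load_lar_table("incidence")
  set.seed(31)
  for (i in 1:40) {
    sex <- sample(c("M", "F"), 1)
    site <- sample(cancer_sites(sex), 1)
    age <- runif(1, 0, 92)
    expect_equal(interpolate_coefficient(inc, sex, site, age),
                 oracle_lar_coefficient(beir_csv("incidence"), "incidence",
                                        sex, site, age),
                 tolerance = 1e-12)
  }
})

test_that("site risk scales by the stated convention", {
  expect_equal(lar_for_site(100, 64, "canonical"), 64)
  expect_equal(lar_for_site(100, 64, "per_10mGy"), 640)
  expect_equal(lar_for_site(0, 64, "canonical"), 0)
  expect_error(lar_for_site(10, 5, "per_gray"), "arg")
})

test_that("the female-colon worked case matches the pre-computed oracle", {
  # frozen before implementation: grid values 73 (age 50) and 62 (age 60)
  # give 73 + 0.9 * (62 - 73) = 63.1 per 100,000 per 0.1 Gy at age 59;
  # at 222.48 mGy under the per-10-mGy reading: 63.1 * 22.248 = 1403.8488
  # per 100,000, i.e. 1.4038 per 100 against a printed 1.41.
  inc <- load_lar_table("incidence")
  co <- interpolate_coefficient(inc, "F", "colon", 59)
  expect_equal(co, 63.1, tolerance = 1e-12)
  risk <- lar_for_site(222.48, co, "per_10mGy")
  expect_equal(risk, 1403.8488, tolerance = 1e-9)
  expect_equal(risk / 1000, 1.41, tolerance = 0.01)
})

test_that("risk profiles are linear, site-summed, and sex-consistent", {
  inc <- load_lar_table("incidence")
  mor <- load_lar_table("mortality")
  doses <- c(colon = 40, liver = 25, lung = 60, stomach = 15, bladder = 30,
             thyroid = 5, prostate = 20, bone_marrow = 12)
  p <- lar_profile(doses, "M", 45, incidence_table = inc,
                   mortality_table = mor)
  expect_equal(p$incidence$total, sum(p$incidence$per_site),
               tolerance = 1e-9)

  # independent per-site oracle: hand-interpolated coefficient times dose
  expect_total <- 0
  for (site in c("colon", "liver", "lung", "stomach", "bladder", "thyroid",
                 "prostate")) {
    co <- oracle_lar_coefficient(beir_csv("incidence"), "incidence", "M",
                                 site, 45)
    expect_total <- expect_total + co * doses[[site]] / 100
  }
  expect_equal(p$incidence$total, expect_total, tolerance = 1e-9)

  # dosed organs without a site coefficient (bone marrow) contribute nothing
  no_marrow <- lar_profile(doses[names(doses) != "bone_marrow"], "M", 45,
                           incidence_table = inc, mortality_table = mor)
  expect_equal(p$incidence$per_site, no_marrow$incidence$per_site)

  # homogeneity of degree 1 in the dose vector
  p2 <- lar_profile(2 * doses, "M", 45, incidence_table = inc,
                    mortality_table = mor)
  expect_equal(p2$incidence$per_site, 2 * p$incidence$per_site,
               tolerance = 1e-9)
  expect_equal(p2$mortality$total, 2 * p$mortality$total, tolerance = 1e-9)

  # all-zero doses give zero risk
  z <- lar_profile(c(colon = 0, lung = 0), "F", 30, incidence_table = inc,
                   mortality_table = mor)
  expect_equal(z$incidence$total, 0)
  expect_equal(z$mortality$total, 0)

  expect_error(lar_profile(c(prostate = 10), "F", 50,
                           incidence_table = inc, mortality_table = mor),
               "male-only")
})

test_that("mortality never exceeds incidence, per cell and per profile", {
  inc <- load_lar_table("incidence")
  mor <- load_lar_table("mortality")
  merged <- merge(inc, mor, by = c("sex", "site", "age"))
  expect_true(all(merged$coefficient.y <= merged$coefficient.x))

  set.seed(13)
  for (i in 1:20) {
    sex <- sample(c("M", "F"), 1)
    organs <- intersect(names(organ_site_map()), organ_set(sex))
    doses <- stats::setNames(runif(length(organs), 0, 250), organs)
    p <- lar_profile(doses, sex, runif(1, 15, 90), incidence_table = inc,
                     mortality_table = mor)
    expect_true(all(p$mortality$per_site <= p$incidence$per_site + 1e-12))
    expect_lte(p$mortality$total, p$incidence$total + 1e-9)
  }
})
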