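ct_exam <- function(id, dates, doses) {
  exam_records(data.frame(patient_id = id, study_date = dates,
                          modality = "CT", protocol = "OTHER",
                          effective_dose_mSv = doses,
                          stringsAsFactors = FALSE))
}

test_that("CED of simple histories follows the window definition", {
  # singleton
  one <- ct_exam("s", as.Date("2021-03-01"), 12.5)
  expect_equal(compute_ced(one)$ced_mSv, 12.5)

  # two exams six years apart never share a five-year window
  far <- ct_exam("f", as.Date(c("2015-01-01", "2021-01-01")), c(60, 60))
  r <- compute_ced(far, window_years = 5)
  expect_equal(r$ced_mSv, 60)
  expect_equal(r$contributing_exam_count, 1L)

  # the same pair inside one window sums
  near <- ct_exam("n", as.Date(c("2019-01-01", "2021-01-01")), c(60, 60))
  expect_equal(compute_ced(near, window_years = 5)$ced_mSv, 120)

  # an exam exactly on the half-open start boundary is excluded
  w <- 2
  d0 <- as.Date("2020-01-01")
  boundary <- ct_exam("b", c(d0, d0 + w * 365.25), c(10, 5))
  expect_equal(compute_ced(boundary, window_years = w)$ced_mSv, 10)

  # empty (or all-nuclear) histories are an error
  nm <- exam_records(data.frame(patient_id = "x",
                                study_date = as.Date("2021-01-01"),
                                modality = "NUCLEAR", protocol = "NM",
                                effective_dose_mSv = 3))
  expect_error(compute_ced(nm), "non-nuclear")
})

test_that("windowed CED equals the exhaustive brute force on random histories", {
  set.seed(101)
  for (rep in 1:60) {
    h <- random_history(sample(1:50, 1), patient_id = "bf")
    keep <- h[h$modality != "NUCLEAR", , drop = FALSE]
    if (nrow(keep) == 0) next
    got <- compute_ced(h, window_years = 5)
    want <- brute_force_ced(keep$study_date, keep$effective_dose_mSv,
                            5 * 365.25)
    expect_equal(got$ced_mSv, want$ced, tolerance = 1e-12)
    expect_equal(as.numeric(got$window_end), want$anchor)
  }
})

test_that("CED is additive across co-windowed histories", {
  set.seed(7)
  dates <- as.Date("2021-01-01") + sample.int(300, 12, replace = TRUE)
  a <- ct_exam("p", dates, runif(12, 1, 20))
  b <- ct_exam("p", dates, runif(12, 1, 20))
  combined <- exam_records(rbind(as.data.frame(a), as.data.frame(b)))
  expect_equal(compute_ced(combined)$ced_mSv,
               compute_ced(a)$ced_mSv + compute_ced(b)$ced_mSv,
               tolerance = 1e-12)
})

test_that("shortlisting filters, sorts, and respects thresholds", {
  histories <- expand_all_fixture_histories()
  sl <- shortlist_patients(histories, threshold_mSv = 100)
  expect_equal(nrow(sl), 22)
  expect_true(all(diff(sl$ced_mSv) <= 0))

  sl150 <- shortlist_patients(histories, threshold_mSv = 150)
  expect_equal(nrow(sl150), 7)
  expect_setequal(sl150$patient_id, as.character(1:7))

  expect_equal(nrow(shortlist_patients(histories, threshold_mSv = 0)), 22)
  expect_equal(nrow(shortlist_patients(list(), threshold_mSv = 100)), 0)

  # monotonicity: raising the threshold never enlarges the shortlist
  thresholds <- c(0, 50, 100, 120, 150, 200, 250)
  sizes <- vapply(thresholds, function(t)
    nrow(shortlist_patients(histories, threshold_mSv = t)), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("data.frame and history-list shortlisting agree", {
  histories <- expand_all_fixture_histories()
  records <- do.call(rbind, lapply(histories, function(h)
    as.data.frame(h$exams)))
  sl_df <- shortlist_patients(records, threshold_mSv = 100)
  sl_h <- shortlist_patients(histories, threshold_mSv = 100)
  expect_equal(sl_df$patient_id, sl_h$patient_id)
  expect_equal(sl_df$ced_mSv, sl_h$ced_mSv)
})

test_that("average study interval is the mean successive gap", {
  d0 <- as.Date("2021-01-01")
  expect_equal(average_study_interval(
    ct_exam("i", d0 + c(0, 2, 4), c(1, 1, 1))), 2.0)
  expect_equal(average_study_interval(
    ct_exam("i", d0 + c(0, 1, 5), c(1, 1, 1))), 2.5)
  expect_error(average_study_interval(ct_exam("i", d0, 1)), "fewer than 2")

  # a fixture history built at the printed spacing returns it
  fx <- load_study_fixture()
  h7 <- expand_fixture_history(fx[fx$id == 7, ])
  expect_equal(average_study_interval(h7), 1.2, tolerance = 1e-9)
  expect_equal(nrow(h7$exams), 33)
})

test_that("the per-study recurrence definition counts repeat CTs", {
  d0 <- as.Date("2021-02-01")
  three <- ct_exam("r", d0 + c(0, 30, 60), c(5, 5, 5))
  r <- recurrent_ct_rate(three, "2021-01-01", "2021-12-31")
  expect_equal(r$recurrent_count, 2L)
  expect_equal(r$total_ct_count, 3L)
  expect_equal(r$rate, 2 / 3)

  distinct <- exam_records(data.frame(
    patient_id = c("a", "b", "c"), study_date = d0 + c(0, 1, 2),
    modality = "CT", protocol = "KUB", effective_dose_mSv = 5,
    stringsAsFactors = FALSE))
  expect_equal(recurrent_ct_rate(distinct, "2021-01-01",
                                 "2021-12-31")$recurrent_count, 0L)

  # studies outside the period are invisible to the rate
  r2 <- recurrent_ct_rate(three, "2021-03-01", "2021-12-31")
  expect_equal(r2$total_ct_count, 2L)
  expect_equal(r2$recurrent_count, 1L)

  xray_only <- exam_records(data.frame(
    patient_id = "a", study_date = d0, modality = "RADIOGRAPH",
    protocol = "XRAY_GENERAL", effective_dose_mSv = 0.05))
  expect_error(recurrent_ct_rate(xray_only, "2021-01-01", "2021-12-31"),
               "undefined")
})

test_that("age-band assignment matches the cohort scheme", {
  expect_equal(assign_age_group(70), "61-70")
  expect_equal(assign_age_group(71), "71-80")
  expect_equal(assign_age_group(15), "15-20")
  expect_equal(assign_age_group(90), "81-90")
  expect_error(assign_age_group(14), "outside")
  expect_error(assign_age_group(91), "outside")

  # every integer age in [15, 90] belongs to exactly one band
  scheme <- age_group_scheme()
  for (a in 15:90) {
    hits <- sum(a >= scheme$lo & a <= scheme$hi)
    expect_equal(hits, 1L)
  }

  # printed-range patients band at the top of their range
  fx <- load_study_fixture()
  expect_equal(assign_age_group(patient_age(fx[fx$id == 13, ])), "81-90")
  expect_equal(assign_age_group(patient_age(fx[fx$id == 5, ])), "61-70")
})
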