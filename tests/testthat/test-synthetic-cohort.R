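test_that("config validation names the offending field", {
  expect_error(cohort_config(n_patients = -1), "n_patients",
               class = "pkdresp_validation_error")
  expect_error(cohort_config(responder_fraction = 1.2), "responder_fraction",
               class = "pkdresp_validation_error")
  expect_error(cohort_config(pre_scan_window = 0.5), "pre_scan_window",
               class = "pkdresp_validation_error")
  expect_error(cohort_config(sequence_cv = -0.1), "sequence_cv",
               class = "pkdresp_validation_error")
  expect_error(cohort_config(pre_growth_mean = c(responder = 7.1)),
               "pre_growth_mean", class = "pkdresp_validation_error")
})

test_that("config round-trips through YAML and JSON files", {
  cfg <- cohort_config(n_patients = 5, seed = 9,
                       uosm_median = c(responder = 400, `non-responder` = 200))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_patients = 5, seed = 9,
                        uosm_median = list(responder = 400,
                                           `non-responder` = 200)), yml)
  cfg2 <- read_cohort_config(yml)
  expect_equal(cfg2$n_patients, cfg$n_patients)
  expect_equal(cfg2$uosm_median, cfg$uosm_median)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(not_a_field = 1), bad)
  expect_error(read_cohort_config(bad), "not_a_field",
               class = "pkdresp_validation_error")
})

test_that("empty cohort and exact group allocation", {
  empty <- simulate_cohort(cohort_config(n_patients = 0, seed = 1))
  expect_equal(nrow(empty$patients), 0)
  expect_equal(nrow(empty$scans), 0)
  expect_equal(nrow(empty$labs), 0)

  co <- simulate_cohort(cohort_config(n_patients = 32,
                                      responder_fraction = 18 / 32, seed = 1))
  expect_equal(sum(co$patients$true_group == "responder"), 18)
  expect_equal(sum(co$patients$true_group == "non-responder"), 14)
})

test_that("same seed gives byte-identical cohort tables", {
  cfg <- cohort_config(n_patients = 10, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$scans, b$scans)
  expect_identical(a$labs, b$labs)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in c("patients.csv", "scans.csv", "labs.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generated quantities match the configured distributions", {
  co <- simulate_cohort(cohort_config(n_patients = 2000, seed = 11))
  resp <- dplyr::filter(co$patients, true_group == "responder")
  nonresp <- dplyr::filter(co$patients, true_group == "non-responder")
  # law of large numbers against the generative truth
  expect_lt(abs(mean(resp$true_pre_rate) - 7.1), 0.2)
  expect_lt(abs(mean(nonresp$true_pre_rate) - 3.7), 0.2)
  # responder-group delta mean within 3 SE of the configured -5.1
  se <- sd(resp$true_delta) / sqrt(nrow(resp))
  expect_lt(abs(mean(resp$true_delta) - (-5.1)) / se, 3)
  # group deltas equal during - pre exactly, by construction
  expect_equal(co$patients$true_during_rate - co$patients$true_pre_rate,
               co$patients$true_delta)
  # physiologic truncation
  expect_true(all(co$patients$treatment_start_age >= 18 &
                    co$patients$treatment_start_age <= 70))
  expect_true(all(co$patients$height_m >= 1.4 & co$patients$height_m <= 2.1))
})

test_that("scan schedule satisfies the eligibility geometry", {
  cfg <- cohort_config(seed = 1)
  set.seed(5)
  for (i in 1:50) {
    sched <- simulate_scan_schedule(cfg, treatment_start_age = 45)
    pre <- sched$age_years[sched$window == "pre"]
    during <- sched$age_years[sched$window == "during"]
    expect_gte(length(pre), 2)
    expect_gte(length(during), 2)
    expect_true(all(pre < 45))
    expect_true(all(during > 45))
    expect_gte(max(pre) - min(pre), 1)
    expect_gte(max(during) - min(during), 1)
  }
  # forced scan count
  cfg2 <- cohort_config(scans_per_window_range = c(2L, 2L))
  sched <- simulate_scan_schedule(cfg2, 45)
  expect_equal(as.vector(table(sched$window)[c("pre", "during")]), c(2L, 2L))
  # determinism under an external seed
  s1 <- withr::with_seed(4, simulate_scan_schedule(cfg, 45))
  s2 <- withr::with_seed(4, simulate_scan_schedule(cfg, 45))
  expect_identical(s1, s2)
})

test_that("eGFR series follows the monitoring schedule and group slope", {
  cfg <- cohort_config(egfr_resid_sd = 0)
  ser <- simulate_egfr_series(cfg, "non-responder", egfr_baseline = 67)
  expect_equal(nrow(ser), 28) # 18 monthly + 10 quarterly visits
  expect_equal(ser$months_since_start, c(1:18, seq(21, 48, 3)))
  # noiseless line: delta at month 48 is slope * 4 years
  expect_equal(ser$delta_egfr[ser$months_since_start == 48], -0.40 * 4)
  expect_true(all(ser$egfr > 0))
})

test_that("noiseless measurements sit exactly on the true trajectory", {
  co <- simulate_cohort(cohort_config(n_patients = 20, sequence_cv = 0,
                                      seed = 21))
  joined <- dplyr::left_join(co$scans, co$patients, by = "patient_id")
  expected <- joined$tkv_at_start *
    exp(log1p(ifelse(joined$age_years <= joined$treatment_start_age,
                     joined$true_pre_rate, joined$true_during_rate) / 100) *
          (joined$age_years - joined$treatment_start_age))
  expect_equal(joined$tkv_ml, expected, tolerance = 1e-12)
})
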