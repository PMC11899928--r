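test_that("per-scan TKV is the mean over sequences covering both kidneys", {
  one <- tibble::tibble(patient_id = "P1", age_years = 40,
                        tkv_ml = 1500, covers_both_kidneys = TRUE)
  expect_equal(mean_tkv_per_scan(one)$mean_tkv, 1500)

  two <- tibble::tibble(patient_id = "P1", age_years = 40,
                        tkv_ml = c(1000, 1020), covers_both_kidneys = TRUE)
  expect_equal(mean_tkv_per_scan(two)$mean_tkv, 1010)
  expect_equal(mean_tkv_per_scan(two)$n_sequences, 2L)

  partial <- tibble::tibble(patient_id = "P1", age_years = 40,
                            tkv_ml = c(1000, 5000),
                            covers_both_kidneys = c(TRUE, FALSE))
  expect_equal(mean_tkv_per_scan(partial)$mean_tkv, 1000)

  none <- tibble::tibble(patient_id = "P1", age_years = 40,
                         tkv_ml = 1000, covers_both_kidneys = FALSE)
  expect_error(mean_tkv_per_scan(none), class = "pkdresp_missing_data")
})

test_that("log-linear fit annualises the exponential growth rate", {
  flat <- exact_exponential_points(c(40, 41), 1000, 0)
  expect_equal(fit_exponential_growth(flat)$annual_rate, 0)

  ten <- tibble::tibble(age_years = c(40, 41), mean_tkv = c(1000, 1100))
  expect_equal(fit_exponential_growth(ten)$annual_rate, 10)

  five <- exact_exponential_points(c(40, 41, 42), 1000, 5)
  fit <- fit_exponential_growth(five)
  expect_equal(fit$annual_rate, 5, tolerance = 1e-12)
  expect_equal(fit$tkv_at_ref_age, 1000, tolerance = 1e-9)
  expect_equal(fit$n_points, 3L)
  expect_lt(fit$log_residual_rms, 1e-12)

  expect_error(fit_exponential_growth(five[1, ]),
               class = "pkdresp_insufficient_data")
  same_age <- tibble::tibble(age_years = c(40, 40), mean_tkv = c(1000, 1100))
  expect_error(fit_exponential_growth(same_age),
               class = "pkdresp_insufficient_data")
})

test_that("growth rate is invariant to TKV scaling and age shifts", {
  set.seed(301)
  for (i in 1:20) {
    ages <- sort(runif(4, 35, 45))
    pts <- tibble::tibble(age_years = ages,
                          mean_tkv = exp(rnorm(4, log(1500), 0.1)))
    base <- fit_exponential_growth(pts)$annual_rate
    scaled <- fit_exponential_growth(dplyr::mutate(pts, mean_tkv = mean_tkv * 3.7))
    shifted <- fit_exponential_growth(dplyr::mutate(pts, age_years = age_years + 11.3))
    expect_equal(scaled$annual_rate, base, tolerance = 1e-9)
    expect_equal(shifted$annual_rate, base, tolerance = 1e-9)
  }
})

test_that("noiseless exponential data are recovered regardless of spacing", {
  set.seed(302)
  for (i in 1:50) {
    rate <- runif(1, -8, 12)
    ages <- sort(40 + cumsum(runif(sample(2:6, 1), 0.1, 3)))
    pts <- exact_exponential_points(ages, runif(1, 500, 4000), rate)
    expect_lt(abs(fit_exponential_growth(pts)$annual_rate - rate), 1e-9)
  }
})

test_that("pre/during split fits each window independently", {
  scans <- piecewise_scan_table("P1", pre_ages = c(38, 39, 39.9),
                                during_ages = c(41, 42.5),
                                start_age = 40, v0 = 1500,
                                pre_rate = 3.4, during_rate = -5.6)
  pts <- mean_tkv_per_scan(scans)
  fits <- split_pre_during(pts, 40)
  expect_equal(fits$annual_rate[fits$window == "pre"], 3.4, tolerance = 1e-9)
  expect_equal(fits$annual_rate[fits$window == "during"], -5.6, tolerance = 1e-9)

  # all scans before start: no during window
  expect_error(split_pre_during(pts[pts$age_years < 40, ], 40),
               "during", class = "pkdresp_eligibility_error")

  # a scan exactly at treatment start belongs to the pre window
  boundary <- tibble::tibble(age_years = c(38, 40, 41, 42),
                             mean_tkv = c(1000, 1100, 1200, 1300))
  fits_b <- split_pre_during(boundary, 40)
  expect_equal(fits_b$n_points[fits_b$window == "pre"], 2L)
  expect_equal(fits_b$n_points[fits_b$window == "during"], 2L)
})

test_that("cohort-level fitting recovers simulated truth without noise", {
  co <- simulate_cohort(cohort_config(n_patients = 25, sequence_cv = 0,
                                      seed = 8))
  fits <- fit_growth_rates(co$scans, co$patients)
  wide <- tidyr::pivot_wider(
    dplyr::select(fits, patient_id, window, annual_rate),
    names_from = window, values_from = annual_rate
  ) %>%
    dplyr::left_join(co$patients, by = "patient_id")
  expect_equal(nrow(wide), 25)
  expect_lt(max(abs(wide$pre - wide$true_pre_rate)), 1e-9)
  expect_lt(max(abs(wide$during - wide$true_during_rate)), 1e-9)
})

test_that("estimation error is small under realistic measurement noise", {
  # 1.3% CV, 3 scans over 2 years: |error| < 2 %/yr in >= 95% of runs
  set.seed(303)
  n_sim <- 1000
  err <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    rate <- runif(1, -5, 10)
    pts <- exact_exponential_points(c(40, 41, 42), 1500, rate)
    noisy <- dplyr::mutate(pts, mean_tkv = mean_tkv *
                             exp(rnorm(3, 0, sqrt(log(1 + 0.013^2)))))
    err[i] <- fit_exponential_growth(noisy)$annual_rate - rate
  }
  expect_gte(mean(abs(err) < 2), 0.95)
})

test_that("eligibility filters flag each violated criterion", {
  roster <- eligibility_roster()
  dec <- apply_eligibility_filters(roster$scans, roster$patients)
  expect_equal(sum(dec$eligible), 1L)
  expect_true(dec$eligible[dec$patient_id == "OK"])
  get_reasons <- function(id) dec$reasons[[which(dec$patient_id == id)]]
  expect_equal(get_reasons("SPAN"), "PRE_SPAN_LT_1Y")
  expect_equal(get_reasons("ONEPRE"), "PRE_SCANS_LT_2")
  expect_equal(get_reasons("DURSPAN"), "DURING_SPAN_LT_1Y")
  expect_equal(get_reasons("INTR"), "TREATMENT_INTERRUPTION")
  expect_equal(get_reasons("CYST"), "CYST_EVENT")
  # eligible <=> reasons empty
  expect_equal(dec$eligible, lengths(dec$reasons) == 0)
})
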