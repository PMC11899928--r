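#' Simulate a synthetic tolvaptan-treated ADPKD cohort
#'
#' Draws a cohort whose statistical structure matches the configured
#' distributions: each patient carries a true piecewise-exponential TKV
#' trajectory (one compound annual growth rate before treatment start, one
#' during), serial MRI scans whose per-sequence TKV measurements are the
#' trajectory value times multiplicative lognormal noise (mean 1, CV
#' `sequence_cv`), a baseline spot urine osmolality, and an eGFR series on
#' the monthly-then-quarterly monitoring schedule.
#'
#' Group sizes use exact allocation (`round(n_patients *
#' responder_fraction)` responders) so small cohorts have deterministic
#' composition. With a non-`NULL` `seed` the output is byte-identical
#' across calls and does not disturb the caller's RNG state.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `"pkd_cohort"`: a list of three tibbles,
#'   `patients` (one row per patient: demographics, treatment-start age,
#'   baseline TKV/Uosm/eGFR, true group and true growth rates, eligibility
#'   flags), `scans` (one row per pulse sequence: `patient_id`,
#'   `age_years`, `window`, `sequence_id`, `tkv_ml`,
#'   `covers_both_kidneys`), and `labs` (one row per lab visit:
#'   `months_since_start`, `creatinine_mg_dl`, `egfr`, `delta_egfr`,
#'   `uosm_baseline`). The config is attached as attribute `"config"`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 6, seed = 42))
#' cohort$patients
#' @export
simulate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  if (is.null(config$seed)) {
    .simulate_cohort_impl(config)
  } else {
    withr::with_seed(config$seed, .simulate_cohort_impl(config))
  }
}

.simulate_cohort_impl <- function(cfg) {
  n <- as.integer(cfg$n_patients)
  if (n == 0L) {
    out <- list(patients = empty_patients(), scans = empty_scans(),
                labs = empty_labs())
    return(structure(out, class = c("pkd_cohort", "list"), config = cfg))
  }

  n_resp <- as.integer(round(n * cfg$responder_fraction))
  group <- rep(.groups, c(n_resp, n - n_resp))

  patients <- tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    true_group = group,
    sex = ifelse(runif(n) < cfg$male_fraction, "male", "female"),
    height_m = rnorm_trunc(n, cfg$height_mean, cfg$height_sd,
                           cfg$height_range[1], cfg$height_range[2]),
    treatment_start_age = rnorm_trunc(n, cfg$age_mean, cfg$age_sd,
                                      cfg$age_range[1], cfg$age_range[2]),
    tkv_at_start = exp(rnorm(n, log(cfg$baseline_tkv_median),
                             cfg$baseline_tkv_log_sd)),
    true_pre_rate = rnorm(n, cfg$pre_growth_mean[group],
                          cfg$pre_growth_sd[group]),
    true_delta = rnorm(n, cfg$delta_growth_mean[group],
                       cfg$delta_growth_sd[group]),
    uosm_baseline = exp(rnorm(n, log(cfg$uosm_median[group]),
                              cfg$uosm_log_sd[group])),
    egfr_baseline = rnorm_trunc(n, cfg$egfr_baseline_mean,
                                cfg$egfr_baseline_sd,
                                cfg$egfr_range[1], cfg$egfr_range[2]),
    interruption_gt_1mo = FALSE,
    non_adherent = FALSE,
    cyst_event = FALSE
  ) %>%
    mutate(true_during_rate = .data$true_pre_rate + .data$true_delta)

  scans <- purrr::pmap(
    list(patients$patient_id, patients$treatment_start_age,
         patients$tkv_at_start, patients$true_pre_rate,
         patients$true_during_rate),
    function(pid, start, v0, pre, during) {
      sched <- simulate_scan_schedule(cfg, start)
      k <- nrow(sched)
      nseq <- resample(seq(cfg$n_sequences_range[1], cfg$n_sequences_range[2]),
                       k, replace = TRUE)
      rate <- ifelse(sched$age_years <= start, pre, during)
      true_tkv <- v0 * exp(log1p(rate / 100) * (sched$age_years - start))
      idx <- rep(seq_len(k), nseq)
      tibble(
        patient_id = pid,
        age_years = sched$age_years[idx],
        window = sched$window[idx],
        sequence_id = unlist(lapply(nseq, function(m) sprintf("S%d", seq_len(m)))),
        tkv_ml = true_tkv[idx] * lognormal_noise(length(idx), cfg$sequence_cv),
        covers_both_kidneys = TRUE
      )
    }
  ) %>% bind_rows()

  labs <- purrr::pmap(
    list(patients$patient_id, patients$true_group, patients$egfr_baseline,
         patients$treatment_start_age, patients$sex, patients$uosm_baseline),
    function(pid, grp, base, start, sex, uosm) {
      series <- simulate_egfr_series(cfg, grp, base)
      months <- c(0, series$months_since_start)
      egfr <- c(base, series$egfr)
      tibble(
        patient_id = pid,
        months_since_start = months,
        creatinine_mg_dl = inverse_ckd_epi_2021(egfr, start + months / 12, sex),
        egfr = egfr,
        delta_egfr = egfr - base,
        uosm_baseline = uosm
      )
    }
  ) %>% bind_rows()

  structure(list(patients = patients, scans = scans, labs = labs),
            class = c("pkd_cohort", "list"), config = cfg)
}

# mean-1 multiplicative lognormal noise with the requested CV; CV 0 -> exactly 1
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

empty_patients <- function() {
  tibble(patient_id = character(), true_group = character(), sex = character(),
         height_m = double(), treatment_start_age = double(),
         tkv_at_start = double(), true_pre_rate = double(),
         true_delta = double(), uosm_baseline = double(),
         egfr_baseline = double(), interruption_gt_1mo = logical(),
         non_adherent = logical(), cyst_event = logical(),
         true_during_rate = double())
}
empty_scans <- function() {
  tibble(patient_id = character(), age_years = double(), window = character(),
         sequence_id = character(), tkv_ml = double(),
         covers_both_kidneys = logical())
}
empty_labs <- function() {
  tibble(patient_id = character(), months_since_start = double(),
         creatinine_mg_dl = double(), egfr = double(), delta_egfr = double(),
         uosm_baseline = double())
}

#' Simulate an MRI scan schedule around a treatment start
#'
#' Places scans in a pre-treatment and an on-treatment window, satisfying the
#' eligibility minimum of >= 2 scans spanning >= 1 year on each side: the
#' first and last scan of each window are placed to enforce the span, interior
#' scans fall uniformly in between, and all pre-treatment scans are strictly
#' before `treatment_start_age`.
#'
#' @inheritParams simulate_cohort
#' @param treatment_start_age Age (years) at tolvaptan initiation.
#' @return A tibble with columns `window` (`"pre"`/`"during"`) and
#'   `age_years`, sorted by age.
#' @export
simulate_scan_schedule <- function(config, treatment_start_age) {
  cfg <- validate_cohort_config(config)
  one_window <- function(window_max) {
    k <- resample(seq(cfg$scans_per_window_range[1],
                      cfg$scans_per_window_range[2]), 1)
    span <- runif(1, 1, window_max)
    edge_gap <- runif(1, 0.02, 0.25)
    first <- edge_gap
    last <- edge_gap + span
    sort(c(first, last, if (k > 2) runif(k - 2, first, last)))
  }
  pre_offsets <- one_window(cfg$pre_scan_window)      # years before start
  during_offsets <- one_window(cfg$during_scan_window) # years after start
  tibble(
    window = rep(c("pre", "during"), c(length(pre_offsets), length(during_offsets))),
    age_years = c(treatment_start_age - rev(pre_offsets),
                  treatment_start_age + during_offsets)
  )
}

#' Simulate an eGFR monitoring series for one patient
#'
#' eGFR is generated directly on the eGFR scale: the change from baseline at
#' month `t` is `slope * t / 12` plus Gaussian residual noise, with the
#' group-specific annual slope from the configuration. Points follow the
#' routine tolvaptan monitoring schedule (monthly to month 18, quarterly to
#' month 48; 28 timepoints). eGFR is floored at 1 mL/min/1.73m2 and
#' `delta_egfr` recomputed so the baseline-difference invariant holds.
#'
#' @inheritParams simulate_scan_schedule
#' @param group `"responder"` or `"non-responder"`.
#' @param egfr_baseline eGFR at treatment start (mL/min/1.73m2).
#' @return A tibble with `months_since_start`, `egfr`, `delta_egfr`.
#' @export
simulate_egfr_series <- function(config, group, egfr_baseline) {
  cfg <- validate_cohort_config(config)
  group <- match.arg(group, .groups)
  months <- cfg$egfr_months
  drift <- cfg$egfr_slope[[group]] * months / 12
  egfr <- pmax(egfr_baseline + drift + rnorm(length(months), 0, cfg$egfr_resid_sd), 1)
  tibble(months_since_start = months, egfr = egfr,
         delta_egfr = egfr - egfr_baseline)
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes `patients.csv`, `scans.csv`, `labs.csv` and `truth.json` (the
#' generative configuration) into `dir`.
#'
#' @param cohort A `"pkd_cohort"` object from [simulate_cohort()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pkd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             scans = file.path(dir, "scans.csv"),
             labs = file.path(dir, "labs.csv"),
             truth = file.path(dir, "truth.json"))
  readr::write_csv(cohort$patients, paths[["patients"]])
  readr::write_csv(cohort$scans, paths[["scans"]])
  readr::write_csv(cohort$labs, paths[["labs"]])
  jsonlite::write_json(unclass(attr(cohort, "config")), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#'
#' @param dir Directory containing `patients.csv`, `scans.csv`, `labs.csv`.
#' @return A `"pkd_cohort"` list of tibbles.
#' @export
read_cohort <- function(dir) {
  out <- list(
    patients = readr::read_csv(file.path(dir, "patients.csv"),
                               show_col_types = FALSE),
    scans = readr::read_csv(file.path(dir, "scans.csv"),
                            show_col_types = FALSE),
    labs = readr::read_csv(file.path(dir, "labs.csv"), show_col_types = FALSE)
  )
  structure(out, class = c("pkd_cohort", "list"))
}

#' @export
print.pkd_cohort <- function(x, ...) {
  cat(sprintf("<pkd_cohort> %d patients, %d scan measurements, %d lab visits\n",
              nrow(x$patients), nrow(x$scans), nrow(x$labs)))
  if (nrow(x$patients)) {
    tab <- table(x$patients$true_group)
    cat("  groups:", paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
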