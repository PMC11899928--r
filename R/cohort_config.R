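#' Configuration for the synthetic ADPKD cohort generator
#'
#' Bundles every distributional parameter of the synthetic tolvaptan cohort.
#' Defaults emulate a published single-centre tolvaptan cohort of 32 ADPKD
#' patients: exponential kidney growth with per-sequence multiplicative
#' measurement noise (1.3% coefficient of variation), group-specific
#' pre-treatment growth rates (responders 7.1 +/- 3.6 %/yr, non-responders
#' 3.7 +/- 2.4 %/yr), group-specific treatment effects on the growth rate
#' (responders -5.1 +/- 2.5, non-responders +2.4 +/- 2.7 percentage points
#' per year), right-skewed baseline TKV (median 1622 mL, IQR 1067--2715),
#' group-specific lognormal spot urine osmolality (medians 393 vs 194
#' mOsm/kg), and eGFR trajectories declining at -0.25 (responders) vs -0.40
#' (non-responders) mL/min/1.73m2 per year around a baseline of 67 +/- 27.
#'
#' Lognormal log-scale SDs default to `log(q3/q1) / (2 * qnorm(0.75))`, the
#' value matching the quoted interquartile ranges.
#'
#' @param n_patients Number of patients to simulate.
#' @param responder_fraction Fraction of patients labelled responder; group
#'   sizes use exact allocation, `round(n_patients * responder_fraction)`.
#' @param age_mean,age_sd Age at treatment start (years), truncated normal.
#' @param age_range Truncation bounds for age (years).
#' @param male_fraction Probability a simulated patient is male.
#' @param height_mean,height_sd Height (m), truncated normal.
#' @param height_range Truncation bounds for height (m).
#' @param baseline_tkv_median Median TKV at treatment start (mL); lognormal.
#' @param baseline_tkv_log_sd Log-scale SD of baseline TKV.
#' @param pre_growth_mean,pre_growth_sd Named numeric (responder,
#'   non-responder): pre-treatment annual TKV growth rate, % per year.
#' @param delta_growth_mean,delta_growth_sd Named numeric: change in annual
#'   growth rate during treatment, percentage points per year.
#' @param sequence_cv Coefficient of variation of per-sequence TKV
#'   measurement noise (multiplicative lognormal, mean 1).
#' @param n_sequences_range Integer range of usable pulse sequences per scan.
#' @param pre_scan_window,during_scan_window Maximal span (years) over which
#'   pre-/during-treatment scans are placed; must be >= 1 so the >= 1 year
#'   eligibility span is attainable.
#' @param scans_per_window_range Integer range of scans per window.
#' @param uosm_median,uosm_log_sd Named numeric: baseline spot urine
#'   osmolality (mOsm/kg), lognormal per group.
#' @param egfr_baseline_mean,egfr_baseline_sd Baseline eGFR
#'   (mL/min/1.73m2), truncated normal.
#' @param egfr_range Truncation bounds for baseline eGFR.
#' @param egfr_slope Named numeric: annual eGFR decline per group
#'   (mL/min/1.73m2 per year).
#' @param egfr_resid_sd Residual SD of eGFR points around the group line.
#' @param egfr_months Creatinine/eGFR sampling schedule in months since
#'   treatment start: monthly to month 18, then quarterly to month 48.
#' @param seed Integer seed that fully determines the simulated cohort, or
#'   `NULL` to use the ambient RNG state.
#'
#' @return A validated list of class `"cohort_config"`.
#' @seealso [simulate_cohort()]
#' @examples
#' cfg <- cohort_config(n_patients = 8, seed = 1)
#' cfg$responder_fraction
#' @export
cohort_config <- function(n_patients = 32,
                          responder_fraction = 18 / 32,
                          age_mean = 42,
                          age_sd = 9,
                          age_range = c(18, 70),
                          male_fraction = 17 / 32,
                          height_mean = 1.70,
                          height_sd = 0.10,
                          height_range = c(1.4, 2.1),
                          baseline_tkv_median = 1622,
                          baseline_tkv_log_sd = log(2715 / 1067) / (2 * qnorm(0.75)),
                          pre_growth_mean = c(responder = 7.1, `non-responder` = 3.7),
                          pre_growth_sd = c(responder = 3.6, `non-responder` = 2.4),
                          delta_growth_mean = c(responder = -5.1, `non-responder` = 2.4),
                          delta_growth_sd = c(responder = 2.5, `non-responder` = 2.7),
                          sequence_cv = 0.013,
                          n_sequences_range = c(2L, 5L),
                          pre_scan_window = 3,
                          during_scan_window = 3,
                          scans_per_window_range = c(2L, 4L),
                          uosm_median = c(responder = 393, `non-responder` = 194),
                          uosm_log_sd = c(responder = log(519 / 256) / (2 * qnorm(0.75)),
                                          `non-responder` = log(239 / 167) / (2 * qnorm(0.75))),
                          egfr_baseline_mean = 67,
                          egfr_baseline_sd = 27,
                          egfr_range = c(15, 140),
                          egfr_slope = c(responder = -0.25, `non-responder` = -0.40),
                          egfr_resid_sd = 1.2,
                          egfr_months = c(1:18, seq(21, 48, by = 3)),
                          seed = NULL) {
  cfg <- list(
    n_patients = n_patients,
    responder_fraction = responder_fraction,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    male_fraction = male_fraction,
    height_mean = height_mean, height_sd = height_sd, height_range = height_range,
    baseline_tkv_median = baseline_tkv_median,
    baseline_tkv_log_sd = baseline_tkv_log_sd,
    pre_growth_mean = pre_growth_mean, pre_growth_sd = pre_growth_sd,
    delta_growth_mean = delta_growth_mean, delta_growth_sd = delta_growth_sd,
    sequence_cv = sequence_cv,
    n_sequences_range = as.integer(n_sequences_range),
    pre_scan_window = pre_scan_window,
    during_scan_window = during_scan_window,
    scans_per_window_range = as.integer(scans_per_window_range),
    uosm_median = uosm_median, uosm_log_sd = uosm_log_sd,
    egfr_baseline_mean = egfr_baseline_mean, egfr_baseline_sd = egfr_baseline_sd,
    egfr_range = egfr_range,
    egfr_slope = egfr_slope, egfr_resid_sd = egfr_resid_sd,
    egfr_months = egfr_months,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

.groups <- c("responder", "non-responder")

# internal: a per-group parameter must name both groups
check_group_param <- function(x, field) {
  check_that(is.numeric(x) && all(.groups %in% names(x)), field,
             "must be a numeric vector named 'responder' and 'non-responder'")
  x[.groups]
}

#' Validate a cohort configuration
#'
#' @param cfg A `"cohort_config"` object (see [cohort_config()]).
#' @return The validated config, invisibly usable in pipelines.
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  check_that(length(cfg$n_patients) == 1 && cfg$n_patients >= 0 &&
               cfg$n_patients == trunc(cfg$n_patients),
             "n_patients", "must be a single non-negative integer")
  for (f in c("responder_fraction", "male_fraction")) {
    check_that(length(cfg[[f]]) == 1 && cfg[[f]] >= 0 && cfg[[f]] <= 1,
               f, "must be a proportion in [0, 1]")
  }
  for (f in c("age_sd", "height_sd", "baseline_tkv_log_sd",
              "egfr_baseline_sd", "egfr_resid_sd")) {
    check_that(length(cfg[[f]]) == 1 && cfg[[f]] >= 0, f, "must be >= 0")
  }
  check_that(cfg$sequence_cv >= 0, "sequence_cv", "must be >= 0")
  check_that(cfg$baseline_tkv_median > 0, "baseline_tkv_median", "must be > 0")
  check_that(cfg$pre_scan_window >= 1, "pre_scan_window",
             "must be >= 1 year so eligible pre-treatment spans exist")
  check_that(cfg$during_scan_window >= 1, "during_scan_window",
             "must be >= 1 year so eligible on-treatment spans exist")
  for (f in c("n_sequences_range", "scans_per_window_range")) {
    check_that(length(cfg[[f]]) == 2 && cfg[[f]][1] >= 1 &&
                 cfg[[f]][1] <= cfg[[f]][2],
               f, "must be an ordered integer range with minimum >= 1")
  }
  check_that(cfg$scans_per_window_range[1] >= 2, "scans_per_window_range",
             "must allow at least 2 scans per window")
  cfg$pre_growth_mean <- check_group_param(cfg$pre_growth_mean, "pre_growth_mean")
  cfg$pre_growth_sd <- check_group_param(cfg$pre_growth_sd, "pre_growth_sd")
  cfg$delta_growth_mean <- check_group_param(cfg$delta_growth_mean, "delta_growth_mean")
  cfg$delta_growth_sd <- check_group_param(cfg$delta_growth_sd, "delta_growth_sd")
  cfg$uosm_median <- check_group_param(cfg$uosm_median, "uosm_median")
  cfg$uosm_log_sd <- check_group_param(cfg$uosm_log_sd, "uosm_log_sd")
  cfg$egfr_slope <- check_group_param(cfg$egfr_slope, "egfr_slope")
  check_that(all(cfg$pre_growth_sd >= 0) && all(cfg$delta_growth_sd >= 0) &&
               all(cfg$uosm_log_sd >= 0),
             "pre_growth_sd", "group SDs must be >= 0")
  check_that(all(cfg$egfr_months > 0), "egfr_months",
             "months since treatment start must be positive")
  cfg
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Fields absent from the file keep the [cohort_config()] defaults.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A `"cohort_config"` object.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(sprintf("Unknown configuration field(s): %s",
                  paste(extra, collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  # YAML maps come back as named lists; per-group params need named vectors
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohort_config, raw)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  patients: %d (responder fraction %.3f)\n",
              x$n_patients, x$responder_fraction))
  cat(sprintf("  pre-treatment growth %%/yr: responder %.1f +/- %.1f, non-responder %.1f +/- %.1f\n",
              x$pre_growth_mean[1], x$pre_growth_sd[1],
              x$pre_growth_mean[2], x$pre_growth_sd[2]))
  cat(sprintf("  growth-rate change pp/yr:  responder %.1f +/- %.1f, non-responder %+.1f +/- %.1f\n",
              x$delta_growth_mean[1], x$delta_growth_sd[1],
              x$delta_growth_mean[2], x$delta_growth_sd[2]))
  cat(sprintf("  sequence CV: %.3f; scans/window: %d-%d; seed: %s\n",
              x$sequence_cv, x$scans_per_window_range[1],
              x$scans_per_window_range[2],
              if (is.null(x$seed)) "ambient" else x$seed))
  invisible(x)
}
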