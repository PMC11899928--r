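#' Run the full tolvaptan-response pipeline
#'
#' Orchestrates simulate -> eligibility filter -> growth fits -> responder
#' clustering -> group statistics -> eGFR slopes -> power design, writing
#' every stage's output as delimited text or JSON under `outdir` and
#' returning a run manifest. A failure halts the run with the stage name in
#' the error; outputs of completed stages are retained.
#'
#' All randomness flows through the single seed in the configuration
#' (optionally overridden by `seed`), so a rerun with the same seed
#' produces byte-identical outputs.
#'
#' @param config A [cohort_config()] object, or a path to a YAML/JSON
#'   config file (see [read_cohort_config()]).
#' @param outdir Output directory, created if needed.
#' @param seed Optional integer overriding `config$seed`.
#' @param cohort Optional existing cohort to analyse instead of simulating:
#'   a `"pkd_cohort"` object or a directory readable by [read_cohort()].
#' @return Invisibly, the manifest: config snapshot, seed, package version,
#'   output paths, per-stage record counts, and the key stage results
#'   (`responder_calls`, `univariate`, `model`, `egfr`, `power`). Also
#'   written as `manifest.json`.
#' @export
run_full_pipeline <- function(config = cohort_config(), outdir, seed = NULL,
                              cohort = NULL) {
  if (is.character(config)) config <- read_cohort_config(config)
  config <- validate_cohort_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline halted at stage '%s': %s", name,
                    conditionMessage(e)),
            class = c("pkdresp_pipeline_error", class(e)[1]))
    })
  }
  files <- character(0)
  counts <- list()

  cohort <- if (is.null(cohort)) {
    stage("simulate", simulate_cohort(config))
  } else if (is.character(cohort)) {
    stage("read_input", read_cohort(cohort))
  } else {
    stopifnot(inherits(cohort, "pkd_cohort"))
    cohort
  }
  if (is.null(attr(cohort, "config"))) attr(cohort, "config") <- config
  files <- c(files, write_cohort(cohort, outdir))
  counts$patients_simulated <- nrow(cohort$patients)

  elig <- stage("eligibility",
                apply_eligibility_filters(cohort$scans, cohort$patients))
  elig_out <- mutate(elig,
                     reasons = purrr::map_chr(elig$reasons, paste, collapse = ";"))
  p_elig <- file.path(outdir, "eligibility.csv")
  readr::write_csv(elig_out, p_elig)
  files <- c(files, eligibility = p_elig)
  keep <- elig$patient_id[elig$eligible]
  counts$patients_eligible <- length(keep)
  if (length(keep) == 0) {
    abort("Pipeline halted at stage 'classification': ELIGIBILITY_EMPTY (no eligible patients).",
          class = c("pkdresp_pipeline_error", "pkdresp_eligibility_empty"))
  }
  patients <- filter(cohort$patients, .data$patient_id %in% keep)
  scans <- filter(cohort$scans, .data$patient_id %in% keep)
  labs <- filter(cohort$labs, .data$patient_id %in% keep)

  fits <- stage("growth_fit", fit_growth_rates(scans, patients))
  p_fits <- file.path(outdir, "growth_fits.csv")
  readr::write_csv(fits, p_fits)
  files <- c(files, growth_fits = p_fits)
  counts$growth_fits <- nrow(fits)

  calls <- stage("classification", classify_responders(fits))
  km <- attr(calls, "cluster")
  p_calls <- file.path(outdir, "responder_calls.csv")
  readr::write_csv(calls, p_calls)
  p_clust <- file.path(outdir, "cluster_summary.json")
  jsonlite::write_json(
    list(schema_version = 1L,
         split_value = km$split_value,
         cluster_means = as.list(km$cluster_means),
         gap = km$gap, within_ss = km$within_ss,
         n = as.list(table(calls$label))),
    p_clust, auto_unbox = TRUE, digits = NA)
  files <- c(files, responder_calls = p_calls, cluster_summary = p_clust)
  counts$responders <- sum(calls$label == "responder")
  counts$non_responders <- sum(calls$label == "non-responder")

  stats_res <- stage("statistics", {
    tab <- patients %>%
      add_mayo_classification() %>%
      left_join(select(calls, "patient_id", "pre_rate", "delta", "label"),
                by = "patient_id")
    vars <- c(treatment_start_age = "continuous", sex = "categorical",
              height_m = "continuous", tkv_at_start = "continuous",
              httkv = "continuous", mic_class = "categorical",
              uosm_baseline = "continuous", egfr_baseline = "continuous",
              pre_rate = "continuous")
    uni <- compare_groups_univariate(tab, label_col = "label",
                                     variables = vars)
    # model battery: univariate hits (raw p < 0.05) + age and sex, then
    # bidirectional AIC over the candidate set
    hits <- uni$variable[uni$p_raw < 0.05 & uni$variable %in%
                           c("pre_rate", "uosm_baseline")]
    forced <- c("treatment_start_age", "sex")
    full <- fit_logistic_response_model(tab, "label",
                                        unique(c(hits, forced)))
    sel <- stepwise_aic_select(tab, "label",
                               candidates = unique(c(forced, "pre_rate",
                                                     "uosm_baseline")))
    list(table = tab, univariate = uni, full = full, selection = sel)
  })
  p_uni <- file.path(outdir, "univariate_summary.csv")
  readr::write_csv(stats_res$univariate, p_uni)
  p_model <- file.path(outdir, "logistic_model.json")
  final_fit <- if (is.null(stats_res$selection$fit)) stats_res$full else stats_res$selection$fit
  jsonlite::write_json(
    list(schema_version = 1L,
         coding = final_fit$coding,
         full_model = list(terms = tidy(stats_res$full),
                           aic = AIC(stats_res$full$fit)),
         selected = stats_res$selection$selected,
         selected_model = list(terms = tidy(final_fit),
                               aic = AIC(final_fit$fit)),
         aic_trail = stats_res$selection$aic_trail),
    p_model, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, univariate_summary = p_uni, logistic_model = p_model)
  counts$univariate_variables <- nrow(stats_res$univariate)

  egfr_res <- stage("egfr", {
    pts <- delta_egfr_series(labs)
    fit_group_slopes(pts, labels = calls)
  })
  p_egfr <- file.path(outdir, "egfr_slopes.json")
  jsonlite::write_json(
    list(schema_version = 1L,
         per_group = tidy(egfr_res),
         interaction_p = egfr_res$interaction_p,
         excess_percent = egfr_res$excess_percent),
    p_egfr, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, egfr_slopes = p_egfr)
  counts$egfr_points <- nrow(egfr_res$data)

  power_res <- stage("power", {
    d <- cohen_d_paired(5.5, 2.8, 3.0)
    list(d = d, design = sample_size_paired(d, alpha = 0.01, power = 0.90))
  })

  manifest <- list(
    schema_version = 1L,
    package_version = as.character(utils::packageVersion("pkdresp")),
    seed = config$seed,
    config = unclass(config),
    files = as.list(files),
    counts = counts,
    power = list(d = power_res$d, n = power_res$design$n,
                 n_raw = power_res$design$n_raw)
  )
  p_manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest$files$manifest <- p_manifest
  manifest$results <- list(responder_calls = calls,
                           univariate = stats_res$univariate,
                           model = final_fit, egfr = egfr_res,
                           power = power_res$design)
  invisible(manifest)
}

#' Plot per-patient TKV trajectories around treatment start
#'
#' Log-scale TKV against age with the per-visit sequence means, faceted by
#' patient, with the treatment start marked — the per-patient view of the
#' piecewise-exponential growth model.
#'
#' @param scans Sequence-level scan table (see [mean_tkv_per_scan()]).
#' @param patients Tibble with `patient_id` and `treatment_start_age`.
#' @param patient_ids Patients to show; default first 6.
#' @return A ggplot object.
#' @export
plot_tkv_trajectories <- function(scans, patients, patient_ids = NULL) {
  pts <- mean_tkv_per_scan(scans)
  if (is.null(patient_ids)) patient_ids <- head(unique(pts$patient_id), 6)
  pts <- filter(pts, .data$patient_id %in% patient_ids)
  starts <- filter(as_tibble(patients), .data$patient_id %in% patient_ids)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$age_years, y = .data$mean_tkv)) +
    ggplot2::geom_vline(data = starts,
                        ggplot2::aes(xintercept = .data$treatment_start_age),
                        linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~patient_id, scales = "free") +
    ggplot2::labs(x = "age (years)", y = "TKV (mL, log scale)") +
    ggplot2::theme_minimal()
}
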