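#' Average TKV across pulse sequences, per scan
#'
#' Each MRI visit can yield several TKV measurements, one per pulse sequence
#' that covers both kidneys in their entirety. The per-visit TKV is the
#' arithmetic mean over the qualifying sequences; sequences not covering both
#' kidneys are excluded.
#'
#' @param scans Tibble of sequence-level measurements with columns
#'   `patient_id`, `age_years`, `tkv_ml` and (optionally)
#'   `covers_both_kidneys`; a missing coverage column is treated as all
#'   `TRUE`.
#' @return A tibble with one row per (`patient_id`, `age_years`):
#'   `mean_tkv` and `n_sequences`.
#' @examples
#' scans <- tibble::tibble(
#'   patient_id = "P1", age_years = 40,
#'   tkv_ml = c(1000, 1020), covers_both_kidneys = TRUE
#' )
#' mean_tkv_per_scan(scans)
#' @export
mean_tkv_per_scan <- function(scans) {
  scans <- as_tibble(scans)
  required <- c("patient_id", "age_years", "tkv_ml")
  missing_cols <- setdiff(required, names(scans))
  if (length(missing_cols)) {
    abort(sprintf("`scans` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  if (!"covers_both_kidneys" %in% names(scans)) {
    scans$covers_both_kidneys <- TRUE
  }
  if (any(scans$tkv_ml <= 0, na.rm = TRUE) || anyNA(scans$tkv_ml)) {
    abort("`tkv_ml` must be positive and non-missing.",
          class = "pkdresp_validation_error")
  }
  visits <- distinct(scans, .data$patient_id, .data$age_years)
  kept <- scans %>%
    filter(.data$covers_both_kidneys) %>%
    group_by(.data$patient_id, .data$age_years) %>%
    summarise(mean_tkv = mean(.data$tkv_ml), n_sequences = n(),
              .groups = "drop")
  dropped <- dplyr::anti_join(visits, kept, by = c("patient_id", "age_years"))
  if (nrow(dropped)) {
    abort(sprintf(
      "No sequence covering both kidneys for: %s",
      paste(sprintf("%s @ %.2f y", dropped$patient_id, dropped$age_years),
            collapse = "; ")),
      class = "pkdresp_missing_data")
  }
  arrange(kept, .data$patient_id, .data$age_years)
}

#' Fit an exponential TKV growth rate by two-parameter least squares
#'
#' Ordinary least squares of `log(mean_tkv)` on age. The slope `b` of the
#' log-linear fit is annualised as the compound rate `(exp(b) - 1) * 100`
#' (% per year), matching the convention of annual percent TKV growth.
#'
#' @param points Tibble with columns `age_years` and `mean_tkv`
#'   (a `tkv_ml` column is accepted as a synonym). At least two distinct
#'   ages are required.
#' @return A one-row tibble: `annual_rate` (% per year), `tkv_at_ref_age`
#'   (fitted TKV at `ref_age`, the earliest scan age), `ref_age`,
#'   `n_points`, `log_residual_rms`.
#' @examples
#' pts <- tibble::tibble(age_years = c(40, 41, 42),
#'                       mean_tkv = 1000 * 1.05^(0:2))
#' fit_exponential_growth(pts) # 5 % per year
#' @export
fit_exponential_growth <- function(points) {
  points <- as_tibble(points)
  if (!"mean_tkv" %in% names(points) && "tkv_ml" %in% names(points)) {
    points <- rename(points, mean_tkv = "tkv_ml")
  }
  if (!all(c("age_years", "mean_tkv") %in% names(points))) {
    abort("`points` needs columns `age_years` and `mean_tkv`.",
          class = "pkdresp_validation_error")
  }
  pts <- filter(points, !is.na(.data$age_years), !is.na(.data$mean_tkv))
  if (nrow(pts) < 2 || length(unique(pts$age_years)) < 2) {
    abort("Growth fit needs >= 2 scans at distinct ages.",
          class = "pkdresp_insufficient_data")
  }
  if (any(pts$mean_tkv <= 0)) {
    abort("TKV must be positive for the log-linear fit.",
          class = "pkdresp_validation_error")
  }
  fit <- lm(log(mean_tkv) ~ age_years, data = pts)
  b <- unname(coef(fit)[["age_years"]])
  ref_age <- min(pts$age_years)
  tibble(
    annual_rate = (exp(b) - 1) * 100,
    tkv_at_ref_age = exp(unname(coef(fit)[[1]]) + b * ref_age),
    ref_age = ref_age,
    n_points = nrow(pts),
    log_residual_rms = sqrt(mean(residuals(fit)^2))
  )
}

#' Fit separate growth rates before and during treatment
#'
#' Splits one patient's per-visit TKV points at the treatment-start age and
#' fits [fit_exponential_growth()] independently in each window. A visit at
#' exactly the treatment-start age is assigned to the pre-treatment window
#' (treatment cannot yet have acted at initiation).
#'
#' @inheritParams fit_exponential_growth
#' @param treatment_start_age Age (years) at tolvaptan initiation.
#' @return A two-row tibble (one per `window`, `"pre"` then `"during"`)
#'   with the [fit_exponential_growth()] columns.
#' @export
split_pre_during <- function(points, treatment_start_age) {
  points <- as_tibble(points)
  pre <- filter(points, .data$age_years <= treatment_start_age)
  during <- filter(points, .data$age_years > treatment_start_age)
  for (w in list(list(d = pre, name = "pre"), list(d = during, name = "during"))) {
    if (nrow(w$d) < 2 || length(unique(w$d$age_years)) < 2) {
      abort(sprintf("Fewer than 2 scans at distinct ages in the %s-treatment window.",
                    w$name),
            class = c("pkdresp_eligibility_error", "pkdresp_insufficient_data"))
    }
  }
  bind_rows(
    mutate(fit_exponential_growth(pre), window = "pre", .before = 1),
    mutate(fit_exponential_growth(during), window = "during", .before = 1)
  )
}

#' Per-patient pre/during growth rates for a whole cohort
#'
#' Applies [mean_tkv_per_scan()] and [split_pre_during()] to every patient.
#' Patients whose scan layout cannot support both fits are dropped with a
#' warning naming them (use [apply_eligibility_filters()] first to make the
#' reasons explicit).
#'
#' @param scans Sequence-level scan table (see [mean_tkv_per_scan()]).
#' @param patients Tibble with `patient_id` and `treatment_start_age`.
#' @return A tibble with columns `patient_id`, `window`, `annual_rate`,
#'   `tkv_at_ref_age`, `ref_age`, `n_points`, `log_residual_rms`.
#' @export
fit_growth_rates <- function(scans, patients) {
  pts <- mean_tkv_per_scan(scans) %>%
    left_join(select(patients, "patient_id", "treatment_start_age"),
              by = "patient_id")
  if (anyNA(pts$treatment_start_age)) {
    bad <- unique(pts$patient_id[is.na(pts$treatment_start_age)])
    abort(sprintf("No treatment_start_age for: %s", paste(bad, collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  fits <- purrr::map(split(pts, pts$patient_id), function(d) {
    tryCatch(
      mutate(split_pre_during(d, d$treatment_start_age[1]),
             patient_id = d$patient_id[1], .before = 1),
      error = function(e) e
    )
  })
  failed <- purrr::map_lgl(fits, inherits, "error")
  if (any(failed)) {
    warn(sprintf("Dropped %d patient(s) without a fittable pre and during window: %s",
                 sum(failed), paste(names(fits)[failed], collapse = ", ")))
  }
  bind_rows(fits[!failed])
}

# eligibility reason codes, in reporting order
.eligibility_codes <- c("PRE_SCANS_LT_2", "PRE_SPAN_LT_1Y",
                        "DURING_SCANS_LT_2", "DURING_SPAN_LT_1Y",
                        "TREATMENT_INTERRUPTION", "NON_ADHERENCE",
                        "CYST_EVENT")

#' Apply the cohort eligibility criteria
#'
#' Inclusion requires at least two MRI visits spanning at least one year both
#' before and during treatment; exclusion flags are treatment interruption
#' over one month, non-adherence, and cyst rupture/aspiration. Flags are
#' inputs (columns `interruption_gt_1mo`, `non_adherent`, `cyst_event` on
#' `patients`; absent columns are treated as all-`FALSE`), never inferred.
#' A visit at exactly the treatment-start age counts as pre-treatment.
#'
#' @inheritParams fit_growth_rates
#' @return A tibble with one row per patient: `patient_id`, `eligible`,
#'   and `reasons` (list-column of violated criterion codes; empty iff
#'   eligible).
#' @export
apply_eligibility_filters <- function(scans, patients) {
  patients <- as_tibble(patients)
  for (fl in c("interruption_gt_1mo", "non_adherent", "cyst_event")) {
    if (!fl %in% names(patients)) patients[[fl]] <- FALSE
  }
  visits <- distinct(as_tibble(scans), .data$patient_id, .data$age_years)
  windows <- visits %>%
    left_join(select(patients, "patient_id", "treatment_start_age"),
              by = "patient_id") %>%
    mutate(pre = .data$age_years <= .data$treatment_start_age) %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_pre = sum(.data$pre),
      pre_span = if (any(.data$pre)) diff(range(.data$age_years[.data$pre])) else 0,
      n_during = sum(!.data$pre),
      during_span = if (any(!.data$pre)) diff(range(.data$age_years[!.data$pre])) else 0,
      .groups = "drop"
    )
  out <- patients %>%
    select("patient_id", "interruption_gt_1mo", "non_adherent", "cyst_event") %>%
    left_join(windows, by = "patient_id") %>%
    mutate(across(c("n_pre", "n_during", "pre_span", "during_span"),
                  ~ dplyr::coalesce(.x, 0)))
  reasons <- purrr::pmap(
    list(out$n_pre, out$pre_span, out$n_during, out$during_span,
         out$interruption_gt_1mo, out$non_adherent, out$cyst_event),
    function(np, sp, nd, sdur, intr, nonadh, cyst) {
      c(if (np < 2) "PRE_SCANS_LT_2",
        if (np >= 2 && sp < 1) "PRE_SPAN_LT_1Y",
        if (nd < 2) "DURING_SCANS_LT_2",
        if (nd >= 2 && sdur < 1) "DURING_SPAN_LT_1Y",
        if (isTRUE(intr)) "TREATMENT_INTERRUPTION",
        if (isTRUE(nonadh)) "NON_ADHERENCE",
        if (isTRUE(cyst)) "CYST_EVENT")
    }
  )
  tibble(patient_id = out$patient_id,
         eligible = lengths(reasons) == 0,
         reasons = reasons)
}
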