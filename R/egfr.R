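#' CKD-EPI 2021 creatinine eGFR (race-free)
#'
#' `eGFR = 142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age *
#' 1.012 [if female]`, with `k = 0.7` (female) / `0.9` (male) and
#' `a = -0.241` (female) / `-0.302` (male). Constants are those of the
#' published 2021 refit of the CKD-EPI creatinine equation.
#'
#' @param creatinine_mg_dl Serum creatinine, mg/dL (vectorised).
#' @param age_years Age in years.
#' @param sex `"male"`/`"female"` (or `"M"`/`"F"`).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckd_epi_2021(1.0, 50, "male")    # ~91.7
#' ckd_epi_2021(0.7, 40, "female")  # ~112.1
#' @export
ckd_epi_2021 <- function(creatinine_mg_dl, age_years, sex) {
  if (any(!is.finite(creatinine_mg_dl)) || any(creatinine_mg_dl <= 0)) {
    abort("`creatinine_mg_dl` must be positive.",
          class = "pkdresp_validation_error")
  }
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    abort("`age_years` must be positive.", class = "pkdresp_validation_error")
  }
  sex <- normalise_sex(sex)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  ratio <- creatinine_mg_dl / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.200 *
    0.9938^age_years * ifelse(female, 1.012, 1)
}

#' Invert the CKD-EPI 2021 equation for creatinine
#'
#' Solves the piecewise power law for serum creatinine given an eGFR, using
#' the male/female branch structure of the forward equation: the
#' below-threshold branch (`Scr <= kappa`) applies when the
#' age/sex-normalised eGFR exceeds 142, the above-threshold branch
#' otherwise. Used to back-convert simulated eGFR trajectories into
#' plausible creatinine series.
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (vectorised).
#' @inheritParams ckd_epi_2021
#' @return Serum creatinine, mg/dL.
#' @export
inverse_ckd_epi_2021 <- function(egfr, age_years, sex) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be positive.", class = "pkdresp_validation_error")
  }
  sex <- normalise_sex(sex)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  g <- egfr / (142 * 0.9938^age_years * ifelse(female, 1.012, 1))
  # g >= 1 -> Scr/kappa <= 1 branch (negative exponent alpha), else the
  # -1.2 branch
  kappa * ifelse(g >= 1, g^(1 / alpha), g^(-1 / 1.2))
}

#' Fill per-patient change-from-baseline eGFR
#'
#' The baseline is the month-0 value when present, otherwise the earliest
#' visit; `delta_egfr = egfr - baseline`, so the baseline row gets 0.
#' Patients with no usable baseline (all-missing eGFR) are dropped with a
#' warning naming them; the rest are processed.
#'
#' @param labs Tibble with columns `patient_id`, `months_since_start`,
#'   `egfr`.
#' @return `labs` with a `delta_egfr` column (recomputed if present).
#' @export
delta_egfr_series <- function(labs) {
  labs <- as_tibble(labs)
  missing_cols <- setdiff(c("patient_id", "months_since_start", "egfr"),
                          names(labs))
  if (length(missing_cols)) {
    abort(sprintf("`labs` is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  baseline <- labs %>%
    filter(!is.na(.data$egfr)) %>%
    group_by(.data$patient_id) %>%
    arrange(.data$months_since_start, .by_group = TRUE) %>%
    summarise(egfr_at_start = .data$egfr[1], .groups = "drop")
  no_base <- setdiff(unique(labs$patient_id), baseline$patient_id)
  if (length(no_base)) {
    warn(sprintf("No baseline eGFR for %s; dropped.",
                 paste(no_base, collapse = ", ")))
  }
  labs %>%
    dplyr::inner_join(baseline, by = "patient_id") %>%
    mutate(delta_egfr = .data$egfr - .data$egfr_at_start) %>%
    select(-"egfr_at_start")
}

#' Percent excess of the faster eGFR decline
#'
#' How much faster (in percent of the responder slope magnitude) eGFR
#' declines in non-responders: `(|slope_nr| - |slope_r|) / |slope_r| * 100`.
#'
#' @param slope_responder,slope_nonresponder Annual eGFR slopes
#'   (mL/min/1.73 m^2 per year); the responder slope must be nonzero.
#' @return Percent excess decline.
#' @examples
#' slope_excess_percent(-0.25, -0.40) # 60
#' @export
slope_excess_percent <- function(slope_responder, slope_nonresponder) {
  if (any(slope_responder == 0)) {
    abort("Responder slope is zero: percent excess is undefined.",
          class = "pkdresp_validation_error")
  }
  (abs(slope_nonresponder) - abs(slope_responder)) / abs(slope_responder) * 100
}

#' Compare eGFR decline slopes between response groups
#'
#' Per-group ordinary least squares of change-from-baseline eGFR on time
#' since treatment start (reported per year), plus a pooled model with
#' group, time and group-by-time terms whose interaction p-value tests the
#' slope difference. Raw (unbinned) visit times are used for fitting.
#'
#' @param egfr_points Tibble with `patient_id`, `months_since_start`,
#'   `delta_egfr` (see [delta_egfr_series()]).
#' @param labels Tibble with `patient_id` and `label`
#'   (`"responder"`/`"non-responder"`), or `NULL` if `egfr_points` already
#'   has a `label` column.
#' @param horizon_months Only visits up to this month enter the fit
#'   (default 48).
#' @return An object of class `"egfr_slopes"`: per-group tibble of `slope`,
#'   `std.error`, `conf.low`, `conf.high` (t-based 95% CI), `n_points`;
#'   `interaction_p`; `excess_percent`; with [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
fit_group_slopes <- function(egfr_points, labels = NULL, horizon_months = 48) {
  pts <- as_tibble(egfr_points)
  if (!is.null(labels)) {
    pts <- left_join(pts, select(as_tibble(labels), "patient_id", "label"),
                     by = "patient_id")
  }
  if (!"label" %in% names(pts)) {
    abort("No `label` column or `labels` table supplied.",
          class = "pkdresp_validation_error")
  }
  pts <- pts %>%
    filter(!is.na(.data$label), !is.na(.data$delta_egfr),
           .data$months_since_start <= horizon_months) %>%
    mutate(years = .data$months_since_start / 12)
  present <- unique(pts$label)
  if (!all(.groups %in% present)) {
    abort(sprintf("Group(s) absent from the eGFR data: %s",
                  paste(setdiff(.groups, present), collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  per_group <- purrr::map(.groups, function(grp) {
    d <- filter(pts, .data$label == grp)
    if (length(unique(d$years)) < 2) {
      abort(sprintf("Fewer than 2 distinct timepoints for %s.", grp),
            class = "pkdresp_insufficient_data")
    }
    fit <- lm(delta_egfr ~ years, data = d)
    sm <- summary(fit)$coefficients
    se <- sm["years", "Std. Error"]
    est <- sm["years", "Estimate"]
    tq <- qt(0.975, fit$df.residual)
    tibble(label = grp, slope = est, std.error = se,
           conf.low = est - tq * se, conf.high = est + tq * se,
           n_points = nrow(d))
  }) %>% bind_rows()
  pooled <- lm(delta_egfr ~ years * label, data = pts)
  sm <- summary(pooled)$coefficients
  int_row <- grep("^years:label", rownames(sm))
  interaction_p <- unname(sm[int_row, "Pr(>|t|)"])
  excess <- slope_excess_percent(
    per_group$slope[per_group$label == "responder"],
    per_group$slope[per_group$label == "non-responder"]
  )
  structure(
    list(per_group = per_group, interaction_p = interaction_p,
         excess_percent = excess, data = pts, pooled_fit = pooled),
    class = "egfr_slopes"
  )
}

#' @export
print.egfr_slopes <- function(x, ...) {
  cat("<egfr_slopes> annual eGFR decline by response group\n")
  print(as.data.frame(x$per_group), digits = 3)
  cat(sprintf("  interaction p = %.4g; non-responder decline %.1f%% greater\n",
              x$interaction_p, x$excess_percent))
  invisible(x)
}

#' @describeIn fit_group_slopes Per-group slope table.
#' @param x An `"egfr_slopes"` object.
#' @param ... Unused.
#' @method tidy egfr_slopes
#' @export
tidy.egfr_slopes <- function(x, ...) x$per_group

#' @describeIn fit_group_slopes One-row summary: interaction p, percent
#'   excess decline, total points.
#' @method glance egfr_slopes
#' @export
glance.egfr_slopes <- function(x, ...) {
  tibble(interaction_p = x$interaction_p, excess_percent = x$excess_percent,
         n_points = nrow(x$data))
}

#' Plot the group eGFR trajectories
#'
#' Scatter of change-from-baseline eGFR against months since treatment
#' start, with the pooled and per-group least-squares trendlines. Points are
#' binned to the nominal 4-month visit grid for display; the fitted lines
#' come from the raw visit times.
#'
#' @param object An `"egfr_slopes"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot egfr_slopes
#' @export
autoplot.egfr_slopes <- function(object, ...) {
  d <- mutate(object$data,
              month_bin = 4 * round(.data$months_since_start / 4))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$month_bin, y = .data$delta_egfr,
                                  colour = .data$label)) +
    ggplot2::geom_jitter(width = 0.8, alpha = 0.35, size = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(x = .data$months_since_start),
                         method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.8) +
    ggplot2::geom_smooth(ggplot2::aes(x = .data$months_since_start),
                         method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(responder = "#3366cc",
                                            `non-responder` = "#cc3333")) +
    ggplot2::labs(x = "months since tolvaptan initiation",
                  y = expression(Delta * "eGFR (mL/min/1.73" * m^2 * ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
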