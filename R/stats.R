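#' Route a variable to its two-group test
#'
#' Continuous variables go to Student's t-test when both groups pass the
#' Shapiro-Wilk normality test (p > 0.05), and to the Mann-Whitney U test
#' otherwise; categorical variables go to the chi-squared test. The 0.05
#' Shapiro threshold is the conventional default.
#'
#' @param values Vector of observations.
#' @param group Two-level grouping vector aligned with `values`.
#' @param kind `"continuous"` or `"categorical"`.
#' @return One of `"t-test"`, `"mann-whitney"`, `"chi-squared"`.
#' @export
route_test <- function(values, group, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (kind == "categorical") return("chi-squared")
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- as.character(group[keep])
  sizes <- table(group)
  if (length(sizes) != 2 || any(sizes < 3)) {
    abort("Routing needs two groups with >= 3 observations each.",
          class = "pkdresp_routing_error")
  }
  normal <- vapply(split(values, group), function(x) {
    if (length(unique(x)) < 3) return(FALSE) # shapiro undefined on constants
    shapiro.test(x)$p.value > 0.05
  }, logical(1))
  if (all(normal)) "t-test" else "mann-whitney"
}

# internal: run the routed test, returning p-value and per-group summaries
run_routed_test <- function(values, group, kind) {
  test <- route_test(values, group, kind)
  g <- as.character(group)
  lv <- sort(unique(g))
  if (test == "chi-squared") {
    p <- suppressWarnings(chisq.test(table(g, as.character(values)),
                                     correct = FALSE))$p.value
    summ <- vapply(lv, function(l) {
      tab <- table(values[g == l])
      paste(sprintf("%s %d", names(tab), as.integer(tab)), collapse = ", ")
    }, character(1))
  } else if (test == "t-test") {
    p <- t.test(values[g == lv[1]], values[g == lv[2]], var.equal = TRUE)$p.value
    summ <- vapply(lv, function(l) {
      x <- values[g == l]
      sprintf("%.2f +/- %.2f", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
    }, character(1))
  } else {
    x1 <- values[g == lv[1]]
    x2 <- values[g == lv[2]]
    # exact distribution for small untied samples, normal approximation
    # (with tie correction) otherwise
    use_exact <- min(length(x1), length(x2)) < 8 && !any(duplicated(c(x1, x2)))
    p <- suppressWarnings(wilcox.test(x1, x2, exact = use_exact))$p.value
    summ <- vapply(lv, function(l) {
      q <- quantile(values[g == l], c(0.25, 0.5, 0.75), na.rm = TRUE)
      sprintf("%.2f [%.2f, %.2f]", q[2], q[1], q[3])
    }, character(1))
  }
  list(test = test, p = p, summary = setNames(summ, lv))
}

#' Univariate responder vs non-responder comparisons
#'
#' Runs the routed test for every variable, summarises each group
#' (mean +/- SD for normally distributed continuous variables, median
#' \[IQR\] otherwise, level counts for categorical), and applies the
#' Benjamini-Hochberg correction across the whole battery.
#'
#' @param data Tibble with one row per patient.
#' @param label_col Name of the two-level grouping column.
#' @param variables Named character vector mapping column names to
#'   `"continuous"` or `"categorical"`; `NULL` infers the type of every
#'   column except `label_col` and `patient_id` from its class.
#' @return A tibble with one row per variable: `variable`, `kind`, `test`,
#'   one summary column per group level, `p_raw`, `p_bh`. Variables that
#'   are entirely missing are excluded with a warning.
#' @export
compare_groups_univariate <- function(data, label_col = "label",
                                      variables = NULL) {
  data <- as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("No grouping column `%s`.", label_col),
          class = "pkdresp_validation_error")
  }
  if (is.null(variables)) {
    cols <- setdiff(names(data), c(label_col, "patient_id"))
    variables <- vapply(cols, function(v) {
      if (is.numeric(data[[v]])) "continuous" else "categorical"
    }, character(1))
  }
  g <- data[[label_col]]
  rows <- list()
  for (v in names(variables)) {
    x <- data[[v]]
    if (all(is.na(x))) {
      warn(sprintf("Variable `%s` is entirely missing; excluded.", v))
      next
    }
    res <- run_routed_test(x[!is.na(x)], g[!is.na(x)], variables[[v]])
    row <- tibble(variable = v, kind = unname(variables[[v]]), test = res$test)
    for (l in names(res$summary)) row[[l]] <- res$summary[[l]]
    row$p_raw <- res$p
    rows[[v]] <- row
  }
  out <- bind_rows(rows)
  out$p_bh <- bh_adjust(out$p_raw)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values: step-up, monotone-enforced,
#' capped at 1 (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= the raw values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must be in [0, 1] and non-missing.",
          class = "pkdresp_validation_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Variance inflation factors from auxiliary regressions
#'
#' For each predictor, regresses it linearly on the remaining predictors and
#' reports `1 / (1 - R^2)`. With a single predictor the VIF is 1 by
#' definition; with exactly two predictors both VIFs equal
#' `1 / (1 - r^2)` for their sample correlation `r`.
#'
#' @param x Numeric matrix or data frame of predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
variance_inflation <- function(x) {
  X <- as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (p == 1) return(setNames(1, colnames(X)))
  vifs <- vapply(seq_len(p), function(j) {
    y <- X[, j]
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }, numeric(1))
  setNames(vifs, colnames(X))
}

# internal: 0/1 outcome from a label column or numeric/logical vector.
# Default clinical coding: non-responder = 1, responder = 0, the only coding
# under which higher baseline growth rate and Uosm (responder features) get
# negative coefficients.
encode_outcome <- function(y, nonresponder_as_one = TRUE) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), .groups)
    if (length(bad)) {
      abort(sprintf("Unknown outcome label(s): %s", paste(bad, collapse = ", ")),
            class = "pkdresp_validation_error")
    }
    as.integer(y == if (nonresponder_as_one) "non-responder" else "responder")
  } else {
    as.integer(y)
  }
}

#' Multivariate logistic model of tolvaptan response status
#'
#' Maximum-likelihood logistic regression of response status on the supplied
#' predictors, with Wald standard errors and 95% confidence intervals
#' (estimate +/- 1.96 SE) and a VIF per predictor from auxiliary linear
#' regressions. The outcome is coded non-responder = 1 by default (see
#' `nonresponder_as_one`) so that predictors elevated in responders carry
#' negative coefficients. (Quasi-)complete separation is detected from
#' degenerate fitted probabilities; the fit is still returned, flagged, with
#' its Wald intervals marked unreliable.
#'
#' @param data Tibble with the outcome and predictor columns.
#' @param outcome Name of the outcome column (labels
#'   `"responder"`/`"non-responder"`, logical, or 0/1).
#' @param predictors Character vector of predictor column names; none may be
#'   constant.
#' @param nonresponder_as_one If `TRUE` (default) non-responder is the
#'   positive class; set `FALSE` to flip the coding.
#' @return An object of class `"responder_logit"` with [tidy()] and
#'   [glance()] methods.
#' @export
fit_logistic_response_model <- function(data, outcome = "label", predictors,
                                        nonresponder_as_one = TRUE) {
  data <- as_tibble(data)
  if (length(predictors) < 1) {
    abort("At least one predictor is required.",
          class = "pkdresp_validation_error")
  }
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  df <- data[, c(outcome, predictors)]
  df <- df[complete.cases(df), ]
  y <- encode_outcome(df[[outcome]], nonresponder_as_one)
  if (length(unique(y)) < 2) {
    abort("Outcome has a single level after removing incomplete rows.",
          class = "pkdresp_validation_error")
  }
  mm <- df[, predictors, drop = FALSE]
  # categorical predictors (e.g. sex) enter as dummies
  mm <- as.data.frame(lapply(mm, function(x) {
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      as.integer(factor(x)) - 1L
    } else x
  }))
  constant <- vapply(mm, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    abort(sprintf("Constant predictor(s): %s",
                  paste(names(mm)[constant], collapse = ", ")),
          class = "pkdresp_validation_error")
  }
  fit_df <- cbind(.y = y, mm)
  glm_flag <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = fit_df, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        glm_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separated <- glm_flag || !fit$converged
  if (separated) {
    warn("Possible (quasi-)complete separation: Wald intervals are unreliable.")
  }
  sm <- summary(fit)$coefficients
  z <- qnorm(0.975)
  vifs <- if (ncol(mm) >= 1) variance_inflation(mm) else numeric(0)
  terms_tbl <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    conf.low = sm[, "Estimate"] - z * sm[, "Std. Error"],
    conf.high = sm[, "Estimate"] + z * sm[, "Std. Error"],
    p.value = sm[, "Pr(>|z|)"],
    # intercept gets no VIF; predictors aligned by name
    vif = c(NA_real_, unname(vifs[match(rownames(sm)[-1], names(vifs))]))
  )
  structure(
    list(fit = fit, terms = terms_tbl, separation = separated,
         coding = if (nonresponder_as_one) "non-responder = 1" else "responder = 1",
         n = nrow(fit_df)),
    class = "responder_logit"
  )
}

#' @export
print.responder_logit <- function(x, ...) {
  cat(sprintf("<responder_logit> n = %d, outcome coding: %s, AIC = %.2f%s\n",
              x$n, x$coding, AIC(x$fit),
              if (x$separation) " [separation flagged]" else ""))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' @describeIn fit_logistic_response_model Per-term coefficients, Wald SEs
#'   and 95% CIs, p-values and VIFs.
#' @param x A `"responder_logit"` object.
#' @param ... Unused.
#' @method tidy responder_logit
#' @export
tidy.responder_logit <- function(x, ...) x$terms

#' @describeIn fit_logistic_response_model One-row fit summary (AIC,
#'   deviances, n, separation flag, outcome coding).
#' @method glance responder_logit
#' @export
glance.responder_logit <- function(x, ...) {
  tibble(aic = AIC(x$fit), deviance = x$fit$deviance,
         null.deviance = x$fit$null.deviance, nobs = x$n,
         separation = x$separation, coding = x$coding)
}

#' Bidirectional stepwise AIC selection for the response model
#'
#' Greedy bidirectional stepwise search over the candidate predictors,
#' starting from the full candidate set: at each step the single addition or
#' removal that most lowers the AIC is taken (ties resolve to the earliest
#' move in fixed candidate order, additions before removals); the search
#' stops when no move lowers the AIC. All fits use the same complete-case
#' rows so AICs are comparable. If nothing beats the intercept-only model,
#' that model is returned.
#'
#' @inheritParams fit_logistic_response_model
#' @param candidates Character vector of candidate predictor columns, in the
#'   order used for deterministic tie-breaking.
#' @return A list: `selected` (character vector, possibly empty), `fit`
#'   (a `"responder_logit"`, or `NULL` for the intercept-only model),
#'   `aic_trail` (tibble of every step: action, term, AIC), `final_aic`.
#' @export
stepwise_aic_select <- function(data, outcome = "label", candidates,
                                nonresponder_as_one = TRUE) {
  data <- as_tibble(data)
  df <- data[, c(outcome, candidates)]
  df <- df[complete.cases(df), ]
  y <- encode_outcome(df[[outcome]], nonresponder_as_one)
  aic_of <- function(terms) {
    if (length(terms) == 0) {
      AIC(glm(y ~ 1, family = binomial()))
    } else {
      AIC(fit_logistic_response_model(df, outcome, terms,
                                      nonresponder_as_one)$fit)
    }
  }
  current <- candidates
  trail <- list(tibble(step = 0L, action = "start", term = NA_character_,
                       aic = aic_of(current)))
  step_i <- 0L
  repeat {
    current_aic <- trail[[length(trail)]]$aic
    moves <- bind_rows(
      purrr::map(setdiff(candidates, current),
                 ~ tibble(action = "add", term = .x)),
      purrr::map(intersect(candidates, current),
                 ~ tibble(action = "drop", term = .x))
    )
    if (nrow(moves) == 0) break
    moves$aic <- purrr::map2_dbl(moves$action, moves$term, function(a, t) {
      aic_of(if (a == "add") c(current, t) else setdiff(current, t))
    })
    best <- which(moves$aic < current_aic - 1e-10)
    if (length(best) == 0) break
    best <- best[which.min(moves$aic[best])]
    step_i <- step_i + 1L
    current <- if (moves$action[best] == "add") {
      c(current, moves$term[best])
    } else {
      setdiff(current, moves$term[best])
    }
    current <- candidates[candidates %in% current] # keep canonical order
    trail[[length(trail) + 1]] <- tibble(step = step_i,
                                         action = moves$action[best],
                                         term = moves$term[best],
                                         aic = moves$aic[best])
  }
  final_fit <- if (length(current)) {
    fit_logistic_response_model(df, outcome, current, nonresponder_as_one)
  } else NULL
  list(selected = current, fit = final_fit, aic_trail = bind_rows(trail),
       final_aic = trail[[length(trail)]]$aic)
}

#' Interobserver agreement: two-way random-effects ICC
#'
#' Single-measure, absolute-agreement intraclass correlation ICC(2,1) from
#' the two-way ANOVA mean squares: with `n` subjects and `k` raters,
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`, where MSR, MSC
#' and MSE are the subject, rater and residual mean squares. Absolute
#' agreement (rather than consistency) is used because a fixed rater bias
#' in kidney volume is a real disagreement clinically.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns; complete (no missing cells — no imputation is attempted).
#' @return An object of class `"icc_result"` with fields `icc`, `form`,
#'   `n_subjects`, `n_raters` and the mean squares; has a [glance()]
#'   method.
#' @export
icc_agreement <- function(ratings) {
  X <- as.matrix(as.data.frame(ratings))
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    abort("Missing cells in the rating matrix; agreement needs complete data.",
          class = "pkdresp_validation_error")
  }
  n <- nrow(X)
  k <- ncol(X)
  if (n < 2 || k < 2) {
    abort("Need >= 2 subjects and >= 2 raters.",
          class = "pkdresp_validation_error")
  }
  grand <- mean(X)
  row_m <- rowMeans(X)
  col_m <- colMeans(X)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((X - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc, form = "ICC(2,1) absolute agreement",
                 n_subjects = n, n_raters = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s = %.4f (%d subjects x %d raters)\n",
              x$form, x$icc, x$n_subjects, x$n_raters))
  invisible(x)
}

#' @describeIn icc_agreement One-row summary of the ICC.
#' @param x An `"icc_result"` object.
#' @param ... Unused.
#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble(icc = x$icc, form = x$form, n_subjects = x$n_subjects,
         n_raters = x$n_raters)
}
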