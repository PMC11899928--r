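#' Change in annual TKV growth rate
#'
#' The treatment effect per patient: during-treatment minus pre-treatment
#' annual growth rate, in percentage points per year. Negative values mean
#' the kidney grew more slowly on tolvaptan; the "absolute reduction"
#' sometimes quoted clinically is the negative of this signed delta.
#'
#' @param pre_rate,during_rate Annual growth rates, % per year (vectorised).
#' @return `during_rate - pre_rate`.
#' @examples
#' delta_growth_rate(3.4, -5.6) # -9: a strong responder
#' @export
delta_growth_rate <- function(pre_rate, during_rate) {
  if (!all(is.finite(pre_rate)) || !all(is.finite(during_rate))) {
    abort("Growth rates must be finite.", class = "pkdresp_validation_error")
  }
  during_rate - pre_rate
}

#' Exact two-cluster k-means in one dimension
#'
#' For one-dimensional data the k = 2 k-means optimum is a contiguous split
#' of the sorted values, so the global minimum of the within-cluster sum of
#' squares is found deterministically by scanning all `n - 1` contiguous
#' splits (prefix-sum arithmetic; no random restarts, no seed sensitivity).
#' Ties in the objective resolve to the smallest low-cluster size.
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @return An object of class `"kmeans1d"`: `labels` (integer, 1 = low
#'   cluster, 2 = high cluster, in input order), `cluster_means`,
#'   `split_value` (midpoint between the adjacent cluster edges),
#'   `within_ss`, `gap` (distance between the facing cluster edges), and
#'   the input `values`.
#' @examples
#' km <- kmeans1d_exact(c(-9, -5, -3, 0.5, 2, 5.3))
#' km$split_value
#' @export
kmeans1d_exact <- function(values) {
  if (length(values) < 2 || anyNA(values) || !all(is.finite(values))) {
    abort("Need >= 2 finite values.", class = "pkdresp_validation_error")
  }
  if (diff(range(values)) == 0) {
    abort("All values identical: no two-cluster structure exists.",
          class = "pkdresp_degenerate_input")
  }
  ord <- order(values)
  x <- values[ord]
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  m <- seq_len(n - 1)
  ss_low <- cs2[m] - cs[m]^2 / m
  ss_high <- (cs2[n] - cs2[m]) - (cs[n] - cs[m])^2 / (n - m)
  wss <- ss_low + ss_high
  best <- which.min(wss) # first minimum -> smallest low cluster on ties
  labels_sorted <- rep(c(1L, 2L), c(best, n - best))
  labels <- integer(n)
  labels[ord] <- labels_sorted
  structure(
    list(
      labels = labels,
      cluster_means = c(low = mean(x[1:best]), high = mean(x[(best + 1):n])),
      split_value = (x[best] + x[best + 1]) / 2,
      within_ss = wss[best],
      gap = x[best + 1] - x[best],
      values = values
    ),
    class = "kmeans1d"
  )
}

#' @export
print.kmeans1d <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("<kmeans1d> split at %.3f; low n=%d mean=%.3f | high n=%d mean=%.3f; gap %.3f\n",
              x$split_value, sizes[["1"]], x$cluster_means[["low"]],
              sizes[["2"]], x$cluster_means[["high"]], x$gap))
  invisible(x)
}

#' @describeIn kmeans1d_exact Per-cluster summary (`cluster`, `size`,
#'   `mean`, `min`, `max`).
#' @param x A `"kmeans1d"` object.
#' @param ... Unused.
#' @method tidy kmeans1d
#' @export
tidy.kmeans1d <- function(x, ...) {
  tibble(
    cluster = c("low", "high"),
    size = as.integer(c(sum(x$labels == 1L), sum(x$labels == 2L))),
    mean = unname(x$cluster_means),
    min = c(min(x$values[x$labels == 1L]), min(x$values[x$labels == 2L])),
    max = c(max(x$values[x$labels == 1L]), max(x$values[x$labels == 2L]))
  )
}

#' @describeIn kmeans1d_exact One-row model summary (`split_value`,
#'   `within_ss`, `gap`, `n`).
#' @method glance kmeans1d
#' @export
glance.kmeans1d <- function(x, ...) {
  tibble(split_value = x$split_value, within_ss = x$within_ss,
         gap = x$gap, n = length(x$labels))
}

#' Label clusters as responders and non-responders
#'
#' The cluster with the lower mean growth-rate change (the larger decrease
#' in TKV growth during treatment) is labelled `"responder"`, the other
#' `"non-responder"`.
#'
#' @param deltas Numeric vector of per-patient growth-rate changes
#'   (percentage points per year).
#' @param cluster Optional `"kmeans1d"` fit of `deltas`; computed if absent.
#' @return A character vector of labels aligned with `deltas`, with the
#'   `"kmeans1d"` fit attached as attribute `"cluster"`.
#' @export
assign_response_labels <- function(deltas, cluster = NULL) {
  if (is.null(cluster)) cluster <- kmeans1d_exact(deltas)
  stopifnot(inherits(cluster, "kmeans1d"))
  if (cluster$cluster_means[["low"]] == cluster$cluster_means[["high"]]) {
    abort("Cluster means coincide: responder assignment is ambiguous.",
          class = "pkdresp_degenerate_input")
  }
  labels <- ifelse(cluster$labels == 1L, "responder", "non-responder")
  attr(labels, "cluster") <- cluster
  labels
}

#' Classify a cohort into tolvaptan responders and non-responders
#'
#' Takes the long table of per-patient pre/during growth fits, computes the
#' signed change in annual growth rate, clusters it with [kmeans1d_exact()],
#' and labels the lower-mean cluster as responders.
#'
#' @param growth_fits Tibble as returned by [fit_growth_rates()]: columns
#'   `patient_id`, `window` (`"pre"`/`"during"`), `annual_rate`.
#' @return A tibble with one row per patient: `patient_id`, `pre_rate`,
#'   `during_rate`, `delta`, `label`; the `"kmeans1d"` fit is attached as
#'   attribute `"cluster"`.
#' @examples
#' fits <- tibble::tibble(
#'   patient_id = rep(c("A", "B", "C", "D"), each = 2),
#'   window = rep(c("pre", "during"), 4),
#'   annual_rate = c(7, 1, 6, 0.5, 4, 6, 3, 5)
#' )
#' classify_responders(fits)
#' @export
classify_responders <- function(growth_fits) {
  wide <- growth_fits %>%
    select("patient_id", "window", "annual_rate") %>%
    tidyr::pivot_wider(names_from = "window", values_from = "annual_rate")
  if (!all(c("pre", "during") %in% names(wide)) ||
      anyNA(wide$pre) || anyNA(wide$during)) {
    abort("Every patient needs both a 'pre' and a 'during' growth fit.",
          class = "pkdresp_validation_error")
  }
  delta <- delta_growth_rate(wide$pre, wide$during)
  labels <- assign_response_labels(delta)
  out <- tibble(
    patient_id = wide$patient_id,
    pre_rate = wide$pre,
    during_rate = wide$during,
    delta = delta,
    label = as.character(labels)
  )
  attr(out, "cluster") <- attr(labels, "cluster")
  out
}

#' Plot the one-dimensional responder clustering
#'
#' Dot plot of the sorted per-patient growth-rate changes, coloured by
#' cluster, with the optimal split marked — the visual check that the
#' two-group separation is real rather than imposed.
#'
#' @param object A `"kmeans1d"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kmeans1d
#' @export
autoplot.kmeans1d <- function(object, ...) {
  d <- tibble(
    delta = sort(object$values),
    rank = seq_along(object$values),
    cluster = ifelse(sort(object$values) <= object$split_value,
                     "responder (low)", "non-responder (high)")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$delta,
                                  colour = .data$cluster)) +
    ggplot2::geom_hline(yintercept = object$split_value, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "patient (sorted)",
                  y = "change in TKV growth rate (pp/yr)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
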