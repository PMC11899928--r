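# Shared fixtures and independent oracles, built in code at test time.

# exact exponential TKV points: rate in % per year
exact_exponential_points <- function(ages, v0, rate, age0 = ages[1]) {
  tibble::tibble(age_years = ages,
                 mean_tkv = v0 * (1 + rate / 100)^(ages - age0))
}

# sequence-level scan table for one patient on a piecewise-exponential
# trajectory (noiseless unless a noise factor matrix is given)
piecewise_scan_table <- function(patient_id, pre_ages, during_ages,
                                 start_age, v0, pre_rate, during_rate) {
  ages <- c(pre_ages, during_ages)
  rate <- ifelse(ages <= start_age, pre_rate, during_rate)
  tkv <- v0 * exp(log1p(rate / 100) * (ages - start_age))
  tibble::tibble(patient_id = patient_id, age_years = ages,
                 sequence_id = "S1", tkv_ml = tkv,
                 covers_both_kidneys = TRUE)
}

# brute-force oracle: minimal within-cluster SS over ALL 2-partitions
brute_force_2partition <- function(values) {
  n <- length(values)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^n - 2)) { # skip the two empty-cluster codes
    assign <- as.integer(intToBits(code))[1:n]
    ss <- 0
    for (k in 0:1) {
      x <- values[assign == k]
      ss <- ss + sum((x - mean(x))^2)
    }
    if (ss < best - 1e-12) {
      best <- ss
      best_assign <- assign
    }
  }
  list(within_ss = best, assign = best_assign)
}

# independent ICC(2,1) oracle via R's two-way ANOVA mean squares
icc21_via_aov <- function(X) {
  d <- data.frame(y = as.vector(X),
                  subject = factor(rep(seq_len(nrow(X)), ncol(X))),
                  rater = factor(rep(seq_len(ncol(X)), each = nrow(X))))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(X); k <- ncol(X)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# six-patient eligibility roster: exactly one patient passes every criterion
eligibility_roster <- function() {
  mk <- function(id, pre, during, start) {
    tibble::tibble(patient_id = id, age_years = c(pre, during),
                   sequence_id = "S1", tkv_ml = 1000,
                   covers_both_kidneys = TRUE)
  }
  scans <- dplyr::bind_rows(
    mk("OK", c(38.0, 39.5), c(40.5, 41.7), 40),   # all criteria met
    mk("SPAN", c(39.0, 39.5), c(40.5, 41.7), 40), # pre span 0.5 y
    mk("ONEPRE", 39.0, c(40.5, 41.7), 40),        # single pre scan
    mk("DURSPAN", c(38.0, 39.5), c(40.2, 40.6), 40), # during span 0.4 y
    mk("INTR", c(38.0, 39.5), c(40.5, 41.7), 40),
    mk("CYST", c(38.0, 39.5), c(40.5, 41.7), 40)
  )
  patients <- tibble::tibble(
    patient_id = c("OK", "SPAN", "ONEPRE", "DURSPAN", "INTR", "CYST"),
    treatment_start_age = 40,
    interruption_gt_1mo = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    non_adherent = FALSE,
    cyst_event = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  list(scans = scans, patients = patients)
}
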