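# pkdresp

Assessing tolvaptan efficacy in **individual** ADPKD patients from serial
MRI total-kidney-volume (TKV) measurements.

Randomized trials established that tolvaptan slows kidney growth and eGFR
decline in autosomal dominant polycystic kidney disease *on average*, but a
nephrologist treating one patient needs to know whether *that* patient is
responding. With modern segmentation, TKV can be measured with ~1.3%
variability, which makes per-patient growth-rate estimation feasible:
`pkdresp` implements the resulting analysis pipeline as a set of
tibble-in/tibble-out functions, plus a seeded synthetic-cohort generator so
the whole pipeline is testable without patient data.

## The model

Kidney volume grows exponentially, so for each patient and each treatment
window (before / during tolvaptan) the per-visit mean TKV over usable MRI
pulse sequences is fit by ordinary least squares on the log scale,

&nbsp;&nbsp;&nbsp;&nbsp;log V(t) = a + b·t&nbsp;&nbsp;(t = age at scan, years),

and the slope is annualised as a compound growth rate
r = (e^b − 1) × 100 (% per year). The per-patient treatment effect is the
signed change Δ = r_during − r_pre (percentage points per year). The cohort
is dichotomised by **exact one-dimensional k-means** (k = 2) on Δ — a
deterministic scan over the contiguous splits of the sorted values, with no
random restarts — and the cluster with the lower mean Δ is labelled
*responder*. Downstream, the package provides the Mayo Imaging
Classification (1A–1E) from height-adjusted TKV and age, normality-routed
univariate group comparisons with Benjamini–Hochberg correction, a
multivariate logistic response model with Wald intervals, variance-inflation
factors and bidirectional stepwise-AIC selection, CKD-EPI 2021 eGFR with
group eGFR-decline slopes, and the paired pre/during power calculation.

## Worked example

```r
library(pkdresp)

cohort <- simulate_cohort(cohort_config(n_patients = 32, seed = 2026))
fits   <- fit_growth_rates(cohort$scans, cohort$patients)
calls  <- classify_responders(fits)

table(calls$label)
#> non-responder     responder
#>            15            17

glance(attr(calls, "cluster"))
#> # A tibble: 1 × 4
#>   split_value within_ss   gap     n
#>         <dbl>     <dbl> <dbl> <int>
#> 1      -0.900      175. 0.571    32

dplyr::summarise(dplyr::group_by(calls, label),
                 pre = mean(pre_rate), during = mean(during_rate),
                 delta = mean(delta))
#> # A tibble: 2 × 4
#>   label           pre during delta
#> 1 non-responder  3.92   6.69  2.76
#> 2 responder      5.87   1.47 -4.40
```

The 17 patients labelled responders slowed from 5.9 to 1.5 %/yr on
treatment (mean Δ ≈ −4.4 points), while the 15 non-responders accelerated;
the optimal split falls at −0.9 points per year. Their kidney function
diverges accordingly:

```r
slopes <- fit_group_slopes(delta_egfr_series(cohort$labs), labels = calls)
tidy(slopes)
#> # A tibble: 2 × 6
#>   label          slope std.error conf.low conf.high n_points
#> 1 responder     -0.266    0.0454   -0.355    -0.176      493
#> 2 non-responder -0.391    0.0459   -0.482    -0.301      435
```

eGFR declines ~0.27 mL/min/1.73 m²/yr in responders versus ~0.39 in
non-responders (47% faster in this draw). The paired design behind such a
study:

```r
sample_size_paired(cohen_d_paired(5.5, 2.8, 3.0), alpha = 0.01, power = 0.9)
#> <power_calc> d = 0.900, alpha = 0.01 (two-sided), power = 0.9 -> n = 18 (raw 18.37, truncate)
```

`autoplot()` methods draw the cluster-separation and eGFR-trajectory
figures; `run_full_pipeline()` executes every stage and writes the CSV/JSON
outputs plus a run manifest.

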