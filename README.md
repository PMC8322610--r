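# headtrunk

Analysis of head-trunk coordination for horizontal reorientation in an
acoustic virtual-reality steering task, for movement scientists studying
how early blindness affects the development of the adult "articulated"
head-trunk strategy.

Seated participants steer a virtual arrow (10 m/s, 60 m flight) toward a
pink-noise target at −15°, 0° or +15° azimuth, using head yaw alone
(*free* coordination) or head-minus-trunk yaw with voluntary trunk
immobilization (*forced*). The package implements the whole study as
tested code:

* **Task simulator** — trial geometry, trigger-window dwell rule (1–3 s),
  arrow state machine, acoustic feedback mappings, signed final error
  (endpoint-to-target distance, signed by the hemispace of the initial
  trajectory).
* **Synthetic cohort** — 10 "blind" (high head-trunk coupling κ ≈ 0.85,
  trunk damping γ ≈ 0.3 under forced coordination) and 11 "sighted" agents
  (κ ≈ 0.15, γ = 1), 4 conditions × 20 trials, with 90 Hz sampling jitter,
  dropout, IMU-like trunk drift and 0.1° quantization.
* **Kinematic measures** — resample at 90 Hz, 18-sample moving average,
  angular jerk (three central differences, deg·s⁻³), trunk jerk RMS, and
  the head-trunk cross-correlation peak after AR prewhitening
  (|r| maximized over lags within ±0.5 s).
* **Performance measures** — accuracy (median signed error), precision
  (IQR), Monte-Carlo Lilliefors normality screen.
* **Inference** — 2×2×2 mixed-design ANOVA on aligned-rank-transformed
  data (group between; direction, coordination within; partial
  η² = F·df₁/(F·df₁+df₂)), exact Mann-Whitney / Wilcoxon signed-rank
  post-hocs (authored null distributions, verified by full enumeration),
  Bonferroni correction, rank-biserial effect sizes
  (r = 2U/(n₁n₂) − 1; (2W − T)/T) with bootstrap confidence intervals.

## Worked example

```r
library(headtrunk)

# a small synthetic cohort through the full pipeline
res <- run_pipeline(cohort_spec(n_blind = 4, n_sighted = 4,
                                trials_per_condition = 5, rng_seed = 42))
aggregate(cbind(trunk_rms, cross_peak) ~ group + coordination,
          res$aggregated, median)
#>     group coordination trunk_rms cross_peak
#> 1   blind       forced  1471.569  0.5024860
#> 2 sighted       forced  1435.850  0.4358238
#> 3   blind         free  3587.682  0.9045886
#> 4 sighted         free  1422.838  0.4488614
```

High-coupling agents show a larger cross-correlation peak than
low-coupling agents in both coordination levels (their head and trunk
jerks are more similar), and their trunk jerk RMS drops under forced
coordination (the "damping" response to the immobilization demand), while
low-coupling agents are unaffected — the qualitative group pattern the
inference layer is built to detect:

```r
cp <- res$long_table[res$long_table$measure == "cross_peak", ]
art_anova(cp)[1:3, ]
#>         effect            F df1 df2            p partial_eta_sq
#> 1        group  18.60000000   1   6 5.022189e-03     0.75609756
#> 2    direction   0.06741573   1   6 8.038168e-01     0.01111111
#> 3 coordination 174.11575563   1   6 1.169903e-05     0.96668809
posthoc_suite(cp, "group:coordination", ci = FALSE)[, c(1, 3, 6, 7, 8)]
#>                  comparison statistic      p_raw p_adjusted  r_rb
#> 1 blind vs sighted | forced        10 0.68571429  1.0000000  0.25
#> 2   blind vs sighted | free        16 0.02857143  0.1142857  1.00
#> 3    forced vs free | blind         0 0.12500000  0.5000000 -1.00
#> 4  forced vs free | sighted         4 0.87500000  1.0000000 -0.20
```

The full-size study layout (10 + 11 participants, 20 trials per condition)
is the default `cohort_spec()`; `analysis/01_simulate.R` …
`analysis/04_stats.R` run it stage by stage, writing traces, per-trial
measures, the long analysis table and the JSON stats report under
`results/`. Real data enter the same path through
`import_final_dataset()`, a mapping-driven CSV importer.

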