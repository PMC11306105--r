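# growthlag

Quantifying how supplements shift the bacterial lag phase — and whether a
trace methylated compound can plausibly pay for it.

Algal-associated marine bacteria (e.g. *Phaeobacter inhibens*) start
growing hours earlier when trace amounts of methylated compounds such as
DMSP are present, without any change in growth rate. `growthlag` is for
microbiologists and biostatisticians analysing 96-well plate-reader growth
experiments of this kind. It provides:

* **Plate-reader ingest** — long/wide CSV dialects, instrument calibration
  (×3.8603 by default, microtitre → 1-cm-cuvette OD600), per-well
  background subtraction over a configurable non-growth window (2–8 h),
  and trimming to the growth span.
* **Logistic growth fitting** — least squares on
  N_t = K / [1 + ((K − N0)/N0) e^(−rt)], returning a `logistic_fit` object
  with the usual `print`/`summary`/`coef`/`predict`/`plot`/`simulate`/
  `residuals` methods.
* **Closed-form statistics** — lag time, defined as the time N_t reaches
  OD600 = 0.01: t = (−1/r)[ln((K−N_t)/(K−N0)) − ln(N_t/N0)]; doubling time
  from N_t = 2N0.
* **Δlag inference** — Δlag = mean control lag − mean treatment lag
  (positive = shortening), with uncertainty σ = sqrt(σ₁²/n₁ + σ₂²/n₂) and
  ANOVA + Dunnett many-to-one adjusted p-values.
* **Per-cell C1/ATP budget** — assimilatory one-carbon demand (190.1
  amol C1/cell by default), dissimilatory ATP demand (85 mmol/gDW × 280 fg
  = 23,800 amol/cell), and percent coverage by an external methyl supply.
* **Expression-table filters** — TPM conversion, top-k abundance ranking,
  DE thresholds (padj ≤ 0.05, |log2FC| ≥ 0.585), ≥50 mean TPM floor.
* **Synthetic data** — plate and feature-table generators with exact
  closed-form ground truth, used throughout the test suite.

## Worked example

Simulate a plate with a known 2.5 h lag shortening at four replicates per
condition, then run the full file-based analysis:

```r
library(growthlag)

sim <- simulate_plate(plate_config(seed = 101))   # control vs treatment
path <- tempfile(fileext = ".csv")
write_plate_csv(sim, path, "long")

series <- read_plate_table(path, "long", sim$layout)
curves <- lapply(calibrate_absorbance(series, 3.8603),
                 function(s) trim_to_growth_span(subtract_background(s, c(2, 8))))
fits <- lapply(curves, fit_logistic)
summary(fits$A1)
#> Logistic growth fit — well A1, condition 'control'
#>   K = 0.5011  N0 = 9.757e-08  r = 0.8012 /h   (SSE 0.00061)
#>   lag time (OD 0.01): 14.425 h   doubling time: 0.865 h   RMSE 0.0029

compare_lag_times(fits, control = "control")
#>   treatment control n_treat n_ctrl mean_lag_treat_h mean_lag_ctrl_h delta_lag_h
#> 1 treatment control       4      4         11.91842        14.41841    2.499992
#>    sd_diff_h delta_doubling_h   p_adjusted significance
#> 1 0.02901672     8.565279e-05 1.646798e-10          ***
```

The fitted K, N0 and r recover the generating parameters; the control lag
of 14.42 h minus the treatment lag of 11.92 h gives Δlag ≈ 2.50 h
(`2.5 (±0.0)` in table formatting), the injected truth, detected at
p ≤ 0.001 while the doubling-time difference is ~0.0001 h — the signature
of a lag-specific effect.

The stoichiometric side of the story:

```r
budget <- c1_budget()                    # 190.1 amol C1; GAM-derived ATP
coverage(supply_scenario("DMSP", 2e-9, 2, 25000), budget)
#> <coverage_result> DMSP supplies 160 amol C1 per cell
#>   covers 84% of assimilatory C1 needs, 0.7% of dissimilatory ATP needs
```

2 nM DMSP shared among 25,000 CFU/ml provides 160 amol of methyl groups
per cell: enough to cover ~84% of the one-carbon building-block demand of
a duplication but under 1% of its ATP demand — trace methyl donors act
through biosynthesis, not energy.

See `vignettes/growthlag-methods.Rmd` for the models, defaults and their
rationale.

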