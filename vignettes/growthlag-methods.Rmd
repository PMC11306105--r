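---
title: "Models and methods behind growthlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind growthlag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthlag)
```

## The question the package answers

Marine heterotrophic bacteria such as *Phaeobacter inhibens* respond to
trace concentrations of algal methylated compounds (DMSP, betaine and
relatives) by starting to grow earlier: the lag phase shortens while the
exponential growth rate stays put. `growthlag` packages the quantitative
machinery needed to measure that effect from 96-well plate-reader data and
to rationalise it with a per-cell methyl-group budget.

## Growth model

Each well's background-corrected OD600 series is fitted to the logistic
equation

$$N_t = \frac{K}{1 + \frac{K - N_0}{N_0}\,e^{-rt}}$$

with carrying capacity $K$, effective initial size $N_0$ and intrinsic rate
$r$ (per hour). Two derived statistics are obtained in closed form rather
than numerically:

* **lag time** — the time at which $N_t$ reaches a fixed threshold
  (default 0.01 OD600 on the background-subtracted scale),
  $t = (-1/r)\left[\ln\frac{K - N_t}{K - N_0} - \ln\frac{N_t}{N_0}\right]$;
* **doubling time** — the solution of $N_t = 2N_0$,
  $t = (-1/r)\left[\ln\frac{K - 2N_0}{K - N_0} - \ln 2\right]$, which tends
  to $\ln(2)/r$ when $N_0 \ll K$.

Both formulas are verified against bisection root-finding on the forward
curve in the test suite (agreement to $10^{-8}$ h over randomized
parameters).

$N_0$ is an *effective* parameter: a culture inoculated from stationary
phase grows later than its cell count alone predicts, and the fit absorbs
that physiological delay into a small $N_0$. Fitted values far below the
nominal inoculum OD are therefore expected and meaningful. If a fitted
$N_0$ exceeds the lag threshold the closed form yields a negative lag; it
is reported as-is (never clamped) so that differences between conditions
remain well defined.

## Preprocessing conventions

* **Calibration.** Plate absorbances are multiplied by an
  instrument-specific factor (default 3.8603) mapping the microtitre path
  length onto the 1-cm-cuvette OD600 scale. The factor is a configuration
  constant; re-measure it for other instruments.
* **Background.** The mean absorbance over the stable non-growth window —
  default 2–8 h, configurable because the flat phase depends on the
  inoculum — is subtracted *per well*, never plate-wide. Negative
  corrected values are retained; clipping at zero would bias $N_0$ upward.
* **Trimming.** The fit sees the contiguous span from the global minimum to
  the global maximum OD600. If the maximum precedes the minimum the well
  never grew; it is flagged non-growing and excluded from lag statistics,
  as are wells whose dynamic range falls below a floor (default 0.02 OD).

## Fitting

`fit_logistic()` minimises the residual sum of squares with the
Levenberg–Marquardt algorithm (`minpack.lm`), parameterised in
$(\log K, \log N_0, \log r)$ so positivity is structural rather than
bound-enforced. Starting values come from the data: $K$ from the curve
maximum, and $r$ and $N_0$ from the slope and intercept of a log-linear
regression over the exponential window (readings between 10% and 70% of
the maximum). The intercept route matters: on realistic curves with a long
noisy flat phase, the smallest positive reading reflects the noise floor,
not the initial population, and adjacent-point log-slopes are dominated by
noise. Convergence uses a relative SSE tolerance of $10^{-10}$ with up to
1,000 iterations.

## Lag statistics

For each condition the per-replicate lag times are summarised by their
sample mean and standard deviation ($n-1$ denominator). The effect of a
supplement is

$$\Delta\mathrm{lag} = \bar t_{\mathrm{control}} - \bar t_{\mathrm{treatment}},$$

positive when the supplement shortened the lag, with uncertainty propagated
as the standard deviation of the estimated difference between means,
$\sigma_{M_1-M_2} = \sqrt{\sigma_1^2/n_1 + \sigma_2^2/n_2}$. Significance
comes from a one-way ANOVA followed by Dunnett's two-sided many-to-one
comparisons against the control (`multcomp::glht`), which share the pooled
error variance across the conditions supplied in one call and control the
family-wise error over the $K-1$ treatments. Categories: `***` ≤ 0.001,
`**` ≤ 0.01, `*` ≤ 0.05, `NS` above — the `*` band is included because
"not significant" beginning above 0.05 implies 0.01–0.05 is significant.
Doubling times run through the identical machinery, since supplements are
expected to leave them unchanged.

## Per-cell one-carbon budget

The stoichiometric module asks how far an external methylated compound can
go towards a duplicating cell's needs. Two demands are computed:

* **Assimilatory C1** — the one-carbon groups built into biosynthetic end
  points (the seven canonical sinks: ATP, GTP, dATP, dGTP, dTTP, histidine,
  methionine). A sink table (per-cell amol × net C1 per molecule, summed)
  can be supplied as a CSV; because the per-sink source data live in
  supplementary material not redistributed here, the default is a
  fallback-constant mode using the published total of 190.1 amol C1 per
  cell. The CSV in `inst/extdata/synthetic_c1_sinks.csv` is a synthetic
  illustration of the format, not a transcription of the source data.
* **Dissimilatory ATP** — the growth-associated maintenance cost
  (GAM, default 85 mmol ATP/gDW) converted per cell via the dry weight
  (default 280 fg); the conversion is the exact identity
  1 mmol/g × 1 fg = 1 amol, giving 23,800 amol ATP per cell. One ATP per
  dissimilated methyl group is assumed (formate–THF ligase route),
  overridable.

Supply is medium concentration × methyl groups per molecule ÷ cell density
(CFU equated with cells). Coverages are kept at full precision; the print
method rounds to the conventional display (integer percent assimilatory,
one decimal dissimilatory). For 2 nM DMSP shared among 25,000 CFU/ml the
supply is 160 amol/cell — about 84% of the assimilatory and 0.7% of the
dissimilatory demand, which is the quantitative argument that trace methyl
donors act through biosynthesis, not energy.

## Expression-table filters

The RNA-seq module implements only downstream numeric rules on an input
feature table (DE statistics are inputs, not computed — count modelling and
shrinkage belong to dedicated DE packages): rRNA-flag removal; TPM
conversion (counts ÷ length, rescaled per sample to sum to $10^6$); top-k
ranking of a tagged gene set by mean TPM with deterministic lexicographic
tie-breaks; a DE filter with *inclusive* thresholds padj ≤ 0.05 and
|log2FC| ≥ 0.585 (a 1.5-fold change); and an abundance floor of ≥ 50 mean
TPM in at least one sample group, with groups interpreted as sampling
points. Compute TPM once on the full table before filtering if you need
the DE and abundance filters to commute — TPM recomputed on a subset
renormalises to the subset.

## Synthetic data and what passing tests show

`simulate_plate()` generates raw readings as
$(N_t + \mathrm{background} + \varepsilon)/\mathrm{factor}$ with additive
Gaussian noise, mimicking a 20-min read cycle over 30 h. Defaults encode
the study conditions of interest: $K = 0.5$, $r = 0.8$/h, control
$N_0 = 10^{-7}$ (lag ≈ 14.4 h, comfortably beyond the 2–8 h background
window so the pre-growth phase is genuinely flat), noise sd 0.003 OD,
four replicates per condition, and a treatment whose lag is shortened by
2.5 h — the largest effect size of interest. Lag effects are injected by
adjusting $N_0$ through the closed-form inverse (`lag_effect_via_n0`), so
the generative model stays inside the fitted family and exact ground truth
exists; a rigid `time_shift` mode is provided as a deliberate
model-misspecification stressor. One global seed drives all draws in fixed
well order, so output is bit-reproducible.

Problem sizes used by the validation suite — 200 simulated plates for
delta-lag recovery and power, 1,000 trials for Dunnett calibration, 1,000
random parameter sets for the closed-form/bisection comparison, a
1,000-gene table for filter determinism — are large enough for the
Monte-Carlo error on each property to be well below its margin.

The generator emulates measurement noise and lag shifts, not everything
real plates do: no well-to-well carrying-capacity variation, no plate
edge effects or drift, no evaporation optics, no biological replicate
heterogeneity beyond the injected effect. Passing the recovery and power
properties therefore demonstrates the estimator and test machinery are
correct and well calibrated under the stated noise model — not that any
particular wet-lab effect size will reproduce.

## Known limitations

* One growth model: no Gompertz/Baranyi alternatives or model selection.
* Single-plate inference: no mixed-effects or batch correction across
  plates; Dunnett pools variance over the conditions passed in one call.
* The lag threshold interacts with background subtraction: 0.01 OD is
  interpreted on the background-subtracted scale and should be revisited
  if the calibration factor changes substantially.
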