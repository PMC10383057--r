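---
title: "Quantifying metabolites with weighted calibration and relative response factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolites with weighted calibration and relative response factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrfquant)
```

## The problem

Targeted LC-MS metabolomics can measure hundreds of metabolites per
injection, but turning peak areas into concentrations is the bottleneck.
Classical external calibration (EC) needs a multi-level standard series per
compound in neat solvent, and its accuracy degrades in biological matrices
where co-eluting components suppress (or enhance) electrospray ionization.
The alternative implemented here is single-point internal calibration via
relative response factors (RRF): characterize each metabolite's ionization
efficiency once, relative to a stable-isotope-labeled reference compound,
and from then on quantify any sample from the analyte/reference area ratio
in that same injection.

`rrfquant` implements both routes and the machinery around them:
weighted external calibration with a back-calculation bias filter, LOD/LOQ
estimation, reference-compound selection among internal standards, RRF
computation and single-point quantification, ion-suppression evaluation,
and AutoQC-style system-suitability metrics. A synthetic LC-MS response
simulator with known ground truth makes every stage testable end to end.

## The model

For a metabolite $m$, the standard series is fitted with a weighted
straight line $y = a + b\,x$ ($y$ peak area, $x$ concentration in µM),
minimizing $\sum_i w_i (y_i - a - b x_i)^2$ with $w_i = 1/x_i$ by default.
LC-MS replicate noise is approximately proportional to the signal, so over
a 3.5-decade series ($0.03$–$100$ µM) unweighted least squares would fit
the top levels at the expense of the bottom ones; $1/x$ weighting restores
the low end's influence.

A reference compound $r$ — an internal standard spiked at a fixed
$c_r = 1.25$ µM into every sample — has a single-point response factor

$$\mathrm{RF}_r = \frac{\bar A_r}{c_r},$$

the mean peak area over all replicate injections divided by the spike
concentration. The relative response factor of metabolite $m$ against $r$
is the dimensionless ratio

$$\mathrm{RRF}_{m,r} = \frac{b_m}{\mathrm{RF}_r},$$

and single-point quantification of $m$ in any sample $s$ is

$$\hat c_m(s) = \frac{A_m(s)\, c_r}{A_r(s)\, \mathrm{RRF}_{m,r}}.$$

Because $A_m$ and $A_r$ come from the same injection, any multiplicative
response change shared by analyte and reference — matrix suppression,
spray drift, detector gain — cancels in the ratio. Two exact algebraic
consequences (both enforced by tests): if analyte and reference share a
suppression factor $s$, RRF quantification is unbiased while EC
under-reads by exactly the factor $s$; if they differ ($s_a$, $s_r$), the
RRF estimate is biased by exactly $s_a/s_r$. Reference choice therefore
matters, and isotope-matched references (the analyte's own heavy-labeled
form) are tagged as a distinguished tier in the output.

## Calibration curation

Each curve goes through one curation pass:

1. A reference line is fitted on the lowest `min_points` (default 3)
   concentration levels.
2. Every level's mean back-calculated accuracy,
   $100 \cdot ((\bar A - a)/b)/x$, is computed against that line.
3. Levels outside the closed band $100 \pm 15\%$ (i.e. 85–115%) are
   excluded, with the reason recorded.
4. The curve is refitted once on all replicate points of the surviving
   levels.

The curve is *quantifiable* when the refit weighted $R^2$ exceeds 0.9,
at least `min_points` levels survive, and the slope is positive;
otherwise it is reported with a reason rather than raising an error.

Why a low-anchored reference line rather than a fit of all levels? With
$1/x$ weighting a point's leverage on the slope is $w x^2 = x$, so the top
levels dominate any global fit. When the top of the series saturates, the
global line tilts toward the saturated region and the *clean* low levels
appear biased — on an 8-level series whose 100 µM level responds at half
its linear value, a global reference line reads every clean mid level at
~134% and would exclude nearly everything except the saturated points.
Anchoring on the lowest levels, where response is linear by construction,
lets the filter remove exactly the saturated levels. The pass runs once;
iterating exclusion to a fixed point can cascade (or re-admit) exclusions
unpredictably and is deliberately avoided.

Two ambiguities are resolved as follows: the fit uses all replicate points
individually (not per-level means), which preserves the heteroscedasticity
rationale for $1/x$; and exclusion operates on whole concentration levels,
not single replicates. The 85% and 115% boundary values are *included*
(closed interval). The weighted $R^2$ is
$1 - \sum w\,e^2 / \sum w\,(y - \bar y_w)^2$ with $\bar y_w$ the weighted
mean — other tools leave their formula undocumented, so ours is stated and
tested.

A limitation worth stating plainly: a bias filter with a ±15% band keeps
levels whose true response is up to ~15% attenuated. Under deep saturation
(hyperbolic response with midpoint $c_{50} = 50$ µM, where even the 6 µM
level is ~11% attenuated) the refit slope on the surviving levels is
systematically below the true response factor by roughly 9–15%, whichever
reasonable variant of the filter is used — we verified this bound holds
even for an oracle filter that judges levels against the true line. The
filter removes grossly saturated levels; it cannot make mildly saturated
data linear.

## LOD and LOQ

The LOD extrapolates the fitted line to the concentration where the
expected response reaches `sn_lod_threshold` (default 2) times the noise
level: $x = (\mathrm{S/N_{thr}} \cdot \mathrm{noise} - a)/b$. "Noise" is
not defined by convention everywhere; the default here is the mean blank
peak area for the metabolite (fallback: maximum blank area; undefined
without blanks). Extrapolation can give non-positive solutions when the
intercept already exceeds the noise threshold; these are not meaningful
detection limits and are returned as `NA` with a reason rather than
reported — in practice a substantial fraction of metabolites get no
defined LOD this way, which mirrors what line-extrapolation LODs do on
real data.

The LOQ is the lowest standard level whose mean replicate area exceeds a
detection threshold, by default the blank mean + 3 SD (fallback: any
positive mean area counts as identified). Both definitions are
operational choices exposed in the configuration, and both are
"mathematical" limits that would need experimental confirmation in a real
validation.

## Reference selection

Internal standards are summarized per polarity over the standard-series
injections (where their spike is the only source of signal); blanks are
excluded, and a configuration switch (`reference_scope`) allows matrix
runs or all runs instead. The `n_references` (default 6) candidates with
the smallest peak-area CV are selected, ties broken lexicographically by
id so pipelines are reproducible. RF uses the single-point mean-area
ratio, not a fitted IS slope; `rf_from_slope = TRUE` enables the
slope-based variant for sensitivity analysis. In Eq. 2 the reference area
is taken from the same injection as the analyte (per-replicate pairing);
`rrf_reference_area = "mean"` switches to per-sample mean reference areas.

## The synthetic-data generator

`synth_spec()` draws a true response factor per compound log-uniformly
over `rf_range` (default $10^3$–$10^5$ area·µM⁻¹, a plausible span of
ionization efficiencies), and generates

$$A = \left[\frac{\mathrm{rf}\cdot c}{1 + c/c_{50}} + a_0\right]
      \cdot s \cdot e^{\varepsilon},
  \qquad \varepsilon \sim N(-\tfrac{\sigma^2}{2},\, \sigma^2),$$

with $\sigma^2 = \log(1 + \mathrm{CV}^2)$ so the noise is multiplicative,
lognormal, and mean-unbiased; $s$ is the per-compound matrix suppression
factor (1 outside matrices). Defaults mirror the validated study design:
8 levels at 0.03, 0.3, 3, 6, 12, 25, 50, 100 µM, triplicate injections, a
17-compound labeled amino-acid internal-standard panel spiked at 1.25 µM,
and 2% replicate noise in the `clean` preset. Saturation uses the
one-parameter hyperbola above — the simplest monotone model that induces
level exclusion by the bias filter. The `suppressed_plasma` preset draws
per-compound suppression log-uniformly in (0.2, 0.95), the qualitative
spread between weakly and strongly suppressed amino acids in plasma.

What the generator does *not* emulate: chromatographic peak shapes, RT
drift structure, isotope patterns, ion-ratio interferences, additive
electronic noise, carryover, or any correlation of suppression with
chemistry. Passing tests on this generator therefore demonstrate the
*algebra and statistics* of the workflow — recovery of known response
factors, exact suppression cancellation, weighting behavior — not
performance on real chromatograms.

## Numerical and degenerate-input choices

* Weighted fits require ≥ 2 distinct concentrations; reciprocal weighting
  requires strictly positive concentrations. All-equal responses give
  $R^2 = 1$ if residuals vanish, else 0.
* Fewer than `min_points` surviving levels, a non-positive slope, or an
  $R^2$ at or below the gate produce `quantifiable = FALSE` with a reason
  string — never an exception — so one dead metabolite cannot abort a run.
* Negative EC concentrations are reported with a `below_zero` flag, not
  clamped; truncation would bias replicate-CV summaries.
* Replicate CV with zero mean is `NA` (flagged undefined).
* Ion suppression with a zero solvent area is a typed error; negative
  suppression (enhancement) is flagged, not dropped.
* All randomness flows from explicit seeds; generation restores the
  caller's RNG state. Identical configuration and inputs give
  byte-identical CSV outputs.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at 5–50
metabolites with the 8-level triplicate design (a few thousand measurement
rows per scenario) and 200–1000 random point sets for the regression
oracle checks. These sizes give stable medians and sub-minute runtimes;
the engine itself is linear in the number of measurement rows and has been
run comfortably at panel sizes in the hundreds of metabolites.

## A worked example

```{r example, eval = FALSE}
spec <- scenario_presets("clean", n_metabolites = 10, seed = 42)
std <- generate_standard_series(spec)
cfg <- run_config(seed = 42)

cal <- calibrate_run(std$measurements, std$transitions, cfg)
refs <- select_references(
  summarize_references(std$measurements, std$transitions, cfg),
  cfg$n_references)
rrf <- build_rrf_table(cal$curves, refs)
quant <- quantify_run(std$measurements, cal$curves, refs, rrf, cfg,
                      sample_types = "standard")
compare_methods(quant)$method_summary
```

The same stages are available as file-to-file commands (`rrfq_synth()`,
`rrfq_calibrate()`, `rrfq_rrf()`, `rrfq_quantify()`, `rrfq_qc()`) and via
the bundled CLI script (`system.file("cli", "rrfquant.R", package =
"rrfquant")`).

## Known limitations

* Only singly charged `[M+H]+` / `[M-H]-` adducts are supported; other
  adducts are rejected explicitly rather than silently mis-massed.
* Peak areas are consumed as exported (no background subtraction or
  re-integration); peak width is accepted as an input column but never
  computed — there are no chromatograms at this layer.
* Nonlinear (quadratic, log-log) calibration models are out of scope; the
  response is modeled as linear within the surviving levels.
* LOD/LOQ values are mathematical extrapolations of the fitted line and
  blank statistics, not experimentally confirmed limits.
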