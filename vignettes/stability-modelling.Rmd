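---
title: "Stability modelling of probiotic powders: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability modelling of probiotic powders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probistab)
```

## The model and its assumptions

`probistab` implements the classical two-step approach of predictive
microbiology for the loss of viability of dried bacteria in storage.

**Step 1 — first-order inactivation per temperature.** The viable count
`Nt` (CFU/g) is assumed to decay exponentially, so the log-ratio is linear
in time:

$$\ln\!\frac{N_t}{N_0} = -k\,t,$$

with `k` the destruction rate in months⁻¹. The decimal-reduction times
follow directly: `D1 = ln(10)/k` (time for a 90 % drop), `D2 = 2 D1`,
`D3 = 3 D1`. First-order kinetics is an assumption, not a finding of the
fit: survival curves with shoulders, tails or biphasic behaviour (common
after severe processing stress) are *not* representable, and the per-fit
R² is the only in-package diagnostic of that misfit. Weibull or
log-logistic alternatives are deliberately out of scope.

**Step 2 — Arrhenius dependence of the rate on temperature.** The fitted
rates at several storage temperatures are regressed as

$$\ln k = \ln A - \frac{E_a}{R}\cdot\frac{1}{T},$$

with `T` in Kelvin (`T_K = T_{°C} + 273.15`) and `R = 8.314` J mol⁻¹ K⁻¹
exactly. The activation energy `Ea = -slope × R` measures how strongly heat
accelerates viability loss; the frequency factor `A = exp(intercept)`
anchors the absolute rate. The fitted line is then evaluated at any
temperature — including temperatures *outside* the fitted range, which is
the entire point of accelerated stability testing. Extrapolations are
flagged in the result, never refused.

From the two steps together the package predicts counts at any (T, t),
solves shelf-life `t* = ln(N0/N_min)/k`, and evaluates a new batch against
a reference kinetic (below).

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `fit_mode` | — | `free_intercept` | the time-0 aggregate is itself a noisy measurement; forcing the line through 0 transfers its error into the slope. `through_origin` is available because the ratio form fixes ln(N0/N0) = 0 by construction. |
| `replicate_aggregation` | — | `mean_log` | averaging ln(count) across replicates equals plotting the geometric mean on a log scale, the convention for plate counts; `pooled` keeps each replicate's own series for uncertainty work. |
| `acceptance_band` | fraction | 0.30 | the commonly accepted overall variability of plate counts, bundling biological variability, sampling and serial dilution. |
| `lod_policy` | — | `drop` | counts at the detection limit carry no usable magnitude; halving the limit (`substitute_half_lod`) is offered as the conventional imputation. |
| `report_sig_figs` | — | 2 | kinetic parameters are conventionally quoted at two significant figures; all computation is full precision and rounding happens only at presentation. |

## Batch evaluation

A new batch is compared against a reference Arrhenius model by setting its
fitted rates against the rates the reference predicts at the same
temperatures. Two summaries are produced:

- **band verdicts**: each observed value must satisfy
  `|observed − predicted| ≤ band × predicted`. The band is applied relative
  to the *predicted* value so that the verdict is well defined (the
  measured value has no privileged uncertainty scale of its own).
- **the guiding coefficient**: the slope of a through-origin regression of
  observed on predicted k, `Σ(obs·pred)/Σ(pred²)`, with its uncentered R².
  Through-origin is the right choice because the claim under test is
  proportionality — a batch that decays, say, 20 % faster at every
  temperature should show a coefficient of 1.2, not an intercept offset.
  Free-intercept diagnostics are attached for reference when three or more
  pairs are available.

The robustness question — does a 6-month study give the same kinetic as a
12-month one? — is answered by `truncation_robustness()`, which reruns the
whole pipeline on the same study truncated at each horizon and reports
relative differences per rate and in Ea. The package's `concordant` verdict
requires *both* every per-temperature Δk/k and ΔEa/Ea within the threshold
(default 15 %, configurable); note that short-horizon rates at the coldest
temperature are intrinsically the noisiest (little decay has happened over
few checkpoints), so the Ea comparison is the stabler summary and the
per-temperature deltas are diagnostic.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure of a plate-count
stability study so every stage is testable without laboratory data:

- **truth**: exponential decay per temperature, with rates given directly
  or derived from an (Ea, A) pair; checkpoint grids default to the ICH-style
  schedules of `ich_schedule()` (long-term arms at 20/25/30 °C every
  3 months, an accelerated 40 °C arm monthly).
- **biological variability**: each replicate's starting count N0 is
  lognormal with geometric mean `N0_mean` (default 1e10 CFU/g, a typical
  probiotic powder load) and CV `biological_cv` (default 0.30). The draw is
  per replicate and constant over time — a level shift in log space — which
  is why it barely degrades slope recovery; an optional lognormal CV on k
  (`k_cv`, default 0) makes replicates differ in kinetics too.
- **counting noise**: plate counting after serial dilution is emulated as a
  single effective Poisson layer. At the starting count a plate carries
  `plated_volume_equivalent` expected colonies (default 200, the middle of
  the 30–300 countable range); the observed CFU/g is the Poisson draw
  rescaled, so it is unbiased with relative error growing as counts decay.
  Zero-colony draws are recorded at the one-colony detection limit with
  `below_lod = TRUE`. The explicit 10-fold dilution chain is not simulated;
  its extra variance is regarded as part of `biological_cv`.

What passing tests on this generator do **not** show about real data: real
studies can violate first-order kinetics, have between-batch variance
distinct from within-batch variance (the generator exposes a single CV
knob), and pair temperature with humidity, which is not modelled at all.

## Numerical choices

- All fits are ordinary least squares (`stats::lm`); the Arrhenius fit is
  unweighted, as the near-unity R² values typical of these data make
  weighting by the per-rate uncertainty immaterial.
- R² is the standard centered `1 − SSE/SST` for free-intercept fits and the
  uncentered `1 − SSE/Σy²` for through-origin fits, where the centered
  version is ill-defined.
- Natural logarithms throughout; D-values re-express the kinetics in
  log10 decades for intuition.
- Temperatures within 0.01 °C are grouped as one storage condition, so
  float-valued keys cannot fragment a series.
- CSV output writes doubles as `%.17g`, making write→read an exact identity.
- Degenerate inputs fail loudly and early: all-equal times are a singular
  design; free-intercept fitting needs ≥3 points and through-origin ≥2;
  non-positive rates cannot enter the Arrhenius log and are rejected;
  a non-decaying series (k ≤ 0) is flagged and carries no D-values rather
  than failing the pipeline.

## Problem sizes used in the checks

The test-suite and the acceptance script work at desk scale by design:
published rate tables (three temperatures), simulated studies of 3
replicates on the 7-checkpoint long-term grid (63 observations), 10⁴
replicate draws for the CV calibration check and 10⁵ draws for the
counting-noise moments. The full suite runs in seconds on one CPU.

## Known limitations

- Strictly first-order, temperature-only kinetics: no humidity covariate,
  no non-Arrhenius temperature models (Eyring, square-root), no shoulders
  or tails.
- Rounded published rates propagate: an Arrhenius line refitted from rates
  quoted at two significant figures reproduces an extrapolated accelerated
  rate only to within a few percent of the value obtained from the original
  unrounded fit, and D-values recomputed from rounded k differ visibly from
  D-values computed from unrounded k (e.g. ln 10/0.03 = 76.8 vs a published
  80.2 months). The package always computes from its own inputs and does
  not attempt to reproduce numbers that depend on unpublished precision.
- Confidence intervals are limited to the propagated OLS slope standard
  error (`k_se`); no bootstrap or Bayesian machinery.
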