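# probistab

Mechanistic shelf-life prediction for dried probiotic products from
plate-count stability studies.

## The problem

Probiotic powders and capsules must guarantee a minimum viable dose (CFU/g)
until expiry, and stability guidelines (ICH Q1A) require long real-time
follow-up — typically 12 months at several storage temperatures — before a
shelf-life claim can be made. Predictive microbiology offers a shortcut: if
viability loss follows known kinetics, rates measured over a shorter window
at a few temperatures determine the product's behaviour at *any* temperature
and time, so stability can be forecast instead of waited out. `probistab`
implements that workflow for quality and formulation scientists working with
freeze-dried bacteria: it fits the kinetics, extrapolates them, predicts
counts, solves for shelf-life and formalises the accept/reject comparison of
a new batch against a reference kinetic.

## The model

Two classical equations are chained:

1. **First-order viability loss** at each storage temperature:
   `ln(Nt/N0) = -k t`, with `Nt` the viable count (CFU/g) after `t` months
   and `k` the destruction rate (months⁻¹). The decimal-reduction time —
   the time for a 90 % drop — is `D1 = ln(10)/k`, with `D2 = 2 D1` and
   `D3 = 3 D1` for 99 % and 99.9 % reductions.

2. **Arrhenius temperature dependence** of the rate:
   `k = A exp(-Ea/(R T))`, linear as `ln k` versus `1/T` (T in Kelvin,
   R = 8.314 J mol⁻¹ K⁻¹). The slope gives the activation energy `Ea`; the
   fitted line yields `k` at any temperature, including accelerated
   conditions (40 °C) outside the fitted range.

From the two together: predicted counts `Nt = N0 exp(-k t)` at any (T, t),
shelf-life `t* = ln(N0/N_min)/k` against a specification limit `N_min`, and
a batch-evaluation procedure in which observed rates are compared to
predicted ones with a ±30 % relative band and a through-origin *guiding
coefficient* (slope of observed on predicted k, 1 under perfect agreement).

## Worked example

Fit the Arrhenius model to destruction rates measured on a marketed
probiotic capsule at the three long-term storage temperatures, then
extrapolate to the accelerated condition:

```r
library(probistab)

ref <- fit_arrhenius(data.frame(temperature_C = c(20, 25, 30),
                                k = c(0.03, 0.08, 0.19)))
ref
#> Arrhenius fit of ln k vs 1/T (3 temperatures, 20-30 degC)
#>   Ea = 140 kJ/mol   (full: 136.41434)
#>   A  = 6.179e+22 months^-1
#>   R2 = 0.9993

predict_k(ref, 40)          # accelerated condition, flagged as extrapolated
#> [1] 1.085493  (attr extrapolated: TRUE)

predict_viability(ref, N0 = 1e10, time = 12, temperature = 25)
#> Predicted viability at t = 12 months, T = 25 degC
#>   k used = 0.07777 months^-1;  ln(Nt/N0) = -0.9332
#>   Nt = 3.93e+09 CFU/g  [band +/-30%: 2.75e+09 - 5.11e+09]

shelf_life(ref, N0 = 1e10, N_min = 1e9, temperature = 25)
#> [1] 29.6   # months to fall one decade
```

The activation energy of ~140 kJ/mol says this product's viability loss is
strongly temperature-accelerated; a one-decade drop that takes ~30 months at
25 °C takes about 2 months at 40 °C. A new batch whose measured 40 °C rate is
1.17 months⁻¹ against a predicted 1.15 passes the ±30 % band with a guiding
coefficient of 1.017:

```r
band_check(1.17, 1.15, band = 0.30)
#> [1] TRUE
```

The whole pipeline also runs end to end on simulated data — exponential
decay, lognormal between-replicate variability, Poisson plate-count noise on
an ICH checkpoint grid:

```r
cfg <- synthetic_study_config(
  Ea = 140e3, A = arrhenius_frequency_factor(140e3, 0.08, 25),
  schedule = ich_schedule("long_term"), seed = 1)
run_characterize(simulate_study(cfg))
#> -- kinetic parameters per temperature --
#>  temperature_C          k ... r_squared n_points       D1
#>             20 0.02864490 ... 0.9643806        7 80.38377
#>             25 0.08456269 ... 0.9980412        7 27.22933
#>             30 0.20927030 ... 0.9972613        7 11.00292
#> -- Arrhenius model --
#>   Ea = 150 kJ/mol   (full: 146.99098)   R2 = 0.9983
```

The recovered Ea of 147 kJ/mol sits within 5 % of the generating 140 kJ/mol
despite 30 % biological noise — the level of agreement the package's
acceptance checks require.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/probistab-cli` (subcommands `simulate`, `fit-kinetics`,
`fit-arrhenius`, `predict`, `shelf-life`, `compare`, `robustness`,
`characterize`, `evaluate-batch`).

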