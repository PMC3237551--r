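# mase

Dissociation kinetics of protein complexes from metabolically labeled
subunit exchange.

## The problem

The dissociation rate constant k_off of a protein complex — how fast the
bound complex falls apart, in s⁻¹ — is hard to measure for most complexes:
surface plasmon resonance needs purified, immobilizable material, and
stopped-flow needs an engineered fluorescence switch. Subunit exchange
offers a lysate-level alternative. Mix a lysate containing an
affinity-tagged, isotopically *unlabeled* complex A·B with one containing
the untagged, ¹⁵N-*labeled* complex. As complexes dissociate and re-form,
the tagged subunit acquires labeled partners, and the abundance ratio of
hybrid to original tagged complex,

    R_t = [AᵀU·B_L] / [AᵀU·B_U],

measurable by affinity purification plus quantitative proteomics, rises
from 0 toward 1. With equivalent lysates the free-subunit pool is constant
throughout, and R_t follows the one-parameter curve

    R_t = (1 − e^(−k_off·t)) / (1 + e^(−k_off·t)) = tanh(k_off·t / 2),

which depends on k_off **alone** — not on k_on, concentrations, or
purification efficiency. Fitting this curve to a measured time series
estimates k_off directly in crude lysate. The package is for proteomics
and biophysics groups designing or analyzing such exchange experiments.

It provides:

* `exchange_ratio()`, `invert_ratio()`, `exchange_sensitivity()` — the
  closed-form curve, its single-point inversion, and the information each
  sampling time carries (peak at t ≈ 1.543/k_off);
* `simulate_exchange()` — the full 8-species mass-action ODE of lysate
  equilibration, 1:1 mixing, and exchange (the brute-force oracle), with
  `verify_propositions()` checking the structural assumptions numerically;
* `simulate_exchange_stochastic()` — an exact event-driven (Gillespie)
  realization in copy numbers, for small-copy-number behavior;
* `sample_series()` / `default_design()` — synthetic noisy ratio series
  emulating median-of-peptides isotope-ratio quantification;
* `fit_koff()` — weighted least-squares estimation of k_off with
  residual-bootstrap confidence intervals, returning a model object with
  the standard `print`/`summary`/`coef`/`confint`/`predict`/`plot`/
  `residuals`/`simulate` methods;
* a command-line interface (`inst/scripts/mase.R`) with subcommands
  `simulate`, `simulate-stochastic`, `sample`, `fit`, `curves`, `verify`.

## Worked example

```r
library(mase)

# 9 sampling times covering candidate rates 1e-5..1e-3 s^-1 within 8 h
design <- default_design(1e-5, 1e-3, n_points = 9)
round(design)
#> [1]     0   100   225   504  1132  2543  5711 15434 28800

# synthetic measurements at true k_off = 1e-4 (10% peptide-level CV)
series <- sample_series(1e-4, design, noise_model(cv = 0.1, seed = 42))

fit <- fit_koff(series, n_boot = 500, seed = 7)
summary(fit)
#> Subunit-exchange dissociation-rate fit
#> Call:  fit_koff(series = series, n_boot = 500, seed = 7)
#>
#>   k_off = 9.728e-05 s^-1  (95% CI 9.095e-05 - 0.0001077)
#>   RSS = 0.006289 on 9 points
#>   half-exchange time (R = 0.5): 1.129e+04 s (3.14 h)
#>   RMSE of residuals: 0.02643
#>   bootstrap resamples used: 500
```

The true rate 1e-4 s⁻¹ is recovered within 3% and covered by the 95%
interval; the half-exchange time says half the tagged complex has swapped
partners after ~3.1 h. The two anchor points of the theory locate the
practical window:

```r
exchange_ratio(1e-5, 8 * 3600)   # slow complex: 0.1430129 -> "0.14" after 8 h
exchange_ratio(1e-3, 2 * 3600)   # fast complex: 0.9985079 -> "1.00" in 2 h
```

From the shell:

```sh
Rscript inst/scripts/mase.R sample --k-off 1e-4 --seed 5 --out series.csv
Rscript inst/scripts/mase.R fit --input series.csv --n-boot 1000 --seed 7 --out fit.json
Rscript inst/scripts/mase.R curves --out curves.csv --plot curves.png
```

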