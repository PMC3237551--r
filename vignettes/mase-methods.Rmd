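---
title: "Subunit-exchange kinetics: model, simulators and the k_off estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subunit-exchange kinetics: model, simulators and the k_off estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mase)
```

## The measurement this package models

The dissociation rate constant $k_{off}$ of a protein complex sets the time
scale on which the complex falls apart, and with it the complex's residence
time in the bound state. Classical routes to $k_{off}$ — surface plasmon
resonance, stopped-flow fluorescence — need purified, immobilized or
fluorescently switchable material, which rules out most complexes one can
pull down by affinity purification.

Subunit exchange offers a different route. Grow one culture expressing an
affinity-tagged subunit $A$ on normal medium (all protein unlabeled) and a
wild-type culture on ${}^{15}\mathrm{N}$ medium (all protein labeled). Lyse
both, let each lysate's binding reaction

$$A + B \; \underset{k_{off}}{\overset{k_{on}}{\rightleftharpoons}} \; AB$$

come to equilibrium, then mix 1:1. At mixing, every complex is either
$A^T_U B_U$ (tagged, unlabeled) or $A_L B_L$ (labeled). As complexes
dissociate and re-form, the tagged subunit picks up labeled partners, and
the hybrid complex $A^T_U B_L$ accumulates. Affinity purification captures
everything tagged; quantitative proteomics reads out the abundance ratio

$$R_t = \frac{[A^T_U B_L]_t}{[A^T_U B_U]_t},$$

which rises from 0 at mixing toward 1 at full equilibration. The package's
central result is that with *equivalent lysates* (same complex
concentration in both cultures), this ratio follows

$$R_t \;=\; \frac{1 - e^{-k_{off} t}}{1 + e^{-k_{off} t}}
       \;=\; \tanh\!\left(\frac{k_{off}\,t}{2}\right),$$

a one-parameter curve depending on $k_{off}$ alone — not on $k_{on}$, not
on any concentration, not on the purification (both isotopic variants
purify identically). Measuring $R_t$ at a handful of time points and
fitting this curve therefore estimates $k_{off}$ directly in crude lysate.

### Why the curve is $k_{on}$-free

Three structural facts hold under equivalent 1:1 mixing, and
`verify_propositions()` checks them numerically on any simulated run:

1. Mixing dilutes the tagged species two-fold but leaves total free $B$
   unchanged (the labeled lysate contributes the same amount), so the
   pre-mix detailed balance $k_{on}[A][B] = k_{off}[AB]$ is undisturbed:
   all four free-subunit concentrations stay constant throughout.
2. Consequently the total tagged complex $[A^T_U B_U] + [A^T_U B_L]$ is
   constant: exchange only re-partitions it.
3. With $[B_U] = [B_L]$, the partition relaxes to parity, $R_\infty = 1$.

The hybrid complex then obeys a linear relaxation with rate constant
$k_{off}$ toward half the (constant) tagged-complex pool, which integrates
to the $\tanh$ form above. Two anchor values locate the practical window:
a complex with $k_{off} = 10^{-3}\,\mathrm{s^{-1}}$ reads as fully
equilibrated ($R = 1.00$ at two decimals) within two hours, while one with
$k_{off} = 10^{-5}\,\mathrm{s^{-1}}$ only reaches $R = 0.14$ after eight
hours — so an eight-hour sampling window separates rates across at least
two orders of magnitude.

```{r curves, fig.width = 6, fig.height = 4}
tab <- exchange_curves(c(1e-3, 1e-4, 1e-5), horizon = 8 * 3600, step = 600)
matplot(tab$t_seconds / 3600, tab[, -1], type = "l", lty = 1, lwd = 2,
        xlab = "time since mixing (h)", ylab = expression(R[t]))
legend("right", sprintf("k_off = %g /s", c(1e-3, 1e-4, 1e-5)),
       col = 1:3, lwd = 2, bty = "n")
```

## Units and parameter conventions

Time is seconds internally ($k_{off}$ in $\mathrm{s^{-1}}$); the
command-line interface accepts hours and converts. Concentrations are in
arbitrary units throughout — every deliverable quantity ($R_t$, $k_{off}$)
is unit-free or $\mathrm{s^{-1}}$, so no concentration system is imposed.
$k_{on}$ is treated as a bimolecular constant
(concentration$^{-1}\,\mathrm{s^{-1}}$) with default magnitude $10^6$ in
simulator protocols; since the observable is provably $k_{on}$-independent,
this choice only affects how stiff the simulated system is.

## The deterministic oracle

`simulate_exchange()` integrates the full eight-species mass-action
network (4 free subunits, 4 complexes; association
$k_{on}[\mathrm{free}\,A][\mathrm{free}\,B]$, dissociation
$k_{off}[\mathrm{complex}]$) with deSolve's `lsoda` at `rtol = 1e-9`,
`atol = 1e-12`. Tolerances are tight because $k_{on}\cdot$concentration
can exceed $k_{off}$ by many orders of magnitude, making the system stiff;
`lsoda` switches to a stiff method automatically, and the result is
checked to be invariant under a 10$\times$ tolerance tightening. Pre-mix
equilibration is computed analytically by `equilibrium_split()` (the
stable root of the binding quadratic, solved for the scarcer subunit's
free concentration to avoid cancellation at high affinity) rather than by
burn-in integration — exact and fast. Mass conservation is asserted to
relative 1e-8 on every run; a solver failure raises an error carrying the
solver diagnostics, never a silent `NaN`.

This simulator, run on equivalent lysates, is the brute-force oracle for
the closed form: agreement is within $10^{-6}$ absolute in $R$ across
$k_{off} \in \{10^{-5}, 10^{-4}, 10^{-3}\}$ and 17 time points over 8 h,
and invariant to $k_{on}$ over four orders of magnitude. Run on
*non-equivalent* lysates (e.g. unequal total $B$), the free pool drifts and
$R_\infty \ne 1$ — the negative control confirming the propositions'
premises are needed, and a caution for real experiments where expression
levels differ between cultures.

One reporting subtlety: the equilibrium proposition is judged only on
trajectories long enough to have reached equilibrium. A run shorter than
$5/k_{off}$ reports "not reached" rather than a failure; the package's own
verification runs extend to $14/k_{off}$, where $|R - 1| < 2\times10^{-6}$
at the solver's accuracy.

## The stochastic simulator and a real small-number effect

`simulate_exchange_stochastic()` is an exact direct-method event
simulation of the same network in integer copy numbers (the Gillespie
algorithm, implemented in C++ with R's RNG so `seed` gives bit-identical
event sequences). A `volume_scale` parameter converts concentrations to
copies; stoichiometry conserves each subunit's total exactly.

The ensemble mean of $R$ should match the deterministic curve — but only
in the mean-field regime. At high affinity ($K_d = k_{off}/k_{on} =
10^{-9}$ with the default $k_{on} = 10^6$), a lysate with 1000 copies of
complex holds far *less than one* free copy of each subunit on average.
A dissociated pair then almost always geminately re-binds before any other
free partner exists, and label mixing nearly stalls: the true ensemble
mean falls far below the mass-action curve. This is a physically real
consequence of molecular discreteness, not a solver artifact, and the
package reproduces it. The stochastic-vs-deterministic consistency checks
therefore use a moderate-affinity parameterization ($K_d = 1$ in
concentration units, i.e. $k_{on} = k_{off}$), under which 1000 copies per
complex coexist with $\sim$1600 free copies per subunit and the ensemble
mean of 200 replicates agrees with $\tanh(k_{off}t/2)$ within 3 standard
errors at every grid point. $R_t$ itself is $k_{on}$-independent, so this
choice tests exactly the same curve.

## The synthetic-measurement generator

No error model is inherited from the upstream quantification literature,
so the generator states its own, mirroring standard isotope-ratio
practice: each protein-level ratio is the **median** over `n_peptides`
peptide-level ratios, each carrying **multiplicative log-normal** error
with coefficient of variation `cv`; the reported `sigma` is the scaled
median absolute deviation of the peptide ratios. Defaults are `cv = 0.15`
and `n_peptides = 5`, typical of metabolic-labeling proteomics, and both
are user-set parameters, not constants. The $t = 0$ point passes through
as exactly 0 (no hybrid complex exists at mixing; the instrument would see
no hybrid signal), and an optional detection `floor` flags — never drops —
sub-threshold points as censored.

What this emulates: multiplicative peptide-level quantification noise and
median summarization. What it does not: spectral interference,
identification error, incomplete ${}^{15}$N incorporation, or
purification losses — all upstream of the ratio abstraction the model
works in. Passing recovery tests on these synthetic data therefore shows
the estimator handles realistic ratio noise, not that every real-data
pathology is covered.

`default_design()` places sampling times for a prior range
$[k_{low}, k_{high}]$: always $t = 0$, the rest log-spaced from
$0.1/k_{high}$ to $3/k_{low}$, capped at a practical horizon (default
8 h). Because the information about $k_{off}$ in a single point,
$\partial R_t/\partial k_{off} = (t/2)\,\mathrm{sech}^2(k_{off}t/2)$,
peaks at $t^\* \approx 1.543/k_{off}$ (the product $k_{off}t^\*$ is a
universal constant), the log-spaced candidate nearest $1.543/\sqrt{k_{low}
k_{high}}$ is replaced by that time, guaranteeing the most informative
region is sampled. Pure log-spacing can straddle the peak without landing
near it; the explicit insertion removes that failure mode.

## The estimator

`fit_koff()` minimizes $\sum_i w_i\,(R_i - \tanh(k_{off}t_i/2))^2$ on the
untransformed ratio scale — weights optional ($1/\sigma_i^2$ when
requested and available, else 1). The objective in $\log_{10} k_{off}$ is
scanned on a 21-point grid over $[-8, -1]$, then polished by bounded
golden-section minimization (bounds $[-10, 0]$; an estimate pinned at a
bound is flagged non-physical). The polished optimum never regresses
behind the best grid point. Ratios $\ge 1$, possible under noise at
equilibrium, are retained (the model approaches 1); censored points are
excluded with a recorded count; an all-zero series (no exchange detected)
yields a flagged non-converged result whose $k_{off}$ is the detection
upper bound from single-point inversion at the latest time.

Uncertainty comes from a residual bootstrap that preserves the fixed time
design. The residuals are standardized by their fitted values before
resampling: ratio noise is multiplicative, so raw residuals are strongly
heteroscedastic (tiny at early times, large mid-curve), and pooling them
raw lets the near-zero early-time errors masquerade as the uncertainty of
the informative points — in calibration runs that naive variant covered
the truth only $\sim$50–65% of the time at a nominal 95%. With relative
residuals, coverage in 100-replicate studies at `cv = 0.1` is 95–100%
across $k_{off} \in \{10^{-5}, 10^{-4}, 10^{-3}\}$ (deliberately
conservative rather than anti-conservative). Percentile 2.5/97.5 bounds
form the interval, widened if necessary to bracket the point estimate.

A single informative point admits a closed-form estimate by inversion,
$k_{off} = \log\big((1+R)/(1-R)\big)/t$ (`invert_ratio()`); an observation of a
measured $R = 0.14$ at 8 h maps back to $0.98 \times 10^{-5}
\,\mathrm{s^{-1}}$. Inversion rejects $R \ge 1$ (at/past equilibrium,
uninformative) and $R \le 0$. The analytic inverse is used rather than a
bracketed root search: it is exact, and valid for any rate rather than a
hard-coded bracket.

```{r fit-example}
design <- default_design(1e-5, 1e-3, n_points = 9)
series <- sample_series(1e-4, design, noise_model(cv = 0.1, seed = 42))
fit <- fit_koff(series, n_boot = 500, seed = 7)
summary(fit)
```

```{r fit-plot, fig.width = 6, fig.height = 4}
plot(fit)
```

## Numerical choices and degenerate inputs

* $\tanh$ saturates to exactly 1 in double precision once $k_{off}t
  \gtrsim 37$; strict monotonicity and $R < 1$ hold mathematically
  everywhere but are only representable below saturation. Property tests
  respect this.
* `equilibrium_split()` solves the binding quadratic in the
  cancellation-free form for the scarcer subunit's free concentration and
  derives the complex from detailed balance, so the detailed-balance
  residual is at machine precision even at $K_d \ll$ totals.
* The ODE grid must start at $t = 0$ (the mixing instant) and increase
  strictly; `extract_R()` errors if the original tagged complex is ever
  non-positive (impossible for positive initial tagged complex).
* Ties in the bootstrap or an all-zero resample are dropped from the
  percentile computation (they carry no estimate); at least 10 finite
  resamples are required for an interval.

## Problem sizes used in the package's own studies

Verification and calibration runs use: 17-point 8-h grids for
oracle-equivalence across three rates and three $k_{on}$ values; 29-point
grids to $14/k_{off}$ for the propositions; 200 stochastic replicates at
1000 copies per complex over 8 post-mix time points; and 100 replicate
synthetic datasets per true rate (9 points, `cv = 0.1`, 200 bootstrap
resamples each) for recovery and coverage. These sizes give Monte-Carlo
standard errors comfortably below the margins being tested while keeping
any single study in the seconds-to-a-minute range.

## Known limitations

* The closed form assumes a heterodimer with equivalent lysates; unequal
  expression between cultures violates the constant-free-pool premise
  (and the simulator shows exactly how). Multi-subunit complexes would
  need an apparent-$k_{off}$ treatment that is out of scope here.
* Degradation, purification losses and labeling incompleteness are
  assumed away (the experimental design suppresses or cancels them); the
  generator does not emulate them.
* The measurement error model is the package's own stated convention, not
  an empirically fitted one; `cv` and `n_peptides` should be set from the
  user's instrument performance.
* At very small copy numbers with high affinity, the mean-field curve is
  biased upward relative to the true stochastic mean (geminate
  recombination); $k_{off}$ estimates from single-molecule-scale systems
  would need the stochastic model, not the closed form.
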