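---
title: "Finite absorption time models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite absorption time models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbftpk)
```

## The model

Classical oral pharmacokinetics describes absorption with a first-order
rate constant $k_a$, which implies that absorption continues forever.
Physiologically, absorption terminates when the drug leaves the
absorptive segments of the gut: the finite absorption time (F.A.T.)
premise. Moreover, the high portal-vein blood flow keeps the absorption
step under sink conditions, so while it lasts, drug input is well
approximated as *zero-order* (constant rate). Changes of absorptive
environment along the gastrointestinal tract (stomach to small
intestine to colon, or staged release from an extended-release dosage
form) appear as *successive* zero-order stages with different rates.

`pbftpk` implements this model family: an absorption schedule of $n$
stages (durations $\tau_1,\dots,\tau_n$ in hours, input rates
$r_1,\dots,r_n$ on the concentration-per-hour scale), feeding either

* one-compartment disposition with elimination rate constant $k_{el}$, or
* two-compartment disposition with micro-constants $k_{12}, k_{21},
  k_{10}$ and hybrid constants $\alpha > \beta > 0$.

The central concentration is the superposition of shifted constant-rate
infusion solutions: each stage contributes a start/stop pair. For one
compartment, a stage of rate $r$ running on $(s, e]$ contributes
$\tfrac{r}{k_{el}}\big[(1-e^{-k_{el}(t-s)})_+ - (1-e^{-k_{el}(t-e)})_+\big]$;
for two compartments the same construction uses the integral of the
central-compartment impulse response
$h(t) = A e^{-\alpha t} + B e^{-\beta t}$,
$A = (\alpha-k_{21})/(\alpha-\beta)$, $B = (k_{21}-\beta)/(\alpha-\beta)$.
This closed form is numerically stable (no ODE solver in the hot path),
exactly continuous at stage breakpoints, and is verified in the test
suite against independent Runge–Kutta/LSODA integration of the
underlying ODEs at relative tolerance $10^{-6}$ over randomized
parameter draws.

Rates are expressed per volume of distribution: the data only ever
identify the composite $F_i D / V_d$ (stage amount on the concentration
scale), never dose and volume separately, so the package never asks for
either. The classical first-order Bateman curve
$C(t) = \mathrm{scale}\cdot\tfrac{k_a}{k_a-k_{el}}(e^{-k_{el}t}-e^{-k_a t})$
is included purely as a comparator; its degenerate case $k_a = k_{el}$
is rejected rather than given the $t\,e^{-kt}$ limit form, since it is
never needed in this role.

## Fitting

`fit_pbftpk()` minimizes the unweighted sum of squared residuals with
Levenberg–Marquardt (`minpack.lm::nls.lm`) on log-transformed
parameters, which enforces positivity and breakpoint ordering without
constraint machinery. Residual plots in this literature are on the
concentration scale, hence ordinary (unweighted) least squares.

The SSR surface of staged-input models is multimodal in the stage
breakpoints, so the optimizer uses three ingredients:

* **Structured multistart.** The base start takes $k_{el}$ (or the slow
  hybrid constant) from a log-linear regression on the last third of
  positive observations, splits $[0, 1.2\,t_{max}]$ evenly into stage
  durations, and sets rates to the crude rising-limb slope
  $C_{max}/t_{max}$. Starts combine coarse rescalings of the guessed
  total duration (x0.6, x1, x1.5, x2.2) with log-normal jitter whose
  standard deviation cycles from 0.15 to 0.8; at least
  $2\,p + 4$ starts are run for a $p$-parameter model. Tight jitter
  alone proved unable to reach the narrow global basins of 3-stage and
  two-compartment problems, which is why the duration rescalings and the
  complexity-scaled start count are part of the design.
* **Cascade initialization.** For $n > 1$ stages, the $(n-1)$-stage
  model is fitted first (with a small start budget) and each of its
  stages is split in half to seed the $n$-stage fit. These
  data-informed starts resolve shoulder stages that grid-based starts
  miss.
* **Termination.** Each start runs to relative SSR change
  $< 10^{-13}$ or parameter step $< 10^{-11}$ within 400 iterations;
  the best SSR wins, ties to the first found, and the winner is
  polished by one further run from its own optimum. All randomness is
  drawn under the caller's seed (and the caller's RNG state is
  restored), so identical seeds give bit-identical fits.

Standard errors come from the Jacobian-based covariance at the optimum,
$\widehat{\mathrm{cov}} = s^2 (J^\top J)^{-1}$ with
$s^2 = \mathrm{SSR}/(n_{obs}-p)$ and $J$ evaluated by central
differences on the natural parameter scale; a Monte-Carlo test checks
that these standard errors track the replicate-to-replicate spread of
the estimates within a factor of two. Near-singular $J^\top J$ falls
back to a pseudoinverse, which happens exactly in the weakly identified
regimes discussed below.

`compare_models()` ranks candidate stage counts (and the Bateman
comparator) by the small-sample-corrected information criterion
$\mathrm{AICc} = n\log(\mathrm{SSR}/n) + 2k + \tfrac{2k(k+1)}{n-k-1}$,
$k = p + 1$. The SSR entering the criterion is floored at
$(10^{-9} C_{max})^2$ per point: on noiseless data every adequate model
reaches SSR at floating-point rounding level, where log-SSR differences
are meaningless, and the floor lets the parsimony penalty decide.
Observations below a user-supplied limit of quantification are excluded
from fitting, never imputed.

## Bioavailability from oral data alone

For one-compartment drugs the bioavailable fraction follows from
comparing the oral AUC with the AUC of the *hypothetical IV bolus*
obtained by back-extrapolating the post-absorption elimination phase
($t > \tau$) to $t = 0$. Three routes are implemented:

* `estimate_F_eq3(kel, tau)` — single stage, closed form
  $F = k_{el}\tau / (e^{k_{el}\tau} - 1)$: strictly decreasing in
  $k_{el}\tau$, tending to 1 as absorption becomes instantaneous.
* `estimate_F_eq4(a1, a2, tau1, tau2, kel)` — two stages with amounts
  $a_i = r_i \tau_i$:
  $F = (a_1+a_2)k_{el}\big[\tfrac{a_1}{\tau_1}(e^{k_{el}\tau_1}-1) +
  \tfrac{a_2}{\tau_2}e^{k_{el}\tau_1}(e^{k_{el}\tau_2}-1)\big]^{-1}$.
  It reduces algebraically to the single-stage form when $a_2 = 0$ (at
  $\tau_1$) or when the stage rates are equal (at $\tau_1+\tau_2$);
  both reductions are asserted at machine precision in the tests, and
  both closed forms are checked against an independent numeric
  AUC-ratio oracle to $10^{-8}$.
* `estimate_F_star_eq5(series, tau, exponent)` — the
  semi-noncompartmental route, applicable to any stage count:
  log-linear regression on all observations beyond $\tau$ gives
  $\hat k_{el}$ and the back-extrapolated intercept,
  $AUC_{hyp.iv} = \mathrm{intercept}/\hat k_{el}$; the oral AUC uses
  the linear trapezoid plus tail $C_{last}/\hat k_{el}$ with the *same*
  $\hat k_{el}$, keeping the estimator self-contained in oral data; the
  estimate is $(AUC_{oral}/AUC_{hyp.iv})^{\mathrm{exponent}}$. This
  estimates the fraction of dose absorbed $F^*$, which equals $F$ only
  in the absence of a first-pass effect.

Design choices worth stating explicitly:

* The eq5 exponent defaults to $1/2$ but is an argument, because the
  source material for this estimator is typographically ambiguous
  between the square root and the plain ratio; with `exponent = 1` the
  estimator coincides, on model-consistent data, with the closed forms
  above — an identity the acceptance tests verify to 0.5% on densely
  sampled noiseless profiles.
* Quadrature is the linear trapezoid throughout; no log-down variant is
  applied silently.
* The terminal window is *all* points with $t > \tau$, not a subset
  chosen by maximizing $r^2$; nonpositive concentrations in the window
  are excluded with a warning and at least three usable points are
  required.
* The dominant error source in every route is $\hat\tau$ itself: a
  sensitivity test confirms that the derivative of the single-stage
  closed form with respect to $\tau$ matches its finite-difference
  perturbation, so reported absorption-duration uncertainty propagates
  predictably into $F$.

## Fraction-absorbed curves

`fraction_absorbed_curve()` builds
$FA(t) = \sum_i r_i\,\mathrm{overlap}(t, \mathrm{stage}_i) / \sum_i r_i \tau_i$
from the fitted schedule only — no Wagner–Nelson-style reconstruction
from observed data. The curve is piecewise linear with slopes
proportional to stage rates and reaches exactly 1 at the finite
absorption time, by construction rather than asymptotically; classical
deconvolution curves that plateau below 1 are a different (and out of
scope) computation.

## The synthetic-data generator

The published analyses behind this model family were performed on
concentration–time points digitized from figures; the raw numbers are
not printed anywhere. The generator therefore stands in for those
datasets with known ground truth. `generate_profile()` applies
$C_{obs} = \max(0,\; C_{true}(1+\varepsilon_p) + \varepsilon_a)$,
$\varepsilon_p \sim N(0, cv^2)$, $\varepsilon_a \sim N(0, sd^2)$, then
an optional limit of quantification (sub-LOQ values dropped by default,
zero-filled on request). Draws are seed-deterministic.

Six `study_template()` fixtures carry the published fitted absorption
schedules (stage durations and rates) for a single-stage NSAID
(ketoprofen-like), a two-stage two-compartment drug (amlodipine-like),
three theophylline formulations (immediate-release, and the Theotrim
and TheoDur extended-release products), and a single-stage
two-compartment contraceptive (levonorgestrel-like, reference
formulation; its published duration is quoted with an inconsistent
"h^-1" unit, read here as hours). Two ingredients of each template are
**synthetic choices, not published values**, and are chosen once as
literature-plausible:

* Disposition constants: $k_{el}$ = 0.64 (ketoprofen-like), 0.12
  (immediate-release theophylline-like), 0.07 (Theotrim-like), 0.09
  (TheoDur-like) h$^{-1}$; $(k_{12}, k_{21}, k_{10})$ = (0.08, 0.05,
  0.04) h$^{-1}$ for the amlodipine-like template (terminal half-life
  about 55 h) and (0.6, 0.4, 0.1) h$^{-1}$ for the
  levonorgestrel-like template (about 18 h).
* Sampling schedules: 11–18 points, dense during absorption and sparse
  in the terminal phase, spanning 8 h (ketoprofen-like) to 96 h
  (amlodipine-like), as clinical designs do.

What passing round-trip tests show, and what they do not: they show
that *if* a profile is generated by a staged zero-order model and
sampled on a clinical grid, the pipeline recovers the generating
parameters (exactly without noise; total duration to a few percent at
5% proportional noise for most templates). They do not show that real
digitized profiles obey the model, nor do they reproduce
between-subject variability, assay heteroscedasticity beyond the
proportional+additive form, or digitization bias — none of which the
generator attempts to emulate.

Two templates are *honestly hard* at 5% noise, and the test suite
records this rather than hiding it: the amlodipine-like template
(consecutive stage rates differing by only 1.45x, smoothed further by
two-compartment distribution) and the immediate-release
theophylline-like template (second-stage input flux nearly cancelling
elimination flux, so the curve is almost flat around the final
breakpoint). For both, the median total-duration error across noisy
replicates lands slightly above 10%, while the fitted SSR is below the
SSR at the true parameters in every replicate — a flat-likelihood
identifiability limit of the study design, not an optimizer failure.
Practically: when consecutive fitted stage rates are within a factor of
about 1.5, or a late stage's rate is comparable to $k_{el} C$, the
reported $\hat\tau$ standard error should be taken seriously.

## Numerical choices and degenerate inputs

* Time is hours, $t = 0$ is dose administration; concentrations carry a
  declared unit label and are never converted.
* Input-rate units follow the composite-amount convention: a stage rate
  times its duration is a concentration-scale amount.
* $\alpha = \beta$ cannot occur for positive micro-constants with
  $k_{12} > 0$, so the two-exponential form needs no limit handling;
  the $k_{12} \to 0$ limit reproduces the one-compartment model and is
  tested.
* All-zero series, series too short for the parameter count, schedules
  with no observation beyond the initial total-duration guess, fewer
  than three usable terminal points, zero total absorbed amount, and
  unknown template names are rejected with messages naming the
  requirement.
* Problem sizes used by the test suite: 100 randomized models for the
  ODE-equivalence check, 18 randomized simulate-then-fit scenarios plus
  all six templates noiseless, 100 noisy replicates per template for
  the stochastic recovery study, 200 replicates for the
  standard-error calibration, 100 replicates for the
  Bateman-inferiority comparison.

## Known limitations

* Absorption models are limited to successive zero-order stages:
  no transit-compartment, first-order, or saturable absorption, no
  enterohepatic recirculation, no multiple dosing.
* Estimation is per-series ordinary least squares: no weighting
  schemes, no mixed-effects/population estimation, no bootstrap
  intervals; fits of related series (e.g. formulations of the same
  drug) do not share parameters.
* The closed-form bioavailability routes require one-compartment
  disposition; for two-compartment drugs only the generic AUC-ratio
  route applies.
* The two-stage closed form has no three-stage counterpart here; for
  three stages use the semi-noncompartmental route.
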