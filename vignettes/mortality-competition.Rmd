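---
title: "Methods: mortality-driven shifts in microbial competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mortality-driven shifts in microbial competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmort)
```

## The model and its assumptions

`lvmort` analyses competition under added mortality with the Lotka–Volterra
model

$$\dot N_i = r_i N_i \left(1 - \textstyle\sum_j \alpha_{ij} N_j\right) - \delta N_i,$$

with densities normalized to each species' carrying capacity (so
$\alpha_{ii} = 1$), maximum growth rates $r_i$ in h⁻¹, and dimensionless
competition coefficients $\alpha_{ij} \ge 0$. The model's assumptions are the
usual ones: pairwise, density-dependent inhibition with no higher-order
interactions, no explicit resources, no spatial structure, and deterministic
dynamics. Mortality is uniform across species by default (a dilution step
kills indiscriminately); every routine that accepts a scalar $\delta$ also
accepts a per-species vector for the species-specific extension, which moves
a pair along the same 45° line in log-coefficient space but in a direction
set by the rate differences.

Two mortality modes are implemented and linked by
$\delta = \ln(\mathrm{DF})/T$ (equal per-cycle survival):

* **continuous death** — $\delta$ acts throughout; integrated in 24-h blocks
  until the composition settles;
* **serial dilution** — growth with $\delta = 0$ for $T$ hours (default 24),
  then division of all densities by DF. Trajectories record the
  *pre-dilution* state, which is what an experimenter plates.

## Re-parameterization and outcome classification

With $\delta < \min_i r_i$ the mortality model maps exactly onto the
death-free model with rescaled densities
$\tilde N_i = N_i/(1-\delta/r_i)$, effective rates $r_i - \delta$, and

$$\tilde\alpha_{ij} = \alpha_{ij}\,
  \frac{1-\delta/r_j}{1-\delta/r_i}.$$

`classify_pair()` reads the outcome off the classical phase diagram: both
$\tilde\alpha < 1$ → coexistence; both $> 1$ → bistability (the unstable
interior point is the separatrix); one of each → exclusion by the species
with the smaller incoming coefficient. Since
$\tilde\alpha_{ij}\tilde\alpha_{ji}$ does not depend on $\delta$, a mortality
sweep moves the pair along a slope $-1$ line in
$(\log\tilde\alpha_{ij}, \log\tilde\alpha_{ji})$; a pair dominated by its
slow grower at $\delta = 0$ therefore crosses either the coexistence quadrant
(coefficient product $< 1$) or the bistable quadrant (product $> 1$) before
the fast grower wins. The crossings are closed-form
(`critical_mortalities()`):
$\delta^*_{ij} = r_i r_j (1-\alpha_{ij})/(r_j - \alpha_{ij} r_i)$.
`locate_transitions()` finds the same transitions by bisection on the
classification itself and is used as an independent numerical check.

Beyond $\delta \ge \min_i r_i$ the re-parameterization is undefined;
`mortality_sweep()` then falls back to monoculture viability (a species with
$r_i \le \delta$ cannot persist even alone) and reports `NA` effective
coefficients.

### Discrete versus continuous mortality

The qualitative outcome of the discrete growth–dilution process matches the
continuous-death classification, and the package's tests verify this on
ensembles of random pairs. Two caveats discovered and kept visible in the
design:

* The *interior composition* of the discrete cycle map at its pre-dilution
  equilibrium is not the continuous interior fixed point. Only the outcome
  type transfers. Inference tests therefore validate coexistence fractions
  against noise-free simulations of the same discrete process.
* *Basins of attraction* of bistable pairs differ substantially between the
  two processes: each dilution resets the culture to low density, where
  composition shifts at the bare growth-rate difference before competition
  kicks in, so a starting fraction can sit in different basins under the two
  mortality modes. Equivalence checks are therefore made
  attractor-by-attractor (rare-invader starts placed on each resident's own
  monoculture attractor) and, for single-attractor pairs, from arbitrary
  shared starts. Even then the equivalence is slightly approximate for
  strongly bistable pairs at large $\delta$: the invader's per-cycle growth
  exponent integrates the resident's within-cycle logistic transient rather
  than its continuous equilibrium density, and for a small percentage of
  random pairs (about 1% under the ensemble of the tests) the two processes
  disagree about an attractor's stability. The tests assert ≥ 98% agreement
  rather than identity for this reason.

## Calling outcomes from colony counts

`endpoint_fractions()` turns final-cycle colony counts into composition
estimates with beta-distribution error bars
($\sigma = \sqrt{(a+1)(b+1)/((a+b+2)^2(a+b+3))}$, focal count against the
sum of all others — a flat-prior posterior SD). Thresholds, all
configurable, with defaults chosen for ~42-colony platings:

* **extinction call** (`extinction_call_threshold = 0.005`): a species is
  absent from a condition when its endpoint count is 0 or its fraction falls
  below half a percent — below one colony at the design's mean plating
  depth, guarding against single miscounts.
* **shared attractor** (`convergence_window = 0.10`): coexisting starts are
  deemed to have converged to the same interior point when their endpoint
  fractions lie within 0.10 of their mean; multinomial sampling alone
  scatters 42-colony fractions by ~0.08 at two standard deviations.
* **per-condition convergence**: fractions moved by less than 0.1 over the
  final 3 of the 7 cycles.

A condition whose endpoint plating has zero total colonies is flagged
unusable but still carries signal (an empty survivor set); it is never
silently dropped. Mixtures of an interior state and an exclusion state
across starts are not a Lotka–Volterra outcome; they are reported as
bistability with a `non_LV` flag rather than coerced into a model category.

## Assembly rules and baselines

A candidate survivor set $S$ is allowed iff every pair inside $S$ coexists
and every species outside $S$ is excluded by some member of $S$ on some
branch (an exclusion outcome, or the losing branch of a bistable pair).
Bistable pairs never count as coexisting inside $S$; they generate
alternative allowed states instead. Enumeration is exhaustive over the
$2^n$ subsets ($n \le 5$ here). Monoculture-inviable species can be barred
via the `viable` argument, mirroring the monoculture platings run alongside
competition experiments.

Predicted compositions use the pairwise coexisting fractions: verbatim for a
pair; for $|S| \ge 3$ each survivor gets the weighted geometric mean
$f_i = (\prod_{j} f_{ij}^{w_j})^{1/\sum_j w_j}$ with opponent weights
$w_j = (\prod_{k \ne j} f_{jk})^{1/(|S|-1)}$ — the geometric mean of $j$'s
own pairwise fractions, which reduces to $w_2 = \sqrt{f_{21}f_{23}}$ for a
trio. For quads and larger this same weighting is the package's declared
extrapolation of the trio rule; it is the unique natural extension but is
not itself derived from the model.

Two baselines calibrate the errors: the **carrying-capacity** null (all
species coexist at fractions proportional to monoculture density, zero for
monoculture-extinct species) and a **random** composition. How a random
baseline should be constructed is genuinely open; the package draws from the
flat (uniform) distribution on the simplex — the maximum-entropy choice with
no information beyond the species count — via normalized i.i.d.
exponentials, seeded.

## Error statistics

Quantitative error is $\lVert \hat f - f \rVert_2 / \sqrt 2$; the
normalization is the largest distance two compositions can attain (a species
predicted extinct in fact dominates), putting every error in $[0, 1]$.
Scoring a benchmark case groups observed starting conditions by the survivor
set they reached, averages within groups, scores each allowed predicted
state against its matching group (falling back to the closest group,
flagged, when nothing matches), and lets multi-state (bistable) cases
contribute the smallest state error. Qualitative error is the fraction of
species miscalled present/absent, best-matching state for multi-state
predictions. Competitive scores average a species' endpoint fraction over
its pairs (replicates averaged per pair first); their uncertainty is a
seeded bootstrap (default 5000 resamples) over replicate-level pair
outcomes — resampling replicates within pairs, then recomputing pair means
and the species mean.

## Growth rates from OD curves

The primary estimator assumes exponential growth from the starting OD to a
threshold of 0.1 and divides $\ln(\mathrm{OD_{thr}}/\mathrm{OD_0})$ by the
first crossing time (linear interpolation between 15-min samples). Lag time
is deliberately folded in: in daily dilution a lag costs a species every
cycle, so a time-to-threshold rate is the competitively relevant one. The
explicit route fits $\log \mathrm{OD}$ over a declared exponential window
(OD 0.01–0.1 by default; the bounds are a package choice) for the lag and
exponential rate separately, and `effective_rate()` converts the pair into a
cycle-effective rate by the fraction of the cycle spent growing,
$r(T-\lambda)/T$ — a declared, labelled form of the lag correction, chosen
for transparency; with equal lags it preserves rate ordering.

## The synthetic generator

`sample_params()` draws communities in the regime the analysis targets: a
pervasive growth/competitive-ability tradeoff. Growth rates are log-uniform
on 0.2–1.5 h⁻¹ (a realistic span for soil heterotrophs in rich medium, and
wide enough that the six-decade dilution range spans sub- to super-critical
mortality for most pairs); coefficients are
$\alpha_{ij} = \exp(\log\alpha_0 + \gamma (r_i - r_j) + \varepsilon_{ij})$
with geometric centre $\alpha_0 = 0.5$, tradeoff strength $\gamma = 4$ (so
rate gaps above $\ln 2/\gamma \approx 0.17$ h⁻¹ give slow-grower dominance),
and log-normal scatter $\sigma = 0.3$ (enough to produce both
coexistence-crossing and bistability-crossing pairs). Carrying capacities
are log-uniform on 0.5–5 × 10⁹ CFU/ml and lags uniform on 0–4 h. These
defaults are fixed study conditions, not tuning knobs.

`simulate_experiment()` reproduces the serial-dilution design: dilution
factors 10–10⁶, 7 cycles of 24 h, starting compositions "equal" plus one
90%-dominant start per species (remainder split evenly — 90–5–5 for a trio,
90–10 for a pair), day-0 predilution by the daily factor except that DF 10⁶
starts at 10⁻⁵ to avoid day-0 stochastic extinction. Observed fractions
weight model densities by absolute carrying capacity
($K_i N_i / \sum_j K_j N_j$): plating counts cells, while the model's
densities are normalized — a deliberate mismatch that lets the tests probe
the analysis' robustness to exactly this ambiguity (a `fraction_mode`
switch provides unweighted fractions). Counts are multinomial with
Poisson-distributed totals (mean 42), reflecting plating variability. All
randomness flows from one seed; identical seeds give identical tables.

Simulated OD curves are flat at the starting OD through the lag, grow
exponentially at the true rate, and saturate smoothly (slope-continuous
exponential approach) to a per-species plateau of $K_i/10^9$ OD units from
half-saturation upward. Growth is kept exactly exponential through the
measurement threshold because rich-medium cultures remain effectively
exponential well past OD 0.1; this is what makes 1% rate recovery a fair
test of the estimator rather than of the curve model.

What the generator does *not* emulate — and hence what passing tests cannot
certify about real data: mechanism-specific interactions (pH modification,
secreted inhibitors, cross-feeding) that violate the pairwise LV form;
demographic stochasticity beyond plating noise; measurement artefacts such
as colony-morphology misidentification; and any deviation from the strict
24-h cycle.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable, adaptive), rtol $10^{-8}$,
  atol $10^{-12}$ — exclusion runs push densities toward zero, where loose
  tolerances oscillate negative. Tiny negative excursions are clamped; zero
  densities are pinned (extinction is absorbing).
* Extinction threshold: normalized density $10^{-10}$, applied after each
  dilution or continuous block. Pure LV exclusion is only asymptotic; finite
  populations go extinct, and the threshold makes exclusion realizable in
  finitely many cycles.
* Convergence of a run: composition change $< 10^{-4}$ (L∞) *and* settled
  log-densities over the trailing 3 recorded states; the log-density
  condition prevents a rare species still growing or decaying geometrically
  from being declared converged. Runs cap at `n_cycles` either way, and both
  the flag and the cycle count are reported.
* Survivor extraction from trajectories uses a final-fraction floor of
  $10^{-3}$, separating decaying remnants from genuine interior fractions.
* Effective coefficients within $10^{-9}$ of 1 (and coefficient products
  within $10^{-9}$ of 1, where a line of fixed points appears) are reported
  as a distinct degenerate category/condition, never silently assigned a
  side.
* Interior fractions are reported on the normalized-density scale
  ($N_1/(N_1+N_2)$ after undoing the rescaling), matching what plating
  measures up to carrying-capacity weighting.

## Validation scale

The test suite validates the classification against brute-force dynamics on
200 random pairs (three starts each), the discrete/continuous
correspondence attractor-by-attractor on the same ensemble, and the full
generate → simulate → infer → predict → score pipeline on 20 seeded
communities of 3–5 species, where inferred pair outcomes match analytic
truth away from boundaries (margin 0.15 in $|\log\tilde\alpha|$ and
$\delta \le 0.9\,\min r$) in well over 95% of conditions and the mean
normalized errors order as assembly < carrying capacity < random. These
sizes were chosen to make the properties statistically decisive while
keeping the suite quick to run.

## Known limitations

* The assembly weights for $|S| \ge 4$ are an extrapolation (above).
* The package predicts equilibria, not transient dynamics, and does not fit
  LV parameters to multispecies data.
* The discrete/continuous correspondence is qualitative and, for strongly
  bistable pairs near the edge of the re-parameterization's domain, only
  approximate (quantified above).
* Real communities violating the pairwise LV form will produce non-LV
  flags rather than forced classifications; the package surfaces these, it
  does not model them.
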