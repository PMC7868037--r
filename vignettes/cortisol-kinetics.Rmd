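---
title: "Methods: Bayesian cubic kinetics for multi-tissue cortisol time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian cubic kinetics for multi-tissue cortisol time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery: the
model and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where more than one defensible
option existed. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## The model and its assumptions

Cortisol concentration (ng/ml) in a given tissue subset is modelled as a
cubic function of time post-injection (hours) with independent Gaussian
errors:

$$y_i \sim \mathrm{Normal}(b_0 + b_1 t_i + b_2 t_i^2 + b_3 t_i^3,\ \sigma^2).$$

The cubic is a *heuristic*: it is the lowest-order polynomial whose shape can
express a concentration peak followed by decline to a local minimum, which is
exactly the kinetic vocabulary (distribution, peak, elimination) the derived
parameters speak. It is not a mechanistic pharmacokinetic model, and the
package deliberately performs no model selection around it.

Assumptions worth stating plainly:

- **Raw-scale Gaussian errors.** The likelihood is on the concentration
  scale, not the log scale. This is coherent with the a-priori filtering
  step: requiring fitted curves to be positive over the window only makes
  sense if the model is able to produce negative values.
- **Independence across observations.** Fish are sampled at most twice and
  never twice within a window, and the model treats every row as
  independent; there is no fish- or tank-level random effect. The
  repeated-measures structure of the design is intentionally not modelled —
  plasma analyses are instead restricted to the first sampling window
  (0–12 h) so that second samplings cannot contaminate the short-timescale
  plasma curve.
- **Separate fits per group.** Models are fit separately per trial
  (ACTH / cortisol), matrix (plasma / mucus) and arm, with control arms
  pooled across trials per matrix. Six fits in total for the full design.

## Priors and sampling

"Uninformed priors" are concretised as independent Normal(0, 10^6) on each
coefficient (on the raw-hours basis) and Uniform(0, 10^4 ng/ml) on σ. At the
data's scale (hundreds of ng/ml, windows of tens of hours) both contribute
essentially nothing, and the flat-prior-equals-least-squares acceptance
criterion verifies this numerically against a closed-form QR solution.

Sampling is by a conjugate Gibbs sampler written for this package: the
coefficient block has a multivariate-normal full conditional, and the
uniform-on-σ prior induces an exact Gamma((n−1)/2, SS/2) full conditional on
the precision, truncated at σ ≤ 10^4 by rejection (the rejection region has
vanishing mass in practice). No MCMC library is involved; the sampler is
~150 lines and seed-deterministic by construction, with chain *c* seeded at
`seed + 7919 (c − 1)`.

Numerical conditioning: a cubic design in raw hours up to 84 h has entries
spanning nine orders of magnitude, so time is internally rescaled by 10
(`t/10`), priors are mapped onto the scaled basis exactly
(sd 10^3 · 10^j for coefficient j), and draws are transformed back. Users
only ever see the raw-hours basis.

Defaults mirror the reported analysis settings: 3 chains × 100 000
iterations, thinned to every 3rd draw, discarding the first 100
post-thinning draws per chain. The phrase "removing the first 100 samples"
is interpreted as post-thinning draws per chain (the sentence orders
thinning before burn-in); both the count and the interpretation are
configurable via `sampler_settings()`. Convergence is checked with the
classic (non-split) Gelman–Rubin statistic,
$\hat R = \sqrt{(\frac{n-1}{n} W + \frac{B}{n})/W}$, with zero
within-chain variance flagged as degenerate and reported as 1.

## Constraint filtering and derived parameters

Two a-priori constraints screen posterior draws: (i) the cubic has a local
maximum at t > 0, and (ii) the fitted curve is strictly positive at every
grid point across the sampling window (default step 0.1 h, configurable).
Positivity is checked on a grid rather than by exact root-finding because
the constraint concerns pointwise concentration estimates over the window,
and a grid is robust to every coefficient sign pattern. Draws are never
deleted — a retained mask is recorded — and shrinking the window can only
enlarge the retained set.

For retained draws, the critical points are the roots of
$3 b_3 t^2 + 2 b_2 t + b_1 = 0$, classified by the sign of
$6 b_3 t + 2 b_2$. Then `cort_max` is the **cubic itself** evaluated at
`t_max`. (Back-substituting `t_max` into the first-derivative equation — one
published description of this step — yields identically zero; the package
treats that as a typo and evaluates the curve, which matches the reported
magnitudes' scale.) Distribution time equals `t_max`; elimination time is
`t_min − t_max`.

Two deliberate edge policies:

- `t_max` is *not* required to lie inside the sampling window — published
  credible intervals for these quantities extend past the window — only
  t > 0 is enforced.
- Draws with `b3 < 0` place the local minimum before the maximum; they
  satisfy constraint (i) and stay retained, but their elimination time is
  undefined under the min-after-max convention and is reported as `NA` with
  a flag rather than as a negative number.

Summaries are the posterior mean plus the equal-tailed 90% interval using
linearly interpolated order statistics (R quantile type 7), chosen so that
hand examples are exact (draws 1…100 give CI (5.95, 95.05)). The mean of a
derived quantity can fall outside its own 90% CI: `t_max` and `cort_max`
are heavy-tailed functionals of the coefficients, and no unimodality is
assumed.

## Treatment/control comparison

Treatment and control posteriors are fit independently, so no natural
pairing of draws exists. The package's rule: both retained sets are
shuffled with a seeded RNG, truncated to the shorter length, and paired by
index; a `pairing = "index"` option skips the shuffle, which makes
identities exact (treatment ≡ control gives a ratio of exactly 1 with a
zero-width band). Per pair, the proportional curve is the treatment cubic
divided by the control cubic on a 0.1 h grid, summarised pointwise by the
mean and 5th/95th percentiles. Grid points where a pair's control curve is
non-positive are dropped for that pair and counted; since control
posteriors are themselves positivity-filtered over the same window, this is
a guard, not a routine event.

Exceedance significance is the proportion of retained draws whose
`cort_max` exceeds (a) the mean time-0 concentration of the same subset and
(b) the paired control cubic evaluated at that draw's own `t_max` — the
closest literal reading of "temporally aligned modelled control values". An
alternative alignment at the posterior-mean `t_max` is available behind a
switch. Exceedance uses retained draws only, consistent with filtering
preceding all derived reporting. One known subtlety: under treatment ≡
control, evaluating the control draw at the *treatment* draw's argmax makes
`p_above_control` slightly exceed 0.5 (a draw's own maximum is compared to
another draw off its maximum); the bias is second-order in the posterior
spread of `t_max` and vanishes for well-identified fits, which the identity
acceptance criterion checks within binomial bounds.

## The synthetic-data generator

`simulate_study()` emulates the study design: per trial, tanks randomised
to arm (default ACTH trial 3+1, cortisol trial 2+2, 5 fish/tank), sampling
at 0, 2, 4, 8, 12, 24, 36, 48, 72, 84 h, one fish per tank per event, each
fish sampled once in 0–12 h and once in 24–84 h with ≥ 24 h between — the
rank-preserving round-robin assignment satisfies the gap by construction.

Ground truth is a two-compartment shape: plasma = baseline + handling
spike `A_h e^{-k_h t}` + (treatment only) Bateman pulse
`A_p \frac{k_a}{k_a-k_e}(e^{-k_e t} - e^{-k_a t})`; mucus follows the
plasma excess through first-order transfer and elimination, solved in
closed form as two-exponential convolutions with the `t e^{-at}` analytic
limit when rates coincide within 1e-8 (the unit tests verify the closed
form against RK4 integration at step 1e-3 h to 1e-6 relative).

Default parameters state the world the analysis is tested in: baselines 50
(plasma) and 5 (mucus) ng/ml; handling spike 180 ng/ml decaying at 0.25/h
(time-0 plasma ≈ 230 ng/ml); pulse amplitude 750 ng/ml with k_abs = 0.125/h
and k_elim = 0.05/h, placing the noiseless plasma peak near the 12 h window
edge at ≈ 470 ng/ml; transfer 0.0013/h and mucus elimination 0.0045/h,
placing the mucus peak near 62 h at ≈ 21 ng/ml — i.e. the ~50 h
plasma-to-mucus delay and the order-of-magnitude attenuation the study
reports. Between-fish variability is a mean-one lognormal multiplier with
log-sd 0.3 (moderate inter-individual cortisol variability; no quantitative
value is published for this design, so this is a choice, not a claim — the
same goes for the handling-spike magnitude). Assay noise is mean-one
lognormal with CV 10.95% (plasma) and 12.66% (mucus), the intra-assay ELISA
CVs reported for the two matrices.

What the generator does **not** emulate — and hence what a green recovery
test does not establish: water temperature, photoperiod, feeding, sex/size
covariates; assay non-linearity near the standard curve's limits; any
difference in kinetics between endogenous (ACTH-induced) and exogenous
(injected) cortisol — both trials share one parameter set, whereas real
exogenous cortisol shows little mucus transfer; and tank effects beyond arm
assignment. Fish identities are distinct across trials (the real study
reused its 20 fish after a washout), because the measurement-table key
(fish, time, matrix) must stay unique across the pooled table.

## Numerical choices, degenerate inputs, limitations

- Positivity grid step 0.1 h; filter and curve grids include the window
  endpoint even when the step does not divide the window.
- Cubic fits need ≥ 5 observations over ≥ 4 distinct times; fewer is an
  error, not a warning.
- `critical_points()` treats absence (negative discriminant, or a
  degenerate cubic with no interior extremum) as a value (`NA`), never an
  error; a quadratic (`b3 = 0, b2 ≠ 0`) yields the single critical point of
  that parabola.
- All-draws-filtered is an explicit downstream error rather than an empty
  summary.
- Known limitation: with data that rise monotonically to the window edge
  (the plasma ACTH case by design), many draws have `t_max` at or beyond
  the edge and retention rates drop; reported plasma peaks are then
  window-edge-conservative, exactly as in the motivating analysis.
- Monte Carlo artifacts: derived-quantity posterior means are heavy-tailed;
  prefer the CIs for interpretation.
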