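---
title: "Designing and stress-testing trials where treatment slows a rate of change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and stress-testing trials where treatment slows a rate of change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slopesim)
library(dplyr)
```

## The problem

In progressive diseases — secondary progressive multiple sclerosis,
Huntington's disease, Alzheimer's disease — a treatment's goal is often to
slow deterioration rather than reverse it. Trials of such treatments
measure a continuous outcome repeatedly over years and are usually
analysed with a *random slopes* mixed model: each person gets a random
intercept and a random slope over time, and the treatment effect is the
difference between the mean slopes of the two arms,

$$y_{ij} = \beta_0 + \beta_1 t_j + \gamma z_i t_j + u_{0i} + u_{1i} t_j + e_{ij},$$

with $(u_{0i}, u_{1i})$ bivariate Gaussian (variances $\sigma^2_{u0}$,
$\sigma^2_{u1}$, covariance $\sigma_{u01}$) and
$e_{ij} \sim N(0, \sigma^2_e)$. The shared baseline mean $\beta_0$
exploits randomisation and makes the analysis more efficient than
estimating a separate baseline per arm. The implied covariance of one
person's visit vector is
$\Sigma_{jk} = \sigma^2_{u0} + t_j t_k \sigma^2_{u1} + (t_j + t_k)\sigma_{u01} + 1\{j=k\}\sigma^2_e$,
and because the model is parametric in time this covariance can be
evaluated on *any* visit schedule, not just the one the components were
estimated from.

Sample sizes for such trials are computed in two stages: estimate the
variance components from an existing dataset (typically an observational
study in a similar population, analysed with the same model minus the
treatment term), then plug them into
$$N = 2\left\lceil \frac{(z_{1-\alpha/2} + z_{1-\beta})^2}{d^2}\,V(\hat\gamma)\right\rceil,$$
where $V(\hat\gamma)$ is the treatment-slope variance in a hypothetical
two-person trial (one person per arm) and $d$ is the target slope
difference. The two-person device works because the variance of an
$N$-person 1:1 trial is exactly $V(\hat\gamma)/(N/2)$.

The random slopes model assumes linear mean trajectories and a group
difference growing proportionally with time. `slopesim` exists to measure
what happens to the resulting trial — its power, type-I error and
standard-error calibration — when either assumption fails, and to compare
the random slopes analysis with less restrictive alternatives.

## The data-generating mechanism

`simulate_observational()` and `simulate_trial()` generate balanced,
complete long-format cohorts with mean $6 + 0.2 f(t)$ in untreated
people. The transform $f$ takes four shapes (`f_shape()`): `steady`
($f(t) = t$), `early` ($-5e^{-2t}+5$), `late` ($e^{2t}/4400$) and
`intermediate` (a logistic decline centred at 2.5 years). All four start
at 6 and end at 7.00 (2 dp) at five years, so they differ only in *when*
the decline happens. Non-linearity enters the fixed part only — the
random-effect term $u_{1i} t_j$ stays linear — so all shapes share one
covariance structure and mean-shape effects are isolated from covariance
effects.

Treatment effects (`treatment_effect()`) take three shapes: proportional
to time ($\gamma t$, the shape the analysis model assumes), proportional
to the control arm's own change ($\gamma f(t)$), and delayed decline
(flat for `delay` years, then the control curve shifted right — defined
only for the steady shape, where the other two coincide). The default
parameters ($\gamma = -0.05$/year with $\sigma^2_e = 0.15$,
$\gamma = -0.1$/year with $\sigma^2_e = 2$, delays 1.25 and 2.5 years)
are calibrated so every scenario has the same treated-minus-control
difference of $-0.25$ (or $-0.5$) at five years; with shorter follow-up
the non-proportional effects differ sharply across shapes, which is the
point of the exercise.

Reference variance components are $\sigma^2_{u0} = 0.5$,
$\sigma^2_{u1} = 0.01$, $\sigma_{u01} = 0.5\sqrt{0.005}$ (correlation
0.5), with $\sigma^2_e \in \{0.15, 2\}$. Allocation is exactly 1:1
(half the subjects per arm, ids shuffled under the seed) rather than
per-subject Bernoulli, keeping arms exactly balanced as the two-person
variance formula assumes.

What the generator deliberately does **not** emulate: missing visits and
dropout, non-Gaussian outcomes, unequal allocation, measurement-timing
jitter, and person-level variation in *when* a non-linear decline occurs.
Passing tests therefore speak to estimator behaviour under clean,
complete data; real cohorts add complications (informative missingness
above all) that sit outside this package's scope.

## The four analysis models

* **Random slopes (`fit_random_slopes()`)** — the model above, by
  constrained REML. Optimisation runs on log-variances plus an atanh
  correlation clamped to $\pm 0.999$, which makes the familiar
  "correlation on the boundary" failure a finite, well-defined point of
  the search space; fits with a back-transformed correlation of magnitude
  above 0.99 carry `boundary = TRUE`. A fixed optimiser ladder
  (`fit_with_ladder()`) — BFGS from method-of-moments starts, a
  Nelder-Mead restart, BFGS from a diagonal random-effects start — is
  worked through until a rung converges; a rung counts as converged when
  the optimiser reports success and the central-difference score norm is
  below $10^{-4}(1 + |\ell_R|)$. Non-convergence is recorded, never
  raised.
* **Linear trajectories, free covariance (`ltfc`)** — same mean
  structure, unstructured covariance.
* **Free control-group trajectory, free covariance (`fctfc`)** — a free
  mean per visit in the control arm, treatment effect still
  $\gamma z t$. On steady-decline data this reproduces the `ltfc`
  treatment effect essentially exactly, which is why the scenario grid
  carries it only in the one cell where the comparison is informative.
* **Free trajectories, free covariance (`ftfc`)** — a free mean per visit
  per arm with the baseline difference constrained to zero
  ($\gamma_0 = 0$). Its final-visit coefficient is the model-free
  estimand.

The marginal models are fitted by iterated GLS: alternate
$\hat\beta = (X^T\hat\Sigma^{-1}X)^{-1}X^T\hat\Sigma^{-1}Y$ with the ML
covariance update $\hat\Sigma = N^{-1}\sum_i r_i r_i^T$ until the
log-likelihood changes by less than $10^{-10}$ (relative), with a
200-iteration budget. ML rather than REML is used for $\hat\Sigma$
because the fixed effects — the quantities compared across models — are
identical under either, and at the trial sizes involved (hundreds of
subjects) the SE difference is far below Monte-Carlo resolution.

Every fit reduces the data to per-arm sufficient statistics (counts,
visit-mean vectors, raw scatter matrices), so one likelihood evaluation
costs $O(n_{\text{visits}}^3)$ regardless of cohort size; this is what
makes thousand-replicate simulation loops affordable in pure R.

All four fits funnel into one estimand (`final_time_effect()`): the
treated-minus-control mean difference at the final visit.
Slope-parameterised models convert by multiplying $\hat\gamma$ and its SE
by the follow-up time, which leaves the Wald statistic unchanged.

### Degrees of freedom

Mixed-model trial analyses of this kind conventionally apply
Kenward-Roger small-sample corrections. Exact Kenward-Roger is not
implemented here;
instead the Wald test uses a $t$ reference with Satterthwaite-style
degrees of freedom for the random slopes model (from the REML information
of the variance components and the gradient of $V(\hat\gamma)$, with a
residual-df fallback when the information matrix is unusable) and
residual degrees of freedom ($N$ minus the between-subject design rank,
i.e. $N-2$) for the marginal models. At the trial sizes these scenarios
produce ($N$ from roughly 230 to over 2000) both corrections are
numerically negligible — the simulation suite verifies that rejection
rates sit within Monte-Carlo error of their nominal values — but at small
$N$ the substitution is *not* claimed equivalent.

## Sample-size machinery

`var_gamma_two_person()` builds the stacked two-person design and returns
the $(3,3)$ element of $(X^T\Sigma^{-1}X)^{-1}$; `slopes_sample_size()`
applies the ceiling formula (normal quantiles, exactly as the standard
formula prints them, not $t$); `sample_size_curve()` sweeps trial
lengths. One notational wrinkle: with visits indexed $0,\dots,n_t$ the
two-person covariance is $2(n_t{+}1)$-square, although it is often
loosely written as $2n_t \times 2n_t$; the implementation always builds
it from the schedule including baseline.

`expected_rs_effect()` computes the *pseudo-true* slope: the large-sample
expectation of $\hat\gamma$ when the true group difference is not
proportional to time, i.e. element $\gamma$ of
$(X^T\Sigma^{-1}X)^{-1}X^T\Sigma^{-1}\mu$. The weights depend on the
covariance supplied; since a misspecified-mean fit converges to the
KL-projection covariance rather than the generating one, the recommended
input is the random-slopes fit to a large simulated control-arm cohort
under the target mechanism (that is what the harness cross-check uses),
but any `variance_components` may be supplied.

## The simulation harness

`run_replicate()` executes the six-step loop: simulate a 1000-person
observational study; fit the observational random slopes model through
the ladder; size the trial from the estimates ($d = -0.05$ or $-0.1$ per
year, $\alpha = 0.05$, power 80%); simulate the trial under the
scenario's true effect; fit each requested model; extract the final-visit
estimand. `run_scenario()` repeats and aggregates into power/type-I
error, mean effect, empirical SE (SD of estimates), mean model-based SE
(root mean variance) and percentage SE bias, with Monte-Carlo SEs
throughout. Estimation metrics use only replicates where every requested
model converged; the exclusion count is always reported.

Seeding follows a two-level scheme: each replicate derives a child seed
(`child_seed()`, a multiplicative hash into $[1, 2^{31}-1]$) from the
scenario base seed and the replicate index, so replicates are
individually reproducible and order-independent. Observational-stage
seeds are keyed on (shape, $\sigma^2_e$, replicate) only — *not* on the
treatment-effect kind — so scenarios differing only in their effect share
the identical sequence of observational studies and trial sizes — a
computational shortcut that also removes sample-size noise from the
comparison across effect shapes.

The optional `boundary_filter = "exclude_obs_boundary"` drops whole
replicates whose *observational* fit landed on the correlation boundary,
mirroring the sensitivity analysis an analyst would run after noticing a
degenerate pilot fit; it never alters surviving estimates. The exact
stage at which such filtering should apply is ambiguous in general — this
package resolves it by filtering on the observational fit, before any
trial data are analysed.

## Numerical choices and degenerate inputs

* REML/ML evaluations fail softly (singular covariance returns a large
  penalty inside optimisation; an explicit error from the public
  log-likelihood function).
* Variance floors of $10^{-6}$–$10^{-8}$ appear only in starting values
  and back-transforms, never as estimation constraints beyond the
  parameterisation itself.
* Zero-residual-variance fixtures are handled in tests through
  `gls_fixed_effects()` (fixed effects at a *known* covariance, exact on
  noiseless data); production fitting expects $\sigma^2_e > 0$ data.
* `fctfc`/`ftfc` need at least two visits; `rs`/`ltfc` need at least two
  distinct times. Trials must have even $N$; odd totals are rejected
  rather than rounded.

## Problem sizes used by the test and acceptance suites

A full-scale study of these scenarios would run thousands of replicates
(5000 give a Monte-Carlo SE of 0.6% at 80% power). This package's own
reproductions run at desk scale — 200 to 500
replicates per scenario, chosen so the full acceptance computation
completes in a few minutes on one core — and every comparison carries a
tolerance of three Monte-Carlo SEs *at the replicate count actually
used*. Measured this way: steady-decline proportional-effect power lands
within noise of 80%, the null scenario within noise of 5%, the
free-trajectories analysis of non-proportional 5-year scenarios bottoms
out near 70%, the early-decline 3-year scenario's mean random-slopes
effect is about $-0.080$/year against a $-0.05$/year target, and the
residual variance is over-estimated by under 5% for non-linear shapes at
$\sigma^2_e = 2$. These are scaled-down reproductions, not the full
grids.

## Package shape

The package is tidyverse-native: generators and summaries return tibbles,
fitted objects carry `tidy()`/`glance()` methods, result types have
`autoplot()`/`plot_*()` builders, and all user-facing functions compose
with the pipe. A thin command-line wrapper
(`inst/cli/slopesim.R`) exposes simulate / fit / samplesize /
run-scenario subcommands for shell use; the R functions remain the
primary interface.

## Known limitations

Beyond the generator's idealisations listed above: exact Kenward-Roger
inference is not implemented; likelihoods assume balanced complete data
(by design — the engines exploit it); there is no covariate adjustment
beyond arm and time; sample-size support for the free-trajectories
estimand is out of scope (it would require imposing a covariance
structure to extrapolate across schedules); and convergence behaviour is
that of this package's optimiser ladder, not of any particular commercial
mixed-model implementation — boundary *rates* are comparable, exact
convergence counts are not.
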