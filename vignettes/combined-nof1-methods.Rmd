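---
title: "Combining N-of-1 trials with a hierarchical Bayesian model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining N-of-1 trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1bayes)
```

## The problem

Randomized evidence for treatments of rare diseases is hard to produce:
eligible patients are few, and conventional parallel-group trials are
underpowered or infeasible. When the disease is chronic and stable and the
drug acts and washes out quickly — as with mexiletine for the myotonia of
non-dystrophic myotonia (NDM) — a series of **N-of-1 trials** is an
attractive alternative: each patient repeatedly crosses over between active
drug and placebo in randomized order, serving as their own control, and a
hierarchical Bayesian model pools the single-patient trials into a
population estimate while returning individualized, shrinkage-stabilized
effect estimates.

The package implements that whole pipeline: the trial schedule, a
data-generating model for design work, the hierarchical analysis, the
per-patient sequential stopping rules, the simulation-based sample-size
("assurance") calculation, expert prior elicitation, a cost-effectiveness
layer and the deterministic scoring rules of the quantitative myotonia
instruments.

## Trial design

A **treatment set** is two 4-week treatment periods (one active, one
placebo, order block-randomized within the set), a 1-week washout between
them, and 2 weeks of analysis at the end: 11 weeks. A patient completes one
to four sets (11–44 weeks). Weeks are 1-based integer indices and
`build_schedule()` lays sets out contiguously; `randomize_orders()` draws
each set's order independently with probability ½ under a recorded seed. We
deliberately do not constrain orders across sets (e.g., forbidding four
identical orders): the protocol randomizes within set only, and the
analysis model can estimate an order effect rather than design it away.

The diary outcome is self-rated symptom severity on a 1–9 ordinal scale,
collected daily during the last two weeks of each period (14 scheduled
calls). The analysis assumes 10 usable observations per arm per pair; the
gap between 14 scheduled and 10 modeled observations is anticipated
missingness, and `obs_per_arm_per_pair` is configurable.

The minimal clinically important difference uses the distribution-based
half-SD rule: with the previously reported within-subject SD of 1.5, the
MCID is `mcid_half_sd(1.5) = 0.75` points.

## The data-generating model

`simulate_cohort()` draws, for patient $i$:

$$a_i \sim N(0, \sigma_a^2), \quad b_i \sim N(0, \sigma_b^2),$$

and then diary observations

$$y_{ij} = \mu + a_i - T_{ij}\,(\beta_0 + \beta_{sub} x_i + b_i) + \varepsilon_{ij},
  \quad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with $T_{ij}$ the active-arm indicator and $x_i$ the centered subgroup
contrast (chloride $-\tfrac12$, sodium $+\tfrac12$). **Sign convention**
(fixed package-wide): $\beta_0 > 0$ means active treatment *lowers*
severity; active outcomes are generated by subtracting the effect.

Defaults are the study conditions: 30 patients split 15/15 by channelopathy
subgroup, 2 pairs × 10 observations per arm, placebo level $\mu = 4.21$
(the placebo mean of the earlier crossover RCT), residual SD
$\sigma = 1.5$ (the reported within-subject SD). The random-effect SDs are
not reported anywhere, so they are fixed once at values we consider
clinically realistic for this scale — $\sigma_a = 1.0$ (patients differ
visibly in baseline severity) and $\sigma_b = 0.5$ (moderate heterogeneity
of response) — and exposed as configuration for sensitivity sweeps.

Outcomes are continuous by default, matching the normal model used for
design calculations; ordinal clipping to the 1–9 grid (`clip_to_ivr()`) is
an opt-in stress test. The generator reproduces the random-effects normal
structure; it does not emulate serial correlation within periods, carryover
across the washout, missingness patterns, floor/ceiling compression of the
ordinal scale, or reporting behaviors — passing tests say the *method*
works under its assumed model, not that real diary data satisfy those
assumptions. Per-patient residual SDs may optionally be drawn
log-normally around $\sigma$ (`resid_heterogeneity`), but a common residual
SD is the default, which we consider the more defensible reading of the
power-simulation setup.

## The hierarchical analysis

`fit_hierarchical()` samples the posterior of the same model (plus optional
treatment×set and treatment×order interaction slopes with flat priors)
with a **conjugate Gibbs sampler**: all location parameters have normal
full conditionals, variances inverse-gamma ones. Two residual-variance
modes are provided:

* `"common"` — one $\sigma^2$ with an inverse-gamma prior; fully conjugate,
  fast, used for oracle tests and the assurance path;
* `"per_patient"` — patient-specific $\sigma_i^2$ tied together by a shared
  scaled-inverse-$\chi^2$ distribution ($\nu = 4$ by default) whose scale
  carries a gamma hyperprior — the "within-person residual variance drawn
  from a common distribution" construction.

Priors on $\beta_0$ may be normal (the informative Normal(1.75, 0.89)
carried over from the earlier RCT is the default), flat, or a
piecewise-constant histogram from elicitation, in which case the full
conditional is a mixture of truncated normals over the bins and is sampled
exactly. The "flat" prior is a proper normal with SD 100 — effectively flat
on a 1–9 scale while keeping every posterior proper; the same constant
backs the flat priors on $\mu$ and the fixed-effect slopes. The subgroup
contrast is centered so that $\beta_0$ always remains the *overall* mean
effect the priors refer to.

Two sampler-efficiency devices are worth noting because they change mixing,
not the posterior. First, each scan includes *recentering (interweaving)
moves*: shifting $(\mu + c, a_i - c)$ or $(\beta_0 + c, b_i - c)$ leaves the
likelihood invariant, so the shift $c$ has a conjugate normal conditional
derived from the priors alone; sampling it decorrelates the fixed effects
from the random-effect means. Second, the single-patient sampler
(`fit_single_patient()`, the interim-analysis engine) draws the effect with
the patient level $\mu_i$ integrated out exactly — the integrated
log-likelihood is quadratic in the effect, so its mean and precision are
recovered from three evaluations — removing that autocorrelation entirely.

Convergence is never assumed: split-$\widehat R$ and effective sample size
are computed for every sampled parameter, and the documented acceptance
gate is $\widehat R \le 1.05$ **and** ESS $\ge 400$ on $\beta_0$; failures
raise a warning and clear the `converged` flag.

Per-patient effects $\theta_i = \beta_0 + \beta_{sub} x_i + b_i$ exhibit
shrinkage: posterior means lie between the patient's raw period-mean
difference and the population mean, approaching the former as
$\sigma_b \to \infty$ and the latter as $\sigma_b \to 0$ — both limits are
exercised in the tests with fixed variance components, where the
normal–normal closed form is available as an oracle.

`fit_crossover_frequentist()` supplies the traditional comparator: each
patient reduced to the difference of placebo and active period means,
analyzed by a paired t-test. With a flat prior and many patients the
Bayesian posterior mean and the frequentist estimate agree, which the tests
check.

## Sequential interim analyses

After sets 1, 2 and 3 (never 4 — the final set feeds only the combined
analysis), the patient's cumulative data are fit with the single-patient
model under a **flat prior only** (the stopping advice should rest on the
patient's own data), and the posterior probability of an effect of at least
0.75 is mapped to advice: $\ge 0.80$ stop and start open-label treatment,
$\le 0.20$ stop without it, otherwise continue. Boundaries are inclusive,
matching the protocol's "at least"/"at most" phrasing. The interim fit
deliberately borrows nothing from other patients: the protocol frames the
interim as individual advice during the trial; a cohort-borrowing interim
would change its operating characteristics and is out of scope.

## Assurance: the five-step sample-size simulation

No closed-form power calculation exists for this design, so the sample size
is justified by simulation (`run_assurance()`): per iteration (1) draw a
true mean effect from a *truth prior*; (2) simulate 30 N-of-1 trials of
2 × 10 × 2 observations under the random-effects model; (3) fit the
hierarchical model with the *analysis prior*; (4) take the marginal
posterior of $\beta_0$; (5) record $P(\beta_0 \ge 0.75)$. The average over
iterations is the **expected posterior probability** of a clinically
meaningful effect — a Bayesian analogue of power.

Both priors default to Normal(1.75, 0.89), the only elicited prior whose
parameters are printed in the protocol; treating it as the truth prior as
well is an assumption, exposed as configuration. Per-iteration sub-seeds
are drawn once from the master seed, making the run bit-reproducible, and
iterations failing the $\beta_0$ convergence gate are re-run on a reserved
sub-seed and counted. The assurance path uses the common-residual-variance
conjugate sampler (2 chains, 300 warmup + 900 kept scans per iteration by
default) for speed; the per-patient variance mode is available behind
`residual_variance_mode = "per_patient"` at higher cost.

At the default conditions the expected posterior probability computes to
about 0.88 (Monte-Carlo SE ≈ 0.02 at 300 iterations; the acceptance script
recomputes it at every run). An analytic sanity check lands in the same
place: the preposterior distribution of the posterior mean is roughly
$N(1.75, 0.87^2)$ and the posterior SD of $\beta_0$ about $0.13$, giving
$E[P] \approx \Phi(1.00/0.88) \approx 0.87$. Values nearer 0.80 would
require substantially larger between-patient or residual variability than
our documented defaults — those components are exactly what the protocol
does not print — so the defaults stay put and the number is what it is.

## Prior elicitation

`make_histogram_prior()` normalizes a single expert's bin weights;
`pool_priors()` aggregates experts by the **linear opinion pool** (the
protocol says "aggregated" without naming a rule; the linear pool is the
transparent default — it preserves normalization exactly, is linear in the
expert weights, and its mean is the weighted mean of expert means;
logarithmic pooling is out of scope). Pooled histograms can be used
directly as $\beta_0$ priors (the sampler handles piecewise-constant
densities exactly) or bridged to a moment-matched normal with
`fit_normal_to_histogram()`; the two routes agree when the histogram is
near-Gaussian, which a test checks on a fixture. The elicitation grid
(bin width and range) is not specified by the protocol and is left to the
user.

## Cost-effectiveness

Per-patient costs are resource volumes × unit costs (Dutch national
guideline rates; currency and price year are labels, EUR/2014 by default).
The incremental cost-effectiveness ratio is reported only in the
sign-concordant quadrants ("more effective and more expensive, or less
effective and less expensive"); a cheaper-and-better configuration returns
a dominance flag and a zero effect difference an undefined-ICER flag rather
than a number. Intervals are **percentile bootstrap** (not BCa — the
protocol names only "nonparametric bootstrapping"), resampling patients
with replacement within arm; the ICER interval is suppressed with an
explanatory flag whenever any resample leaves the concordant quadrants,
while cost and effect intervals are always returned. Effects enter as a
supplied per-patient scalar (quality-of-life units); within-patient arm
contrasts are the default comparison.

## Instrument rules

Three deterministic rules are implemented exactly as defined clinically:

* **Needle-EMG grading** (Streib): discharges in 0–2 of 10 insertions →
  grade 0; 3–5 → 1+; 6–9 → 2+; 10/10 → 3+. A total monotone step function
  on 0..10.
* **Grip relaxation time**: time from the force falling through 90% of peak
  to first falling through 5% of peak after a maximal voluntary isometric
  contraction. Crossings are linearly interpolated between samples (bedside
  timings are recorded to two decimals, so sub-sample precision matters).
  On a non-monotone decay the *last* 90% down-crossing before the 5%
  crossing is used — the intervening rebound is contraction, not
  relaxation. A trace that never reaches 5% of peak raises a not-relaxed
  error rather than returning a number.
* **Transient paresis**: percent decline from peak force within a 3-second
  window after the peak; a peak at the window end returns 0 with a warning.

## Numerical choices and degenerate inputs

* Variance hyperpriors default to inverse-gamma(0.01, 0.01) — weakly
  informative on the scale of a 1–9 score; fixed variance components
  (`fixed =`) switch the corresponding updates off, enabling exact
  conjugate oracles.
* Histogram-prior sampling clamps the inverse-CDF argument to
  $[10^{-12}, 1 - 10^{-12}]$ and falls back to the nearest supported bin
  when the likelihood mass lies entirely outside the histogram's support.
* Patients observed in only one arm are retained (they inform $\mu$ and
  $\sigma$) but flagged: their individual effects are prior-dominated.
* Degenerate zero-variance inputs (all differences equal, zero-SD
  simulators) are handled explicitly rather than through the generic path.
* Chain initial values are mildly overdispersed around data-driven centers;
  chain seeds derive deterministically from the master seed.

## Problem sizes used in the test suite

Module tests run on deliberately small configurations (4–20 patients, 100
replicate loops for coverage-style checks, 200–500 bootstrap replicates);
the study-scale checks use the full 30-patient design with 200 assurance
iterations and 50 replicate cohorts for bias. These sizes give Monte-Carlo
error comfortably below the tolerances asserted, which is the criterion by
which they were chosen.

## Known limitations

* The outcome model is Gaussian; the 1–9 ordinal scale is treated as
  continuous (as in the design calculations). No ordinal likelihood.
* No carryover or serial-correlation modeling; the washout is assumed to
  work.
* The interim analysis is per-patient only; borrowing at interim is not
  implemented.
* Model comparison/selection machinery is out of scope.
* The CEA layer ignores discounting (time horizon under a year) and does
  not produce acceptability curves.
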