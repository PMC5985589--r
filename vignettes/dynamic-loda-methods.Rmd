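---
title: "Dynamic longitudinal discriminant analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic longitudinal discriminant analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Clinical cohorts often carry several longitudinal biomarkers of mixed
type — a binary indicator, a transformed count treated as continuous, a
raw count — observed at irregular, marker-specific visit times, and the
question of interest is a *group* label that only becomes known later:
in the motivating epilepsy setting, whether a patient will fail to
achieve a 12-month remission within five years of diagnosis
("refractory", the rarer target group) or not ("remission").  `dloda`
fits a joint longitudinal model per prognostic group on labelled
training data and then, for a new subject, converts the accumulating
marker history into a posterior probability of group membership that is
refreshed at every visit, together with a one-shot allocation rule that
classifies as early as the evidence allows.

## The group model

Within group $g$, marker $r$'s observation $y_{r,j}$ at time $t_{r,j}$
follows an exponential-family distribution with canonical link $h_r$
and mean

$$h_r^{-1}\{E(y_{r,j} \mid b)\} = x_{r,j}^\top \alpha_r^g + z_{r,j}^\top b_r,$$

where $b = (b_1, \dots, b_R)$ is a subject-level random-effects vector
shared across markers.  Correlation within and between markers is
carried entirely by $b$, which follows a group-specific finite normal
mixture

$$b \mid g \sim \sum_{k=1}^{K_g} w_k^g\, \mathrm{MVN}(\mu_k^g, D_k^g).$$

The mixture robustifies the analysis against misspecification of the
random-effects law (skewness, subpopulations) that a single normal
cannot capture.

**No fixed intercept.**  Every marker's random part contains an
intercept whose mixture mean is left free, so a fixed intercept would
be non-identified beside it (any constant shifts freely between the
two).  `dloda` therefore puts *no* intercept column in the fixed
design; the marker's overall level in group $g$ is read off the
mixture-implied mean of the random intercept, and the fixed effects are
exactly the declared covariates (e.g. time since diagnosis, in days).
This matches how the motivating application reports its results — the
"expected value of the random intercept" is quoted as the group-level
marker level — and is the single deliberate departure from the
convention of carrying an implicit leading 1 in both designs.

Two derived covariates are available without being present in the data:
`time_since_diagnosis` (the visit time, days) and
`time_since_last_visit` (the gap to the previous visit *of that
marker*, since markers keep their own grids; at a marker's first visit
it equals the time since diagnosis).  Covariates are used as supplied —
no automatic standardization.

## Estimation

Each group is fitted independently by MCMC on the augmented model
(mixture allocations and subject random effects as latent variables):

* allocations: categorical Gibbs given $b$ and the mixture;
* weights: Dirichlet Gibbs;
* $(\mu_k, D_k)$: conjugate normal and inverse-Wishart Gibbs; an empty
  component is refreshed from its prior, keeping the chain irreducible;
* $b_i$: random-walk Metropolis, proposed jointly for all subjects and
  accepted subject-wise;
* $\alpha_r$: conjugate Gibbs for gaussian markers, random-walk
  Metropolis (proposal shaped by the fixed-effects-only GLM covariance)
  otherwise;
* gaussian dispersions: inverse-gamma Gibbs.

Proposal scales adapt toward ~0.3 acceptance during burn-in and are
frozen afterwards to preserve detailed balance.  Initialization is
deterministic given the seed: fixed effects from per-marker GLM fits
ignoring random effects, $b_i = 0$, mixture means by k-means on crude
subject-level intercepts.

**Weakly informative priors, concretized.**  Fixed effects are
independent N(0, $10^4$); gaussian dispersions inverse-gamma(1, 0.005);
weights symmetric Dirichlet(1).  The mixture-mean prior is centred at 0
with variance $4 \times$ the range of crude subject-level intercepts
(winsorized working-residual means from the initial GLM fits —
winsorizing matters because working residuals of near-saturated binary
fits are unbounded and would make the prior vacuous in exactly the
wrong way, letting near-empty components wander far out and corrupt
moment summaries).  The covariance prior is inverse-Wishart with df
$q+1$ and scale the diagonal of the crude intercept variances.  All
hyperparameters can be overridden in `prior_spec()`.

**Label switching** is not corrected during sampling.  Every quantity
used for discrimination depends on the mixture only through its density,
which is invariant to relabeling; `posterior_summary()` applies an
optional post-hoc ordering by the first coordinate of $\mu_k$ for
readable tables, and `mcmc_diagnostics()` computes effective sample
sizes on label-invariant functionals (fixed effects, the mixture
density at fixed points).

## Prediction rules

With prior group probabilities $\pi_g$ (assumed known; defaulting to
training frequencies with a warning) and posterior samples
$S^g = \{(\psi^{g,(m)}, \theta^{g,(m)})\}$, three estimators of
$P(U = g \mid \text{history up to } t)$ are available, each averaging
per-draw probabilities over the $M$ retained draws (the posterior-mean
estimator — not probabilities at averaged parameters):

* **marginal** — Bayes' rule on the marginal density of the history
  with random effects integrated out;
* **conditional** — the history's conditional density given a
  random-effects value sampled, per draw and group, from its predictive
  distribution (data-augmentation style, one draw per retained
  parameter draw);
* **random-effects** — the mixture density of those sampled
  random-effects values themselves.

The marginal integrals are approximated by a *per-component* Laplace
expansion: within each mixture component the integrand is log-concave
under canonical links, so Newton ascent from $\mu_k$ (warm-started
across draws) is reliable, and components are combined by weighted
log-sum-exp.  A single global Laplace on the multimodal mixture
integrand would not be safe; this per-component form follows the
model's own rewriting of the likelihood as a mixture of
single-component integrals.  The approximation is exact for all-gaussian
models and is validated against a tensor-product adaptive Gauss–Hermite
oracle (64 nodes per dimension, feasible for $q \le 4$) in the test
suite: across randomized mixed-family instances the absolute
log-density error stays below 0.05 and group rankings agree.

The predictive sampler for $b_{\text{new}}$ is an independence
Metropolis–Hastings step whose proposal is the mixture of per-component
Laplace normal approximations.  With an empty history the proposal
*equals* the target (the mixture prior), so draws are i.i.d. and
predictions reduce to the prior exactly for the marginal and
conditional rules.  One caveat is worth stating plainly: the
random-effects rule samples a *different* $b^g$ per group from
different laws, so with an empty history its estimator
$E[\pi_0 f_0(b^0) / \sum_{\tilde g} \pi_{\tilde g} f_{\tilde g}(b^{\tilde g})]$
is exactly $\pi$ only in symmetric configurations — equal priors *and*
identically distributed density values $f_g(b^g)$ across groups (for
normals, equal covariances; the means cancel since each $b^g$ is drawn
from its own law); away from symmetry, e.g. $\pi = (0.9, 0.1)$, it sits
a few percent toward uniform.  This is
a property of the estimator as defined, not of its implementation, and
is one reason the marginal rule is the default.

Numerical policy throughout: log-scale arithmetic with log-sum-exp;
gaussian dispersion parameterized as a variance; Newton convergence by
scale-invariant Newton decrement ($< 10^{-8}$, 50 iterations,
step-halving line search) with a quadrature fallback on the rare
non-convergence; probability vectors renormalized so they sum to 1 to
machine precision.

## The dynamic allocation scheme

Interest centres on detecting the target group early.  Scanning a
subject's visits in time order (visits strictly before the subject's
status-confirmation time — the five-year horizon for target-group
subjects, the final visit for the others), the subject is allocated to
the target group at the *first* visit where its probability strictly
exceeds a cutoff $c$; ties remain under observation; a subject never
allocated is assigned to the other group at the final considered visit.
Exactly one decision is made per subject, so ordinary ROC analysis
applies.  The decision *score* used for the ROC is the maximum
target-group probability attained over the considered visits — the
monotone-equivalent scalar of a first-exceedance rule, an
interpretation recorded in the CV report's metadata since other scores
(e.g. last-visit probability) are conceivable.  Cutoffs are candidate
midpoints of sorted unique scores; the default selection takes the
point closest to the top-left ROC corner, with Youden and
fixed-sensitivity/specificity rules available.

`cross_validate()` repeats stratified 70/30 splits: models fitted on
the training portion, the cutoff selected on training-subject scores
(no test leakage; pooled selection on the test side is available as an
option since either choice is defensible), the scheme run on the test
portion, metrics (sensitivity, specificity, PPV, NPV, PCC, AUC, lead
and prediction times over true positives) averaged arithmetically
across splits.  `full_data_compare()` evaluates, on the same fitted
models and trajectories, a non-dynamic alternative that uses only the
final pre-confirmation visit's probability, quantifying how much lead
time the dynamic scheme buys at what (if any) accuracy cost.

## Choosing the number of mixture components

`expected_deviance()` is the posterior mean of $-2 \log$
subject-marginal likelihood (random effects integrated out — the same
Laplace layer as prediction, and invariant to relabeling).
`penalized_deviance()` adds an optimism penalty: the default
`ped_pair` uses two independent chains and evaluates each chain's
per-subject plug-in at the *other* chain's best draw, summing both
directions — a deliberately simple cross-chain approximation to the
importance-sampling optimism estimator of the penalized-expected-
deviance literature; `dic` (single chain) uses twice the gap between
expected deviance and the deviance at the best retained draw, a
mixture-safe plug-in.  Negative penalties are flagged, never clipped.
`choose_K()` reports both criteria per candidate and, optionally,
cross-validated accuracy of each candidate, preferring predictive
accuracy with deviance as tiebreak — mirroring the view that for a
discriminant tool the predictive yardstick is the natural one.  Groups
may select different $K$.

## The synthetic-data generator

No public dataset carries the motivating study's structure, so
`sanad_like_scenario()` generates one with exactly the statistical
structure the model assumes: two groups with prevalences (0.9, 0.1);
three markers — a bernoulli-logit seizure indicator, a gaussian
log-scale seizure count, a poisson-log adverse-event count — with
correlated random intercepts ($q = 3$); a two-component mixture in the
remission-like group (a low-seizure and a moderate-seizure
subpopulation) against a single elevated component in the
refractory-like group; time-since-diagnosis slopes (per day, order
$10^{-3}$) whose sign flips between groups for both seizure markers;
roughly annual visits (gamma gaps, mean 330 days, SD 80, minimum 30
days) capped at five years, with per-marker observation probabilities
0.9–0.95 producing unequal grids.  Latent truths (component, $b$,
follow-up) ride along in an attribute, never in the emitted tables.
One global seed is split deterministically into per-subject streams.

What the generator does *not* emulate: informative follow-up length
(remission subjects in the real study stop early at remission — a
per-group follow-up cap is configurable but not the default), missing
or measurement-error covariates, visit schedules that react to disease
state, and any deviation of the data-generating law from the fitted
model family.  Passing tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to their
violation.

## Problem sizes and observed behaviour of the checks

The test suite exercises the full pipeline at sizes chosen for a single
CPU: parameter recovery uses 20 replicates of $n = 300$ subjects with
4000-iteration chains (at materially shorter chains the slope
components of the binary marker mix slowly — effective sample sizes
near 10 — and interval coverage degrades); the end-to-end experiment
uses 5 cross-validation splits at $n = 300$ with 800-iteration chains
and 40 prediction draws; mixture-order recovery uses 10 replicates of
$n = 80$ with paired 700-iteration chains.  Two finite-sample effects
are worth knowing about when reading recovery results: posterior means
of variance components sit above the truth when per-subject information
is low (with ~5 binary observations per subject the binary marker's
random-intercept variance runs ~20% high — stable across chain lengths,
i.e. not a mixing artifact), and the random-effects rule's empty-history
behaviour described above.  Both are properties of the estimators, and
both are asserted at their observed magnitudes in the tests rather than
hidden.

## Limitations

Nominal and ordinal marker families are out of scope, as are
time-to-event formulations of dynamic prediction (landmarking, joint
longitudinal-survival models) — a different question from the group
membership addressed here.  $K$ is chosen by comparing separately
fitted models, not sampled transdimensionally.  The Laplace layer
assumes canonical links (log-concavity in $b$ is what makes the
per-component mode search safe).  Random-effect dimension is expected
to stay small (random intercepts, possibly a slope); no sparse-Hessian
machinery is provided, and the quadrature oracle refuses $q > 4$.
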