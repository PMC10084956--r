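---
title: "Historical priors for the double burden of malnutrition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Historical priors for the double burden of malnutrition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dbmbayes)
```

This vignette is the package's account of its statistical methods: the
outcome definition, the three regression models and how they are fitted, the
prior-elicitation and sampling machinery, the diagnostics and the
model-comparison rule, what the synthetic generator does and does not
emulate, and the numerical and design choices that were genuinely open.

## Outcome: WHO BMI categories and the DBM recode

BMI is weight (kg) over height (m) squared. The four-category classification
uses strict/closed bounds exactly as printed in the source tables this
package mirrors: underweight `BMI < 18.5`, normal `18.5 ≤ BMI ≤ 24.9`,
overweight `24.9 < BMI ≤ 29.9`, obese `BMI > 29.9`. The boundary values 24.9
and 29.9 therefore belong to the *lower* category. WHO reference documents
sometimes state the cut-points as 25.0 and 30.0; we follow the inequality
signs of the survey analysis we reimplement, and a property test sweeps a
fine BMI grid to confirm the four intervals partition the plausible range.
BMI values outside [10, 60] kg/m² are treated as implausible instrument
readings: they are excluded with a reported count rather than classified.

The double burden of malnutrition is operationalised per woman as *any*
malnutrition: `DBM = 1` for underweight, overweight or obese, `0` for
normal. This matches the arithmetic of the published prevalence
(44.9 = 12 + 26.1 + 6.8); the "coexistence within a population" phrasing in
the literature is reporting language about the same quantity, not a
different estimand.

## The three models

With dummy-coded covariates (one indicator per non-reference level, named
`covariate=level`), all three models share the logistic linear predictor.

**Model 1 (classical).** Weighted Bernoulli log-likelihood maximised by
Newton–Raphson with step-halving; weights enter as frequency-style
multipliers (pseudo-likelihood). The covariance is the inverse observed
information at the optimum, and intervals are Wald — the conventional output
of the survey-analysis packages this mirrors. No design-based (linearised)
variance is attempted: the source analysis applied none, and the DHS cluster
design is explicitly out of scope here (weights are row weights only).
Convergence requires the largest score component below 1e-8 or a relative
log-likelihood change below 1e-10; divergence past |β| > 20 is reported as
separation. Initialisation is β = 0.

**Model 2 (flat prior).** Independent `N(0, 10⁶)` priors on every
coefficient including the intercept. Over the plausible coefficient range
(|β| ≤ 10) this prior's log-density varies by less than 1e-4, so the
posterior essentially reproduces the likelihood.

**Model 3 (historical prior).** The model is first fitted by ML on the
earlier survey wave; the estimator is then bootstrapped B times (default
1,000) and each coefficient's prior is `N(bootstrap mean, bootstrap
variance)`. Priors are univariate by construction — bootstrap covariances
are computed and attached for logging but deliberately unused, because the
elicitation targets the independent-normal form `β_j ~ N(μ_j, σ_j²)`.

### Parametric versus nonparametric bootstrap

The literature this package follows names the method "parametric bootstrap"
while describing with-replacement resampling, which is the nonparametric
scheme; which was actually run is not determinable from the text. Both are
first-class here: parametric (default) simulates outcomes from the fitted
probabilities on the fixed historical design and refits; nonparametric
resamples rows. On well-behaved data the two agree on prior variances within
a factor of two (tested), and the parametric variances track the asymptotic
inverse-information variances within 20% at B = 2,000 (tested). The
intercept receives a historical prior like every other coefficient by
default; pass a modified prior to `run_chains()` to override.

## The Metropolis–Hastings sampler

The posterior is sampled with a componentwise Gaussian random-walk
Metropolis–Hastings kernel. Design choices:

* **Componentwise proposals with incremental evaluation.** Dummy designs are
  sparse; updating one coefficient only changes the linear predictor on the
  rows where its column is non-zero, so each proposal costs O(rows touched),
  not O(n·p). The per-row `log(1 + exp(η))` terms are cached and patched.
* **Adaptation.** Proposal scales start at 2.4 × the Wald SE (or 2.4 × the
  prior SD when no MLE exists, e.g. prior-only runs) and follow a
  Robbins–Monro recursion toward the target acceptance rate (default 0.234)
  *during burn-in only*; scales are frozen afterwards, so the retained draws
  come from a fixed kernel satisfying detailed balance.
* **Settings.** The published run used 150,000 iterations per chain, burn-in
  500, thinning every 99th post-burn-in draw, 4 chains; that is the `"paper"`
  profile (1,510 kept draws per chain). The `"test"` profile
  (2,000 / 200 / 5 / 4; 360 kept per chain) keeps the identical sampler at
  interpreted-code runtimes and is the default used throughout the test
  suite and the acceptance script. Kept draws per chain are always
  `floor((iterations − burn_in)/thin)`; the three knobs are exposed because
  the published settings do not pin down a posterior sample size.
* **Initialisation.** `"mle"` (default) starts at the MLE; `"overdispersed"`
  jitters it by ±4 Wald SE per chain (uniform), which is what the
  Gelman–Rubin diagnostic needs to be meaningful; `"zero"` and
  `"prior-draw"` cover prior-only and robustness runs.
* **Stability.** The log-likelihood uses the stable `log1p(exp(·))` form and
  is overflow-free for |η| ≤ 700; a NaN in the accept ratio aborts with the
  offending iteration and component.

Correctness is established against independent oracles rather than another
MCMC implementation: a 10-row log-posterior against a naive per-row product;
a one-parameter posterior against numerical quadrature (mean and SD within
2%); the prior-only limit against the prior's own moments; and the flat-prior
posterior against the MLE sampling distribution at n = 5,000 (means within
0.5 Wald SE, SDs within 15% — the Bernstein–von Mises regime).

## Diagnostics and model comparison

`gelman_rubin()` implements the classical non-split Brooks–Gelman statistic
on whole chains — `Rc = sqrt(((n−1)/n · W + B/n) / W)` — matching the
criterion the source analysis cites; a `split = TRUE` flag provides the
modern split-chain variant. Degenerate chains (zero within-chain variance)
are an error, not an Rc of 1. Trace data are exported long-format for
overlaid trace plots; plot rendering is intentionally left to the user.

The three models are compared on the odds-ratio scale, where the published
tables print their intervals. "Narrowest interval" is not a fully specified
aggregation rule across 10 coefficients in the source; our formalisation —
per-coefficient narrowest labels (ties listed), overall winner by majority of
coefficients, ties broken by smallest mean relative width (width/OR), and a
declared tie if that still does not separate — is stated in all outputs. The
comparison is symmetric in its arguments: the winner follows interval
content, not argument position.

## The synthetic generator

The generator is the package's stand-in for the access-restricted survey
microdata and is itself first-class, tested code. It emulates:

* the nine covariates' **marginal** distributions, renormalised from the
  published percentage table (n = 18,328);
* a logistic outcome model whose default coefficients are the natural logs
  of the published historical-prior-model odds ratios, with zero effects for
  the three covariates the published selection screened out;
* an intercept calibrated by root-finding on the exact finite mixture over
  covariate combinations so the marginal DBM prevalence is 0.449;
* BMI drawn uniformly within the category interval (normal rows on
  [18.5, 24.9]; malnourished rows first draw a category from the published
  conditional split 12 : 26.1 : 6.8, then uniformly within it) — the
  simplest law that makes classification exactly invertible, which the
  round-trip test exploits;
* a paired **historical wave** with every true coefficient perturbed by an
  independent `N(0, drift²)` draw (default drift 0.05 in the end-to-end
  runs).

It does **not** emulate covariate dependence (only marginals are published;
an explicit joint sampler can be passed via the covariate columns), the
two-stage cluster design, non-response, or the pregnancy exclusion (only
eligible rows are produced). Consequently, passing tests demonstrate the
correctness of the algorithms under independent covariates and unit weights;
they do not certify design-based inference on real DHS data.

## Variable selection

`run_boruta()` is a bespoke implementation of the Boruta all-relevant
algorithm: every feature is duplicated as a row-permuted "shadow", a random
forest (via `ranger`, out-of-bag permutation importance) scores originals
and shadows, a feature scores a hit when it beats the best shadow, and a
two-sided binomial test (p = 0.5, Bonferroni-corrected across features,
α = 0.01) confirms or rejects features as hits accumulate; rejected features
leave the model matrix permanently. Shadows are padded to a minimum of five
probes, the reference implementation's convention — with fewer probes the
shadow maximum is weak and null features hit near 1/3 rather than ~1/6,
stalling rejection. Categorical covariates enter integer-coded (trees split
on codes); an impurity importance option exists but permutation is the
default and the original definition. A median-based `resolve_tentative()`
post-step is provided explicitly rather than applied silently.

Under the generator's defaults the selection has full power for the stronger
conditional effects (age, residence, wealth, employment at the full survey
size) but can leave the weakest ones (e.g. media access, conditional
OR 0.88) Tentative or miss one at moderate n: the generator's truth is the
*conditional* effect sizes, whereas selection on real survey data also sees
the larger marginal associations. The test suite therefore asserts the
defensible properties — strong signals confirmed, pure noise rejected,
nothing confirmed under a shuffled outcome, determinism under a fixed seed —
rather than an exact six-variable reproduction, and the pipeline accepts a
forced variable list mirroring the published selection.

## Bivariate stage and a documented misprint

`chi_square()` computes the Pearson statistic on weighted counts directly
(no continuity correction, no Rao–Scott adjustment — the source applied
none). `reconstruct_counts()` inverts the published presentation (level
totals plus row percentages) so the printed chi-squares can be recomputed:
five of the six published values are reproduced within 2.5% (the slack is
percentage rounding). The published wealth chi-square (3331.73) reconstructs
to ≈ 332 from the same tables; we flag it as a likely misprint via a
`consistent = FALSE` marker and exclude it from numeric reproduction checks
rather than silently "fixing" either number.

## Problem sizes and numerical defaults

The shipped test and example runs use: n = 50,000 for marginal/prevalence
checks (±0.7 percentage points on a 44.9% prevalence); n = 5,000 with the
test-scale MCMC profile for the sampler-accuracy and Gelman–Rubin checks;
n = 18,000 current / 15,000 historical with bootstrap B = 400 for the
end-to-end narrowest-interval run; B = 2,000 at n = 2,500 for the
bootstrap-versus-asymptotic variance check; and 200 replicates at n = 4,000
for MLE parameter recovery (each coefficient within 3 Wald SE in ≥95% of
cases). These sizes are the package's choices for stable, reasonably fast
simulation evidence; the generator and configs accept any size.

Other numerical policies: all-zero weights are an error wherever a weighted
mean is taken; zero row/column totals are an error in the chi-square;
`summarize_posterior()` refuses fewer than 100 pooled draws; equal-tailed
percentile credible intervals (not HPD) are used, so odds-ratio interval
endpoints are exactly the exponentials of the coefficient endpoints; and
every stage that draws random numbers takes an explicit or derived seed and
restores the caller's RNG state.

## Known limitations

* Inference is model-based throughout; survey weights are respected as row
  weights, but variances ignore clustering and stratification.
* The historical prior assumes the two waves share a design-column
  vocabulary; a level unseen historically falls back to a flat prior for
  that coefficient (with a warning) rather than failing.
* The componentwise sampler is adequate for the well-conditioned posteriors
  of dummy-coded logistic models but would mix poorly under strong
  collinearity; no blocked or gradient-based kernel is provided.
* Exact reproduction of the published regression coefficients requires the
  restricted microdata and is out of scope by design; what the package
  reproduces are the quantities recomputable from printed tables and the
  qualitative superiority of the historical prior under emulated conditions.
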