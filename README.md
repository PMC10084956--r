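# dbmbayes

Classical and Bayesian logistic regression for the **double burden of
malnutrition (DBM)** among women of reproductive age, built around DHS-style
survey tables.

In many low- and middle-income countries undernutrition (underweight) now
coexists with rising overnutrition (overweight and obesity). Analyses of this
double burden typically classify each woman's BMI into the WHO categories,
recode any malnutrition as a binary outcome, and model it against
sociodemographic covariates by logistic regression. `dbmbayes` implements
that full workflow for epidemiologists and biostatisticians working with
DHS-like microdata — including a Bayesian arm in which an **informative
"historical" prior**, elicited from an earlier survey wave, is compared
against the usual flat prior and the classical fit by the narrowness of the
resulting interval estimates.

## The model

Each woman `i` contributes a binary outcome `D_i` (1 = underweight,
overweight or obese; 0 = normal, i.e. 18.5 ≤ BMI ≤ 24.9 kg/m²) and
dummy-coded categorical covariates `E_i1, …, E_ip`:

```
logit(π_i) = β₀ + β₁ E_i1 + … + β_p E_ip,   D_i ~ Bernoulli(π_i)
```

Three fits of the same linear predictor are compared:

* **Model 1** — maximum likelihood (Newton–Raphson/IRLS), odds ratios
  `exp(β_j)` with Wald 95% confidence intervals;
* **Model 2** — Bayesian fit under flat priors `β_j ~ N(0, 10⁶)`;
* **Model 3** — Bayesian fit under historical priors `β_j ~ N(μ_j, σ_j²)`,
  where `μ_j` and `σ_j²` are the mean and variance of a bootstrap of the MLE
  on the earlier survey wave.

Models 2 and 3 are sampled with a componentwise Gaussian random-walk
Metropolis–Hastings algorithm (scale adaptation during burn-in only),
convergence is monitored with trace data and the Gelman–Rubin statistic
(Rc < 1.1), and the three models are compared per coefficient by the width of
the odds-ratio-scale interval: the model that is narrowest for the most
coefficients wins, ties broken by mean relative width.

A synthetic DHS-like generator with known ground truth (marginal covariate
distributions and log-odds effects taken from the published survey tables)
makes every stage testable without access-restricted microdata, including a
paired "historical" wave with slightly drifted coefficients.

## Worked example

```r
library(dbmbayes)

cfg <- pipeline_config(
  mode      = "synthetic", outdir = "dbm_run", seed = 42,
  generator = generator_config(n = 8000, seed = 42),
  drift     = 0.05, historical_n = 8000,
  bootstrap = bootstrap_config(B = 300, seed = 43),
  mcmc      = mcmc_config(profile = "test", seed = 44, init = "overdispersed"),
  select_variables = FALSE,
  forced_variables = c("age", "education", "employment", "wealth",
                       "media", "residence"))
res <- run_pipeline(cfg)

res$prevalence
#>      category weighted_n percent
#> 1 underweight        966 12.0750
#> 2      normal       4465 55.8125
#> 3  overweight       2062 25.7750
#> 4       obese        507  6.3375
#> 5         dbm       3535 44.1875

res$diagnostics$comparison
#> <comparison_table> 10 coefficients; winner: model3 (wins: model1=0, model2=0, model3=10)
#>                     term model1_or model1_lower model1_upper model1_width ...
#> 1              age=25-34 1.3062854    1.1617930     1.468748    0.3069552
#> 2              age=35-49 1.5012193    1.3396408     1.682286    0.3426457
#> ...
```

The prevalence table shows the generator reproducing the survey's nutrition
mix (≈ 12 / 55 / 26 / 7 %, DBM ≈ 45%). In the comparison table each
coefficient carries the odds ratio and 95% interval from all three models;
here the historical-prior model (`model3`) produces the narrowest
odds-ratio interval for all 10 coefficients (for example
`employment=unemployed`: width 0.143 versus 0.204 classical and 0.205
flat-prior), so it is declared the overall winner — the earlier wave's
information tightens the posterior without moving the point estimates
appreciably. Both Bayesian fits converge (max Rc 1.008 and 1.004, well under
the 1.1 threshold).

Every stage is also callable on its own: `generate_survey()`,
`classify_bmi()`, `prevalence_table()`, `run_boruta()`, `crosstab()` /
`chi_square()`, `build_design()` / `fit_mle()` / `wald_or_table()`,
`elicit_historical_prior()`, `run_chains()` / `summarize_posterior()`,
`gelman_rubin()`, `compare_models()`.

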