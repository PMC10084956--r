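test_that("covariate_spec validates its invariants", {
  expect_error(covariate_spec("x", c("a", "b"), c(0.6, 0.5)), "sum to 1")
  expect_error(covariate_spec("x", "a", 1), ">= 2 levels")
  expect_error(covariate_spec("x", c("a", "b"), c(0.5, 0.5), "c"), "reference")
  expect_error(covariate_spec("x", c("a", "b"), c(-0.1, 1.1)), "non-negative")
  sp <- covariate_spec("x", c("a", "b"), c(0.3, 0.7), "b")
  expect_s3_class(sp, "covariate_spec")
})

test_that("empirical covariate marginals match the specification", {
  cfg <- generator_config(n = 50000, seed = 31)
  tab <- generate_covariates(cfg)
  for (sp in cfg$specs) {
    emp <- as.vector(prop.table(table(tab[[sp$name]])))
    expect_lt(max(abs(emp - sp$marginal_probs)), 0.01)
  }
  # the rural fraction mirrors the published 71.8%
  expect_equal(mean(tab$residence == "rural"), 0.718, tolerance = 0.015)
})

test_that("generation is deterministic given the seed and handles degenerate n", {
  cfg <- generator_config(n = 200, seed = 5)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  expect_error(generator_config(n = 0), "positive integer")
  one <- generate_covariates(generator_config(n = 1, seed = 2))
  expect_equal(nrow(one), 1L)
})

test_that("outcome assignment hits the target prevalence with null effects", {
  specs <- bdhs_covariate_specs()
  coefs <- lapply(default_coefficients(), function(b) b * 0)
  cfg <- generator_config(n = 50000, seed = 17, specs = specs,
                          coefficients = coefs, intercept = logit(0.449))
  tab <- generate_bmi(assign_outcome(generate_covariates(cfg), cfg), cfg)
  prev <- prevalence_table(tab)
  expect_equal(prev$percent[prev$category == "dbm"], 44.9, tolerance = 0.7 / 44.9)
})

test_that("extreme negative intercept saturates the outcome at zero", {
  cfg <- generator_config(n = 500, seed = 3, intercept = -30)
  tab <- assign_outcome(generate_covariates(cfg), cfg)
  expect_true(all(tab$dbm == 0L))
})

test_that("a single binary effect reproduces its odds ratio empirically", {
  specs <- list(g = covariate_spec("g", c("a", "b"), c(0.5, 0.5)))
  cfg <- generator_config(n = 50000, seed = 23, specs = specs,
                          coefficients = list(g = c(b = log(2))),
                          intercept = -0.5)
  tab <- assign_outcome(generate_covariates(cfg), cfg)
  ct <- table(tab$g, tab$dbm)
  emp_or <- (ct["b", "1"] * ct["a", "0"]) / (ct["b", "0"] * ct["a", "1"])
  expect_equal(log(emp_or), log(2), tolerance = 0.1)
})

test_that("coefficients referencing unknown covariates or levels are rejected", {
  specs <- list(g = covariate_spec("g", c("a", "b"), c(0.5, 0.5)))
  cfg <- generator_config(n = 50, seed = 1, specs = specs,
                          coefficients = list(g = c(zz = 1)), intercept = 0)
  tab <- generate_covariates(cfg)
  expect_error(assign_outcome(tab, cfg), "unknown level")
  cfg2 <- generator_config(n = 50, seed = 1, specs = specs,
                           coefficients = list(h = c(b = 1)), intercept = 0)
  expect_error(assign_outcome(generate_covariates(cfg2), cfg2), "absent from table")
})

test_that("generated BMI round-trips through classification", {
  cfg <- generator_config(n = 10000, seed = 11)
  tab <- generate_survey(cfg)
  expect_false(anyNA(tab$category))
  expect_identical(classify_bmi(tab$bmi), tab$category)
  expect_identical(recode_dbm(tab$category), tab$dbm)
})

test_that("degenerate dbm_split sends every malnourished row to underweight", {
  cfg <- generator_config(n = 2000, seed = 13, dbm_split = c(1, 0, 0))
  tab <- generate_survey(cfg)
  expect_true(all(tab$category[tab$dbm == 1L] == "underweight"))
})

test_that("category mix matches the configured split", {
  cfg <- generator_config(n = 50000, seed = 19)
  tab <- generate_survey(cfg)
  pct <- prevalence_table(tab)$percent
  expect_equal(pct[1:4], c(12, 55.1, 26.1, 6.8), tolerance = 0.025)
})

test_that("historical generation drifts coefficients as configured", {
  cfg <- generator_config(n = 400, seed = 7)
  h0 <- generate_historical(cfg, drift = 0)
  expect_equal(attr(h0, "true_coefficients"), cfg$coefficients)
  h1 <- generate_historical(cfg, drift = 0.1)
  h2 <- generate_historical(cfg, drift = 0.1, seed = cfg$seed + 999L)
  expect_false(identical(attr(h1, "true_coefficients"),
                         attr(h2, "true_coefficients")))
  # same seed -> same realisation
  expect_identical(generate_historical(cfg, drift = 0.1),
                   generate_historical(cfg, drift = 0.1))
})

test_that("MLE on a drifted historical table recovers the drifted truth", {
  cfg <- generator_config(n = 2000, seed = 29)
  hist <- generate_historical(cfg, drift = 0.1, n = 15000)
  truth <- attr(hist, "true_coefficients")
  fit <- fit_mle(build_design(hist, six_covariate_spec()))
  se <- sqrt(diag(fit$covariance))
  for (v in selected_covariates) {
    for (l in names(truth[[v]])) {
      term <- paste0(v, "=", l)
      expect_lt(abs(fit$beta[term] - truth[[v]][l]), 3 * se[term])
    }
  }
})

test_that("custom weight laws flow into the table", {
  cfg <- generator_config(n = 100, seed = 3,
                          weight_law = function(n) rep(2.5, n))
  tab <- generate_covariates(cfg)
  expect_true(all(tab$weight == 2.5))
})
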