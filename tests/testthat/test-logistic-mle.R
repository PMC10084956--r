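test_that("design matrix uses reference-level dummy coding", {
  tab <- small_survey(n = 300, seed = 2)
  d <- build_design(tab, model_spec(c("age", "residence")))
  expect_equal(d$terms, c("(Intercept)", "age=25-34", "age=35-49",
                          "residence=urban"))
  ref_rows <- tab$age == "15-24" & tab$residence == "rural"
  expect_true(any(ref_rows))
  expect_true(all(d$X[ref_rows, -1] == 0))
  # at most one dummy per covariate per row
  expect_true(all(rowSums(d$X[, c("age=25-34", "age=35-49"), drop = FALSE]) <= 1))
  bad <- tab
  bad$dbm <- bad$dbm + 1L
  expect_error(build_design(bad, model_spec("age")), "binary")
  expect_error(build_design(tab, model_spec(c(age = "nope"))), "invalid")
})

test_that("intercept-only fit equals the logit of the weighted outcome mean", {
  tab <- toy_table(rep(c("a", "b"), 10), rep(c(1L, 1L, 0L, 1L), 5),
                   weight = rep(c(1, 2), 10))
  d <- build_design(tab, model_spec("g"))
  d$X <- d$X[, 1, drop = FALSE]
  d$terms <- "(Intercept)"
  fit <- fit_mle(d)
  wmean <- sum(d$weights * d$y) / sum(d$weights)
  expect_equal(unname(fit$beta), log(wmean / (1 - wmean)), tolerance = 1e-8)
})

test_that("a single binary predictor reproduces the 2x2 cross-product ratio", {
  # cells: a=exposed/yes, b=exposed/no, c=ref/yes, d=ref/no
  x <- c(rep("b", 40), rep("a", 60))
  y <- c(rep(1L, 25), rep(0L, 15), rep(1L, 20), rep(0L, 40))
  fit <- fit_mle(build_design(toy_table(x, y), model_spec("g")))
  or_hat <- exp(fit$beta[["g=b"]])
  expect_equal(or_hat, (25 * 40) / (15 * 20), tolerance = 1e-8)
})

test_that("fit agrees with glm on weighted synthetic data", {
  tab <- small_survey(n = 3000, seed = 12)
  tab$weight <- stats::rgamma(nrow(tab), 4, 4)
  d <- build_design(tab, six_covariate_spec())
  fit <- fit_mle(d)
  g <- suppressWarnings(stats::glm.fit(d$X, d$y, weights = d$weights,
                                       family = stats::binomial()))
  expect_equal(unname(fit$beta), unname(g$coefficients), tolerance = 1e-7)
  expect_true(fit$converged)
  expect_true(isSymmetric(fit$covariance, tol = 1e-10))
  expect_true(all(eigen(fit$covariance, only.values = TRUE)$values > 0))
})

test_that("fit matches brute-force grid maximization on a small table", {
  set.seed(42)
  x <- sample(c("a", "b"), 20, replace = TRUE)
  y <- rbinom(20, 1, ifelse(x == "b", 0.7, 0.4))
  tab <- toy_table(x, y)
  d <- build_design(tab, model_spec("g"))
  fit <- fit_mle(d)
  # coarse-to-fine grid search over (beta0, beta1)
  ll <- function(b) {
    eta <- b[1] + b[2] * d$X[, 2]
    sum(y * eta - log(1 + exp(eta)))
  }
  centre <- c(0, 0); span <- 5
  for (step in c(0.5, 0.05, 0.005, 5e-4)) {
    grid <- expand.grid(b0 = seq(centre[1] - span, centre[1] + span, by = step),
                        b1 = seq(centre[2] - span, centre[2] + span, by = step))
    vals <- apply(grid, 1, ll)
    centre <- as.numeric(grid[which.max(vals), ])
    span <- 2 * step
  }
  expect_equal(unname(fit$beta), centre, tolerance = 1e-3)
})

test_that("likelihood at the optimum dominates truth and zero", {
  cfg <- generator_config(n = 4000, seed = 8)
  tab <- generate_survey(cfg)
  d <- build_design(tab, six_covariate_spec())
  fit <- fit_mle(d)
  ll <- function(b) {
    eta <- drop(d$X %*% b)
    sum(d$weights * (d$y * eta - log(1 + exp(eta))))
  }
  truth <- c(cfg$intercept, unlist(lapply(selected_covariates, function(v) {
    cfg$coefficients[[v]]
  })))
  expect_gte(fit$log_likelihood, ll(truth))
  expect_gte(fit$log_likelihood, ll(rep(0, ncol(d$X))))
})

test_that("changing the reference level leaves fitted probabilities unchanged", {
  tab <- small_survey(n = 1500, seed = 14)
  d1 <- build_design(tab, model_spec(c("age", "wealth")))
  d2 <- build_design(tab, model_spec(c(age = "35-49", wealth = "rich")))
  f1 <- fit_mle(d1); f2 <- fit_mle(d2)
  p1 <- stats::plogis(drop(d1$X %*% f1$beta))
  p2 <- stats::plogis(drop(d2$X %*% f2$beta))
  expect_lt(max(abs(p1 - p2)), 1e-8)
})

test_that("separation is detected and reported", {
  x <- c(rep("a", 30), rep("b", 30))
  y <- c(rep(0L, 30), rep(1L, 30))
  expect_error(fit_mle(build_design(toy_table(x, y), model_spec("g"))),
               "separation")
})

test_that("Wald odds-ratio intervals follow the closed form", {
  fake <- structure(list(
    beta = c("(Intercept)" = -0.5, "g=b" = 0),
    covariance = diag(c(0.2^2, 0.1^2)),
    converged = TRUE, terms = c("(Intercept)", "g=b")), class = "mle_fit")
  dimnames(fake$covariance) <- list(fake$terms, fake$terms)
  ot <- wald_or_table(fake, 0.95)
  expect_equal(nrow(ot), 1L)  # intercept excluded
  expect_equal(ot$or, 1)
  expect_equal(ot$lower, exp(-stats::qnorm(0.975) * 0.1), tolerance = 1e-9)
  expect_equal(ot$upper, exp(stats::qnorm(0.975) * 0.1), tolerance = 1e-9)
  expect_equal(round(ot$lower, 3), 0.822)
  expect_equal(round(ot$upper, 3), 1.217)
  # zero SE degenerates to a zero-width interval
  fake0 <- fake; fake0$covariance[2, 2] <- 0
  expect_equal(wald_or_table(fake0)$width, 0)
  # wider level, wider interval
  expect_gt(wald_or_table(fake, 0.99)$width, wald_or_table(fake, 0.95)$width)
  fake$converged <- FALSE
  expect_error(wald_or_table(fake), "converge")
})

test_that("parameter recovery holds across replicates", {
  n_rep <- 40
  covered <- 0L; total <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(n = 4000, seed = 5000 + r)
    tab <- generate_survey(cfg)
    fit <- fit_mle(build_design(tab, six_covariate_spec()))
    se <- sqrt(diag(fit$covariance))
    for (v in selected_covariates) {
      b <- cfg$coefficients[[v]]
      for (l in names(b)) {
        term <- paste0(v, "=", l)
        covered <- covered + (abs(fit$beta[term] - b[l]) <= 3 * se[term])
        total <- total + 1L
      }
    }
  }
  expect_gte(covered / total, 0.95)
})
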