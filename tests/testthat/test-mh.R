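test_that("kept-draw count formula holds across configurations", {
  cases <- expand.grid(iterations = c(501, 1501, 150000),
                       burn_in = c(0, 200, 500),
                       thin = c(1, 5, 99))
  cases <- cases[cases$burn_in < cases$iterations, ]
  for (k in seq_len(nrow(cases))) {
    cfg <- mcmc_config(iterations = cases$iterations[k], burn_in = cases$burn_in[k],
                       thin = cases$thin[k], n_chains = 2)
    expect_identical(kept_draws(cfg),
                     as.integer(floor((cases$iterations[k] - cases$burn_in[k]) /
                                        cases$thin[k])))
  }
  expect_error(mcmc_config(iterations = 100, burn_in = 100), "iterations")
  # paper-scale profile mirrors the published settings
  pp <- mcmc_config(profile = "paper")
  expect_equal(c(pp$iterations, pp$burn_in, pp$thin, pp$n_chains),
               c(150000L, 500L, 99L, 4L))
  expect_equal(kept_draws(pp), 1510L)
})

test_that("log posterior at zero with a flat prior reduces to n log(1/2)", {
  tab <- small_survey(n = 120, seed = 6)
  d <- build_design(tab, model_spec("residence"))
  pr <- flat_prior(d)
  prior_part <- sum(stats::dnorm(c(0, 0), 0, 1000, log = TRUE))
  expect_equal(log_posterior(c(0, 0), d, pr) - prior_part, 120 * log(0.5),
               tolerance = 1e-9)
  expect_error(log_posterior(c(0, 0, 0), d, pr), "length")
})

test_that("log posterior matches a naive per-row product on a small table", {
  set.seed(9)
  x <- sample(c("a", "b"), 10, replace = TRUE)
  y <- rbinom(10, 1, 0.5)
  w <- runif(10, 0.5, 2)
  tab <- toy_table(x, y, weight = w)
  d <- build_design(tab, model_spec("g"))
  pr <- flat_prior(d)
  pr$mean <- c(0.2, -0.4); pr$variance <- c(1.5, 2.5)
  beta <- c(0.3, -0.7)
  eta <- beta[1] + beta[2] * d$X[, 2]
  pi_i <- exp(eta) / (1 + exp(eta))
  naive <- sum(w * log(pi_i^y * (1 - pi_i)^(1 - y))) +
    sum(stats::dnorm(beta, pr$mean, sqrt(pr$variance), log = TRUE))
  expect_equal(log_posterior(beta, d, pr), naive, tolerance = 1e-12)
})

test_that("in the flat-prior limit posterior differences equal likelihood differences", {
  tab <- small_survey(n = 200, seed = 16)
  d <- build_design(tab, model_spec("age"))
  pr <- flat_prior(d)
  pr$variance <- rep(1e12, 3)
  b1 <- c(0.1, 0.4, -0.2); b2 <- c(-0.3, 0.0, 0.5)
  ll <- function(b) {
    eta <- drop(d$X %*% b)
    sum(d$weights * (d$y * eta - log(1 + exp(eta))))
  }
  expect_equal(log_posterior(b1, d, pr) - log_posterior(b2, d, pr),
               ll(b1) - ll(b2), tolerance = 1e-6)
})

test_that("chains are bit-reproducible under a fixed master seed", {
  tab <- small_survey(n = 400, seed = 26)
  d <- build_design(tab, model_spec("residence"))
  cfg <- mcmc_config(iterations = 400, burn_in = 100, thin = 2, n_chains = 2,
                     seed = 99, init = "overdispersed")
  c1 <- run_chains(d, flat_prior(d), cfg)
  c2 <- run_chains(d, flat_prior(d), cfg)
  expect_identical(c1$draws, c2$draws)
  expect_identical(c1$acceptance, c2$acceptance)
  expect_equal(nrow(c1$draws[[1]]), kept_draws(cfg))
})

test_that("zero-weight data returns the prior (prior-only limit)", {
  tab <- small_survey(n = 150, seed = 36)
  tab$weight <- 0
  d <- build_design(tab, model_spec("residence"))
  pr <- flat_prior(d)
  pr$mean <- c(0.5, -1); pr$variance <- c(0.25, 1); pr$provenance <- "historical"
  ch <- run_chains(d, pr, mcmc_config(iterations = 8000, burn_in = 500, thin = 2,
                                      n_chains = 2, seed = 3, init = "prior-draw"))
  s <- summarize_posterior(ch)
  expect_equal(s$mean, pr$mean, tolerance = 0.12)
  expect_equal(s$sd, sqrt(pr$variance), tolerance = 0.12)
})

test_that("a dominating informative prior pins the posterior to its mean", {
  tab <- small_survey(n = 500, seed = 46)
  d <- build_design(tab, model_spec("residence"))
  pr <- flat_prior(d)
  pr$mean <- c(0.7, -0.3); pr$variance <- rep(1e-6, 2)
  ch <- run_chains(d, pr, mcmc_config(iterations = 2000, burn_in = 300, thin = 2,
                                      n_chains = 2, seed = 5, init = "zero",
                                      proposal_scale = 0.003))
  s <- summarize_posterior(ch)
  expect_equal(s$mean, pr$mean, tolerance = 0.01)
})

test_that("one-parameter posterior matches numerical quadrature", {
  # intercept-only model with an informative prior; exact posterior by
  # quadrature over the unnormalised density
  set.seed(123)
  y <- rbinom(60, 1, 0.35)
  df <- data.frame(g = rep(c("a", "b"), 30), dbm = y, weight = 1)
  tab <- survey_table(df, list(g = list(levels = c("a", "b"), reference = "a")))
  d <- build_design(tab, model_spec("g", include_intercept = TRUE))
  d$X <- d$X[, 1, drop = FALSE]; d$terms <- "(Intercept)"
  pr <- structure(data.frame(term = "(Intercept)", mean = 0.3, variance = 0.25,
                             provenance = "historical"),
                  class = c("normal_prior", "data.frame"))
  post <- function(b) {
    vapply(b, function(bb) {
      exp(sum(y * bb - log(1 + exp(bb))) +
            stats::dnorm(bb, 0.3, 0.5, log = TRUE) + 40)
    }, 0)
  }
  Z <- stats::integrate(post, -5, 5, rel.tol = 1e-10)$value
  m_exact <- stats::integrate(function(b) b * post(b), -5, 5, rel.tol = 1e-10)$value / Z
  v_exact <- stats::integrate(function(b) (b - m_exact)^2 * post(b), -5, 5,
                              rel.tol = 1e-10)$value / Z
  ch <- run_chains(d, pr, mcmc_config(iterations = 22000, burn_in = 1000, thin = 2,
                                      n_chains = 2, seed = 11, init = "mle"))
  s <- summarize_posterior(ch)
  expect_equal(s$mean, m_exact, tolerance = 0.02 * sqrt(v_exact) / abs(m_exact) + 0.02)
  expect_equal(s$sd, sqrt(v_exact), tolerance = 0.02)
})

test_that("posterior summaries behave under degenerate and transformed draws", {
  const <- matrix(2, nrow = 100, ncol = 1, dimnames = list(NULL, "b"))
  ch <- fake_chains(list(const, const), terms = "b")
  s <- summarize_posterior(ch)
  expect_equal(s$mean, 2)
  expect_equal(s$upper - s$lower, 0)
  expect_equal(s$or_width, 0)
  # OR interval endpoints are exactly the exponentials of the beta endpoints
  set.seed(2)
  draws <- matrix(rnorm(5000, 0.4, 0.8), ncol = 1, dimnames = list(NULL, "b"))
  s2 <- summarize_posterior(fake_chains(list(draws, draws), terms = "b"))
  expect_identical(s2$or_lower, exp(s2$lower))
  expect_identical(s2$or_upper, exp(s2$upper))
  tiny <- fake_chains(list(const[1:20, , drop = FALSE]), terms = "b")
  expect_error(summarize_posterior(tiny), "100")
})

test_that("large standard-normal samples give the textbook credible interval", {
  set.seed(31)
  draws <- matrix(rnorm(1e6), ncol = 1, dimnames = list(NULL, "z"))
  s <- summarize_posterior(fake_chains(list(draws), terms = "z"))
  expect_equal(s$lower, -1.959964, tolerance = 0.01)
  expect_equal(s$upper, 1.959964, tolerance = 0.01)
})
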