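#' MCMC configuration for the random-walk Metropolis-Hastings sampler
#'
#' The paper-scale profile mirrors the published run: 150,000 iterations per
#' chain, burn-in 500, thinning every 99th post-burn-in draw, 4 chains. The
#' test-scale profile (2,000 / 200 / 5 / 4) retains the same sampler and is
#' the practical default for interpreted-code runtimes.
#'
#' @param iterations iterations per chain.
#' @param burn_in burn-in iterations (must be < iterations).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param n_chains number of chains (>= 1).
#' @param seed master seed; chain seeds are derived deterministically.
#' @param target_accept target acceptance probability for the burn-in scale
#'   adaptation (default 0.234).
#' @param proposal_scale optional numeric vector (or scalar) of initial
#'   componentwise proposal SDs; default 2.4 x the Wald SE when an MLE is
#'   available, else 2.4 x the prior SD (capped at 1).
#' @param init initialisation rule: `"mle"`, `"zero"`, `"prior-draw"`, or
#'   `"overdispersed"` (MLE +/- 4 SE uniform jitter, per chain).
#' @param profile `"test"` or `"paper"` preset overriding
#'   iterations/burn-in/thin/n_chains.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 150000L, burn_in = 500L, thin = 99L,
                        n_chains = 4L, seed = 1L, target_accept = 0.234,
                        proposal_scale = NULL,
                        init = c("mle", "zero", "prior-draw", "overdispersed"),
                        profile = NULL) {
  init <- match.arg(init)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("test", "paper"))
    if (profile == "test") {
      iterations <- 2000L; burn_in <- 200L; thin <- 5L; n_chains <- 4L
    } else {
      iterations <- 150000L; burn_in <- 500L; thin <- 99L; n_chains <- 4L
    }
  }
  stopifnot(iterations > burn_in, thin >= 1, n_chains >= 1,
            target_accept > 0, target_accept < 1)
  structure(list(iterations = as.integer(iterations), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), target_accept = target_accept,
                 proposal_scale = proposal_scale, init = init),
            class = "mcmc_config")
}

#' Kept draws per chain implied by an MCMC configuration
#'
#' floor((iterations - burn_in) / thin).
#'
#' @param config an [mcmc_config()].
#' @return Integer count of retained draws per chain.
#' @export
kept_draws <- function(config) {
  as.integer(floor((config$iterations - config$burn_in) / config$thin))
}

#' Log posterior density (up to a constant) of the Bayesian logistic model
#'
#' Weighted Bernoulli log-likelihood plus independent normal log-priors,
#' evaluated with the stable log(1+exp) form so linear predictors up to
#' |eta| = 700 cause no overflow.
#'
#' @param beta coefficient vector (length = design columns, in design order).
#' @param design a [build_design()] result.
#' @param prior a `normal_prior` aligned to the design terms.
#' @return Scalar log posterior.
#' @export
log_posterior <- function(beta, design, prior) {
  if (length(beta) != ncol(design$X)) stop("beta length does not match design", call. = FALSE)
  pr <- align_prior(prior, design$terms)
  eta <- drop(design$X %*% beta)
  ll <- sum(design$weights * (design$y * eta - log1pexp(eta)))
  lp <- sum(stats::dnorm(beta, pr$mean, sqrt(pr$variance), log = TRUE))
  ll + lp
}

# one chain of componentwise random-walk MH with burn-in Robbins-Monro
# scale adaptation (frozen afterwards, so kept draws satisfy detailed balance).
# Dummy-coded designs are sparse, so each component update touches only the
# rows where its column is non-zero; the per-row log(1+exp(eta)) terms are
# cached and patched incrementally.
run_one_chain <- function(design, prior_mean, prior_sd, config, beta0, scale0, seed) {
  X <- design$X; y <- design$y; w <- design$weights
  p <- ncol(X)
  keep_n <- kept_draws(config)
  out <- matrix(NA_real_, nrow = keep_n, ncol = p, dimnames = list(NULL, design$terms))
  set.seed(seed)
  beta <- beta0
  log_s <- log(scale0)
  eta <- drop(X %*% beta)
  L <- log1pexp(eta)                       # per-row normalising terms
  idx <- lapply(seq_len(p), function(j) which(X[, j] != 0))
  xj <- lapply(seq_len(p), function(j) X[idx[[j]], j])
  wj <- lapply(seq_len(p), function(j) w[idx[[j]]])
  a <- vapply(seq_len(p), function(j) sum(w[idx[[j]]] * y[idx[[j]]] * xj[[j]]), 0)
  prior_prec <- 1 / prior_sd^2
  acc_post <- 0L; prop_post <- 0L
  k <- 0L
  for (i in seq_len(config$iterations)) {
    adapt <- i <= config$burn_in
    gamma <- if (adapt) 1 / sqrt(i) else 0
    for (j in seq_len(p)) {
      d <- stats::rnorm(1, 0, exp(log_s[j]))
      bj_new <- beta[j] + d
      r <- idx[[j]]
      eta_r <- eta[r] + xj[[j]] * d
      L_r <- log1pexp(eta_r)
      # likelihood change + normal prior change for component j
      dlp <- a[j] * d - sum(wj[[j]] * (L_r - L[r])) -
        0.5 * prior_prec[j] * ((bj_new - prior_mean[j])^2 - (beta[j] - prior_mean[j])^2)
      if (is.nan(dlp)) {
        stop(sprintf("NaN log-posterior at iteration %d, component %d (beta = %g)",
                     i, j, bj_new), call. = FALSE)
      }
      alpha <- min(1, exp(dlp))
      if (stats::runif(1) < alpha) {
        beta[j] <- bj_new; eta[r] <- eta_r; L[r] <- L_r
        if (!adapt) acc_post <- acc_post + 1L
      }
      if (!adapt) prop_post <- prop_post + 1L
      if (adapt) log_s[j] <- log_s[j] + gamma * (alpha - config$target_accept)
    }
    if (i > config$burn_in && (i - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      if (k <= keep_n) out[k, ] <- beta
    }
  }
  list(draws = out, acceptance = acc_post / max(prop_post, 1L),
       final_scale = exp(log_s))
}

#' Run multiple Metropolis-Hastings chains
#'
#' Componentwise Gaussian random-walk proposals with Robbins-Monro scale
#' adaptation toward the target acceptance rate during burn-in only; the
#' adapted scales are frozen afterwards so the retained draws come from a
#' fixed-kernel chain. Chain seeds are derived deterministically from the
#' master seed and initial points follow the configured rule.
#'
#' @param design a [build_design()] result.
#' @param prior a `normal_prior`; aligned to the design columns by term name.
#' @param config an [mcmc_config()].
#' @return A `posterior_chains`: list of per-chain kept-draw matrices,
#'   acceptance rates, the config, and the design terms.
#' @export
run_chains <- function(design, prior, config = mcmc_config(profile = "test")) {
  pr <- align_prior(prior, design$terms)
  p <- ncol(design$X)
  prior_mean <- pr$mean; prior_sd <- sqrt(pr$variance)
  mle <- NULL
  if (any(design$weights > 0)) {
    mle <- tryCatch(fit_mle(design), error = function(e) NULL)
  }
  se <- if (!is.null(mle)) sqrt(diag(mle$covariance)) else NULL
  scale0 <- if (!is.null(config$proposal_scale)) {
    rep_len(config$proposal_scale, p)
  } else if (!is.null(se)) {
    2.4 * se
  } else {
    pmin(2.4 * prior_sd, 1)
  }
  if (config$init %in% c("mle", "overdispersed") && is.null(mle)) {
    stop(sprintf("init = '%s' requires an obtainable MLE", config$init), call. = FALSE)
  }
  chains <- vector("list", config$n_chains)
  accept <- numeric(config$n_chains)
  with_seed(config$seed, for (c in seq_len(config$n_chains)) {
    chain_seed <- config$seed + 7919L * c
    beta0 <- switch(config$init,
      mle = mle$beta,
      zero = rep(0, p),
      "prior-draw" = with_seed(chain_seed - 1L, stats::rnorm(p, prior_mean, prior_sd)),
      overdispersed = with_seed(chain_seed - 1L,
                                mle$beta + 4 * se * stats::runif(p, -1, 1))
    )
    res <- run_one_chain(design, prior_mean, prior_sd, config,
                         as.numeric(beta0), scale0, chain_seed)
    chains[[c]] <- res$draws
    accept[c] <- res$acceptance
  })
  if (any(accept < 0.01) || any(accept > 0.99)) {
    warning(sprintf("post-adaptation acceptance rate outside (0.01, 0.99): %s",
                    paste(round(accept, 3), collapse = ", ")), call. = FALSE)
  }
  structure(list(draws = chains, acceptance = accept, config = config,
                 terms = design$terms, prior_provenance = unique(as.character(pr$provenance))),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("<posterior_chains> %d chain(s) x %d kept draws x %d coefficients\n",
              length(x$draws), nrow(x$draws[[1]]), length(x$terms)))
  cat(sprintf("acceptance: %s; prior: %s\n",
              paste(round(x$acceptance, 3), collapse = ", "),
              paste(x$prior_provenance, collapse = "+")))
  invisible(x)
}

#' Posterior summary (pooled across chains)
#'
#' Posterior mean, SD and the equal-tailed credible interval per coefficient,
#' plus the odds-ratio scale: OR = exp(mean) with interval endpoints the
#' exponentials of the beta-interval endpoints (percentiles commute with the
#' monotone exp transform).
#'
#' @param chains a `posterior_chains`.
#' @param level credible level (default 0.95).
#' @return A `posterior_summary` data.frame: term, mean, sd, lower, upper,
#'   or, or_lower, or_upper, or_width.
#' @export
summarize_posterior <- function(chains, level = 0.95) {
  stopifnot(inherits(chains, "posterior_chains"), level > 0, level < 1)
  pooled <- do.call(rbind, chains$draws)
  if (nrow(pooled) < 100) stop("fewer than 100 kept draws", call. = FALSE)
  a <- (1 - level) / 2
  qs <- apply(pooled, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(term = chains$terms,
                    mean = colMeans(pooled),
                    sd = apply(pooled, 2, stats::sd),
                    lower = qs[1, ], upper = qs[2, ], row.names = NULL)
  out$or <- exp(out$mean)
  out$or_lower <- exp(out$lower)
  out$or_upper <- exp(out$upper)
  out$or_width <- out$or_upper - out$or_lower
  structure(out, class = c("posterior_summary", "data.frame"))
}
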