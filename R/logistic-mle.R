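#' Model specification for the logistic regressions
#'
#' @param predictors character vector of covariate names, or a named character
#'   vector/list `covariate = reference_level` to override the codebook's
#'   reference levels.
#' @param outcome outcome column name (default `"dbm"`).
#' @param include_intercept include an intercept column (default TRUE).
#' @return A `model_spec` object.
#' @export
model_spec <- function(predictors, outcome = "dbm", include_intercept = TRUE) {
  if (!length(predictors)) stop("predictors must be non-empty", call. = FALSE)
  refs <- NULL
  if (!is.null(names(predictors)) && any(names(predictors) != "")) {
    refs <- unlist(predictors)
    predictors <- names(predictors)
  }
  structure(list(predictors = as.character(predictors), references = refs,
                 outcome = outcome, include_intercept = isTRUE(include_intercept)),
            class = "model_spec")
}

#' Build the dummy-coded design matrix
#'
#' One indicator column per non-reference level of each predictor, named
#' `"covariate=level"`, plus an intercept. At most one indicator per
#' covariate is 1 in any row; a row at the reference level of every covariate
#' has all indicators 0.
#'
#' @param table a `survey_table` containing the outcome and predictors.
#' @param spec a [model_spec()].
#' @return A `design_matrix`: list with `X` (n x (p+1) matrix), `y` (0/1),
#'   `weights`, `terms` (column names) and the spec.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  cb <- survey_codebook(table)
  y <- table[[spec$outcome]]
  if (is.null(y)) stop(sprintf("outcome '%s' missing", spec$outcome), call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("outcome is not binary 0/1", call. = FALSE)
  cols <- list()
  if (spec$include_intercept) cols[["(Intercept)"]] <- rep(1, nrow(table))
  for (v in spec$predictors) {
    if (!v %in% names(cb)) stop(sprintf("predictor '%s' not in codebook", v), call. = FALSE)
    ref <- if (!is.null(spec$references) && v %in% names(spec$references)) {
      spec$references[[v]]
    } else cb[[v]]$reference
    lev <- cb[[v]]$levels
    if (!ref %in% lev) stop(sprintf("reference '%s' invalid for '%s'", ref, v), call. = FALSE)
    x <- as.character(table[[v]])
    if (!ref %in% x) stop(sprintf("reference level '%s' of '%s' unobserved", ref, v), call. = FALSE)
    for (l in setdiff(lev, ref)) {
      cols[[paste0(v, "=", l)]] <- as.numeric(x == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, y = as.integer(y), weights = table$weight,
                 terms = colnames(X), spec = spec),
            class = "design_matrix")
}

# weighted Bernoulli log-likelihood at beta
bernoulli_loglik <- function(beta, design) {
  eta <- drop(design$X %*% beta)
  sum(design$weights * (design$y * eta - log1pexp(eta)))
}

#' Maximum-likelihood fit of the logistic model
#'
#' Newton-Raphson (IRLS) maximisation of the weighted Bernoulli
#' log-likelihood, started at beta = 0 with step-halving whenever a step
#' decreases the likelihood. Convergence when the largest score component
#' falls below `tol_score` or the relative log-likelihood change below
#' `tol_ll`. Coefficients diverging past |beta| > 20 raise a separation
#' error.
#'
#' @param design a [build_design()] result.
#' @param max_iter iteration cap (default 100).
#' @param tol_score score tolerance (default 1e-8).
#' @param tol_ll relative log-likelihood tolerance (default 1e-10).
#' @return An `mle_fit`: `beta`, `covariance` (inverse observed information),
#'   `log_likelihood`, `converged`, `iterations`, `terms`.
#' @export
fit_mle <- function(design, max_iter = 100L, tol_score = 1e-8, tol_ll = 1e-10) {
  X <- design$X; y <- design$y; w <- design$weights
  p <- ncol(X)
  if (sum(w > 0) <= p) stop("fewer weighted rows than parameters", call. = FALSE)
  beta <- rep(0, p)
  ll <- bernoulli_loglik(beta, design)
  converged <- FALSE; it <- 0L
  XtWX <- NULL
  while (it < max_iter) {
    it <- it + 1L
    mu <- stats::plogis(drop(X %*% beta))
    score <- drop(crossprod(X, w * (y - mu)))
    v <- w * mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(v))
    delta <- tryCatch(solve(XtWX, score), error = function(e) {
      stop("information matrix singular (collinear design?)", call. = FALSE)
    })
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- bernoulli_loglik(cand, design)
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- cand
    if (any(abs(beta) > 20)) {
      stop("separation detected: coefficient diverging beyond |beta| > 20", call. = FALSE)
    }
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-12)
    ll <- ll_new
    if (max(abs(score)) < tol_score || rel < tol_ll) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(X %*% beta))
  v <- w * mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(v))
  covariance <- solve(XtWX)
  dimnames(covariance) <- list(design$terms, design$terms)
  structure(list(beta = stats::setNames(beta, design$terms),
                 covariance = covariance, log_likelihood = ll,
                 converged = converged, iterations = it,
                 terms = design$terms, design = design),
            class = "mle_fit")
}

#' @export
print.mle_fit <- function(x, ...) {
  cat(sprintf("<mle_fit> %d coefficients, logLik = %.3f, %s in %d iteration(s)\n",
              length(x$beta), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(round(x$beta, 4))
  invisible(x)
}

#' Odds ratios with Wald confidence intervals
#'
#' OR = exp(beta) with bounds exp(beta +/- z * SE); the intercept is omitted.
#'
#' @param fit a converged `mle_fit`.
#' @param level confidence level (default 0.95).
#' @return An `or_table` data.frame: term, or, lower, upper, width.
#' @export
wald_or_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mle_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  stopifnot(level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  keep <- fit$terms != "(Intercept)"
  b <- fit$beta[keep]
  se <- sqrt(diag(fit$covariance))[keep]
  out <- data.frame(term = names(b), or = exp(b),
                    lower = exp(b - z * se), upper = exp(b + z * se),
                    row.names = NULL)
  out$width <- out$upper - out$lower
  structure(out, class = c("or_table", "data.frame"))
}
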