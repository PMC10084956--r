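#' Flat (noninformative) normal prior
#'
#' Independent N(0, 1e6) priors for every design column including the
#' intercept — so diffuse that the posterior is driven by the data alone.
#'
#' @param terms character vector of design column names, or a
#'   `design_matrix`/`mle_fit` to take them from.
#' @return A `normal_prior` data.frame: term, mean, variance, provenance.
#' @export
flat_prior <- function(terms) {
  if (inherits(terms, "design_matrix") || inherits(terms, "mle_fit")) terms <- terms$terms
  stopifnot(is.character(terms), length(terms) >= 1)
  structure(data.frame(term = terms, mean = 0, variance = 1e6,
                       provenance = "flat", row.names = NULL),
            class = c("normal_prior", "data.frame"))
}

#' Bootstrap configuration for prior elicitation
#'
#' @param B bootstrap replicates (default 1000; warns below 50).
#' @param mode `"parametric"` (simulate outcomes from the fitted model on the
#'   fixed historical design; default) or `"nonparametric"` (resample rows
#'   with replacement).
#' @param seed integer seed.
#' @return A `bootstrap_config` object.
#' @export
bootstrap_config <- function(B = 1000L, mode = c("parametric", "nonparametric"),
                             seed = 1L) {
  stopifnot(B >= 1)
  if (B < 50) warning("B < 50 is too small for stable prior variances", call. = FALSE)
  structure(list(B = as.integer(B), mode = match.arg(mode), seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Elicit a historical normal prior from an earlier survey wave
#'
#' Fits the logistic model on the historical table, then bootstraps the
#' estimator B times — parametric mode refits on outcomes simulated from the
#' fitted probabilities on the fixed historical design; nonparametric mode
#' refits on row resamples — and sets each coefficient's prior to
#' N(bootstrap mean, bootstrap variance). Priors are independent per
#' coefficient; the full bootstrap covariance is attached as an attribute for
#' logging but not used. Replicates whose refit fails are dropped (counted);
#' more than 10\% failures is an error.
#'
#' @param historical a `survey_table` for the earlier wave.
#' @param spec a [model_spec()]; must match the current model's design columns.
#' @param config a [bootstrap_config()].
#' @return A `normal_prior` with provenance `"historical"` and attributes
#'   `B`, `mode`, `seed`, `n_failed`, `bootstrap_covariance`,
#'   `historical_fit`.
#' @export
elicit_historical_prior <- function(historical, spec, config = bootstrap_config()) {
  design <- build_design(historical, spec)
  fit <- tryCatch(fit_mle(design), error = function(e) {
    stop(sprintf("historical MLE failed: %s", conditionMessage(e)), call. = FALSE)
  })
  n <- nrow(design$X)
  pihat <- stats::plogis(drop(design$X %*% fit$beta))
  draws <- matrix(NA_real_, nrow = config$B, ncol = length(fit$beta),
                  dimnames = list(NULL, fit$terms))
  n_failed <- 0L
  with_seed(config$seed, {
    for (b in seq_len(config$B)) {
      rep_design <- design
      if (config$mode == "parametric") {
        rep_design$y <- stats::rbinom(n, 1L, pihat)
      } else {
        idx <- sample.int(n, n, replace = TRUE)
        rep_design$X <- design$X[idx, , drop = FALSE]
        rep_design$y <- design$y[idx]
        rep_design$weights <- design$weights[idx]
      }
      est <- tryCatch(fit_mle(rep_design)$beta, error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else draws[b, ] <- est
    }
  })
  if (n_failed > 0.1 * config$B) {
    stop(sprintf("%d of %d bootstrap refits failed (> 10%%)", n_failed, config$B),
         call. = FALSE)
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  prior <- data.frame(term = fit$terms,
                      mean = colMeans(draws),
                      variance = apply(draws, 2, stats::var),
                      provenance = "historical", row.names = NULL)
  structure(prior,
            class = c("normal_prior", "data.frame"),
            B = config$B, mode = config$mode, seed = config$seed,
            n_failed = n_failed,
            bootstrap_covariance = stats::cov(draws),
            historical_fit = fit)
}

#' Align a prior to a target set of design columns
#'
#' Matches prior rows to `terms` by name; a term absent from the prior falls
#' back to the flat N(0, 1e6) prior with a warning.
#'
#' @param prior a `normal_prior`.
#' @param terms character vector of design column names, in target order.
#' @return A `normal_prior` row-aligned to `terms`.
#' @export
align_prior <- function(prior, terms) {
  stopifnot(inherits(prior, "normal_prior"))
  idx <- match(terms, prior$term)
  if (anyNA(idx)) {
    missing <- terms[is.na(idx)]
    warning(sprintf("no prior for term(s) %s; using flat prior for them",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(term = terms,
                    mean = ifelse(is.na(idx), 0, prior$mean[idx]),
                    variance = ifelse(is.na(idx), 1e6, prior$variance[idx]),
                    provenance = ifelse(is.na(idx), "flat",
                                        as.character(prior$provenance[idx])),
                    row.names = NULL)
  structure(out, class = c("normal_prior", "data.frame"))
}

#' Save / load a normal prior as YAML
#'
#' @param prior a `normal_prior`.
#' @param path YAML file path.
#' @return `write_prior_yaml` returns the path invisibly; `read_prior_yaml`
#'   returns a `normal_prior`.
#' @export
write_prior_yaml <- function(prior, path) {
  stopifnot(inherits(prior, "normal_prior"))
  entries <- lapply(seq_len(nrow(prior)), function(i) {
    list(term = prior$term[i], mean = prior$mean[i], variance = prior$variance[i],
         provenance = as.character(prior$provenance[i]))
  })
  meta <- list(prior = entries,
               B = attr(prior, "B"), mode = attr(prior, "mode"),
               seed = attr(prior, "seed"))
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' @rdname write_prior_yaml
#' @param path YAML file path.
#' @export
read_prior_yaml <- function(path) {
  meta <- yaml::read_yaml(path)
  rows <- do.call(rbind, lapply(meta$prior, function(e) {
    data.frame(term = e$term, mean = e$mean, variance = e$variance,
               provenance = e$provenance)
  }))
  structure(rows, class = c("normal_prior", "data.frame"),
            B = meta$B, mode = meta$mode, seed = meta$seed)
}
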