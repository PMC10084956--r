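#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split, non-rank-normalised) Brooks-Gelman computation on the
#' kept draws: W = mean of within-chain variances, B/n = variance of the chain
#' means, Rc = sqrt(((n-1)/n * W + B/n) / W). Convergence is conventionally
#' declared when Rc < 1.1 for every coefficient.
#'
#' @param chains a `posterior_chains` with >= 2 chains and >= 10 kept draws
#'   per chain.
#' @param split split each chain in half before the computation (modern
#'   split-Rhat variant; default FALSE).
#' @return An `rc_result` data.frame: term, rc, between (B), within (W), pass.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  stopifnot(inherits(chains, "posterior_chains"))
  draws <- chains$draws
  if (split) {
    draws <- unlist(lapply(draws, function(d) {
      h <- floor(nrow(d) / 2)
      list(d[seq_len(h), , drop = FALSE], d[(h + 1):(2 * h), , drop = FALSE])
    }), recursive = FALSE)
  }
  m <- length(draws)
  if (m < 2) stop("need >= 2 chains", call. = FALSE)
  n <- nrow(draws[[1]])
  if (n < 10) stop("need >= 10 kept draws per chain", call. = FALSE)
  terms <- chains$terms
  res <- lapply(seq_along(terms), function(j) {
    means <- vapply(draws, function(d) mean(d[, j]), 0)
    vars <- vapply(draws, function(d) stats::var(d[, j]), 0)
    W <- mean(vars)
    if (W <= 0) stop(sprintf("degenerate chains for '%s': within-chain variance is zero",
                             terms[j]), call. = FALSE)
    Bn <- stats::var(means)        # = B / n
    rc <- sqrt(((n - 1) / n * W + Bn) / W)
    data.frame(term = terms[j], rc = rc, between = n * Bn, within = W,
               pass = rc < 1.1)
  })
  structure(do.call(rbind, res), class = c("rc_result", "data.frame"))
}

#' Export chains as long-format trace data
#'
#' One record per (coefficient, chain, kept-draw index) — the data behind
#' overlaid trace plots.
#'
#' @param chains a `posterior_chains`.
#' @return data.frame with columns term, chain, iteration, value.
#' @export
export_trace <- function(chains) {
  stopifnot(inherits(chains, "posterior_chains"))
  n <- nrow(chains$draws[[1]])
  do.call(rbind, lapply(seq_along(chains$draws), function(c) {
    d <- chains$draws[[c]]
    data.frame(term = rep(chains$terms, each = n),
               chain = c,
               iteration = rep(seq_len(n), times = length(chains$terms)),
               value = as.vector(d),
               row.names = NULL)
  }))
}

# uniform (term, or, lower, upper) view of an or_table / posterior_summary
interval_view <- function(x) {
  if (inherits(x, "or_table")) {
    data.frame(term = x$term, or = x$or, lower = x$lower, upper = x$upper)
  } else if (inherits(x, "posterior_summary")) {
    data.frame(term = x$term, or = x$or, lower = x$or_lower, upper = x$or_upper)
  } else {
    stop("expected an or_table or posterior_summary", call. = FALSE)
  }
}

#' Narrowest-interval comparison of the three models
#'
#' Computes the odds-ratio-scale interval width per coefficient for each
#' model, labels the narrowest model per coefficient (ties list every tied
#' label), and declares the overall winner as the model that is narrowest for
#' the most coefficients, tie-broken by the smallest mean relative width
#' (width / OR). The intercept never carries an interval here; inputs hold
#' non-reference coefficients only.
#'
#' @param m1 classical `or_table` (Model 1).
#' @param m2 flat-prior `posterior_summary` (Model 2).
#' @param m3 historical-prior `posterior_summary` (Model 3).
#' @param labels model labels, default `c("model1", "model2", "model3")`.
#' @return A `comparison_table` data.frame with per-model OR/bounds/width
#'   columns plus `narrowest`; attributes `winner`, `wins`,
#'   `mean_relative_width`.
#' @export
compare_models <- function(m1, m2, m3, labels = c("model1", "model2", "model3")) {
  stopifnot(length(labels) == 3, !anyDuplicated(labels))
  views <- list(interval_view(m1), interval_view(m2), interval_view(m3))
  terms <- views[[1]]$term
  for (v in views[-1]) {
    if (!setequal(v$term, terms) || length(v$term) != length(terms)) {
      stop("models cover different coefficient sets", call. = FALSE)
    }
  }
  views <- lapply(views, function(v) v[match(terms, v$term), , drop = FALSE])
  out <- data.frame(term = terms, row.names = NULL)
  widths <- matrix(NA_real_, nrow = length(terms), ncol = 3)
  for (k in 1:3) {
    v <- views[[k]]
    out[[paste0(labels[k], "_or")]] <- v$or
    out[[paste0(labels[k], "_lower")]] <- v$lower
    out[[paste0(labels[k], "_upper")]] <- v$upper
    w <- v$upper - v$lower
    out[[paste0(labels[k], "_width")]] <- w
    widths[, k] <- w
  }
  out$narrowest <- apply(widths, 1, function(w) {
    paste(labels[w <= min(w) + 1e-12], collapse = "+")
  })
  wins <- vapply(labels, function(l) {
    sum(vapply(strsplit(out$narrowest, "\\+"), function(s) l %in% s, TRUE))
  }, 0)
  rel <- vapply(1:3, function(k) mean(widths[, k] / views[[k]]$or), 0)
  names(rel) <- labels
  best <- labels[wins == max(wins)]
  if (length(best) > 1) {
    # tie-break by mean relative width; a tie there too stays a tie
    r <- rel[best]
    best <- if (sum(r <= min(r) + 1e-12) == 1) best[which.min(r)] else "tie"
  }
  structure(out, class = c("comparison_table", "data.frame"),
            winner = best, wins = wins, mean_relative_width = rel)
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %d coefficients; winner: %s (wins: %s)\n",
              nrow(x), attr(x, "winner"),
              paste(sprintf("%s=%d", names(attr(x, "wins")), attr(x, "wins")),
                    collapse = ", ")))
  NextMethod()
  invisible(x)
}
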