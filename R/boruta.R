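#' Boruta configuration
#'
#' @param max_iterations maximum selection iterations (default 100).
#' @param alpha significance level of the binomial hit test (default 0.01).
#' @param ensemble_size trees per random-forest fit (default 300).
#' @param seed integer seed; iteration seeds are derived from it.
#' @param correction multiple-testing rule across features: `"bonferroni"`
#'   (default) or `"none"`.
#' @param importance `"permutation"` (out-of-bag permutation importance, the
#'   original definition; default) or `"impurity"` (mean decrease in impurity).
#' @return A `boruta_config` object.
#' @export
boruta_config <- function(max_iterations = 100L, alpha = 0.01,
                          ensemble_size = 300L, seed = 1L,
                          correction = c("bonferroni", "none"),
                          importance = c("permutation", "impurity")) {
  stopifnot(max_iterations >= 1, alpha > 0, alpha < 1, ensemble_size >= 1)
  if (max_iterations < 5) {
    warning("max_iterations < 5: decisions are unlikely to be reached", call. = FALSE)
  }
  structure(list(max_iterations = as.integer(max_iterations), alpha = alpha,
                 ensemble_size = as.integer(ensemble_size), seed = as.integer(seed),
                 correction = match.arg(correction),
                 importance = match.arg(importance)),
            class = "boruta_config")
}

#' Integer-encode survey covariates for the tree ensemble
#'
#' Tree learners split on the level codes directly; dummy coding is not used
#' in the selection stage.
#'
#' @param table a `survey_table`.
#' @param covariates covariate names; default all codebook covariates.
#' @return Numeric matrix, one integer-coded column per covariate.
#' @export
encode_covariates <- function(table, covariates = names(survey_codebook(table))) {
  cb <- survey_codebook(table)
  bad <- setdiff(covariates, names(cb))
  if (length(bad)) stop(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  X <- vapply(covariates, function(v) as.numeric(table[[v]]), numeric(nrow(table)))
  colnames(X) <- covariates
  X
}

#' Augment a feature matrix with shadow (permuted) copies
#'
#' Each original column is duplicated and independently row-permuted, breaking
#' any association with the outcome while preserving the marginal distribution.
#'
#' @param X numeric matrix or data.frame with >= 1 column and >= 2 rows.
#' @return Matrix with the originals followed by `shadow_<name>` columns.
#' @export
make_shadow_features <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1 || nrow(X) < 2) stop("need >= 1 feature and >= 2 rows", call. = FALSE)
  shadows <- apply(X, 2, sample)
  colnames(shadows) <- paste0("shadow_", colnames(X))
  cbind(X, shadows)
}

#' One Boruta iteration: ensemble importance of originals and shadows
#'
#' Fits a random forest on the shadow-augmented matrix and scores every
#' column; an original feature scores a "hit" when its importance exceeds the
#' maximum importance among all shadow columns.
#'
#' @param X numeric feature matrix (originals only).
#' @param y binary outcome vector (two classes required).
#' @param config a [boruta_config()].
#' @param seed RNG seed for this iteration.
#' @return List with `importance` (named, originals then shadows), `hits`
#'   (logical per original feature) and `shadow_max`.
#' @export
boruta_iteration <- function(X, y, config = boruta_config(), seed = config$seed) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (length(unique(y)) < 2) stop("y has a single class", call. = FALSE)
  aug <- with_seed(seed, {
    a <- make_shadow_features(X)
    # pad to at least 5 shadow probes (reference-implementation convention):
    # with too few probes the shadow maximum is weak and null features hit
    # far above chance, stalling rejection
    p <- ncol(X)
    if (p < 5) {
      extra <- vapply(seq_len(5 - p), function(k) {
        sample(X[, 1 + (k - 1) %% p])
      }, numeric(nrow(X)))
      colnames(extra) <- paste0("shadow_extra_", seq_len(5 - p))
      a <- cbind(a, extra)
    }
    a
  })
  dat <- data.frame(aug, check.names = FALSE)
  dat$.outcome <- factor(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = dat,
    num.trees = config$ensemble_size,
    importance = if (config$importance == "permutation") "permutation" else "impurity",
    seed = seed, num.threads = 1, verbose = FALSE
  )
  imp <- fit$variable.importance
  orig <- colnames(X)
  shadow_max <- max(imp[startsWith(names(imp), "shadow_")])
  hits <- imp[orig] > shadow_max
  list(importance = imp, hits = hits, shadow_max = shadow_max)
}

#' Run the Boruta all-relevant selection algorithm
#'
#' Iteratively compares each feature's ensemble importance against the best
#' random shadow probe, accumulating hits, and applies a two-sided binomial
#' test (p = 0.5) after every iteration: features with significantly more
#' hits than chance are Confirmed, significantly fewer are Rejected and
#' removed from subsequent iterations; features still undecided at
#' `max_iterations` are Tentative.
#'
#' @param X numeric feature matrix (integer-coded categoricals).
#' @param y binary outcome.
#' @param config a [boruta_config()].
#' @return A `boruta_result`: data.frame `decisions` (feature, decision, hits,
#'   iterations), matrix `importance_history` (iteration x feature, `NA` after
#'   removal), and `shadow_max_history`.
#' @export
run_boruta <- function(X, y, config = boruta_config()) {
  X <- as.matrix(X)
  features <- colnames(X)
  if (is.null(features)) stop("X needs column names", call. = FALSE)
  p <- length(features)
  hits <- stats::setNames(integer(p), features)
  iters <- stats::setNames(integer(p), features)
  decision <- stats::setNames(rep("Tentative", p), features)
  active <- features
  history <- matrix(NA_real_, nrow = config$max_iterations, ncol = p,
                    dimnames = list(NULL, features))
  shadow_hist <- rep(NA_real_, config$max_iterations)
  m_correction <- if (config$correction == "bonferroni") p else 1L

  for (i in seq_len(config$max_iterations)) {
    if (!length(active)) break
    it <- boruta_iteration(X[, active, drop = FALSE], y, config,
                           seed = config$seed + i)
    history[i, active] <- it$importance[active]
    shadow_hist[i] <- it$shadow_max
    hits[active] <- hits[active] + as.integer(it$hits[active])
    iters[active] <- iters[active] + 1L
    for (f in active) {
      p_hi <- stats::pbinom(hits[f] - 1L, iters[f], 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(hits[f], iters[f], 0.5)
      p_two <- min(1, 2 * min(p_hi, p_lo) * m_correction)
      if (p_two < config$alpha) {
        decision[f] <- if (hits[f] / iters[f] > 0.5) "Confirmed" else "Rejected"
      }
    }
    active <- features[decision == "Tentative"]
  }
  used <- max(iters)
  structure(list(
    decisions = data.frame(feature = features, decision = unname(decision),
                           hits = unname(hits), iterations = unname(iters),
                           row.names = NULL),
    importance_history = history[seq_len(used), , drop = FALSE],
    shadow_max_history = shadow_hist[seq_len(used)],
    config = config
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  d <- x$decisions
  cat(sprintf("<boruta_result> %d features after %d iteration(s)\n",
              nrow(d), max(d$iterations)))
  for (dec in c("Confirmed", "Tentative", "Rejected")) {
    f <- d$feature[d$decision == dec]
    if (length(f)) cat(sprintf("  %s: %s\n", dec, paste(f, collapse = ", ")))
  }
  invisible(x)
}

#' Resolve Tentative features by median importance
#'
#' Optional post-step: a Tentative feature whose median importance over the
#' iterations it survived exceeds the median of the per-iteration shadow
#' maxima is promoted to Confirmed, otherwise demoted to Rejected.
#'
#' @param result a `boruta_result`.
#' @return The result with Tentative decisions resolved.
#' @export
resolve_tentative <- function(result) {
  stopifnot(inherits(result, "boruta_result"))
  med_shadow <- stats::median(result$shadow_max_history, na.rm = TRUE)
  d <- result$decisions
  for (k in which(d$decision == "Tentative")) {
    med <- stats::median(result$importance_history[, d$feature[k]], na.rm = TRUE)
    d$decision[k] <- if (is.finite(med) && med > med_shadow) "Confirmed" else "Rejected"
  }
  result$decisions <- d
  result
}
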