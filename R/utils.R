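# internal helpers shared across modules

logit <- function(p) log(p / (1 - p))

#' Numerically stable log(1 + exp(x))
#'
#' Safe for linear predictors of any magnitude (no overflow for |x| <= 700).
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
#' @noRd
log1pexp <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  hi <- !lo
  # for large x, log(1+e^x) = x + e^-x to within double precision
  out[hi] <- x[hi] + exp(-x[hi])
  out
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_count <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 1 || x != floor(x)) {
    stop(sprintf("`%s` must be a single positive integer, got %s",
                 name, deparse(x)), call. = FALSE)
  }
}
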