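#' Weighted contingency table of a covariate against DBM
#'
#' @param table a `survey_table` with `dbm` assigned.
#' @param covariate covariate name.
#' @return A `contingency_table`: numeric matrix of weighted counts with one
#'   row per codebook level (in codebook order) and columns `yes`/`no`.
#' @export
crosstab <- function(table, covariate) {
  cb <- survey_codebook(table)
  if (!covariate %in% names(cb)) {
    stop(sprintf("unknown covariate '%s'", covariate), call. = FALSE)
  }
  if (is.null(table$dbm)) stop("dbm outcome not assigned", call. = FALSE)
  lev <- cb[[covariate]]$levels
  x <- factor(table[[covariate]], levels = lev)
  w <- table$weight
  yes <- vapply(lev, function(l) sum(w[x == l & table$dbm == 1L]), 0)
  no <- vapply(lev, function(l) sum(w[x == l & table$dbm == 0L]), 0)
  ct <- cbind(yes = yes, no = no)
  rownames(ct) <- lev
  structure(ct, class = c("contingency_table", class(ct)))
}

#' Pearson chi-square test on a contingency table
#'
#' The statistic is the classical Pearson form sum((O - E)^2 / E) with
#' E_ij = row_i * col_j / N, df = (r - 1)(c - 1), and an upper-tail p-value.
#' Weighted (non-integer) counts are used as-is; no continuity correction and
#' no design-based adjustment.
#'
#' @param ct numeric matrix of (weighted) counts, r x c.
#' @return A `chi_square_result`: list with `statistic`, `df`, `p_value`,
#'   `expected`.
#' @export
chi_square <- function(ct) {
  ct <- unclass(as.matrix(ct))
  if (any(ct < 0) || any(!is.finite(ct))) stop("counts must be finite and non-negative", call. = FALSE)
  rs <- rowSums(ct); cs <- colSums(ct); N <- sum(ct)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column total", call. = FALSE)
  E <- outer(rs, cs) / N
  stat <- sum((ct - E)^2 / E)
  df <- (nrow(ct) - 1L) * (ncol(ct) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = E),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Reconstruct a contingency table from level totals and row percentages
#'
#' Published bivariate tables print, per covariate level, the level total and
#' the percentage of outcome-positive rows; this inverts that presentation:
#' yes = total * pct / 100, no = the remainder.
#'
#' @param level_totals named numeric vector of level totals (> 0).
#' @param yes_percentages outcome-positive percentage per level, in \[0, 100\].
#' @return A `contingency_table` with columns `yes`/`no`.
#' @export
reconstruct_counts <- function(level_totals, yes_percentages) {
  if (length(level_totals) != length(yes_percentages)) {
    stop("totals and percentages lengths differ", call. = FALSE)
  }
  if (any(level_totals <= 0)) stop("level totals must be positive", call. = FALSE)
  if (any(yes_percentages < 0 | yes_percentages > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  yes <- level_totals * yes_percentages / 100
  ct <- cbind(yes = yes, no = level_totals - yes)
  rownames(ct) <- names(level_totals)
  structure(ct, class = c("contingency_table", class(ct)))
}

#' Published BDHS 2017-18 bivariate reference values
#'
#' Per selected covariate: level totals (from the sample-distribution table),
#' the printed DBM-yes percentage per level, and the printed chi-square. The
#' wealth entry is flagged `consistent = FALSE`: its printed chi-square
#' (3331.73) cannot be reproduced from the printed totals and percentages
#' (reconstruction gives about 332), indicating a likely misprint.
#'
#' @return Named list, one entry per covariate, each with `totals`, `yes_pct`,
#'   `chi_square`, `consistent`.
#' @export
bdhs_reference_tables <- function() {
  list(
    age = list(totals = c("15-24" = 4626, "25-34" = 6399, "35-49" = 7303),
               yes_pct = c(36.9, 45.7, 49.3), chi_square = 179.50, consistent = TRUE),
    education = list(totals = c(no_education = 3220, primary = 5815,
                                secondary = 7116, higher = 2178),
                     yes_pct = c(40.7, 44.8, 45.3, 50.0), chi_square = 45.97,
                     consistent = TRUE),
    employment = list(totals = c(employed = 9035, unemployed = 9293),
                      yes_pct = c(41.7, 48.0), chi_square = 73.21, consistent = TRUE),
    wealth = list(totals = c(poor = 7033, middle = 3705, rich = 7590),
                  yes_pct = c(38.1, 41.8, 52.7), chi_square = 3331.73,
                  consistent = FALSE),
    media = list(totals = c(exposed = 10219, not_exposed = 8109),
                 yes_pct = c(48.7, 40.2), chi_square = 131.78, consistent = TRUE),
    residence = list(totals = c(rural = 13159, urban = 5170),
                     yes_pct = c(41.9, 52.5), chi_square = 166.50, consistent = TRUE)
  )
}

#' Bivariate association table for a set of covariates
#'
#' @param table a `survey_table` with `dbm` (and optionally `category`).
#' @param covariates covariate names; default all codebook covariates.
#' @return data.frame with one row per covariate level: weighted DBM yes/no
#'   percentages within level, plus the covariate-level chi-square and p.
#' @export
bivariate_table <- function(table, covariates = names(survey_codebook(table))) {
  rows <- lapply(covariates, function(v) {
    ct <- crosstab(table, v)
    cs <- chi_square(ct)
    tot <- rowSums(ct)
    data.frame(covariate = v, level = rownames(ct),
               yes_pct = 100 * ct[, "yes"] / tot,
               no_pct = 100 * ct[, "no"] / tot,
               chi_square = cs$statistic, df = cs$df, p_value = cs$p_value,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
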