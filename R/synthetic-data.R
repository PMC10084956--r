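#' Covariate specification for the synthetic generator
#'
#' Describes one categorical covariate: its ordered level set, marginal level
#' probabilities, and the reference level used for dummy coding downstream.
#'
#' @param name covariate name.
#' @param levels character vector of >= 2 level labels.
#' @param marginal_probs probabilities per level; must sum to 1 (to 1e-12).
#' @param reference_level reference level; default first level.
#' @return A `covariate_spec` object.
#' @export
covariate_spec <- function(name, levels, marginal_probs, reference_level = levels[1]) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(levels) < 2) stop("need >= 2 levels", call. = FALSE)
  if (anyDuplicated(levels)) stop("duplicate levels", call. = FALSE)
  if (length(marginal_probs) != length(levels)) {
    stop("marginal_probs and levels lengths differ", call. = FALSE)
  }
  if (any(!is.finite(marginal_probs)) || any(marginal_probs < 0)) {
    stop("marginal_probs must be finite and non-negative", call. = FALSE)
  }
  if (abs(sum(marginal_probs) - 1) > 1e-12) {
    stop(sprintf("marginal_probs must sum to 1 (got %.15f)", sum(marginal_probs)),
         call. = FALSE)
  }
  if (!reference_level %in% levels) stop("reference_level not among levels", call. = FALSE)
  structure(list(name = name, levels = levels,
                 marginal_probs = as.numeric(marginal_probs),
                 reference_level = reference_level),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat(sprintf("<covariate_spec> %s: %s (ref: %s)\n", x$name,
              paste(sprintf("%s=%.3f", x$levels, x$marginal_probs), collapse = ", "),
              x$reference_level))
  invisible(x)
}

#' Default DHS-like covariate specifications
#'
#' Nine sociodemographic covariates of women of reproductive age with marginal
#' probabilities matching the published BDHS 2017-18 percentage distribution
#' (n = 18,328). Printed percentages are renormalised to sum exactly to 1.
#' Reference levels follow the regression tables (youngest age group, no
#' education, employed, poor, media-exposed, rural).
#'
#' @return Named list of [covariate_spec()] objects.
#' @export
bdhs_covariate_specs <- function() {
  mk <- function(name, levels, pct, ref = levels[1]) {
    covariate_spec(name, levels, pct / sum(pct), ref)
  }
  list(
    age = mk("age", c("15-24", "25-34", "35-49"), c(25.2, 34.9, 39.8)),
    education = mk("education", c("no_education", "primary", "secondary", "higher"),
                   c(17.6, 31.7, 38.8, 11.9)),
    employment = mk("employment", c("employed", "unemployed"), c(49.3, 50.7)),
    marital = mk("marital", c("married", "other"), c(93.9, 6.1)),
    wealth = mk("wealth", c("poor", "middle", "rich"), c(38.4, 20.2, 41.4)),
    religion = mk("religion", c("islam", "other"), c(90.5, 9.5)),
    division = mk("division",
                  c("barisal", "chattogram", "dhaka", "khulna",
                    "mymensingh", "rajshahi", "rangpur", "sylhet"),
                  c(5.6, 17.7, 25.2, 11.8, 7.6, 14.2, 12.1, 5.8),
                  ref = "dhaka"),
    media = mk("media", c("exposed", "not_exposed"), c(55.8, 44.2)),
    residence = mk("residence", c("rural", "urban"), c(71.8, 28.2))
  )
}

#' Default generating coefficients (log odds ratios)
#'
#' Natural logs of the published historical-prior model odds ratios for the
#' six selected covariates; the three covariates the selection step screens
#' out (marital status, religion, division) carry zero effects.
#'
#' @return Named list: covariate -> named numeric vector over non-reference
#'   levels (log-odds contrasts against the reference level).
#' @export
default_coefficients <- function() {
  list(
    age = c("25-34" = log(1.30), "35-49" = log(1.59)),
    education = c("primary" = log(1.11), "secondary" = log(1.17), "higher" = log(1.29)),
    employment = c("unemployed" = log(1.19)),
    wealth = c("middle" = log(1.02), "rich" = log(1.31)),
    media = c("not_exposed" = log(0.88)),
    residence = c("urban" = log(1.25)),
    marital = c("other" = 0),
    religion = c("other" = 0),
    division = c("barisal" = 0, "chattogram" = 0, "khulna" = 0,
                 "mymensingh" = 0, "rajshahi" = 0, "rangpur" = 0, "sylhet" = 0)
  )
}

#' Calibrate the generator intercept to a target marginal prevalence
#'
#' Under independent covariates the marginal outcome probability is an exact
#' finite mixture over covariate-level combinations; the intercept solving
#' E[P(DBM=1)] = target is found by root-finding on that closed form (only
#' covariates with a non-zero coefficient enter the enumeration).
#'
#' @param specs list of [covariate_spec()].
#' @param coefficients coefficient map as in [default_coefficients()].
#' @param target target marginal prevalence in (0, 1).
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(specs, coefficients, target = 0.449) {
  stopifnot(target > 0, target < 1)
  active <- names(coefficients)[vapply(coefficients, function(b) any(b != 0), logical(1))]
  if (!length(active)) return(logit(target))
  etas <- 0; probs <- 1
  for (v in active) {
    sp <- specs[[v]]
    if (is.null(sp)) stop(sprintf("coefficient references unknown covariate '%s'", v), call. = FALSE)
    b <- coefficients[[v]]
    if (!all(names(b) %in% setdiff(sp$levels, sp$reference_level))) {
      stop(sprintf("coefficient for '%s' references an unknown or reference level", v),
           call. = FALSE)
    }
    lev_eta <- stats::setNames(rep(0, length(sp$levels)), sp$levels)
    lev_eta[names(b)] <- b
    etas <- as.vector(outer(etas, lev_eta, `+`))
    probs <- as.vector(outer(probs, sp$marginal_probs))
  }
  f <- function(b0) sum(probs * stats::plogis(b0 + etas)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Synthetic-data generator configuration
#'
#' Bundles everything the generator needs: sample size, seed, covariate
#' specifications, true log-odds coefficients, intercept (calibrated to the
#' target prevalence when not supplied), the conditional split of malnourished
#' rows over (underweight, overweight, obese), and an optional sampling-weight
#' law.
#'
#' @param n number of rows (>= 1).
#' @param seed integer RNG seed.
#' @param specs named list of [covariate_spec()]; default [bdhs_covariate_specs()].
#' @param coefficients coefficient map; default [default_coefficients()].
#' @param intercept log-odds intercept; `NULL` calibrates to `prevalence`.
#' @param prevalence target marginal DBM prevalence used when `intercept` is
#'   `NULL` (default 0.449).
#' @param dbm_split probabilities of (underweight, overweight, obese) given
#'   DBM = 1; default proportional to (12, 26.1, 6.8).
#' @param weight_law `NULL` for unit weights, or a `function(n)` returning n
#'   non-negative weights.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n, seed = 1L,
                             specs = bdhs_covariate_specs(),
                             coefficients = default_coefficients(),
                             intercept = NULL,
                             prevalence = 0.449,
                             dbm_split = c(underweight = 12, overweight = 26.1, obese = 6.8) / 44.9,
                             weight_law = NULL) {
  stop_if_not_scalar_count(n, "n")
  stopifnot(length(seed) == 1, is.finite(seed))
  if (any(dbm_split < 0) || abs(sum(dbm_split) - 1) > 1e-9) {
    stop("dbm_split must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(weight_law) && !is.function(weight_law)) {
    stop("weight_law must be NULL or a function(n)", call. = FALSE)
  }
  if (is.null(intercept)) intercept <- calibrate_intercept(specs, coefficients, prevalence)
  structure(list(n = as.integer(n), seed = as.integer(seed), specs = specs,
                 coefficients = coefficients, intercept = intercept,
                 dbm_split = dbm_split, weight_law = weight_law),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n=%d seed=%d intercept=%.4f, %d covariates\n",
              x$n, x$seed, x$intercept, length(x$specs)))
  invisible(x)
}

specs_to_codebook <- function(specs) {
  stats::setNames(lapply(specs, function(s) list(levels = s$levels,
                                                 reference = s$reference_level)),
                  vapply(specs, `[[`, "", "name"))
}

#' Draw the covariate columns of a synthetic survey table
#'
#' Each covariate is sampled independently from its marginal distribution
#' (the published tables document marginals only); weights come from the
#' configured weight law (unit weights by default).
#'
#' @param config a [generator_config()].
#' @param specs covariate specs; default those in `config`.
#' @param seed RNG seed; default `config$seed`.
#' @return A `survey_table` of `config$n` rows.
#' @export
generate_covariates <- function(config, specs = config$specs, seed = config$seed) {
  if (!length(specs)) stop("no covariate specs supplied", call. = FALSE)
  n <- config$n
  with_seed(seed, {
    cols <- lapply(specs, function(s) {
      factor(sample(s$levels, n, replace = TRUE, prob = s$marginal_probs),
             levels = s$levels)
    })
    names(cols) <- vapply(specs, `[[`, "", "name")
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    df$weight <- if (is.null(config$weight_law)) rep(1, n) else config$weight_law(n)
    survey_table(df, specs_to_codebook(specs))
  })
}

# linear predictor under the generator's truth, dummy-coded off reference levels
linear_predictor <- function(table, config) {
  eta <- rep(config$intercept, nrow(table))
  for (v in names(config$coefficients)) {
    if (!v %in% names(table)) {
      stop(sprintf("coefficient references covariate '%s' absent from table", v), call. = FALSE)
    }
    b <- config$coefficients[[v]]
    lev <- levels(table[[v]])
    if (!all(names(b) %in% lev)) {
      stop(sprintf("coefficient for '%s' references unknown level(s): %s", v,
                   paste(setdiff(names(b), lev), collapse = ", ")), call. = FALSE)
    }
    full <- stats::setNames(rep(0, length(lev)), lev)
    full[names(b)] <- b
    eta <- eta + full[as.character(table[[v]])]
  }
  unname(eta)
}

#' Assign the binary DBM outcome from the logistic model
#'
#' DBM ~ Bernoulli(plogis(intercept + sum of level coefficients)), with
#' dummy coding against each covariate's reference level.
#'
#' @param table a `survey_table` containing every covariate the coefficients
#'   reference.
#' @param config a [generator_config()].
#' @param seed RNG seed; default `config$seed + 1`.
#' @return The table with a `dbm` column added.
#' @export
assign_outcome <- function(table, config, seed = config$seed + 1L) {
  eta <- linear_predictor(table, config)
  with_seed(seed, {
    table$dbm <- stats::rbinom(nrow(table), 1L, stats::plogis(eta))
  })
  table
}

# category sampling intervals chosen so classify_bmi() inverts them exactly
bmi_intervals <- list(underweight = c(15, 18.5),
                      overweight = c(24.9, 29.9),
                      obese = c(29.9, 40))

#' Generate BMI values consistent with the assigned outcome
#'
#' Normal-weight rows draw BMI uniformly on \[18.5, 24.9\]; malnourished rows
#' first draw a category from `dbm_split`, then BMI uniformly within that
#' category's interval, so [classify_bmi()] reproduces the drawn category for
#' every row.
#'
#' @param table a `survey_table` with `dbm` assigned.
#' @param config a [generator_config()].
#' @param seed RNG seed; default `config$seed + 2`.
#' @return The table with `bmi` and `category` columns added.
#' @export
generate_bmi <- function(table, config, seed = config$seed + 2L) {
  if (is.null(table$dbm)) stop("assign_outcome() must run before generate_bmi()", call. = FALSE)
  n <- nrow(table)
  with_seed(seed, {
    bmi <- numeric(n)
    normal <- table$dbm == 0L
    bmi[normal] <- stats::runif(sum(normal), 18.5, 24.9)
    n1 <- sum(!normal)
    if (n1 > 0) {
      cat_idx <- sample(3L, n1, replace = TRUE, prob = config$dbm_split)
      lo <- vapply(bmi_intervals, `[`, 0, 1)[cat_idx]
      hi <- vapply(bmi_intervals, `[`, 0, 2)[cat_idx]
      draw <- lo + (hi - lo) * stats::runif(n1)
      # keep draws strictly inside the half-open category bounds:
      # underweight is [15, 18.5), overweight (24.9, 29.9], obese (29.9, 40]
      draw <- pmin(pmax(draw, lo + 1e-9), hi - 1e-9 * (cat_idx == 1L))
      bmi[!normal] <- draw
    }
    table$bmi <- bmi
  })
  table$category <- classify_bmi(table$bmi)
  table
}

#' Generate a complete synthetic survey (covariates, outcome, BMI)
#'
#' @param config a [generator_config()].
#' @return A `survey_table` with `dbm`, `bmi` and `category` assigned, and the
#'   generating truth attached as attributes `true_coefficients` /
#'   `true_intercept`.
#' @export
generate_survey <- function(config) {
  tab <- generate_covariates(config)
  tab <- assign_outcome(tab, config)
  tab <- generate_bmi(tab, config)
  attr(tab, "true_coefficients") <- config$coefficients
  attr(tab, "true_intercept") <- config$intercept
  tab
}

#' Generate a paired historical survey with drifted coefficients
#'
#' Emulates an earlier survey wave: the same covariate structure, with every
#' true log-odds coefficient perturbed by an independent N(0, drift^2) draw.
#' The perturbed truth is attached as an attribute for recovery checks.
#'
#' @param config a [generator_config()] describing the current wave.
#' @param drift standard deviation of the coefficient perturbations (>= 0).
#' @param n historical sample size; default `config$n`.
#' @param seed RNG seed; default derived from `config$seed`.
#' @return A `survey_table` with attributes `true_coefficients` (the drifted
#'   map) and `true_intercept`.
#' @export
generate_historical <- function(config, drift = 0.05, n = config$n,
                                seed = config$seed + 104729L) {
  stopifnot(drift >= 0)
  drifted <- with_seed(seed, {
    lapply(config$coefficients, function(b) b + stats::rnorm(length(b), 0, drift))
  })
  hist_config <- generator_config(
    n = n, seed = seed + 1L, specs = config$specs, coefficients = drifted,
    intercept = config$intercept, dbm_split = config$dbm_split,
    weight_law = config$weight_law
  )
  generate_survey(hist_config)
}
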