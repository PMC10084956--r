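# shared fixtures, all generated in code

selected_covariates <- c("age", "education", "employment", "wealth",
                         "media", "residence")

six_covariate_spec <- function() model_spec(selected_covariates)

# small complete synthetic survey
small_survey <- function(n = 2000, seed = 1) {
  generate_survey(generator_config(n = n, seed = seed))
}

# memoised store for fixtures shared across test files (built at most once
# per test run)
.fixture_store <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (is.null(.fixture_store[[key]])) .fixture_store[[key]] <- force(expr)
  .fixture_store[[key]]
}

# the default synthetic dataset + flat-prior overdispersed test-scale MCMC run
# shared by the sampler-accuracy and convergence checks
default_mcmc_run <- function() {
  fixture("default_mcmc_run", {
    tab <- generate_survey(generator_config(n = 5000, seed = 101))
    design <- build_design(tab, six_covariate_spec())
    fit <- fit_mle(design)
    chains <- run_chains(design, flat_prior(design),
                         mcmc_config(profile = "test", seed = 202,
                                     init = "overdispersed"))
    list(table = tab, design = design, fit = fit, chains = chains)
  })
}

# hand-rolled posterior_chains object from a list of draw matrices
fake_chains <- function(draws, terms = colnames(draws[[1]])) {
  structure(list(draws = draws, acceptance = rep(0.3, length(draws)),
                 config = mcmc_config(profile = "test"), terms = terms,
                 prior_provenance = "flat"),
            class = "posterior_chains")
}

# minimal survey_table with a single binary covariate
toy_table <- function(x, dbm, weight = rep(1, length(x)),
                      levels = sort(unique(x)), reference = levels[1]) {
  survey_table(data.frame(g = x, dbm = dbm, weight = weight),
               list(g = list(levels = levels, reference = reference)))
}
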