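#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the input mode. In synthetic mode
#' the generator produces a current and a drifted historical wave; in csv mode
#' both waves are read from CSV + codebook files.
#'
#' @param mode `"synthetic"` or `"csv"`.
#' @param outdir output directory for stage artifacts.
#' @param seed global seed; stage seeds are derived from it.
#' @param generator a [generator_config()] (synthetic mode).
#' @param drift historical coefficient drift SD (synthetic mode, default 0.05).
#' @param historical_n historical sample size (synthetic mode; default the
#'   generator's n).
#' @param current_path,current_codebook,historical_path,historical_codebook
#'   file paths (csv mode).
#' @param boruta a [boruta_config()].
#' @param bootstrap a [bootstrap_config()].
#' @param mcmc an [mcmc_config()].
#' @param select_variables run the Boruta selection stage (default TRUE); if
#'   FALSE, `forced_variables` must name the model covariates.
#' @param forced_variables optional character vector overriding the selection.
#' @param verbose print stage progress (default TRUE).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv"),
                            outdir = tempfile("dbm_run_"),
                            seed = 1L,
                            generator = generator_config(n = 5000L, seed = seed),
                            drift = 0.05,
                            historical_n = generator$n,
                            current_path = NULL, current_codebook = NULL,
                            historical_path = NULL, historical_codebook = NULL,
                            boruta = boruta_config(seed = seed),
                            bootstrap = bootstrap_config(seed = seed + 1L),
                            mcmc = mcmc_config(profile = "test", seed = seed + 2L,
                                               init = "overdispersed"),
                            select_variables = TRUE,
                            forced_variables = NULL,
                            verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "csv") {
    paths <- list(current_path, current_codebook, historical_path, historical_codebook)
    ok <- vapply(paths, function(p) !is.null(p) && file.exists(p), TRUE)
    if (!all(ok)) {
      stop("csv mode requires existing current/historical CSV and codebook paths",
           call. = FALSE)
    }
  }
  if (!select_variables && is.null(forced_variables)) {
    stop("select_variables = FALSE requires forced_variables", call. = FALSE)
  }
  structure(list(mode = mode, outdir = outdir, seed = as.integer(seed),
                 generator = generator, drift = drift, historical_n = historical_n,
                 current_path = current_path, current_codebook = current_codebook,
                 historical_path = historical_path, historical_codebook = historical_codebook,
                 boruta = boruta, bootstrap = bootstrap, mcmc = mcmc,
                 select_variables = select_variables,
                 forced_variables = forced_variables, verbose = verbose),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the eight stages in order — data, classification, variable
#' selection, bivariate tests, classical fit, prior elicitation, Bayesian
#' fits (flat and historical prior), diagnostics + comparison — writing every
#' artifact as CSV/YAML under `config$outdir` together with a run manifest.
#' Any stage error aborts with a stage-tagged message; MCMC non-convergence
#' (any Rc >= 1.1) completes with a `"warning"` status in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results, the artifact
#'   paths, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(sprintf(...))
  timings <- list()
  stage <- function(name, expr) {
    say("stage %s ...", name)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  art <- function(f) file.path(config$outdir, f)
  wcsv <- function(x, f) {
    utils::write.csv(as.data.frame(x), art(f), row.names = FALSE)
    f
  }
  artifacts <- character()

  # 1. data
  dat <- stage("data", {
    if (config$mode == "synthetic") {
      current <- generate_survey(config$generator)
      historical <- generate_historical(config$generator, drift = config$drift,
                                        n = config$historical_n)
    } else {
      current <- read_survey_csv(config$current_path, config$current_codebook)
      historical <- read_survey_csv(config$historical_path, config$historical_codebook)
    }
    list(current = current, historical = historical)
  })

  # 2. classification + prevalence
  prev <- stage("classify", {
    for (nm in c("current", "historical")) {
      tab <- dat[[nm]]
      if (is.null(tab$bmi)) stop(sprintf("%s table lacks a bmi column", nm))
      tab$category <- classify_bmi(tab$bmi)
      tab$dbm <- recode_dbm(tab$category)
      dat[[nm]] <- tab
    }
    prevalence_table(dat$current)
  })
  artifacts <- c(artifacts, wcsv(prev, "prevalence.csv"))

  # 3. variable selection
  selection <- stage("select", {
    if (config$select_variables) {
      X <- encode_covariates(dat$current)
      res <- run_boruta(X, dat$current$dbm, config$boruta)
      selected <- res$decisions$feature[res$decisions$decision == "Confirmed"]
      if (!is.null(config$forced_variables)) selected <- config$forced_variables
      if (!length(selected)) stop("no covariate confirmed; supply forced_variables")
      h <- res$importance_history
      hist_df <- data.frame(iteration = rep(seq_len(nrow(h)), times = ncol(h)),
                            feature = rep(colnames(h), each = nrow(h)),
                            importance = as.vector(h))
      list(result = res, selected = selected, history = hist_df)
    } else {
      list(result = NULL, selected = config$forced_variables, history = NULL)
    }
  })
  if (!is.null(selection$result)) {
    artifacts <- c(artifacts, wcsv(selection$result$decisions, "boruta_decisions.csv"),
                   wcsv(selection$history, "boruta_importance.csv"))
  }

  # 4. bivariate tests
  bivar <- stage("bivariate", bivariate_table(dat$current, selection$selected))
  artifacts <- c(artifacts, wcsv(bivar, "bivariate.csv"))

  # 5. classical fit
  classical <- stage("fit_classical", {
    spec <- model_spec(selection$selected)
    design <- build_design(dat$current, spec)
    fit <- fit_mle(design)
    list(spec = spec, design = design, fit = fit, or = wald_or_table(fit))
  })
  artifacts <- c(artifacts, wcsv(classical$or, "model1_or.csv"))

  # 6. prior elicitation
  priors <- stage("elicit_prior", {
    historical_prior <- elicit_historical_prior(dat$historical, classical$spec,
                                                config$bootstrap)
    list(flat = flat_prior(classical$design),
         historical = align_prior(historical_prior, classical$design$terms))
  })
  write_prior_yaml(priors$historical, art("prior_historical.yaml"))
  artifacts <- c(artifacts, "prior_historical.yaml")

  # 7. Bayesian fits
  bayes <- stage("fit_bayes", {
    cfg2 <- config$mcmc
    cfg3 <- config$mcmc
    cfg3$seed <- cfg3$seed + 1L
    chains2 <- run_chains(classical$design, priors$flat, cfg2)
    chains3 <- run_chains(classical$design, priors$historical, cfg3)
    list(chains2 = chains2, chains3 = chains3,
         summary2 = summarize_posterior(chains2),
         summary3 = summarize_posterior(chains3))
  })
  artifacts <- c(artifacts, wcsv(bayes$summary2, "model2_summary.csv"),
                 wcsv(bayes$summary3, "model3_summary.csv"))

  # 8. diagnostics + comparison
  final <- stage("diagnose_compare", {
    rc2 <- gelman_rubin(bayes$chains2)
    rc3 <- gelman_rubin(bayes$chains3)
    keep <- function(s) s[s$term != "(Intercept)", , drop = FALSE]
    comparison <- compare_models(classical$or, keep(bayes$summary2), keep(bayes$summary3))
    list(rc2 = rc2, rc3 = rc3, trace3 = export_trace(bayes$chains3),
         comparison = comparison)
  })
  artifacts <- c(artifacts, wcsv(final$rc2, "rc_model2.csv"),
                 wcsv(final$rc3, "rc_model3.csv"),
                 wcsv(final$trace3, "trace_model3.csv"))
  comp_df <- as.data.frame(final$comparison)
  artifacts <- c(artifacts, wcsv(comp_df, "comparison.csv"))

  status <- if (all(final$rc2$pass) && all(final$rc3$pass)) "ok" else "warning"
  if (status == "warning") {
    warning("MCMC non-convergence: some Rc >= 1.1", call. = FALSE)
  }
  manifest <- list(
    package = "dbmbayes",
    version = as.character(utils::packageVersion("dbmbayes")),
    seed = config$seed,
    mode = config$mode,
    stages = names(timings),
    timings_sec = timings,
    winner = attr(final$comparison, "winner"),
    status = status,
    artifacts = as.list(artifacts)
  )
  yaml::write_yaml(manifest, art("manifest.yaml"))
  say("done: winner = %s, status = %s", manifest$winner, status)
  invisible(list(data = dat, prevalence = prev, selection = selection,
                 bivariate = bivar, classical = classical, priors = priors,
                 bayes = bayes, diagnostics = final, manifest = manifest,
                 outdir = config$outdir))
}
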