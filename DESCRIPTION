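Package: dbmbayes
Title: Classical and Bayesian Logistic Regression for the Double Burden of
    Malnutrition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling the double burden of malnutrition (DBM)
    among women of reproductive age from DHS-style survey tables. Implements
    WHO BMI classification and weighted prevalence tables, Boruta all-relevant
    variable selection, weighted Pearson chi-square bivariate tests, classical
    logistic regression by maximum likelihood with Wald intervals, elicitation
    of historical (informative) normal priors from an earlier survey wave via
    bootstrap, a random-walk Metropolis-Hastings sampler for Bayesian logistic
    regression, Gelman-Rubin convergence diagnostics, and a narrowest-interval
    comparison of the classical, flat-prior and historical-prior models. A
    synthetic DHS-like data generator with known ground truth makes the whole
    pipeline testable without restricted survey downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
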