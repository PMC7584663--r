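Package: trustmotives
Title: Utility-Model Classification of Reciprocity Motives in Multiplier
    Trust Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for inferring the psychological motives behind Trustee
    behavior in hidden-multiplier and false-belief-multiplier trust games.
    Implements payoff, guilt and inequity utility terms, four competing
    decision models (greed, guilt aversion, inequity aversion, and a
    two-parameter moral-strategy model), discrete argmax behavioral
    prediction, multi-restart least-squares fitting with AIC model
    comparison, a simulation-driven clustering of the theta-phi parameter
    space into strategy zones, stability statistics (test-retest
    correlation, Stuart-Maxwell marginal homogeneity, prevalence
    chi-square), and a synthetic-agent generator for end-to-end recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
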