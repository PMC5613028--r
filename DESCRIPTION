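Package: agenoise
Title: Stochastic Modeling and Windowed Noise Analysis of Gene
    Expression in Replicatively Aging Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how gene-expression noise changes over the
    replicative lifespan of single yeast mother cells.  Implements an exact
    Gillespie simulator of the two-state (telegraph) promoter model with
    mRNA and protein stages, an exact steady-state moment solver used as an
    independent oracle, moment-matching inference of promoter switching
    rates, parameter sweeps that contrast chromatin-rate and
    non-chromatin-rate routes to noise reduction, a generation-windowed
    noise-quantification pipeline for single-cell fluorescence trajectories
    (background subtraction, ON/OFF classification, lifespan filters,
    two-generation windows, death-aligned catastrophe analysis), and a
    synthetic aging-cohort generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
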