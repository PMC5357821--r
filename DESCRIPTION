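Package: lungfri
Title: Functional Respiratory Imaging Mechanics for Regional Lung Strain
    and Expiratory Time Constants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes regional lung mechanics from lobar volume and airway
    geometry data in the style of functional respiratory imaging (FRI):
    regional and whole-lung strain, expiratory airway resistance from a
    laminar (Hagen-Poiseuille) airway-network flow solution with terminal
    flow inlets and a tracheal pressure outlet, elastance, and expiratory
    time constants (tau = R/E).  Includes a multi-compartment passive
    deflation simulator, a synthetic ex-vivo porcine lung cohort generator
    with known ground-truth mechanics, and the accompanying statistical
    layer: linear mixed-effects models over lobe and PEEP with a random
    animal effect, type-III F-tests, Tukey-Kramer least-squares-mean
    comparisons, Nakagawa-Schielzeth marginal pseudo-R2, and
    Benjamini-Hochberg multiplicity control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    digest,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
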