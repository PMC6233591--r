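Package: bcgdose
Title: Markov Cohort Modelling of Low- Versus Full-Dose Intravesical BCG
    for Non-Muscle-Invasive Bladder Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state Markov cohort model comparing full-dose (81 mg)
    and low-dose (27 mg) intravesical Bacillus Calmette-Guerin (BCG)
    immunotherapy after transurethral resection in intermediate- and
    high-risk non-muscle-invasive bladder cancer. Provides the annual
    transition-probability parameter set with sensitivity ranges,
    declining-exponential (DEALE) rate conversions, a deterministic
    cohort trace with half-cycle-corrected life expectancy and surgery
    accounting, one-way and two-way sensitivity analyses with crossover
    root-finding, tornado diagrams, seedable patient-level Monte Carlo
    microsimulation, probabilistic sensitivity analysis, and a synthetic
    trajectory generator with transition-probability recovery for
    end-to-end testing. Results are returned as tibbles with broom-style
    tidy() and glance() methods and ggplot2 autoplot() graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
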