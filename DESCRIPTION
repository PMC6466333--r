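Package: fertrisk
Title: Trace-Metal Accumulation and Human Health Risk Assessment for
    Organic Fertilizer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assessment pipeline for trace metals (Cr, Ni, Cu, Zn, As, Cd,
    Pb) in composted organic fertilizer: survey summary statistics with
    normality testing and Spearman correlation, screening against national
    fertilizer limit standards, a plow-layer soil accumulation model with
    deterministic and Monte Carlo time-to-limit prediction against the
    GB15618-2018 dry-land soil limits, three-pathway (oral, dermal,
    inhalation) chronic daily dose estimation, hazard quotient / hazard
    index and slope-factor cancer risk indices, and a qualitative risk
    grading matrix.  Ships the regional soil backgrounds, application
    rates, exposure constants, toxicity reference values, and standards
    registry as auditable plain-text data, and includes a seeded synthetic
    survey generator emulating the right-skewed concentration
    distributions of a northern-China fertilizer survey.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
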