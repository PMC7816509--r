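Package: llindur
Title: Resistance-to-Damage Scoring and Hole-Index Metrics for Insecticidal Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the single resistance-to-damage (RD) metric for
    long-lasting insecticidal nets (LLINs) from four laboratory textile-test
    parameters (bursting strength, snag strength, abrasion resistance, hole
    enlargement), by two scoring algorithms: proximity to aspirational values
    and a tiered KPI score matrix with secondary-damage penalties. Also
    implements the WHO proportionate hole index (PHI) for field physical
    integrity, force/pressure conversions with packaged human-factors
    reference constants, lab-versus-field association statistics, and a
    seeded synthetic-data generator for end-to-end testing. Includes a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
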