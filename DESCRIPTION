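Package: delphicos
Title: Delphi Consensus Analysis for Core Outcome Set Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing multi-round Delphi consensus surveys used in
    core outcome set (COS) development: an a priori consensus engine
    (stakeholder-group importance thresholds with mandatory groups), per-round
    outcome filtering and preliminary-COS construction, pooled two-proportion
    z comparisons between randomised rating-scale arms, panel attrition
    analysis, and a latent-trait simulator of ordinal rating panels. Ships the
    summary tables of the PGP-COS (pelvic girdle pain) embedded methodology
    study as fixtures so every reported statistic can be replayed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
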