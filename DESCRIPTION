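Package: qcasynth
Title: Qualitative Comparative Analysis for Evidence Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Crisp- and fuzzy-set qualitative comparative analysis (QCA)
    tailored to systematic-review evidence synthesis. Calibrates study
    effect sizes (odds ratios) into four-level fuzzy outcome sets, builds
    truth tables with fuzzy sufficiency consistency, flags contradictory
    and remainder configurations, minimises positive configurations with
    an exact Quine-McCluskey/Petrick routine, and reports solution
    coverage and consistency. Ships a twelve-study breastfeeding
    intervention data set as a worked example, a synthetic study-set
    generator with known configurational structure, and a command-line
    pipeline for reproducible text/CSV/JSON reports including a
    calibration sensitivity re-run utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
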