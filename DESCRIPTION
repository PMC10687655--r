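Package: mriscreen
Title: Cost-Effectiveness of Annual MRI-Based Prostate Cancer Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic Markov cohort model comparing annual standard
    (TRUS-guided) prostate biopsy against annual MRI with potential MRI-guided
    biopsy for prostate cancer detection in 65-year-old men, stratified by
    serum PSA level. Provides a validated parameter registry with beta/gamma
    distributions fitted from published means and 95% intervals, a 13-state
    annual-cycle cohort engine over a 10-year horizon, discounted cost and
    QALY aggregation, incremental cost-effectiveness ratios and net monetary
    benefit, probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, one-way sweeps and tornado diagrams, and an
    individual-level microsimulation that serves as an independent validation
    oracle for the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
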