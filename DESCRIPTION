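Package: posacea
Title: Cost-Effectiveness of Posaconazole Prophylaxis Against Invasive Fungal Infections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid decision-tree and Markov cohort model for the
    cost-effectiveness of antifungal prophylaxis with posaconazole (oral
    suspension or tablets) versus first-generation triazoles (fluconazole,
    itraconazole) in hematological-malignancy patients at high risk of
    invasive fungal infection. Provides base-case cost/QALY/ICER analysis,
    one-way deterministic sensitivity analysis (tornado), probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    province-level willingness-to-pay scenario sweeps, and a synthetic
    trial-data generator for end-to-end and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
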