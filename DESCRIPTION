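Package: partsaHTA
Title: Partitioned-Survival Cost-Effectiveness Engine for Tumor-Agnostic Therapies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable partitioned-survival (three-state) cost-effectiveness
    engine for life-cycle health technology assessment of tumor-agnostic
    therapies evaluated in basket trials. Builds per-indication overall and
    progression-free survival curves from median survival via exponential
    fits with restricted (treatment-waning) or full extrapolation of the
    intervention effect, accumulates discounted costs and quality-adjusted
    life years on a weekly cycle grid, and propagates parameter uncertainty
    through probabilistic sensitivity analysis. Reports per-indication and
    prevalence-weighted tumor-agnostic incremental costs, QALYs, ICERs,
    incremental net monetary benefit, acceptability probabilities and
    cost-effectiveness planes; supports next-generation-sequencing testing
    cost scenarios via number-needed-to-screen, deterministic
    cost-effectiveness frontiers over every combination of funded tumor
    indications with extended dominance, and per-person expected value of
    perfect information curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
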