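Package: litmine
Title: Literature Mining Pipelines for Systematic Review Automation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A backend-agnostic framework for the three stages of
    evidence synthesis that large language models are being trained to
    automate: boolean search-query synthesis from PICO-framed research
    questions, criterion-level citation screening with eligibility-score
    ranking, and structured data extraction from clinical-trial
    publications. Ships a seeded synthetic linked-corpus generator with
    planted ground truth, an offline boolean retrieval engine,
    deterministic oracle and noisy-oracle backends so every pipeline
    stage is testable without a trained model or network access,
    instruction-dataset construction with review-level splits, and the
    evaluation protocol (recall at K, exact numeric matching, cosine
    soft text matching, difficulty-binned breakdowns).
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
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
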