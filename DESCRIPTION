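Package: biotriage
Title: Evidence-Centric Text Classification for Biocuration Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evidence-centric classification of biomedical full-text
    articles in biocuration workflows. Parses a JATS-subset article model,
    detects figure/panel references in narrative text and delineates
    per-subfigure "evidence fragments", loads pre-trained word-embedding
    tables with declared out-of-vocabulary and padding contracts, and trains
    compact neural text classifiers (CNN and LSTM passage classifiers for
    experimental-method codes; a CNN-BiLSTM passage encoder with additive
    attention for document-level triage). Includes a synthetic-corpus
    generator with plantable class signal so every pipeline stage is testable
    without external data, plus a seeded experiment runner with tidy reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
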