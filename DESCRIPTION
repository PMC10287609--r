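Package: radconcept
Title: Concept-Based Classification of Radiology Reports for Lung Carcinoma
Version: 0.1.0
Authors@R: person("Maastro", "NLP Lab", email = "dev@example.org", role = c("aut", "cre"))
Description: A clinical concept-based classification pipeline for free-text
    radiology reports. Provides a customizable NCIT/UMLS-style lexicon mapping
    colloquial, abbreviated and misspelled lung-carcinoma phrases to UMLS
    concept unique identifiers, a rule-based regular-expression concept
    recognizer with token-boundary handling, tf-idf + gradient-boosted-tree
    and bidirectional-LSTM document classifiers, confusion-matrix /
    bootstrap / ROC evaluation machinery, and a labeled synthetic
    radiology-report generator so the full pipeline can be exercised without
    protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
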