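Package: dreamtext
Title: Computational Analysis of Dream Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for the computational assessment of transcribed dream
    reports: structural connectedness of word graphs (largest connected and
    strongly connected components over a sliding window), dictionary-based
    emotion word proportions (LIWC-style category lexicons with stem
    wildcards), and embedding-based semantic similarity of reports to probe
    words with a qualifying-cosine threshold. A statistics layer links these
    text features to psychometric scores (PANSS subscales, self-evaluation
    items) via rank-based group comparisons with Bonferroni families,
    Spearman correlations, canonical correlation analysis and multiple
    linear regression. A synthetic-data module generates corpora, lexicons,
    embeddings and psychometric records with planted, known structure so
    every stage of the pipeline can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    igraph,
    ggplot2,
    broom,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
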