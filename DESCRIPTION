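Package: lobeconcord
Title: Paired-Site Concordance Analysis of Airway Epithelium Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for asking whether the two sampling sites of a paired
    transcriptome cohort respond concordantly within subjects.  Implements
    median (per-chip, per-gene) normalization and present-call filtering of
    probe-by-sample intensity matrices, paired and empirical-Bayes moderated
    t-tests with Benjamini-Hochberg and q-value false-discovery control,
    derivation of a smoking-responsive probe signature from a case/control
    contrast, a dendrogram sibling-pairing statistic for paired samples under
    correlation-distance hierarchical clustering with an empirical null built
    from random same-size gene lists, principal-component scores and the
    paired vector-length statistic with its random-list null, and a synthetic
    paired-cohort generator that emulates the structure of a smoker upper/lower
    lobe small-airway-epithelium microarray study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
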