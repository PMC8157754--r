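Package: imescan
Title: Discovery and Validation of Intron-Mediated Enhancement Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering candidate intron-mediated-enhancement
    (IME) sequence motifs in first introns of plant genes. Hexamers are scored
    by population-SNP conservation, first-versus-other-intron relative
    frequency, positional entropy against a simulated uniform null, and a
    binned positional contrast test, with Benjamini-Hochberg control.
    Candidates are validated by co-expression effect sizes against
    occurrence-matched control hexamers, by allele-specific expression tests
    over natural variants, collapsed into IUPAC consensus motifs, and fed into
    a random-forest expression classifier with permutation and Shapley
    importances. A synthetic-data generator emits genome, annotation, variant
    and expression fixtures with known planted truth so the full pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    vcfR,
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
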