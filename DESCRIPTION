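Package: circbench
Title: Robustness Benchmarking for Circular RNA Back-Splice Junction Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how robust circular RNA (circRNA) back-splice
    junction predictions are to imperfect total RNA-Seq input. Provides readers
    for FASTQ and for CIRI-, KNIFE- and BED-style circRNA prediction tables;
    simulators that degrade paired-end libraries (single-end projection, read
    pair subsampling, per-read base substitution errors); truth labelling of
    predictions by an RNase R enrichment score E = (m - n)/(m + n); true
    positive rate summaries, multi-caller combination and read-count re-ranking;
    per-circRNA property analysis (splice-site distance, enrichment score,
    junction reads ratio, read count) with a from-scratch two-sample
    Kolmogorov-Smirnov test on empirical CDFs; and a fully synthetic,
    ground-truthed benchmark (toy transcriptome, paired-end read simulation,
    RNase R treatment, anchor-based junction pseudo-predictor) so the whole
    pipeline runs without external data or callers.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
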