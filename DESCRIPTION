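Package: rankmeth
Title: Windowed Differential DNA Methylation Analysis with Coherence
    Filtering and Discriminative-Power Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based differential DNA methylation analysis for
    capture-based (MBD-Seq) read-count data. Tiles a genome into fixed-width
    windows, filters low-information windows, normalises libraries by the
    trimmed mean of M-values, fits per-window negative-binomial generalised
    linear models with age and social-rank fixed effects, tests the rank
    effect by likelihood-ratio tests with Benjamini-Hochberg false discovery
    rate control, and merges adjacent significant same-direction windows
    into differentially methylated regions (DMRs). Adds a leave-one-group-out
    subsample-coherence filter for DMR robustness, random-forest out-of-bag
    error as a measure of discriminative power, age-class effect concordance
    with an empirical permutation p-value, mitochondrial-versus-nuclear
    abundance comparisons, functional annotation of DMRs against a gene
    model (promoter, TSS, exon, intron), and a synthetic-data generator
    with planted DMRs and a machine-readable truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
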