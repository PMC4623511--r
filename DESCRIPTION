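Package: halomiR
Title: Small RNA-Seq miRNA Discovery and Salt-Stress Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA-seq analysis pipeline for plant miRNA
    discovery, built around a halophyte salt-stress study design with two
    libraries (control versus salt-treated). Covers raw-read cleaning by
    the classical elimination rules, tag collapsing, ungapped genome mapping
    with at most two mismatches, hierarchical non-coding RNA annotation,
    Mireap-style novel miRNA hairpin discovery with a bundled
    nearest-neighbor folding engine (MFE, MFEI, duplex geometry criteria),
    homology-based conserved miRNA recovery from transcriptome assemblies,
    Audic-Claverie count-based differential expression, plant-style miRNA
    target prediction with cleavage-site mapping, and local hypergeometric
    GO-term enrichment. Ships a synthetic-data generator that plants known
    and novel miRNA loci, decoy ncRNAs, repeats, and per-miRNA fold-changes
    with a full ground-truth manifest, so every stage is testable against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
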