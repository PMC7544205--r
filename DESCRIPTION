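Package: rnpscreen
Title: Interaction Stoichiometry, CLIP Metagene and Exon-Count Bias
    Analysis for RNP Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling ribonucleoprotein (RNP) composition and
    function from three complementary assays.  For affinity-purification
    mass spectrometry it implements Perseus-style label-free enrichment
    analysis (row filtering, log2 transform, valid-value filtering,
    left-shifted normal imputation, an S0-moderated two-sample test with
    permutation-based FDR) and bait-relative stoichiometric abundance
    scoring with condition clustering and multi-bait overlap sets.  For
    CLIP data it builds annotation-driven metagene and exon-anchored
    binding profiles, calls strand-aware T>C / A>G crosslink conversions
    from samtools mpileup text, and summarises conversion positions
    relative to exon-exon junctions.  For RNA-seq it compares exon-count
    distributions of up- versus down-regulated transcripts from
    DESeq2-format results, including expression-matched subsets.  A
    synthetic-data module generates ground-truthed inputs for all three
    arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
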