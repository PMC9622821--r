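Package: lncorf
Title: Small ORF Translation Detection and Evolution in Long Non-Canonical RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for cataloguing small open reading frames (smORFs) on
    long non-canonical RNAs and deciding whether they are translated. Implements
    footprint-length-resolved reading-frame calibration on canonical ORFs, an
    exact binomial framing test per ribosome-protected-fragment length, a
    four-state translation-status classifier built on RPKM thresholds and
    replicated framing, translation-efficiency Z-ratio calls across
    developmental stages, cis-feature scoring (Kozak position-specific log-odds,
    cistronic rank, MILC codon-usage bias), a reciprocal-best-hit micropeptide
    homology search with conservation-weighted alignment scoring, pairwise
    dN/dS by the Li (1993) counting method, overlap and Poisson clustering
    statistics, and a fully deterministic synthetic-data generator with planted
    ground truth so every stage can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    BiocGenerics,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    ape
Config/testthat/edition: 3
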