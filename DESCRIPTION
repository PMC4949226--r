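Package: cotarget
Title: Transcription-Factor Co-Occupancy and Co-Regulation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for asking whether two transcription factors bind and
    regulate a shared set of target genes. Assigns ChIP peaks to genes with a
    promoter/gene-body/downstream window scheme, tests target-set overlap with
    a log-space hypergeometric tail, tests inter-peak proximity on shared
    promoters against a random-target-promoter permutation null, profiles
    binding positions along a metagene, integrates differential-expression
    experiments (significance filtering, fold-change clamping, hierarchical
    clustering, sign-concordance, a weighted Kolmogorov-Smirnov gene set
    enrichment engine), classifies interdependent versus additive activation
    from wild-type/single/single/double mutant expression panels, and
    simulates all inputs with planted, recorded truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
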