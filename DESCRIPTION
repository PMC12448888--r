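Package: modStream
Title: Streaming Molecular Profiling from Modification-Tagged Long-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time analysis of modification-tagged long-read alignments
    (modBAM) for intraoperative tumor profiling. Merges 5hmC into 5mC
    probabilities per base, summarises sparse CpG methylation over classifier
    site panels, classifies the methylome with three independent strategies
    (random-forest vote share, perceptron margin, nearest-centroid posterior)
    and forms a confidence-thresholded multi-classifier consensus. Alongside
    classification it produces binned copy-number profiles with changepoint
    segmentation and canonical event calls, MGMT promoter methylation status
    over a fixed 137-site CpG panel, depth-gated tumor-only SNV calls with
    clinical-significance filtering, and split-read gene-fusion candidates
    with a minimum-support rule. All analyses update over cumulative read
    batches and serialise to an integrated report. A synthetic-fixture
    generator builds toy genomes, site panels and modification-tagged reads
    carrying planted copy-number states, SNVs, fusions and methylation
    profiles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'cnv.R'
    'fusion.R'
    'mgmt.R'
    'mod-ingest.R'
    'report.R'
    'simulate.R'
    'snv.R'
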