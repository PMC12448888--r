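#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
NULL

#' Sparse binarized methylome over a classifier site panel
#'
#' A \code{BinaryProfile} holds the binary (methylated / unmethylated) state
#' of the CpG sites of a classifier panel that were actually observed in the
#' sequencing data so far. Nanopore runs cover only a small, essentially
#' random subset of a panel at low per-site depth, so the profile is sparse:
#' unobserved sites are simply absent.
#'
#' @slot panelId single string naming the site panel the indices refer to.
#' @slot values named integer vector of 0/1 states; names are panel site
#'   indices (1-based, as character).
#' @slot nObserved number of observed sites, always \code{length(values)}.
#'
#' @seealso [binarize()], [classifyProfile()]
#' @export
setClass("BinaryProfile",
    representation(panelId = "character", values = "integer",
                   nObserved = "integer"))

setValidity("BinaryProfile", function(object) {
    msg <- NULL
    if (length(object@panelId) != 1L)
        msg <- c(msg, "panelId must be a single string")
    v <- object@values
    if (length(v) && (is.null(names(v)) || anyNA(suppressWarnings(as.integer(names(v))))))
        msg <- c(msg, "values must be named by integer panel site indices")
    if (length(v) && !all(v %in% c(0L, 1L)))
        msg <- c(msg, "values must be 0 or 1")
    if (object@nObserved != length(v))
        msg <- c(msg, "nObserved must equal length(values)")
    if (is.null(msg)) TRUE else msg
})

#' Methylome classifier strategy
#'
#' A fitted (or fit-on-demand) classification strategy over a shared class
#' vocabulary and a CpG site panel. Three strategy families are supported,
#' mirroring the three independent classifier designs used for sparse
#' nanopore methylome classification:
#' \describe{
#'   \item{forest}{random-forest vote share, scored 0-100, confident at >= 70.
#'     The forest is trained on the fly on the panel sites observed in the
#'     query profile (the standard way sparse nanopore profiles are handled),
#'     by drawing Bernoulli training profiles from the reference rates.}
#'   \item{perceptron}{multi-class single-layer perceptron margin mapped to
#'     [0,1]; confident at >= 0.2.}
#'   \item{centroid}{nearest-centroid Bernoulli posterior on [0,1]; confident
#'     at >= 0.8.}
#' }
#'
#' @slot strategy one of \code{"forest"}, \code{"perceptron"},
#'   \code{"centroid"}.
#' @slot rates numeric matrix, classes x panel sites, of reference per-site
#'   methylation rates in [0,1]; rownames are the class labels.
#' @slot labels class vocabulary (shared across strategies).
#' @slot panelId panel the columns of \code{rates} index.
#' @slot threshold confidence threshold on the strategy's score scale.
#' @slot scoreScale \code{"0-100"} (forest) or \code{"0-1"}.
#' @slot seed integer seed making training and classification deterministic.
#' @slot params strategy hyper-parameters (list).
#'
#' @seealso [trainReferenceModel()], [classifyProfile()]
#' @export
setClass("ClassifierModel",
    representation(strategy = "character", rates = "matrix",
                   labels = "character", panelId = "character",
                   threshold = "numeric", scoreScale = "character",
                   seed = "integer", params = "list"))

setValidity("ClassifierModel", function(object) {
    msg <- NULL
    if (!object@strategy %in% c("forest", "perceptron", "centroid"))
        msg <- c(msg, "unknown strategy")
    if (nrow(object@rates) < 2L)
        msg <- c(msg, "at least 2 classes are required")
    if (any(object@rates < 0 | object@rates > 1))
        msg <- c(msg, "reference rates must lie in [0,1]")
    if (!identical(rownames(object@rates), object@labels))
        msg <- c(msg, "rownames(rates) must equal labels")
    if (is.null(msg)) TRUE else msg
})

#' Single-strategy classification result
#'
#' @slot strategy strategy that produced the result.
#' @slot label predicted class label, or \code{NA} when no sites were
#'   observed.
#' @slot score score on the strategy's scale (0-100 for forest, 0-1
#'   otherwise).
#' @slot confident whether the score reaches the strategy's confidence
#'   threshold.
#' @slot nSitesUsed number of observed panel sites that contributed.
#' @slot batchIndex cumulative batch the result belongs to (0-based; -1 for
#'   one-shot runs outside a batch context).
#'
#' @seealso [classifyProfile()], [isConfident()], [consensusCall()]
#' @export
setClass("ClassifierResult",
    representation(strategy = "character", label = "character",
                   score = "numeric", confident = "logical",
                   nSitesUsed = "integer", batchIndex = "integer"))

#' Multi-classifier consensus decision
#'
#' The intraoperative call: \code{classified} if and only if two or more
#' strategies are confident and agree on the label.
#'
#' @slot status \code{"classified"} or \code{"unclassified"}.
#' @slot label consensus label (\code{NA} when unclassified).
#' @slot supporting strategies whose confident result carries the consensus
#'   label.
#' @slot batchIndex batch of the contributing results.
#'
#' @seealso [consensusCall()]
#' @export
setClass("ConsensusDecision",
    representation(status = "character", label = "character",
                   supporting = "character", batchIndex = "integer"))

setValidity("ConsensusDecision", function(object) {
    if (object@status == "classified" && length(object@supporting) < 2L)
        return("classified requires >= 2 supporting strategies")
    if (!object@status %in% c("classified", "unclassified"))
        return("status must be classified/unclassified")
    TRUE
})

#' MGMT promoter methylation result
#'
#' Mean methylation over the observed sites of the fixed 137-CpG promoter
#' panel; status is \code{methylated} when the mean exceeds 25\% (strict) and
#' enough sites were observed, \code{insufficient-data} below the site floor.
#'
#' @slot perSiteFractions named numeric vector, observed panel sites
#'   (\code{chrom:pos}) to methylated fraction.
#' @slot nSitesObserved number of panel sites with coverage.
#' @slot meanPct mean of the observed site fractions x 100 (NA when no
#'   sites observed).
#' @slot status \code{"methylated"}, \code{"unmethylated"} or
#'   \code{"insufficient-data"}.
#'
#' @seealso [mgmtScore()]
#' @export
setClass("MGMTResult",
    representation(perSiteFractions = "numeric", nSitesObserved = "integer",
                   meanPct = "numeric", status = "character"))

#' Integrated streaming report
#'
#' One report per cumulative batch (or one-shot run), holding the consensus
#' decision, per-strategy results, copy-number events and segments, MGMT
#' status, SNV calls, fusion candidates, per-stage errors and provenance.
#'
#' @slot batchIndex cumulative batch index (-1 for one-shot).
#' @slot consensus a [ConsensusDecision-class].
#' @slot classifierResults named list of [ClassifierResult-class], one per
#'   strategy.
#' @slot cnvEvents data.frame of called copy-number events.
#' @slot segments data.frame of copy-number segments.
#' @slot mgmt a [MGMTResult-class].
#' @slot snvs data.frame of clinically filtered SNV calls.
#' @slot snvsAll data.frame of all calls before clinical filtering.
#' @slot fusions data.frame of fusion candidates.
#' @slot stageErrors named list of per-stage error messages (empty when all
#'   stages succeeded).
#' @slot provenance list (input paths, seed, parameter hash).
#'
#' @seealso [runPipeline()], [watchPipeline()], [reportToJSON()]
#' @export
setClass("StreamReport",
    representation(batchIndex = "integer", consensus = "ConsensusDecision",
                   classifierResults = "list", cnvEvents = "data.frame",
                   segments = "data.frame", mgmt = "MGMTResult",
                   snvs = "data.frame", snvsAll = "data.frame",
                   fusions = "data.frame", stageErrors = "list",
                   provenance = "list"))
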