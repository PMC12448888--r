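#' @include AllClasses.R
NULL

#' Accessors for modStream S4 objects
#'
#' Small read-only accessors for the package's result classes; use these
#' rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strategy", function(x) standardGeneric("strategy"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("score", function(x) standardGeneric("score"))
#' @rdname accessors
#' @export
setGeneric("nObserved", function(x) standardGeneric("nObserved"))
#' @rdname accessors
#' @export
setGeneric("consensusStatus", function(x) standardGeneric("consensusStatus"))
#' @rdname accessors
#' @export
setGeneric("supportingStrategies",
    function(x) standardGeneric("supportingStrategies"))
#' @rdname accessors
#' @export
setGeneric("mgmtStatus", function(x) standardGeneric("mgmtStatus"))
#' @rdname accessors
#' @export
setGeneric("meanMethylationPct",
    function(x) standardGeneric("meanMethylationPct"))

#' @rdname accessors
#' @export
setMethod("strategy", "ClassifierModel", function(x) x@strategy)
#' @rdname accessors
#' @export
setMethod("strategy", "ClassifierResult", function(x) x@strategy)
#' @rdname accessors
#' @export
setMethod("classLabel", "ClassifierResult", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("classLabel", "ConsensusDecision", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("score", "ClassifierResult", function(x) x@score)
#' @rdname accessors
#' @export
setMethod("nObserved", "BinaryProfile", function(x) x@nObserved)
#' @rdname accessors
#' @export
setMethod("consensusStatus", "ConsensusDecision", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("supportingStrategies", "ConsensusDecision",
    function(x) x@supporting)
#' @rdname accessors
#' @export
setMethod("mgmtStatus", "MGMTResult", function(x) x@status)
#' @rdname accessors
#' @export
setMethod("meanMethylationPct", "MGMTResult", function(x) x@meanPct)

setMethod("show", "BinaryProfile", function(object) {
    cat("BinaryProfile on panel '", object@panelId, "': ",
        object@nObserved, " observed sites (",
        sum(object@values == 1L), " methylated)\n", sep = "")
})

setMethod("show", "ClassifierModel", function(object) {
    cat("ClassifierModel [", object@strategy, "] ",
        nrow(object@rates), " classes x ", ncol(object@rates),
        " sites; confidence threshold ", object@threshold,
        " (scale ", object@scoreScale, ")\n", sep = "")
})

setMethod("show", "ClassifierResult", function(object) {
    cat("ClassifierResult [", object@strategy, "] label=",
        ifelse(is.na(object@label), "<none>", object@label),
        " score=", signif(object@score, 4),
        " confident=", object@confident,
        " sites=", object@nSitesUsed, "\n", sep = "")
})

setMethod("show", "ConsensusDecision", function(object) {
    if (object@status == "classified")
        cat("ConsensusDecision: classified as '", object@label, "' (",
            length(object@supporting), " classifiers: ",
            paste(object@supporting, collapse = ", "), ")\n", sep = "")
    else cat("ConsensusDecision: unclassified\n")
})

setMethod("show", "MGMTResult", function(object) {
    cat("MGMTResult: ", object@status, " (mean ",
        ifelse(is.na(object@meanPct), "NA",
               sprintf("%.1f%%", object@meanPct)),
        " over ", object@nSitesObserved, " observed sites)\n", sep = "")
})

setMethod("show", "StreamReport", function(object) {
    cat("StreamReport (batch ", object@batchIndex, ")\n", sep = "")
    cat("  consensus : ", object@consensus@status,
        ifelse(object@consensus@status == "classified",
               paste0(" [", object@consensus@label, "]"), ""), "\n", sep = "")
    cat("  CNV events: ", nrow(object@cnvEvents), "\n", sep = "")
    cat("  MGMT      : ", object@mgmt@status, "\n", sep = "")
    cat("  SNVs      : ", nrow(object@snvs), " reported (",
        nrow(object@snvsAll), " total)\n", sep = "")
    cat("  fusions   : ", nrow(object@fusions), "\n", sep = "")
    if (length(object@stageErrors))
        cat("  stage errors: ",
            paste(names(object@stageErrors), collapse = ", "), "\n", sep = "")
})
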