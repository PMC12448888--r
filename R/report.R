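## Pipeline orchestration: one-shot analysis of a modBAM, batched replay
## with per-strategy score trajectories, and report serialisation.

defaultParams <- function(params = list()) {
    utils::modifyList(list(
        perReadThreshold = 0.5, binWidth = 10000L,
        minDepth = 10L, minAltReads = 3L, minVaf = 0.30,
        minBaseQuality = 10L, minSupport = 3L, clusterWindow = 500L,
        minBlock = 200L, regionFraction = 0.70, lossCut = -0.35,
        gainCut = 0.30, focalLossCut = -0.8, mgmtMinSites = 10L,
        mgmtCutoffPct = 25, codeletionArms = c("1p", "19q")), params)
}

#' Build the three classifier strategies from one reference matrix
#'
#' @param rates class x panel-site methylation rate matrix.
#' @param seed seed shared by the strategies.
#' @param panelId panel identifier.
#' @param params hyper-parameter overrides passed to
#'   [trainReferenceModel()].
#' @return named list of [ClassifierModel-class] (forest, perceptron,
#'   centroid).
#' @export
buildModels <- function(rates, seed = 1L, panelId = "panel",
                        params = list()) {
    sapply(c("forest", "perceptron", "centroid"), function(s)
        trainReferenceModel(rates, s, seed = seed, panelId = panelId,
                            params = params),
        simplify = FALSE)
}

emptyMGMT <- function() new("MGMTResult", perSiteFractions = numeric(),
                            nSitesObserved = 0L, meanPct = NA_real_,
                            status = "insufficient-data")

emptyConsensus <- function(batchIndex = -1L)
    new("ConsensusDecision", status = "unclassified", label = NA_character_,
        supporting = character(), batchIndex = as.integer(batchIndex))

#' Run the full pipeline on one modBAM
#'
#' Executes methylome classification (three strategies + consensus), MGMT
#' promoter scoring, copy-number profiling, SNV calling with clinical
#' filtering, and fusion detection, and assembles a [StreamReport-class].
#' Stage failures are isolated: a failing stage contributes an entry to
#' \code{stageErrors} while the remaining stages still run.
#'
#' @param bam indexed modBAM path.
#' @param reference FASTA path or DNAStringSet.
#' @param panel classifier panel GRanges (with \code{site_index}).
#' @param mgmtPanel promoter panel GRanges (137 sites).
#' @param targets named gene GRanges.
#' @param regions CNV region definitions GRanges (\code{region_id},
#'   \code{type}).
#' @param models named list of [ClassifierModel-class] from
#'   [buildModels()].
#' @param clinicalTable data.frame from [readClinicalTable()] (optional;
#'   without it every SNV call stays out of the clinical report).
#' @param params list of threshold overrides (see the package vignette).
#' @param batchIndex batch bookkeeping (-1 = one-shot).
#' @return a [StreamReport-class].
#' @export
runPipeline <- function(bam, reference, panel, mgmtPanel, targets, regions,
                        models, clinicalTable = NULL, params = list(),
                        batchIndex = -1L) {
    p <- defaultParams(params)
    errs <- list()
    dna <- if (is(reference, "DNAStringSet")) reference
           else Biostrings::readDNAStringSet(reference)
    names(dna) <- sub("\\s.*$", "", names(dna))
    ## methylation: calls -> summaries -> profile -> 3 strategies -> consensus
    summaries <- NULL
    results <- list()
    consensus <- emptyConsensus(batchIndex)
    mgmt <- emptyMGMT()
    tryCatch({
        sites <- cpgSites(dna)
        calls <- extractCpGCalls(bam, sites)
        summaries <- summarizeSites(calls, p$perReadThreshold)
        profile <- binarize(summaries, panel,
                            panelId = models[[1L]]@panelId)
        results <- lapply(models, classifyProfile, profile = profile,
                          batchIndex = batchIndex)
        consensus <- consensusCall(unname(results), batchIndex)
    }, error = function(e) errs[["classification"]] <<- conditionMessage(e))
    tryCatch({
        if (!is.null(summaries))
            mgmt <- mgmtScore(summaries, mgmtPanel,
                              minSites = p$mgmtMinSites,
                              cutoffPct = p$mgmtCutoffPct)
    }, error = function(e) errs[["mgmt"]] <<- conditionMessage(e))
    ## copy number
    segDf <- data.frame(); events <- data.frame()
    tryCatch({
        bins <- normalizeBins(binCounts(bam, p$binWidth))
        segs <- segmentBins(bins, lossCut = p$lossCut, gainCut = p$gainCut)
        events <- callCNVEvents(bins, segs, regions,
                                regionFraction = p$regionFraction,
                                focalLossCut = p$focalLossCut,
                                codeletionArms = p$codeletionArms)
        segDf <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(segs)),
            start = BiocGenerics::start(segs),
            end = BiocGenerics::end(segs),
            mean_log2 = GenomicRanges::mcols(segs)$mean_log2,
            n_bins = GenomicRanges::mcols(segs)$n_bins,
            state = GenomicRanges::mcols(segs)$state)
    }, error = function(e) errs[["cnv"]] <<- conditionMessage(e))
    ## SNVs
    snvAll <- data.frame(); snvReport <- data.frame()
    tryCatch({
        piles <- pileupSites(bam, dna, targets,
                             minBaseQuality = p$minBaseQuality)
        callsSnv <- callSNVs(piles, minDepth = p$minDepth,
                             minAltReads = p$minAltReads,
                             minVaf = p$minVaf)
        tab <- if (is.null(clinicalTable))
            data.frame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       gene = character(), protein_change = character(),
                       significance = character())
        else clinicalTable
        snvAll <- annotateClinical(callsSnv, tab, targets)
        snvReport <- snvAll[snvAll$in_report, , drop = FALSE]
    }, error = function(e) errs[["snv"]] <<- conditionMessage(e))
    ## fusions
    fus <- data.frame()
    tryCatch({
        fp <- readFootprints(bam, targets, minBlock = p$minBlock)
        fus <- detectFusions(fp, minSupport = p$minSupport,
                             clusterWindow = p$clusterWindow)
    }, error = function(e) errs[["fusion"]] <<- conditionMessage(e))
    new("StreamReport", batchIndex = as.integer(batchIndex),
        consensus = consensus, classifierResults = results,
        cnvEvents = events, segments = segDf, mgmt = mgmt,
        snvs = snvReport, snvsAll = snvAll, fusions = fus,
        stageErrors = errs,
        provenance = list(bam = bam, params = p,
                          package = as.character(
                              utils::packageVersion("modStream"))))
}

#' Batched replay of a modBAM
#'
#' Splits the reads into cumulative batches, reruns the full pipeline on
#' each cumulative read set (recomputation from the cumulative store, so
#' any batch partition yields the same final report), and records the
#' per-strategy score trajectory. \code{firstConsensusBatch} is the first
#' batch (1-based) whose consensus is \code{classified} — the batch-time
#' analogue of time-to-intraoperative-diagnosis.
#'
#' @inheritParams runPipeline
#' @param batchSize reads per batch (>= 1).
#' @return list: \code{reports} (one [StreamReport-class] per batch),
#'   \code{trajectory} (data.frame batch/strategy/label/score/confident),
#'   \code{firstConsensusBatch} (NA when never classified).
#' @export
watchPipeline <- function(bam, reference, panel, mgmtPanel, targets,
                          regions, models, clinicalTable = NULL,
                          params = list(), batchSize = 100L) {
    stopifnot(batchSize >= 1L)
    reads <- scanBamReadIds(bam)
    nBatches <- if (length(reads)) ceiling(length(reads) / batchSize) else 0L
    reports <- vector("list", nBatches)
    traj <- list()
    firstConsensus <- NA_integer_
    for (k in seq_len(nBatches)) {
        keep <- reads[seq_len(min(k * batchSize, length(reads)))]
        sub <- if (k == nBatches) bam else subsetBamByRead(bam, keep)
        rep <- runPipeline(sub, reference, panel, mgmtPanel, targets,
                           regions, models, clinicalTable, params,
                           batchIndex = k)
        reports[[k]] <- rep
        for (r in rep@classifierResults)
            traj[[length(traj) + 1L]] <- data.frame(
                batch = k, strategy = r@strategy,
                label = r@label, score = r@score, confident = r@confident,
                n_sites_used = r@nSitesUsed)
        if (is.na(firstConsensus) && rep@consensus@status == "classified")
            firstConsensus <- k
    }
    list(reports = reports,
         trajectory = if (length(traj)) do.call(rbind, traj)
                      else data.frame(),
         firstConsensusBatch = firstConsensus)
}

## cumulative-batch BAM: all records (incl. supplementary) of the kept reads
subsetBamByRead <- function(bam, keepReads) {
    dest <- tempfile(fileext = ".bam")
    rules <- S4Vectors::FilterRules(list(
        inBatch = function(x) x$qname %in% keepReads))
    Rsamtools::filterBam(bam, dest, filter = rules,
        param = Rsamtools::ScanBamParam(what = "qname"))
    dest
}

resultToList <- function(r) list(
    strategy = r@strategy,
    label = if (is.na(r@label)) NULL else r@label,
    score = r@score, confident = r@confident,
    n_sites_used = r@nSitesUsed)

#' Serialise a report to JSON
#'
#' Stable key order and no timestamps, so reruns on identical inputs are
#' byte-identical.
#'
#' @param report a [StreamReport-class].
#' @param path optional output file.
#' @return the JSON string, invisibly when written to \code{path}.
#' @export
reportToJSON <- function(report, path = NULL) {
    x <- list(
        batch_index = report@batchIndex,
        consensus = list(
            status = report@consensus@status,
            label = if (is.na(report@consensus@label)) NULL
                    else report@consensus@label,
            supporting = as.list(report@consensus@supporting)),
        classifiers = lapply(unname(report@classifierResults),
                             resultToList),
        mgmt = list(status = report@mgmt@status,
                    mean_pct = if (is.na(report@mgmt@meanPct)) NULL
                               else report@mgmt@meanPct,
                    n_sites_observed = report@mgmt@nSitesObserved),
        cnv_events = report@cnvEvents,
        segments = report@segments,
        snvs = report@snvs,
        fusions = report@fusions,
        stage_errors = report@stageErrors,
        provenance = report@provenance)
    js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                           dataframe = "rows", digits = NA, pretty = TRUE)
    if (!is.null(path)) {
        writeLines(js, path)
        return(invisible(as.character(js)))
    }
    as.character(js)
}
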