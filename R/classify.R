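## Sparse methylome classification: site summaries -> binary profile ->
## three independent strategies -> confidence thresholds -> consensus.

#' Summarise per-read CpG calls into per-site counts
#'
#' A read's observation at a site is scored methylated when its merged
#' methylation probability reaches \code{perReadThreshold}; summaries then
#' count methylated reads per reference site. At nanopore depths most sites
#' are covered by one or two reads, so these fractions are essentially
#' binary observations.
#'
#' @param calls data.frame from [extractCpGCalls()].
#' @param perReadThreshold per-read methylated-state cutoff in (0,1);
#'   default 0.5.
#' @return data.frame with columns chrom, pos, n_reads, n_meth, fraction.
#' @export
summarizeSites <- function(calls, perReadThreshold = 0.5) {
    stopifnot(perReadThreshold > 0, perReadThreshold < 1)
    if (is.null(calls) || nrow(calls) == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          n_reads = integer(), n_meth = integer(),
                          fraction = numeric()))
    key <- paste(calls$chrom, calls$pos, sep = ":")
    meth <- as.integer(calls$p_meth >= perReadThreshold)
    nReads <- as.vector(rowsum(rep(1L, length(key)), key))
    nMeth <- as.vector(rowsum(meth, key))
    u <- sort(unique(key))
    parts <- strsplit(u, ":", fixed = TRUE)
    out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      n_reads = nReads, n_meth = nMeth,
                      fraction = nMeth / nReads)
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
}

#' Binarize site summaries over a classifier panel
#'
#' Panel sites with a methylated fraction of at least 0.5 become 1 (ties are
#' methylated), the rest 0; panel sites without observations are absent from
#' the profile.
#'
#' @param summaries data.frame from [summarizeSites()].
#' @param panel GRanges of panel CpG sites with a \code{site_index} column.
#' @param panelId identifier stored in the profile.
#' @return a [BinaryProfile-class].
#' @export
binarize <- function(summaries, panel, panelId = "panel") {
    pKey <- paste(as.character(GenomicRanges::seqnames(panel)),
                  BiocGenerics::start(panel), sep = ":")
    sKey <- paste(summaries$chrom, summaries$pos, sep = ":")
    hit <- match(sKey, pKey)
    sel <- !is.na(hit)
    idx <- GenomicRanges::mcols(panel)$site_index[hit[sel]]
    vals <- as.integer(summaries$fraction[sel] >= 0.5)
    names(vals) <- as.character(idx)
    o <- order(idx)
    new("BinaryProfile", panelId = panelId, values = vals[o],
        nObserved = length(vals))
}

defaultThreshold <- function(strategy) {
    switch(strategy, forest = 70, centroid = 0.8, perceptron = 0.2,
           stop("unknown strategy: ", strategy))
}

#' Build a classifier model from reference methylation rates
#'
#' The reference is a classes x panel-sites matrix of per-site methylation
#' rates. The returned model carries the rates and strategy
#' hyper-parameters; the forest and perceptron strategies fit on the sites
#' observed in each query profile at classification time (the standard
#' approach for sparse nanopore profiles), seeded so results are
#' deterministic.
#'
#' @param rates numeric matrix (>= 2 rows) of rates in [0,1]; rownames are
#'   the class labels.
#' @param strategy \code{"forest"}, \code{"perceptron"} or
#'   \code{"centroid"}.
#' @param seed integer seed.
#' @param threshold confidence threshold; defaults to 70 (forest), 0.8
#'   (centroid) or 0.2 (perceptron).
#' @param panelId panel identifier the model expects profiles from.
#' @param params list of hyper-parameters (\code{nPerClass} training draws
#'   per class, \code{ntree}, \code{epochs}).
#' @return a [ClassifierModel-class].
#' @export
trainReferenceModel <- function(rates, strategy, seed = 1L,
                                threshold = NULL, panelId = "panel",
                                params = list()) {
    if (is.null(rownames(rates)))
        rownames(rates) <- paste0("class", seq_len(nrow(rates)))
    if (nrow(rates) < 2L)
        stop("degenerate model: at least 2 classes are required")
    if (anyDuplicated(apply(rates, 1L, paste, collapse = ",")))
        warning("identical reference rate rows: affected classes are ",
                "indistinguishable")
    p <- utils::modifyList(list(nPerClass = 40L, ntree = 200L,
                                epochs = 25L), params)
    new("ClassifierModel", strategy = strategy, rates = rates,
        labels = rownames(rates), panelId = panelId,
        threshold = if (is.null(threshold)) defaultThreshold(strategy)
                    else threshold,
        scoreScale = if (strategy == "forest") "0-100" else "0-1",
        seed = as.integer(seed), params = p)
}

## Bernoulli training profiles drawn from the reference rates at the
## observed sites; rows grouped by class.
drawTrainingSet <- function(rates, obsIdx, nPerClass) {
    k <- nrow(rates)
    x <- matrix(stats::runif(k * nPerClass * length(obsIdx)) <
                    rates[rep(seq_len(k), each = nPerClass), obsIdx,
                          drop = FALSE],
                nrow = k * nPerClass)
    storage.mode(x) <- "numeric"
    colnames(x) <- paste0("s", obsIdx)
    list(x = x, y = factor(rep(rownames(rates), each = nPerClass),
                           levels = rownames(rates)))
}

softmax <- function(a) {
    e <- exp(a - max(a))
    e / sum(e)
}

#' Classify a sparse binary methylation profile
#'
#' Only the observed sites of the profile contribute. A profile with zero
#' observed sites yields a no-data result (no label, score 0, not
#' confident). Scores: forest = 100 x vote share of the winning class;
#' centroid = Bernoulli posterior of the winning class; perceptron =
#' softmax margin between the top two classes.
#'
#' @param profile a [BinaryProfile-class].
#' @param model a [ClassifierModel-class] on the same panel.
#' @param batchIndex cumulative batch the profile belongs to (bookkeeping).
#' @return a [ClassifierResult-class].
#' @export
classifyProfile <- function(profile, model, batchIndex = -1L) {
    stopifnot(is(profile, "BinaryProfile"), is(model, "ClassifierModel"))
    if (profile@panelId != model@panelId)
        stop("profile panel '", profile@panelId,
             "' does not match model panel '", model@panelId, "'")
    obsIdx <- as.integer(names(profile@values))
    x <- as.numeric(profile@values)
    if (length(obsIdx) == 0L)
        return(new("ClassifierResult", strategy = model@strategy,
                   label = NA_character_, score = 0, confident = FALSE,
                   nSitesUsed = 0L, batchIndex = as.integer(batchIndex)))
    sc <- switch(model@strategy,
        centroid = scoreCentroid(x, model, obsIdx),
        forest = scoreForest(x, model, obsIdx),
        perceptron = scorePerceptron(x, model, obsIdx),
        stop("unknown strategy: ", model@strategy))
    res <- new("ClassifierResult", strategy = model@strategy,
               label = sc$label, score = sc$score, confident = FALSE,
               nSitesUsed = length(obsIdx),
               batchIndex = as.integer(batchIndex))
    res@confident <- isConfident(res, threshold = model@threshold)
    res
}

scoreCentroid <- function(x, model, obsIdx) {
    r <- pmin(pmax(model@rates[, obsIdx, drop = FALSE], 1e-3), 1 - 1e-3)
    ll <- as.vector(log(r) %*% x + log(1 - r) %*% (1 - x))
    post <- softmax(ll)
    top <- which.max(post)
    list(label = model@labels[top], score = unname(post[top]))
}

scoreForest <- function(x, model, obsIdx) {
    withSeed(model@seed, {
        tr <- drawTrainingSet(model@rates, obsIdx, model@params$nPerClass)
        rf <- randomForest::randomForest(tr$x, tr$y,
                                         ntree = model@params$ntree)
        q <- matrix(x, nrow = 1L,
                    dimnames = list(NULL, colnames(tr$x)))
        votes <- stats::predict(rf, q, type = "vote")[1L, ]
        top <- which.max(votes)
        list(label = names(votes)[top], score = unname(100 * votes[top]))
    })
}

scorePerceptron <- function(x, model, obsIdx) {
    withSeed(model@seed, {
        tr <- drawTrainingSet(model@rates, obsIdx, model@params$nPerClass)
        k <- nlevels(tr$y)
        n <- ncol(tr$x)
        X1 <- cbind(tr$x, 1)
        y <- as.integer(tr$y)
        W <- matrix(0, nrow = k, ncol = n + 1L)
        for (ep in seq_len(model@params$epochs)) {
            ord <- sample.int(nrow(X1))
            nErr <- 0L
            for (i in ord) {
                a <- W %*% X1[i, ]
                pred <- which.max(a)
                if (pred != y[i]) {
                    W[y[i], ] <- W[y[i], ] + X1[i, ]
                    W[pred, ] <- W[pred, ] - X1[i, ]
                    nErr <- nErr + 1L
                }
            }
            if (nErr == 0L) break
        }
        a <- as.vector(W %*% c(x, 1))
        s <- stats::sd(a)
        z <- if (is.na(s) || s == 0) rep(0, k) else (a - mean(a)) / s
        p <- softmax(z)
        o <- order(p, decreasing = TRUE)
        list(label = model@labels[o[1L]],
             score = unname(p[o[1L]] - p[o[2L]]))
    })
}

#' Confidence gate for a classifier result
#'
#' Applies the strategy's confidence threshold: forest scores of 70 or more,
#' centroid posteriors of 0.8 or more, perceptron margins of 0.2 or more are
#' confident. A result without a label (no observed sites) is never
#' confident.
#'
#' @param result a [ClassifierResult-class].
#' @param threshold override for the default per-strategy threshold.
#' @return logical.
#' @export
isConfident <- function(result, threshold = NULL) {
    if (is.null(threshold)) threshold <- defaultThreshold(result@strategy)
    !is.na(result@label) && result@score >= threshold
}

#' Multi-classifier consensus
#'
#' The sample is \code{classified} if and only if two or more strategies
#' return a confident result with the same label; that shared label is the
#' consensus call. Two confident but discordant strategies leave the sample
#' unclassified.
#'
#' @param results list of [ClassifierResult-class], at most one per
#'   strategy.
#' @param batchIndex batch bookkeeping.
#' @return a [ConsensusDecision-class].
#' @export
consensusCall <- function(results, batchIndex = -1L) {
    strat <- vapply(results, strategy, character(1))
    if (anyDuplicated(strat))
        stop("at most one result per strategy")
    conf <- vapply(results, function(r) r@confident, logical(1)) &
            !vapply(results, function(r) is.na(r@label), logical(1))
    if (sum(conf) >= 2L) {
        labs <- vapply(results[conf], classLabel, character(1))
        tab <- table(labs)
        if (max(tab) >= 2L) {
            lab <- names(tab)[which.max(tab)]
            sup <- strat[conf][labs == lab]
            return(new("ConsensusDecision", status = "classified",
                       label = lab, supporting = sup,
                       batchIndex = as.integer(batchIndex)))
        }
    }
    new("ConsensusDecision", status = "unclassified", label = NA_character_,
        supporting = character(), batchIndex = as.integer(batchIndex))
}

#' Draw a sparse binary profile from a class reference
#'
#' Samples \code{nSites} panel sites uniformly and draws each site's binary
#' state Bernoulli in the class's reference rate — the generative model for
#' classifier validation.
#'
#' @param rates class x site rate matrix.
#' @param classId generating class (row index).
#' @param nSites number of observed sites.
#' @param seed RNG seed.
#' @param panelId panel identifier.
#' @return a [BinaryProfile-class].
#' @export
simulateBinaryProfile <- function(rates, classId, nSites, seed = 1L,
                                  panelId = "panel") {
    withSeed(seed, {
        idx <- sort(sample.int(ncol(rates), nSites))
        vals <- as.integer(stats::runif(nSites) < rates[classId, idx])
        names(vals) <- as.character(idx)
        new("BinaryProfile", panelId = panelId, values = vals,
            nObserved = length(vals))
    })
}

#' Append classifier results to a JSON-lines trajectory file
#'
#' One JSON object per result: strategy, label, score, confident,
#' n_sites_used, batch_index.
#'
#' @param results list of [ClassifierResult-class].
#' @param path output file (appended to).
#' @return the path, invisibly.
#' @export
writeResultsJSONL <- function(results, path) {
    con <- file(path, open = "a")
    on.exit(close(con))
    for (r in results)
        writeLines(jsonlite::toJSON(list(
            strategy = r@strategy,
            label = if (is.na(r@label)) NULL else r@label,
            score = r@score, confident = r@confident,
            n_sites_used = r@nSitesUsed, batch_index = r@batchIndex),
            auto_unbox = TRUE, null = "null", digits = NA), con)
    invisible(path)
}
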