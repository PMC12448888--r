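## MGMT promoter methylation: mean methylation over a fixed 137-CpG panel,
## reported methylated above 25%.

#' Score MGMT promoter methylation
#'
#' Averages the methylated fraction of the promoter-panel CpG sites that
#' were observed (unweighted site mean, which is robust to uneven depth) and
#' reports \code{methylated} when the mean strictly exceeds 25\%. With fewer
#' than \code{minSites} observed sites the result is
#' \code{insufficient-data}.
#'
#' @param summaries site summaries from [summarizeSites()].
#' @param mgmtPanel GRanges of the promoter CpG panel (137 sites).
#' @param minSites minimum observed panel sites for a status call.
#' @param cutoffPct decision boundary in percent (strict inequality).
#' @return an [MGMTResult-class].
#' @export
mgmtScore <- function(summaries, mgmtPanel, minSites = 10L,
                      cutoffPct = 25) {
    if (length(mgmtPanel) == 0L)
        stop("configuration error: empty MGMT panel")
    stopifnot(minSites >= 1L)
    pKey <- paste(as.character(GenomicRanges::seqnames(mgmtPanel)),
                  BiocGenerics::start(mgmtPanel), sep = ":")
    sKey <- paste(summaries$chrom, summaries$pos, sep = ":")
    sel <- sKey %in% pKey
    fr <- summaries$fraction[sel]
    names(fr) <- sKey[sel]
    n <- length(fr)
    meanPct <- if (n > 0L) mean(fr) * 100 else NA_real_
    status <- if (n < minSites) "insufficient-data"
              else if (meanPct > cutoffPct) "methylated"
              else "unmethylated"
    new("MGMTResult", perSiteFractions = fr, nSitesObserved = n,
        meanPct = meanPct, status = status)
}

#' Per-read x per-site methylation state matrix over the promoter
#'
#' The data behind the read-level promoter plot: one row per read
#' overlapping the panel, one column per panel CpG, entries
#' \code{"methylated"}, \code{"unmethylated"} or \code{"uncovered"}.
#'
#' @param calls per-read calls from [extractCpGCalls()].
#' @param mgmtPanel GRanges of the promoter CpG panel.
#' @param perReadThreshold per-read methylated-state cutoff.
#' @return character matrix, rownames = read ids, colnames =
#'   \code{chrom:pos} site keys.
#' @export
mgmtReadMatrix <- function(calls, mgmtPanel, perReadThreshold = 0.5) {
    pKey <- paste(as.character(GenomicRanges::seqnames(mgmtPanel)),
                  BiocGenerics::start(mgmtPanel), sep = ":")
    sKey <- paste(calls$chrom, calls$pos, sep = ":")
    sel <- sKey %in% pKey
    calls <- calls[sel, , drop = FALSE]
    sKey <- sKey[sel]
    reads <- unique(calls$read_id)
    m <- matrix("uncovered", nrow = length(reads), ncol = length(pKey),
                dimnames = list(reads, pKey))
    if (nrow(calls))
        m[cbind(match(calls$read_id, reads), match(sKey, pKey))] <-
            ifelse(calls$p_meth >= perReadThreshold,
                   "methylated", "unmethylated")
    m
}

#' Write the promoter read matrix as TSV
#'
#' @param mat matrix from [mgmtReadMatrix()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMgmtMatrix <- function(mat, path) {
    utils::write.table(mat, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}

#' Serialise an MGMT result to JSON
#'
#' @param result an [MGMTResult-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeMgmtJSON <- function(result, path) {
    jsonlite::write_json(list(
        status = result@status,
        mean_pct = if (is.na(result@meanPct)) NULL else result@meanPct,
        n_sites_observed = result@nSitesObserved),
        path, auto_unbox = TRUE, null = "null", digits = NA)
    invisible(path)
}
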