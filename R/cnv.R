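## Copy-number profiling: fixed-width bin counts -> log2 ratios ->
## changepoint segmentation -> canonical event calls.

#' Count primary alignments in fixed-width bins
#'
#' Each primary alignment is assigned to exactly one bin by the midpoint of
#' its reference span, so bin counts sum to the number of primary
#' alignments. Both on-target and off-target reads contribute, which is what
#' makes copy-number profiles readable even under adaptive sampling.
#'
#' @param alignments path to an indexed BAM, or a GRanges of alignment
#'   spans (with seqlengths set).
#' @param binWidth bin width in bp (default 10 kb, suited to the toy
#'   genome; at genome scale 1 Mb is the intended width).
#' @return GRanges of bins tiling each chromosome, with a \code{count}
#'   column.
#' @export
binCounts <- function(alignments, binWidth = 10000L) {
    stopifnot(binWidth >= 1L)
    if (is.character(alignments)) {
        flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                       isSecondaryAlignment = FALSE,
                                       isSupplementaryAlignment = FALSE)
        ga <- GenomicAlignments::readGAlignments(alignments,
            param = Rsamtools::ScanBamParam(flag = flag))
        spans <- GenomicRanges::granges(ga)
    } else spans <- alignments
    sl <- GenomeInfoDb::seqlengths(spans)
    if (anyNA(sl)) stop("alignments must carry seqlengths")
    bins <- GenomicRanges::tileGenome(sl, tilewidth = binWidth,
                                      cut.last.tile.in.chrom = TRUE)
    mids <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(spans)),
        IRanges::IRanges((BiocGenerics::start(spans) +
                          BiocGenerics::end(spans)) %/% 2L, width = 1L))
    GenomicRanges::mcols(bins)$count <-
        GenomicRanges::countOverlaps(bins, mids)
    bins
}

#' Normalise bin counts to log2 ratios
#'
#' \code{log2((count + 0.5) / (median + 0.5))} against the genome-wide
#' median bin count; the 0.5 offset keeps zero-count bins finite.
#'
#' @param bins GRanges from [binCounts()].
#' @return the bins with a \code{log2_ratio} column added.
#' @export
normalizeBins <- function(bins) {
    cnt <- GenomicRanges::mcols(bins)$count
    med <- stats::median(cnt)
    if (med == 0 && all(cnt == 0)) stop("no coverage: all bin counts are 0")
    GenomicRanges::mcols(bins)$log2_ratio <- log2((cnt + 0.5) / (med + 0.5))
    bins
}

## Exact least-squares changepoint segmentation of one series by dynamic
## programming (optimal partitioning): minimises sum of within-segment SSE
## plus `penalty` per segment. Returns integer changepoints (last index of
## each segment).
segmentSeries <- function(y, penalty) {
    n <- length(y)
    if (n == 1L) return(1L)
    S <- c(0, cumsum(y))
    Q <- c(0, cumsum(y^2))
    cost <- function(i, j)  # segment (i+1)..j, i vectorised
        (Q[j + 1L] - Q[i + 1L]) - (S[j + 1L] - S[i + 1L])^2 / (j - i)
    F <- c(0, rep(Inf, n))
    prev <- integer(n)
    for (j in seq_len(n)) {
        i <- 0:(j - 1L)
        cand <- F[i + 1L] + cost(i, j) + penalty
        best <- which.min(cand)  # ties: fewest segments (smallest i wins)
        F[j + 1L] <- cand[best]
        prev[j] <- i[best]
    }
    cps <- integer(0)
    at <- n
    while (at > 0L) {
        cps <- c(at, cps)
        at <- prev[at]
    }
    cps
}

#' Segment log2 ratios into copy-number states
#'
#' Per-chromosome exact least-squares changepoint segmentation (dynamic
#' programming with a per-segment penalty), followed by state assignment:
#' segments with mean log2 ratio at or below -0.35 are losses, at or above
#' +0.30 gains, otherwise neutral.
#'
#' @param bins GRanges from [normalizeBins()].
#' @param penalty per-segment penalty; by default \code{3 * sigma^2 *
#'   log(n)} with sigma estimated from the median absolute successive
#'   difference.
#' @param lossCut,gainCut state thresholds on the segment mean.
#' @return GRanges of contiguous segments with \code{mean_log2},
#'   \code{n_bins} and \code{state} columns.
#' @export
segmentBins <- function(bins, penalty = NULL, lossCut = -0.35,
                        gainCut = 0.30) {
    lr <- GenomicRanges::mcols(bins)$log2_ratio
    if (is.null(penalty)) {
        sigma <- max(stats::mad(diff(lr)) / sqrt(2), 1e-3, na.rm = TRUE)
        penalty <- 3 * sigma^2 * log(length(lr))
    }
    segs <- list()
    for (ch in GenomeInfoDb::seqlevels(bins)) {
        sel <- as.character(GenomicRanges::seqnames(bins)) == ch
        if (!any(sel)) next
        y <- lr[sel]
        cps <- segmentSeries(y, penalty)
        from <- c(1L, utils::head(cps, -1L) + 1L)
        mean_log2 <- vapply(seq_along(cps), function(k)
            mean(y[from[k]:cps[k]]), numeric(1))
        segs[[ch]] <- data.frame(chrom = ch,
            start = BiocGenerics::start(bins[sel][from]),
            end = BiocGenerics::end(bins[sel][cps]),
            mean_log2 = mean_log2, n_bins = cps - from + 1L)
    }
    df <- do.call(rbind, unname(segs))
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
        mean_log2 = df$mean_log2, n_bins = df$n_bins,
        state = ifelse(df$mean_log2 <= lossCut, "loss",
                ifelse(df$mean_log2 >= gainCut, "gain", "neutral")),
        seqlengths = GenomeInfoDb::seqlengths(bins))
}

#' Call canonical copy-number events over named regions
#'
#' A gain or loss is called for a region (whole chromosome or arm) when at
#' least \code{regionFraction} of its bins lie in segments of that state.
#' Focal regions (e.g. a CDKN2A/B-like locus) are called deleted when their
#' mean log2 ratio is at or below \code{focalLossCut}. When both arms of the
#' configured codeletion pair are lost, a codeletion event is added.
#'
#' @param bins GRanges from [normalizeBins()].
#' @param segments GRanges from [segmentBins()].
#' @param regions GRanges of region definitions with \code{region_id} and
#'   \code{type} (\code{chromosome}, \code{arm} or \code{focal}) columns.
#' @param regionFraction minimum fraction of region bins in the event state.
#' @param focalLossCut mean log2 cutoff for focal deletions.
#' @param codeletionArms character(2) of arm region_ids whose joint loss is
#'   reported as a codeletion.
#' @return data.frame with region_id, event, fraction, mean_log2.
#' @export
callCNVEvents <- function(bins, segments, regions, regionFraction = 0.70,
                          focalLossCut = -0.8,
                          codeletionArms = c("1p", "19q")) {
    mids <- GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(bins)),
        IRanges::IRanges((BiocGenerics::start(bins) +
                          BiocGenerics::end(bins)) %/% 2L, width = 1L))
    segOf <- GenomicRanges::findOverlaps(mids, segments, select = "first")
    binState <- GenomicRanges::mcols(segments)$state[segOf]
    lr <- GenomicRanges::mcols(bins)$log2_ratio
    out <- list()
    for (i in seq_along(regions)) {
        rid <- GenomicRanges::mcols(regions)$region_id[i]
        rtype <- GenomicRanges::mcols(regions)$type[i]
        ## arms/chromosomes assign bins by midpoint; focal regions may be
        ## smaller than one bin, so any overlap counts there
        inR <- if (rtype == "focal")
            IRanges::overlapsAny(bins, regions[i])
        else IRanges::overlapsAny(mids, regions[i])
        if (!any(inR)) {
            warning("region ", rid, " contains no bins; skipped")
            next
        }
        meanLr <- mean(lr[inR])
        if (rtype == "focal") {
            if (meanLr <= focalLossCut)
                out[[length(out) + 1L]] <- data.frame(
                    region_id = rid, event = "loss",
                    fraction = mean(binState[inR] == "loss"),
                    mean_log2 = meanLr)
        } else {
            for (ev in c("gain", "loss")) {
                fr <- mean(binState[inR] == ev)
                if (fr >= regionFraction)
                    out[[length(out) + 1L]] <- data.frame(
                        region_id = rid, event = ev, fraction = fr,
                        mean_log2 = meanLr)
            }
        }
    }
    events <- if (length(out)) do.call(rbind, out)
              else data.frame(region_id = character(), event = character(),
                              fraction = numeric(), mean_log2 = numeric())
    lost <- events$region_id[events$event == "loss"]
    if (all(codeletionArms %in% lost))
        events <- rbind(events, data.frame(
            region_id = paste(codeletionArms, collapse = "/"),
            event = "codeletion",
            fraction = min(events$fraction[
                events$region_id %in% codeletionArms &
                events$event == "loss"]),
            mean_log2 = NA_real_))
    rownames(events) <- NULL
    events
}

#' Write segments in SEG format
#'
#' @param segments GRanges from [segmentBins()].
#' @param path output file.
#' @param sampleId sample identifier for the first column.
#' @return the path, invisibly.
#' @export
writeSegFile <- function(segments, path, sampleId = "sample") {
    df <- data.frame(ID = sampleId,
                     chrom = as.character(GenomicRanges::seqnames(segments)),
                     loc.start = BiocGenerics::start(segments),
                     loc.end = BiocGenerics::end(segments),
                     num.mark = GenomicRanges::mcols(segments)$n_bins,
                     seg.mean = round(GenomicRanges::mcols(segments)$mean_log2,
                                      4))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write per-bin counts and log2 ratios as TSV
#'
#' @param bins GRanges from [normalizeBins()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBinsTsv <- function(bins, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                     start = BiocGenerics::start(bins) - 1L,
                     end = BiocGenerics::end(bins),
                     count = GenomicRanges::mcols(bins)$count,
                     log2_ratio = GenomicRanges::mcols(bins)$log2_ratio)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
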