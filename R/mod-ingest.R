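#' Merge 5-hydroxymethylcytosine into 5-methylcytosine probability
#'
#' Nanopore modified-base models emit separate probabilities for 5mC and 5hmC
#' at each CpG cytosine. For classification and methylation scoring the two
#' modified states are collapsed into a single methylation probability by
#' summing them. Probabilities from a single model are mutually exclusive and
#' sum to at most 1; the sum is clamped at 1 so that independently produced
#' inputs cannot escape the probability scale.
#'
#' @param pM numeric vector of 5mC probabilities in [0,1].
#' @param pH numeric vector of 5hmC probabilities in [0,1] (recycled against
#'   \code{pM}).
#' @return numeric vector \code{pmin(pM + pH, 1)}.
#' @examples
#' mergeHydroxymethyl(0.3, 0.4)  # 0.7
#' mergeHydroxymethyl(0.7, 0.6)  # clamped to 1
#' @export
mergeHydroxymethyl <- function(pM, pH) {
    if (anyNA(pM) || anyNA(pH))
        stop("invalid probability: NA")
    if (any(pM < 0) || any(pM > 1) || any(pH < 0) || any(pH > 1))
        stop("invalid probability: inputs must lie in [0,1]")
    pmin(pM + pH, 1)
}

#' Locate CpG sites on a reference genome
#'
#' Finds every CpG dinucleotide on the forward strand of the reference and
#' returns the position of the cytosine. Both strands of a CpG are reported
#' against this single forward-strand coordinate: CpG methylation is
#' strand-symmetric, so reverse-strand observations (at the paired G) are
#' pooled onto the forward C by [extractCpGCalls()].
#'
#' @param reference path to a FASTA file or a [Biostrings::DNAStringSet].
#' @return a [GenomicRanges::GRanges] of width-1 ranges at each CpG cytosine
#'   (1-based).
#' @export
cpgSites <- function(reference) {
    dna <- if (is(reference, "DNAStringSet")) reference
           else Biostrings::readDNAStringSet(reference)
    names(dna) <- sub("\\s.*$", "", names(dna))
    hits <- Biostrings::vmatchPattern("CG", dna)
    starts <- lapply(hits, BiocGenerics::start)
    GenomicRanges::GRanges(
        rep(names(dna), lengths(starts)),
        IRanges::IRanges(unlist(starts, use.names = FALSE), width = 1L),
        seqlengths = stats::setNames(Biostrings::width(dna), names(dna)))
}

## ML byte <-> probability. The BAM spec assigns each byte the interval
## [c/256, (c+1)/256); we decode to the grid c/255 so that encode(decode(c))
## round-trips exactly.
decodeML <- function(code) code / 255
encodeML <- function(p) as.integer(round(p * 255))

## fast base-R reverse complement for plain character sequences
revcompChar <- function(x) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Parse one MM string + ML byte vector into per-stored-SEQ-position
## probabilities for the m and h codes on cytosines.
## seqChar: stored SEQ; isReverse: TRUE when FLAG 0x10 is set (MM/ML refer to
## the as-sequenced read, i.e. the reverse complement of SEQ).
parseModTags <- function(seqChar, mm, ml, isReverse) {
    L <- nchar(seqChar)
    asSeq <- if (isReverse) revcompChar(seqChar) else seqChar
    cPos <- which(strsplit(asSeq, "", fixed = TRUE)[[1]] == "C")
    sub <- strsplit(sub(";$", "", mm), ";", fixed = TRUE)[[1]]
    out <- list()
    mlAt <- 0L
    for (s in sub) {
        parts <- strsplit(s, ",", fixed = TRUE)[[1]]
        head <- parts[1]
        deltas <- as.integer(parts[-1])
        n <- length(deltas)
        m <- regmatches(head,
            regexec("^([ACGTUN])([-+])([a-z0-9]+)([.?]?)$", head))[[1]]
        if (length(m) == 0) {
            mlAt <- mlAt + n
            next
        }
        base <- m[2]; code <- m[4]
        vals <- ml[(mlAt + 1L):(mlAt + n)]
        mlAt <- mlAt + n
        if (base != "C" || !code %in% c("m", "h"))
            next
        idx <- cumsum(deltas + 1L)
        keep <- idx <= length(cPos)
        asSeqPos <- cPos[idx[keep]]
        storedPos <- if (isReverse) L - asSeqPos + 1L else asSeqPos
        out[[code]] <- rbind(out[[code]],
            cbind(pos = storedPos, p = decodeML(vals[keep])))
    }
    if (is.null(out$m) && is.null(out$h)) return(NULL)
    pos <- sort(unique(c(out$m[, "pos"], out$h[, "pos"])))
    pm <- ph <- numeric(length(pos))
    if (!is.null(out$m))
        pm[match(out$m[, "pos"], pos)] <- out$m[, "p"]
    if (!is.null(out$h))
        ph[match(out$h[, "pos"], pos)] <- out$h[, "p"]
    list(seqPos = pos, pM = pm, pH = ph)
}

## Reference positions of sorted 1-based query (stored SEQ) positions, given
## CIGAR and leftmost ref pos. Positions falling in insertions/clips map to
## NA; positions deleted from the read never appear as query positions.
queryToRef <- function(cigar, pos, queryPos) {
    ops <- strsplit(gsub("([MIDNSHP=X])", "\\1,", cigar), ",")[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- sub("^[0-9]+", "", ops)
    refAt <- pos
    qAt <- 1L
    out <- rep(NA_integer_, length(queryPos))
    for (i in seq_along(op)) {
        if (op[i] %in% c("M", "=", "X")) {
            hit <- queryPos >= qAt & queryPos < qAt + n[i]
            out[hit] <- refAt + (queryPos[hit] - qAt)
            qAt <- qAt + n[i]; refAt <- refAt + n[i]
        } else if (op[i] %in% c("I", "S")) {
            qAt <- qAt + n[i]
        } else if (op[i] %in% c("D", "N")) {
            refAt <- refAt + n[i]
        }
    }
    out
}

#' Extract per-read CpG methylation calls from a modBAM
#'
#' Reads primary alignments carrying MM/ML modification tags and emits one
#' call per read-covered reference CpG with a modification observation. The
#' 5hmC probability is merged into 5mC per base
#' (see [mergeHydroxymethyl()]). Observations on reverse-strand-aligned reads
#' fall on the G of the CpG and are remapped to the paired forward-strand C,
#' so both strands pool onto one coordinate per site. Reads without
#' modification tags are skipped with a warning; secondary and supplementary
#' alignments never contribute (chimeric reads would otherwise be counted
#' twice).
#'
#' @param bam path to an indexed, coordinate-sorted BAM with MM/ML tags.
#' @param sites [GenomicRanges::GRanges] of reference CpG cytosines, from
#'   [cpgSites()].
#' @param region optional GRanges restricting the scan.
#' @return data.frame with columns \code{read_id}, \code{chrom}, \code{pos}
#'   (1-based forward-strand C), \code{strand} (of the read) and
#'   \code{p_meth} (merged probability).
#' @export
extractCpGCalls <- function(bam, sites, region = NULL) {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    what <- c("qname", "flag", "rname", "pos", "cigar", "seq")
    param <- if (is.null(region))
        Rsamtools::ScanBamParam(what = what, tag = c("MM", "ML"), flag = flag)
    else
        Rsamtools::ScanBamParam(what = what, tag = c("MM", "ML"), flag = flag,
                                which = region)
    res <- Rsamtools::scanBam(bam, param = param)
    res <- list(qname = unlist(lapply(res, `[[`, "qname")),
                flag = unlist(lapply(res, `[[`, "flag")),
                rname = unlist(lapply(res, function(x) as.character(x$rname))),
                pos = unlist(lapply(res, `[[`, "pos")),
                cigar = unlist(lapply(res, `[[`, "cigar")),
                seq = do.call(c, lapply(res, `[[`, "seq")),
                MM = unlist(lapply(res, function(x) {
                    v <- x$tag$MM
                    if (is.null(v)) rep(NA_character_, length(x$qname)) else v
                })),
                ML = do.call(c, lapply(res, function(x) {
                    v <- x$tag$ML
                    if (is.null(v)) vector("list", length(x$qname)) else v
                })))
    siteSet <- split(BiocGenerics::start(sites),
                     as.character(GenomicRanges::seqnames(sites)))
    seqChars <- as.character(res$seq)
    nReads <- length(res$qname)
    calls <- vector("list", nReads)
    nTagless <- 0L
    for (i in seq_len(nReads)) {
        mm <- res$MM[i]; ml <- res$ML[[i]]
        if (is.na(mm) || is.null(ml) || all(is.na(ml))) {
            nTagless <- nTagless + 1L
            next
        }
        isRev <- bitwAnd(res$flag[i], 16L) > 0L
        tags <- parseModTags(seqChars[i], mm, as.numeric(ml), isRev)
        if (is.null(tags)) next
        refPos <- queryToRef(res$cigar[i], res$pos[i], tags$seqPos)
        ok <- !is.na(refPos)
        if (!any(ok)) next
        refPos <- refPos[ok]
        chrom <- res$rname[i]
        ## forward-aligned reads observe the C itself; reverse-aligned reads
        ## observe the G one base to the right of the forward C
        cPos <- if (isRev) refPos - 1L else refPos
        known <- cPos %in% siteSet[[chrom]]
        if (!any(known)) next
        calls[[i]] <- list(
            read_id = res$qname[i], chrom = chrom,
            pos = cPos[known],
            strand = if (isRev) "-" else "+",
            p_meth = mergeHydroxymethyl(tags$pM[ok][known],
                                        tags$pH[ok][known]))
    }
    if (nTagless > 0L)
        warning(nTagless, " read(s) without modification tags skipped")
    calls <- calls[!vapply(calls, is.null, logical(1))]
    if (length(calls) == 0L)
        return(data.frame(read_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          p_meth = numeric()))
    nPer <- vapply(calls, function(x) length(x$pos), integer(1))
    data.frame(
        read_id = rep(vapply(calls, `[[`, "", "read_id"), nPer),
        chrom = rep(vapply(calls, `[[`, "", "chrom"), nPer),
        pos = unlist(lapply(calls, `[[`, "pos"), use.names = FALSE),
        strand = rep(vapply(calls, `[[`, "", "strand"), nPer),
        p_meth = unlist(lapply(calls, `[[`, "p_meth"), use.names = FALSE))
}

#' Replay a BAM in cumulative read batches
#'
#' Splits the reads of a coordinate-sorted BAM (ordered by first appearance)
#' into batches of \code{batchSize} reads and yields, after each batch, the
#' cumulative CpG call store over batches \code{0..k}. The final store is
#' identical to single-pass extraction whatever the partition.
#'
#' @param bam path to an indexed modBAM.
#' @param sites CpG site GRanges from [cpgSites()].
#' @param batchSize reads per batch (>= 1).
#' @return list with \code{stores} (list of cumulative call data.frames, one
#'   per batch), \code{nBatches}, and \code{readBatches} (list of read-id
#'   character vectors).
#' @export
streamBatches <- function(bam, sites, batchSize) {
    stopifnot(batchSize >= 1)
    calls <- extractCpGCalls(bam, sites)
    reads <- scanBamReadIds(bam)
    if (length(reads) == 0L)
        return(list(stores = list(), nBatches = 0L, readBatches = list()))
    nBatches <- ceiling(length(reads) / batchSize)
    readBatches <- split(reads,
                         rep(seq_len(nBatches), each = batchSize,
                             length.out = length(reads)))
    stores <- vector("list", nBatches)
    for (k in seq_len(nBatches)) {
        upTo <- unlist(readBatches[seq_len(k)], use.names = FALSE)
        stores[[k]] <- calls[calls$read_id %in% upTo, , drop = FALSE]
        rownames(stores[[k]]) <- NULL
    }
    list(stores = stores, nBatches = nBatches,
         readBatches = unname(readBatches))
}

## Read ids in order of first appearance in the (sorted) file, primary
## alignments only.
scanBamReadIds <- function(bam) {
    p <- Rsamtools::ScanBamParam(what = "qname",
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE,
                                      isSupplementaryAlignment = FALSE))
    q <- unlist(lapply(Rsamtools::scanBam(bam, param = p), `[[`, "qname"))
    unique(q)
}

#' Write a bedMethyl-style per-site summary
#'
#' @param summaries site summary data.frame from [summarizeSites()].
#' @param path output file.
#' @return the path, invisibly. Columns: chrom, start (0-based), end,
#'   coverage, percent methylated.
#' @export
writeBedMethyl <- function(summaries, path) {
    df <- data.frame(chrom = summaries$chrom,
                     start = summaries$pos - 1L,
                     end = summaries$pos,
                     coverage = summaries$n_reads,
                     pct_methylated = round(100 * summaries$fraction, 2))
    df <- df[order(df$chrom, df$start), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
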