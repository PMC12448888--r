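## Gene-fusion candidates from split-aligned long reads: a read whose
## primary + supplementary alignments hit two disparate targets (or one
## target plus an unannotated locus) supports a fusion; candidates need a
## minimum number of supporting reads.

cigarClip <- function(cigar, side = c("left", "right")) {
    side <- match.arg(side)
    m <- if (side == "left") regmatches(cigar, regexpr("^[0-9]+[SH]", cigar))
         else regmatches(cigar, regexpr("[0-9]+[SH]$", cigar))
    if (length(m) == 0L) 0L else as.integer(sub("[SH]", "", m))
}

#' Per-read alignment footprints over target regions
#'
#' Collects primary and supplementary alignments (secondary excluded),
#' drops aligned blocks shorter than \code{minBlock}, and labels each block
#' with the overlapping target gene or, when none overlaps, with an
#' \code{elsewhere:<chrom>:<bin>} locus (unannotated partners are grouped
#' in \code{elsewhereBin}-wide bins). Query-start coordinates (in
#' as-sequenced read orientation) order the blocks along the read.
#'
#' @param bam indexed BAM path.
#' @param targets named gene GRanges (a \code{name} column).
#' @param minBlock minimum aligned reference length per block (default
#'   200 bp, suppressing spurious supplementary hits).
#' @param elsewhereBin bin width for unannotated loci.
#' @return data.frame: read_id, label, chrom, ref_start, ref_end, strand,
#'   q_start, is_primary.
#' @export
readFootprints <- function(bam, targets, minBlock = 200L,
                           elsewhereBin = 100000L) {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE)
    res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar"), flag = flag))[[1]]
    if (length(res$qname) == 0L)
        return(data.frame(read_id = character(), label = character(),
                          chrom = character(), ref_start = integer(),
                          ref_end = integer(), strand = character(),
                          q_start = integer(), is_primary = logical()))
    refWidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
    refEnd <- res$pos + refWidth - 1L
    isRev <- bitwAnd(res$flag, 16L) > 0L
    qStart <- vapply(seq_along(res$cigar), function(i)
        cigarClip(res$cigar[i], if (isRev[i]) "right" else "left"),
        integer(1)) + 1L
    df <- data.frame(read_id = res$qname,
                     chrom = as.character(res$rname),
                     ref_start = res$pos, ref_end = refEnd,
                     strand = ifelse(isRev, "-", "+"),
                     q_start = qStart,
                     is_primary = bitwAnd(res$flag, 2048L) == 0L)
    df <- df[refWidth >= minBlock, , drop = FALSE]
    if (nrow(df) == 0L) return(cbind(df, label = character(0))[
        c("read_id", "label", "chrom", "ref_start", "ref_end", "strand",
          "q_start", "is_primary")])
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$ref_start, df$ref_end))
    ov <- GenomicRanges::findOverlaps(gr, targets)
    best <- tapply(seq_along(ov),
                   S4Vectors::queryHits(ov), function(k) {
        w <- IRanges::width(IRanges::pintersect(
            IRanges::ranges(gr)[S4Vectors::queryHits(ov)[k]],
            IRanges::ranges(targets)[S4Vectors::subjectHits(ov)[k]]))
        S4Vectors::subjectHits(ov)[k[which.max(w)]]
    })
    df$label <- paste0("elsewhere:", df$chrom, ":",
                       df$ref_start %/% elsewhereBin)
    qh <- as.integer(names(best))
    df$label[qh] <- GenomicRanges::mcols(targets)$name[unlist(best)]
    rownames(df) <- NULL
    df[c("read_id", "label", "chrom", "ref_start", "ref_end", "strand",
         "q_start", "is_primary")]
}

## distinct-locus test: different labels, or the same gene hit twice more
## than sameGeneFarBp apart
distinctLoci <- function(a, b, sameGeneFarBp = 1e6) {
    a$label != b$label ||
        (a$chrom == b$chrom &&
         abs(a$ref_start - b$ref_start) > sameGeneFarBp) ||
        (a$chrom != b$chrom)
}

#' Detect fusion candidates from read footprints
#'
#' Orders each read's aligned blocks along the read, collapses runs within
#' one locus, and treats every junction between consecutive distinct loci
#' as fusion evidence. Junction breakpoints are clustered per canonical
#' partner pair within \code{clusterWindow} bp; clusters supported by at
#' least \code{minSupport} reads become candidates. Reads spanning three or
#' more loci additionally yield multi-partner chain candidates.
#'
#' @param footprints data.frame from [readFootprints()].
#' @param minSupport minimum supporting reads (default 3).
#' @param clusterWindow breakpoint clustering window in bp.
#' @param sameGeneFarBp distance beyond which two blocks in the same gene
#'   count as disparate loci.
#' @return data.frame: partners (\code{"A::B"} or a longer chain),
#'   n_partners, chromA, posA, chromB, posB (first junction cluster
#'   medians; NA for chains), n_support, read_ids (comma separated).
#' @export
detectFusions <- function(footprints, minSupport = 3L, clusterWindow = 500L,
                          sameGeneFarBp = 1e6) {
    stopifnot(minSupport >= 1L)
    empty <- data.frame(partners = character(), n_partners = integer(),
                        chromA = character(), posA = numeric(),
                        chromB = character(), posB = numeric(),
                        n_support = integer(), read_ids = character())
    if (nrow(footprints) == 0L) return(empty)
    junctions <- list()
    chains <- list()
    for (rid in unique(footprints$read_id)) {
        fp <- footprints[footprints$read_id == rid, , drop = FALSE]
        fp <- fp[order(fp$q_start), , drop = FALSE]
        ## collapse consecutive blocks on the same locus
        keep <- c(TRUE, vapply(seq_len(nrow(fp))[-1], function(i)
            distinctLoci(fp[i - 1L, ], fp[i, ], sameGeneFarBp), logical(1)))
        fp <- fp[keep, , drop = FALSE]
        if (nrow(fp) < 2L) next
        for (i in seq_len(nrow(fp) - 1L)) {
            a <- fp[i, ]; b <- fp[i + 1L, ]
            posA <- if (a$strand == "+") a$ref_end else a$ref_start
            posB <- if (b$strand == "+") b$ref_start else b$ref_end
            ## canonical pair orientation: lexicographically smaller first
            if (a$label <= b$label)
                junctions[[length(junctions) + 1L]] <- data.frame(
                    read_id = rid, pair = paste(a$label, b$label, sep = "::"),
                    chromA = a$chrom, posA = posA,
                    chromB = b$chrom, posB = posB)
            else
                junctions[[length(junctions) + 1L]] <- data.frame(
                    read_id = rid, pair = paste(b$label, a$label, sep = "::"),
                    chromA = b$chrom, posA = posB,
                    chromB = a$chrom, posB = posA)
        }
        if (nrow(fp) >= 3L) {
            seqLabels <- fp$label
            rev <- rev(seqLabels)
            key <- if (paste(seqLabels, collapse = "::") <=
                       paste(rev, collapse = "::"))
                paste(seqLabels, collapse = "::")
            else paste(rev, collapse = "::")
            chains[[length(chains) + 1L]] <-
                data.frame(read_id = rid, chain = key,
                           n_partners = nrow(fp))
        }
    }
    out <- list()
    if (length(junctions)) {
        jn <- do.call(rbind, junctions)
        for (pr in unique(jn$pair)) {
            g <- jn[jn$pair == pr, , drop = FALSE]
            g <- g[order(g$posA, g$posB), , drop = FALSE]
            cl <- integer(nrow(g))
            anchorA <- anchorB <- NA_real_
            cur <- 0L
            for (i in seq_len(nrow(g))) {
                if (is.na(anchorA) ||
                    abs(g$posA[i] - anchorA) > clusterWindow ||
                    abs(g$posB[i] - anchorB) > clusterWindow) {
                    cur <- cur + 1L
                    anchorA <- g$posA[i]; anchorB <- g$posB[i]
                }
                cl[i] <- cur
            }
            for (k in unique(cl)) {
                gg <- g[cl == k, , drop = FALSE]
                reads <- unique(gg$read_id)
                if (length(reads) < minSupport) next
                out[[length(out) + 1L]] <- data.frame(
                    partners = pr, n_partners = 2L,
                    chromA = gg$chromA[1L],
                    posA = stats::median(gg$posA),
                    chromB = gg$chromB[1L],
                    posB = stats::median(gg$posB),
                    n_support = length(reads),
                    read_ids = paste(sort(reads), collapse = ","))
            }
        }
    }
    if (length(chains)) {
        cn <- do.call(rbind, chains)
        for (key in unique(cn$chain)) {
            reads <- unique(cn$read_id[cn$chain == key])
            if (length(reads) < minSupport) next
            out[[length(out) + 1L]] <- data.frame(
                partners = key,
                n_partners = cn$n_partners[cn$chain == key][1L],
                chromA = NA_character_, posA = NA_real_,
                chromB = NA_character_, posB = NA_real_,
                n_support = length(reads),
                read_ids = paste(sort(reads), collapse = ","))
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    res <- res[order(-res$n_support, res$partners), ]
    rownames(res) <- NULL
    res
}

#' Write fusion candidates as TSV
#'
#' @param candidates data.frame from [detectFusions()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFusionTsv <- function(candidates, path) {
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
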