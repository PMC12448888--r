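## Tumor-only SNV calling: base-quality-filtered pileups over target
## regions, a transparent depth/VAF threshold caller, and clinical
## significance filtering. A raw allele-count facility supports manual
## inspection of sites below the auto-call line.

#' Pileup base counts over target regions
#'
#' Counts A/C/G/T and deletions per reference position from primary
#' alignments only, applying a base-quality floor.
#'
#' @param bam indexed BAM path.
#' @param reference FASTA path or DNAStringSet (for the reference base).
#' @param regions GRanges of target regions.
#' @param minBaseQuality minimum base quality (default 10).
#' @param maxDepth pileup depth cap.
#' @return data.frame: chrom, pos, ref_base, A, C, G, T, del, depth.
#' @export
pileupSites <- function(bam, reference, regions, minBaseQuality = 10L,
                        maxDepth = 100000L) {
    dna <- if (is(reference, "DNAStringSet")) reference
           else Biostrings::readDNAStringSet(reference)
    names(dna) <- sub("\\s.*$", "", names(dna))
    bad <- setdiff(unique(as.character(GenomicRanges::seqnames(regions))),
                   names(dna))
    if (length(bad))
        stop("region chromosome(s) outside reference: ",
             paste(bad, collapse = ", "))
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    pp <- Rsamtools::PileupParam(max_depth = maxDepth,
                                 min_base_quality = minBaseQuality,
                                 min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 include_deletions = TRUE,
                                 include_insertions = FALSE)
    res <- Rsamtools::pileup(bam,
        scanBamParam = Rsamtools::ScanBamParam(flag = flag, which = regions),
        pileupParam = pp)
    if (nrow(res) == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          ref_base = character(), A = integer(),
                          C = integer(), G = integer(), T = integer(),
                          del = integer(), depth = integer()))
    key <- paste(res$seqnames, res$pos, sep = ":")
    u <- unique(key)
    wide <- matrix(0L, nrow = length(u), ncol = 5L,
                   dimnames = list(u, c("A", "C", "G", "T", "-")))
    nuc <- as.character(res$nucleotide)
    keep <- nuc %in% colnames(wide)
    idx <- cbind(match(key[keep], u), match(nuc[keep], colnames(wide)))
    wide[idx] <- wide[idx] + res$count[keep]
    parts <- strsplit(u, ":", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1L)
    pos <- as.integer(vapply(parts, `[`, "", 2L))
    refBase <- vapply(seq_along(u), function(i)
        substr(as.character(dna[[chrom[i]]]), pos[i], pos[i]), character(1))
    out <- data.frame(chrom = chrom, pos = pos, ref_base = refBase,
                      A = wide[, "A"], C = wide[, "C"], G = wide[, "G"],
                      T = wide[, "T"], del = wide[, "-"],
                      depth = rowSums(wide))
    out <- out[order(out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
}

#' Threshold SNV caller
#'
#' A site is eligible only at a read depth of 10 or more (the depth gate);
#' the top non-reference base is called when it is supported by at least
#' \code{minAltReads} reads at a variant allele fraction of at least
#' \code{minVaf}. The defaults (3 reads, VAF 0.30) put borderline
#' low-fraction variants below the auto-call line, where
#' [inspectSite()] still exposes their raw counts.
#'
#' @param pileups data.frame from [pileupSites()].
#' @param minDepth depth gate (default 10).
#' @param minAltReads minimum supporting reads.
#' @param minVaf minimum variant allele fraction.
#' @return data.frame: chrom, pos, ref, alt, depth, alt_count, vaf.
#' @export
callSNVs <- function(pileups, minDepth = 10L, minAltReads = 3L,
                     minVaf = 0.30) {
    stopifnot(minDepth > 0L, minAltReads > 0L, minVaf > 0)
    empty <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        depth = integer(), alt_count = integer(),
                        vaf = numeric())
    if (nrow(pileups) == 0L) return(empty)
    bases <- c("A", "C", "G", "T")
    out <- list()
    for (i in seq_len(nrow(pileups))) {
        if (pileups$depth[i] < minDepth) next
        ref <- pileups$ref_base[i]
        altBases <- setdiff(bases, ref)
        cnt <- unlist(pileups[i, altBases])
        alt <- altBases[which.max(cnt)]
        altCount <- max(cnt)
        vaf <- altCount / pileups$depth[i]
        if (altCount >= minAltReads && vaf >= minVaf)
            out[[length(out) + 1L]] <- data.frame(
                chrom = pileups$chrom[i], pos = pileups$pos[i], ref = ref,
                alt = alt, depth = as.integer(pileups$depth[i]),
                alt_count = as.integer(altCount), vaf = vaf)
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Read a clinical-significance variant table
#'
#' TSV with columns chrom, pos, ref, alt, gene, protein_change,
#' significance. Rows lacking both a usable variant key (chrom+pos+ref+alt)
#' and a gene name are skipped with a warning.
#'
#' @param path TSV path.
#' @return data.frame of well-formed rows.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    df$pos <- suppressWarnings(as.integer(df$pos))
    hasKey <- !is.na(df$pos) & nzchar(df$ref) & nzchar(df$alt)
    hasGene <- !is.na(df$gene) & nzchar(df$gene)
    bad <- !hasKey & !hasGene
    if (any(bad)) {
        warning(sum(bad), " malformed clinical table row(s) skipped")
        df <- df[!bad, , drop = FALSE]
    }
    df
}

#' Filter SNV calls by clinical significance
#'
#' Calls matching a clinical table row by exact variant key
#' (chrom, pos, ref, alt) — or, as a fallback, by gene for table rows
#' without coordinates — are annotated and flagged for the report; all
#' calls are retained (the full output keeps everything, the report shows
#' only annotated calls).
#'
#' @param calls data.frame from [callSNVs()].
#' @param clinicalTable data.frame from [readClinicalTable()].
#' @param targets optional named gene GRanges used to assign a gene to each
#'   call for the fallback match.
#' @return the calls with added columns gene, clinical_significance and
#'   in_report.
#' @export
annotateClinical <- function(calls, clinicalTable, targets = NULL) {
    calls$gene <- rep(NA_character_, nrow(calls))
    if (!is.null(targets) && nrow(calls)) {
        gr <- GenomicRanges::GRanges(calls$chrom,
                                     IRanges::IRanges(calls$pos, width = 1L))
        hit <- GenomicRanges::findOverlaps(gr, targets, select = "first")
        calls$gene <- GenomicRanges::mcols(targets)$name[hit]
    }
    calls$clinical_significance <- rep(NA_character_, nrow(calls))
    if (nrow(calls) && nrow(clinicalTable)) {
        key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
        hasKey <- !is.na(clinicalTable$pos)
        tKey <- paste(clinicalTable$chrom, clinicalTable$pos,
                      clinicalTable$ref, clinicalTable$alt)
        m <- match(key, tKey[hasKey])
        calls$clinical_significance <-
            clinicalTable$significance[hasKey][m]
        ## fallback: coordinate-free rows match by gene
        fb <- which(is.na(calls$clinical_significance) & !is.na(calls$gene))
        for (i in fb) {
            j <- which(!hasKey & clinicalTable$gene == calls$gene[i])
            if (length(j))
                calls$clinical_significance[i] <-
                    clinicalTable$significance[j[1L]]
        }
    }
    calls$in_report <- !is.na(calls$clinical_significance)
    calls
}

#' Raw allele counts at one position
#'
#' Manual-inspection facility: returns pileup counts at a single site
#' regardless of the calling thresholds, so low-fraction variants the
#' caller leaves out can still be reviewed.
#'
#' @param bam indexed BAM path.
#' @param reference FASTA path or DNAStringSet.
#' @param chrom,pos position to inspect (1-based).
#' @param minBaseQuality base-quality floor (matches [pileupSites()]).
#' @return list: chrom, pos, ref, counts (named A/C/G/T/del), depth,
#'   alt_count (top non-reference base).
#' @export
inspectSite <- function(bam, reference, chrom, pos, minBaseQuality = 10L) {
    region <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    p <- pileupSites(bam, reference, region,
                     minBaseQuality = minBaseQuality)
    if (nrow(p) == 0L) {
        dna <- if (is(reference, "DNAStringSet")) reference
               else Biostrings::readDNAStringSet(reference)
        names(dna) <- sub("\\s.*$", "", names(dna))
        ref <- substr(as.character(dna[[chrom]]), pos, pos)
        return(list(chrom = chrom, pos = pos, ref = ref,
                    counts = c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L),
                    depth = 0L, alt_count = 0L))
    }
    counts <- c(A = p$A, C = p$C, G = p$G, T = p$T, del = p$del)
    altCounts <- counts[setdiff(c("A", "C", "G", "T"), p$ref_base)]
    list(chrom = chrom, pos = pos, ref = p$ref_base, counts = counts,
         depth = as.integer(p$depth), alt_count = as.integer(max(altCounts)))
}

#' Write SNV calls as a minimal VCF
#'
#' VCFv4.2 with DP (depth), AC (alt reads) and AF (allele fraction) INFO
#' fields.
#'
#' @param calls data.frame from [callSNVs()] (optionally annotated).
#' @param path output file.
#' @param onlyReport when TRUE and the calls carry an \code{in_report}
#'   column, write only clinically filtered calls.
#' @return the path, invisibly.
#' @export
writeSnvVcf <- function(calls, path, onlyReport = FALSE) {
    if (onlyReport && "in_report" %in% names(calls))
        calls <- calls[calls$in_report, , drop = FALSE]
    hdr <- c("##fileformat=VCFv4.2",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
        "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count\">",
        "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (nrow(calls))
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AC=%d;AF=%s",
                calls$chrom, calls$pos, calls$ref, calls$alt, calls$depth,
                calls$alt_count, format(calls$vaf, digits = 6,
                                        scientific = FALSE, trim = TRUE))
    else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}
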