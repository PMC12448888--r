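## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
    if (!exists(key, envir = .fixtures))
        assign(key, force(expr), envir = .fixtures)
    get(key, envir = .fixtures)
}

## small toy-genome configuration used across module tests
smallConfig <- function(...) {
    args <- list(
        seed = 42L,
        chromLengths = c(chr1 = 60000L, chr7 = 60000L, chr9 = 60000L,
                         chr10 = 60000L, chr19 = 60000L),
        panelSize = 500L, nClasses = 4L,
        meanReadsPerBin = 8, cnvBinWidth = 5000L,
        readLengthMedian = 2500, readLengthSdlog = 0.3)
    over <- list(...)
    args[names(over)] <- over
    do.call(simulationConfig, args)
}

smallGenome <- function() cachedFixture("genome", makeToyGenome(smallConfig()))

## a plain class-1 simulation with no planted lesions
smallSim <- function() cachedFixture("sim", {
    simulateReads(smallConfig(), classId = 1L,
                  destBase = tempfile("sim"), genome = smallGenome())
})

smallCalls <- function() cachedFixture("calls", {
    suppressWarnings(
        extractCpGCalls(smallSim()$bam, cpgSites(smallGenome()$fasta)))
})

## --- tiny hand-built reference for ingest tests ---------------------------
## chrT: CpGs at known positions; everything else CpG-free.
tinyRef <- function() cachedFixture("tinyRef", {
    s <- rep("T", 120)
    cpgAt <- c(21L, 41L, 61L)          # C positions of three CpGs
    s[cpgAt] <- "C"; s[cpgAt + 1L] <- "G"
    dna <- Biostrings::DNAStringSet(paste(s, collapse = ""))
    names(dna) <- "chrT"
    list(dna = dna, cpgAt = cpgAt, sites = cpgSites(dna))
})

## one-record SAM -> indexed BAM on the tiny reference
tinyBam <- function(records) {
    writeModBam(records, c(chrT = 120L), tempfile("tiny"))
}

## MM/ML tag text for explicit per-position (pM, pH) on a forward read whose
## stored SEQ has cytosines only at the CpG sites it covers
fwdTags <- function(seq, cOffsets, pM, pH) {
    cAll <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C")
    idx <- match(cOffsets, cAll)
    stopifnot(!anyNA(idx))
    deltas <- c(idx[1] - 1L, diff(idx) - 1L)
    d <- paste(deltas, collapse = ",")
    sprintf("MM:Z:C+m?,%s;C+h?,%s;\tML:B:C,%s", d, d,
            paste(c(as.integer(round(pM * 255)),
                    as.integer(round(pH * 255))), collapse = ","))
}

## synthetic bins (GRanges) from per-chromosome log2 series, for
## segmentation tests that need no BAM
binsFromSeries <- function(series, binWidth = 1000L) {
    grl <- lapply(names(series), function(ch) {
        y <- series[[ch]]
        GenomicRanges::GRanges(ch,
            IRanges::IRanges(start = (seq_along(y) - 1L) * binWidth + 1L,
                             width = binWidth),
            count = NA_integer_, log2_ratio = y)
    })
    suppressWarnings(do.call(c, grl))
}

## region GRanges builder for event-call tests
armRegions <- function(chromLengths) {
    half <- floor(chromLengths / 2)
    num <- sub("^chr", "", names(chromLengths))
    c(GenomicRanges::GRanges(names(chromLengths),
          IRanges::IRanges(1L, chromLengths),
          region_id = names(chromLengths), type = "chromosome"),
      GenomicRanges::GRanges(names(chromLengths),
          IRanges::IRanges(1L, half),
          region_id = paste0(num, "p"), type = "arm"),
      GenomicRanges::GRanges(names(chromLengths),
          IRanges::IRanges(half + 1L, chromLengths),
          region_id = paste0(num, "q"), type = "arm"))
}

## footprint-row builder for fusion tests
fpRow <- function(read, label, chrom, start, end, q, strand = "+",
                  primary = TRUE) {
    data.frame(read_id = read, label = label, chrom = chrom,
               ref_start = start, ref_end = end, strand = strand,
               q_start = q, is_primary = primary)
}

## independent brute-force fusion oracle: enumerate each read's footprint in
## query order and count reads per adjacent locus pair (canonical order)
bruteForcePairSupport <- function(footprints) {
    support <- list()
    for (rid in unique(footprints$read_id)) {
        fp <- footprints[footprints$read_id == rid, , drop = FALSE]
        fp <- fp[order(fp$q_start), , drop = FALSE]
        labs <- fp$label
        keep <- c(TRUE, labs[-1] != labs[-length(labs)])
        labs <- labs[keep]
        if (length(labs) < 2L) next
        for (i in seq_len(length(labs) - 1L)) {
            pr <- paste(sort(c(labs[i], labs[i + 1L])), collapse = "::")
            support[[pr]] <- union(support[[pr]], rid)
        }
    }
    sort(vapply(support, length, integer(1)))
}

## --- SNV fixtures -----------------------------------------------------------
## 35 reads over the tiny reference; nAlt of them carry `alt` at `pos`
altDepthBam <- function(nAlt, nRef, pos = 50L, alt = "A",
                        from = 30L, to = 90L) {
    ref <- tinyRef()
    full <- as.character(ref$dna[["chrT"]])
    base <- substr(full, from, to)
    altSeq <- base
    substr(altSeq, pos - from + 1L, pos - from + 1L) <- alt
    n <- nAlt + nRef
    rec <- data.frame(qname = sprintf("r%03d", seq_len(n)), flag = 0L,
                      rname = "chrT", pos = from, mapq = 60L,
                      cigar = paste0(to - from + 1L, "M"),
                      seq = c(rep(altSeq, nAlt), rep(base, nRef)),
                      tags = "")
    tinyBam(rec)
}

pileRow <- function(depth, altCount, ref = "T", alt = "A", pos = 50L) {
    row <- data.frame(chrom = "chrT", pos = pos, ref_base = ref,
                      A = 0L, C = 0L, G = 0L, T = 0L, del = 0L,
                      depth = depth)
    row[[alt]] <- altCount
    row[[ref]] <- depth - altCount
    row
}

## --- full-pipeline lesion fixtures ------------------------------------------
lesionConfig <- function() {
    g <- smallGenome()
    tgt <- g$targets[GenomicRanges::mcols(g$targets)$name == "TP53"]
    snvPos <- BiocGenerics::start(tgt) + 500L
    chrom <- as.character(GenomicRanges::seqnames(tgt))
    refBase <- substr(as.character(g$fasta[[chrom]]), snvPos, snvPos)
    alt <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    list(cfg = smallConfig(
             copyStates = c("7p" = 3L, "7q" = 3L, "10p" = 1L),
             snvs = data.frame(chrom = chrom, pos = snvPos,
                               alt = alt, vaf = 0.55),
             fusions = list(list(partners = c("GENEA", "GENEB"),
                                 n_reads = 5L)),
             meanReadsPerBin = 30),
         snv = list(chrom = chrom, pos = snvPos, ref = refBase, alt = alt))
}

lesionSim <- function() cachedFixture("lesionSim", {
    lc <- lesionConfig()
    sim <- simulateReads(lc$cfg, classId = 2L, destBase = tempfile("les"),
                         genome = smallGenome())
    c(sim, lc["snv"])
})

lesionClinical <- function() cachedFixture("lesionClinical", {
    lc <- lesionConfig()
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c("chrom\tpos\tref\talt\tgene\tprotein_change\tsignificance",
                 sprintf("%s\t%d\t%s\t%s\tTP53\tp.T1X\tpathogenic",
                         lc$snv$chrom, lc$snv$pos, lc$snv$ref, lc$snv$alt),
                 "\t\t\t\tIDH1\t\tpathogenic"), tsv)
    readClinicalTable(tsv)
})

smallModels <- function() cachedFixture("models", {
    buildModels(smallGenome()$classRates, seed = 7L)
})

runLesion <- function(bam = lesionSim()$bam, params = list(),
                      batchIndex = -1L, targets = smallGenome()$targets) {
    g <- smallGenome()
    cfg <- smallConfig()
    ## untagged supplementary records always produce a skip warning
    suppressWarnings(
        runPipeline(bam, g$fasta, g$panel, g$mgmtPanel, targets, g$regions,
                    smallModels(), clinicalTable = lesionClinical(),
                    params = list(binWidth = cfg$cnvBinWidth),
                    batchIndex = batchIndex))
}
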