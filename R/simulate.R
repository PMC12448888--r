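## Synthetic test universe: toy genome, site panels, class methylation
## references and modification-tagged reads carrying planted copy-number
## states, SNVs, fusions and MGMT methylation.

#' Evaluate an expression under a fixed seed
#'
#' Runs \code{expr} with the RNG seeded to \code{seed} and restores the
#' caller's RNG state afterwards, so seeded draws never disturb the
#' surrounding random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-fixture generator. The defaults define
#' the package's reference study conditions: a five-chromosome toy genome
#' (chr1, chr7, chr9, chr10, chr19; 300 kb each) carrying a 2,000-site
#' classifier CpG panel, a 137-site MGMT-like promoter panel, named target
#' genes for SNV/fusion analysis, six reference classes with per-site
#' methylation rates of 0.1/0.9, diploid copy states, and log-normal read
#' lengths with a median of about 11.7 kb.
#'
#' @param seed integer master seed; identical seeds give byte-identical
#'   outputs.
#' @param chromLengths named integer vector of chromosome lengths (>= 10 kb).
#' @param cpgSpacing approximate spacing (bp) of planted background CpGs.
#' @param nClasses number of reference methylation classes.
#' @param panelSize classifier panel size (CpG sites).
#' @param mgmtPanelSize promoter panel size; fixed at 137 sites.
#' @param lowRate,highRate the two per-site methylation rates used for class
#'   reference profiles.
#' @param mgmtLevel uniform methylation rate over the promoter panel.
#' @param copyStates named integer vector of copy states per chromosome arm
#'   (names like \code{"7p"}); unlisted arms are diploid.
#' @param focalStates named integer vector of copy states for focal gene
#'   regions (names matching target gene names).
#' @param snvs data.frame(chrom, pos, alt, vaf) of planted SNVs.
#' @param fusions list of \code{list(partners=, n_reads=)} planted fusions;
#'   partners are target gene names in junction order.
#' @param meanReadsPerBin expected diploid read count per CNV bin.
#' @param cnvBinWidth CNV bin width in bp.
#' @param readLengthMedian,readLengthSdlog log-normal read length parameters.
#' @param hmcFraction fraction of the methylated signal written as 5hmC (so
#'   the hydroxymethyl merge is exercised non-trivially).
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
        chromLengths = c(chr1 = 300000L, chr7 = 300000L, chr9 = 300000L,
                         chr10 = 300000L, chr19 = 300000L),
        cpgSpacing = 120L, nClasses = 6L, panelSize = 2000L,
        mgmtPanelSize = 137L, lowRate = 0.1, highRate = 0.9,
        mgmtLevel = 0.6, copyStates = integer(), focalStates = integer(),
        snvs = NULL, fusions = list(), meanReadsPerBin = 30,
        cnvBinWidth = 10000L, readLengthMedian = 11700,
        readLengthSdlog = 0.45, hmcFraction = 0.1) {
    stopifnot(all(chromLengths >= 10000L), !is.null(names(chromLengths)),
              nClasses >= 1L, mgmtPanelSize == 137L,
              cnvBinWidth >= 1L, meanReadsPerBin > 0)
    ## feasibility: planted CpGs must accommodate the requested panel
    nBackground <- sum(floor((chromLengths - 200) / cpgSpacing))
    if (nBackground < panelSize)
        stop("CpG density infeasible for requested panel size")
    cfg <- list(seed = as.integer(seed), chromLengths = chromLengths,
                cpgSpacing = as.integer(cpgSpacing),
                nClasses = as.integer(nClasses),
                panelSize = as.integer(panelSize),
                mgmtPanelSize = as.integer(mgmtPanelSize),
                lowRate = lowRate, highRate = highRate,
                mgmtLevel = mgmtLevel,
                copyStates = copyStates, focalStates = focalStates,
                snvs = snvs, fusions = fusions,
                meanReadsPerBin = meanReadsPerBin,
                cnvBinWidth = as.integer(cnvBinWidth),
                readLengthMedian = readLengthMedian,
                readLengthSdlog = readLengthSdlog,
                hmcFraction = hmcFraction)
    class(cfg) <- c("SimulationConfig", "list")
    cfg
}

## Target gene layout on the toy genome: each gene is placed at a fixed
## fraction of its chromosome so layouts scale with chromLengths.
toyTargetLayout <- function(chromLengths) {
    spec <- list(
        GENEA  = list(chrom = "chr1",  at = c(0.20, 0.26)),
        GENEB  = list(chrom = "chr7",  at = c(0.35, 0.41)),
        GENEC  = list(chrom = "chr19", at = c(0.20, 0.26)),
        TP53   = list(chrom = "chr19", at = c(0.60, 0.64)),
        IDH1   = list(chrom = "chr1",  at = c(0.60, 0.64)),
        CDKN2A = list(chrom = "chr9",  at = c(0.15, 0.19)),
        MGMT   = list(chrom = "chr10", at = c(0.66, 0.69)))
    spec <- spec[vapply(spec, function(s) s$chrom %in% names(chromLengths),
                        logical(1))]
    gr <- GenomicRanges::GRanges(
        vapply(spec, `[[`, character(1), "chrom"),
        IRanges::IRanges(
            start = vapply(spec, function(s)
                as.integer(s$at[1] * chromLengths[s$chrom]), integer(1)),
            end = vapply(spec, function(s)
                as.integer(s$at[2] * chromLengths[s$chrom]), integer(1))))
    GenomicRanges::mcols(gr)$name <- names(spec)
    gr
}

#' Generate the toy reference genome and site panels
#'
#' Builds a deterministic toy genome in which every CpG dinucleotide is
#' planted at a known position (the background sequence is CpG-free), then
#' derives the classifier panel, the 137-site MGMT-like promoter panel,
#' target gene regions and chromosome-arm definitions. Optionally writes
#' FASTA (+ .fai) and BED files.
#'
#' @param config a [simulationConfig()].
#' @param dir optional directory; when given, \code{genome.fa},
#'   \code{panel.bed}, \code{mgmt_panel.bed}, \code{targets.bed} and
#'   \code{regions.bed} are written there.
#' @return list with \code{fasta} (DNAStringSet), \code{cpg} (GRanges of all
#'   CpG cytosines), \code{panel} (GRanges with \code{site_index}),
#'   \code{mgmtPanel} (GRanges, 137 sites), \code{targets} (named gene
#'   GRanges), \code{regions} (arm/chromosome/focal definitions with
#'   \code{region_id} and \code{type}), \code{classRates} (class x panel-site
#'   rate matrix) and, if written, the file \code{paths}.
#' @export
makeToyGenome <- function(config, dir = NULL) {
    withSeed(config$seed, {
        chroms <- names(config$chromLengths)
        targets <- toyTargetLayout(config$chromLengths)
        mgmtGene <- targets[GenomicRanges::mcols(targets)$name == "MGMT"]
        seqs <- character(length(chroms))
        cpgPos <- vector("list", length(chroms))
        names(cpgPos) <- chroms
        for (ci in seq_along(chroms)) {
            L <- config$chromLengths[[ci]]
            s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
            ## kill every background CpG so planted sites are the only ones
            isCG <- which(s[-L] == "C" & s[-1] == "G")
            if (length(isCG)) s[isCG + 1L] <- "A"
            ## plant background CpGs on a jittered grid
            grid <- seq(100L, L - 100L, by = config$cpgSpacing)
            pos <- grid + sample(-20:20, length(grid), replace = TRUE)
            ## MGMT promoter: exactly 137 CpGs evenly spaced within the gene
            if (length(mgmtGene) && chroms[ci] ==
                    as.character(GenomicRanges::seqnames(mgmtGene))) {
                mStart <- BiocGenerics::start(mgmtGene) + 50L
                spacing <- max(2L, (GenomicRanges::width(mgmtGene) - 100L) %/%
                                   config$mgmtPanelSize)
                mgmtSites <- mStart +
                    spacing * (seq_len(config$mgmtPanelSize) - 1L)
                if (max(mgmtSites) + 1L >= BiocGenerics::end(mgmtGene))
                    stop("MGMT gene region too small for the 137-site panel")
                pos <- pos[pos < BiocGenerics::start(mgmtGene) - 2L |
                           pos > BiocGenerics::end(mgmtGene) + 2L]
                pos <- sort(c(pos, mgmtSites))
            } else pos <- sort(pos)
            pos <- pos[c(TRUE, diff(pos) >= 2L)]
            s[pos] <- "C"; s[pos + 1L] <- "G"
            seqs[ci] <- paste(s, collapse = "")
            cpgPos[[ci]] <- pos
        }
        fasta <- Biostrings::DNAStringSet(seqs)
        names(fasta) <- chroms
        cpg <- cpgSites(fasta)
        ## MGMT panel = the planted promoter sites
        mgmtPanel <- GenomicRanges::GRanges()
        if (length(mgmtGene)) {
            ov <- IRanges::overlapsAny(cpg, mgmtGene)
            mgmtPanel <- cpg[ov]
            stopifnot(length(mgmtPanel) == config$mgmtPanelSize)
        }
        ## classifier panel: sample outside the promoter
        pool <- which(!IRanges::overlapsAny(cpg, mgmtGene))
        idx <- sort(sample(pool, config$panelSize))
        panel <- cpg[idx]
        GenomicRanges::mcols(panel)$site_index <- seq_len(config$panelSize)
        ## region definitions: whole chromosomes, arms (p/q halves), focal
        half <- floor(config$chromLengths / 2)
        num <- sub("^chr", "", chroms)
        regions <- c(
            GenomicRanges::GRanges(chroms,
                IRanges::IRanges(1L, config$chromLengths),
                region_id = chroms, type = "chromosome"),
            GenomicRanges::GRanges(chroms, IRanges::IRanges(1L, half),
                region_id = paste0(num, "p"), type = "arm"),
            GenomicRanges::GRanges(chroms,
                IRanges::IRanges(half + 1L, config$chromLengths),
                region_id = paste0(num, "q"), type = "arm"))
        focal <- targets[GenomicRanges::mcols(targets)$name == "CDKN2A"]
        if (length(focal)) {
            GenomicRanges::mcols(focal) <- NULL
            GenomicRanges::mcols(focal)$region_id <- "CDKN2A"
            GenomicRanges::mcols(focal)$type <- "focal"
            regions <- c(regions, focal)
        }
        classRates <- makeClassRates(config)
        out <- list(fasta = fasta, cpg = cpg, panel = panel,
                    mgmtPanel = mgmtPanel, targets = targets,
                    regions = regions, classRates = classRates)
        if (!is.null(dir)) {
            dir.create(dir, showWarnings = FALSE, recursive = TRUE)
            paths <- list(fasta = file.path(dir, "genome.fa"),
                          panel = file.path(dir, "panel.bed"),
                          mgmt = file.path(dir, "mgmt_panel.bed"),
                          targets = file.path(dir, "targets.bed"),
                          regions = file.path(dir, "regions.bed"))
            Biostrings::writeXStringSet(fasta, paths$fasta)
            Rsamtools::indexFa(paths$fasta)
            writeBed(panel, paths$panel,
                     extra = GenomicRanges::mcols(panel)$site_index)
            writeBed(mgmtPanel, paths$mgmt)
            writeBed(targets, paths$targets,
                     extra = GenomicRanges::mcols(targets)$name)
            writeBed(regions, paths$regions,
                     extra = paste(GenomicRanges::mcols(regions)$region_id,
                                   GenomicRanges::mcols(regions)$type,
                                   sep = ":"))
            out$paths <- paths
        }
        out
    })
}

## class x panel-site reference methylation rates: each class gets an
## independent coin per site choosing the high or low rate.
makeClassRates <- function(config) {
    m <- matrix(ifelse(
            matrix(stats::runif(config$nClasses * config$panelSize) < 0.5,
                   config$nClasses), config$highRate, config$lowRate),
        nrow = config$nClasses)
    rownames(m) <- paste0("class", seq_len(config$nClasses))
    colnames(m) <- paste0("s", seq_len(config$panelSize))
    m
}

writeBed <- function(gr, path, extra = NULL) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr))
    if (!is.null(extra)) df$name <- extra
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a BED-like site panel
#'
#' @param path BED file (0-based half-open); an optional 4th column is kept
#'   as \code{name} (or \code{site_index} when integer-valued).
#' @return GRanges (1-based).
#' @export
readBedPanel <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df[[1]],
        IRanges::IRanges(df[[2]] + 1L, df[[3]]))
    if (ncol(df) >= 4) {
        if (!anyNA(suppressWarnings(as.integer(df[[4]]))))
            GenomicRanges::mcols(gr)$site_index <- as.integer(df[[4]])
        else GenomicRanges::mcols(gr)$name <- df[[4]]
    }
    gr
}

## ---- read simulation ----------------------------------------------------

## MM/ML tag text for one read. sitesOffset: 1-based stored-SEQ positions of
## the CpG cytosine (forward) — for reverse reads pass the G offsets.
modTagText <- function(storedSeq, modPos, pM, pH, isReverse) {
    L <- nchar(storedSeq)
    asSeq <- if (isReverse) revcompChar(storedSeq) else storedSeq
    asPos <- if (isReverse) L - modPos + 1L else modPos
    o <- order(asPos)
    asPos <- asPos[o]; pM <- pM[o]; pH <- pH[o]
    cAll <- which(strsplit(asSeq, "", fixed = TRUE)[[1]] == "C")
    idx <- match(asPos, cAll)
    ## a planted SNV may have overwritten a CpG base; such sites are no
    ## longer cytosines and carry no modification call
    ok <- !is.na(idx)
    if (!any(ok)) return(NULL)
    idx <- idx[ok]; pM <- pM[ok]; pH <- pH[ok]
    deltas <- c(idx[1] - 1L, diff(idx) - 1L)
    dtxt <- paste(deltas, collapse = ",")
    mm <- sprintf("MM:Z:C+m?,%s;C+h?,%s;", dtxt, dtxt)
    ml <- sprintf("ML:B:C,%s",
                  paste(c(encodeML(pM), encodeML(pH)), collapse = ","))
    c(mm, ml)
}

#' Write SAM records and convert to a sorted, indexed BAM
#'
#' Low-level fixture writer: takes a data.frame of SAM fields (qname, flag,
#' rname, pos, mapq, cigar, seq, tags — tags being a single tab-joined
#' string, possibly empty) and produces \code{<destBase>.bam} plus index.
#'
#' @param records data.frame of SAM fields.
#' @param chromLengths named vector for the \code{@SQ} header lines.
#' @param destBase output path without the .bam extension.
#' @return path to the sorted BAM.
#' @export
writeModBam <- function(records, chromLengths, destBase) {
    sam <- tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", names(chromLengths),
                     as.integer(chromLengths)))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*%s",
                    records$qname, records$flag, records$rname, records$pos,
                    records$mapq, records$cigar, records$seq,
                    ifelse(nchar(records$tags) > 0,
                           paste0("\t", records$tags), ""))
    writeLines(c(hdr, body), sam)
    raw <- Rsamtools::asBam(sam, tempfile(), indexDestination = FALSE,
                            overwrite = TRUE)
    out <- Rsamtools::sortBam(raw, destBase)
    Rsamtools::indexBam(out)
    unlink(c(sam, raw))
    out
}

armStateOf <- function(regionId, copyStates) {
    if (regionId %in% names(copyStates)) copyStates[[regionId]] else 2L
}

#' Simulate modification-tagged reads for one methylation class
#'
#' Draws reads across the toy genome with per-arm Poisson counts scaled by
#' planted copy states, plants SNV alt bases at the configured VAFs, emits
#' chimeric (primary + supplementary) reads for planted fusions, and writes
#' per-CpG 5mC/5hmC probability pairs into MM/ML tags. Per read and CpG site
#' the methylated state is Bernoulli in the class's per-site rate (panel
#' sites), the MGMT level (promoter sites) or 0.5 (background); the written
#' probability pair is beta-concentrated around the drawn state with a
#' configurable 5hmC share.
#'
#' @param config a [simulationConfig()].
#' @param classId generating class (1-based row of the class rate matrix).
#' @param destBase output BAM path without extension.
#' @param genome optional result of [makeToyGenome()] (rebuilt from config
#'   when omitted).
#' @return list with \code{bam} (path), \code{truth} (list: class label,
#'   copy/focal states, SNVs, fusions, MGMT level) and \code{genome}.
#' @export
simulateReads <- function(config, classId = 1L, destBase = tempfile(),
                          genome = NULL) {
    if (is.null(genome)) genome <- makeToyGenome(config)
    stopifnot(classId >= 1L, classId <= config$nClasses)
    withSeed(config$seed * 1000L + classId, {
        chroms <- names(config$chromLengths)
        chromSeq <- as.character(genome$fasta)
        cpgByChrom <- split(BiocGenerics::start(genome$cpg),
                            as.character(GenomicRanges::seqnames(genome$cpg)))
        ## per-site methylation rates over all genome CpGs
        rateByChrom <- lapply(cpgByChrom, function(p) rep(0.5, length(p)))
        pchr <- as.character(GenomicRanges::seqnames(genome$panel))
        ppos <- BiocGenerics::start(genome$panel)
        prate <- genome$classRates[classId, ]
        for (ch in unique(pchr)) {
            sel <- pchr == ch
            rateByChrom[[ch]][match(ppos[sel], cpgByChrom[[ch]])] <-
                prate[sel]
        }
        if (length(genome$mgmtPanel)) {
            mch <- as.character(GenomicRanges::seqnames(genome$mgmtPanel))[1]
            mpos <- BiocGenerics::start(genome$mgmtPanel)
            rateByChrom[[mch]][match(mpos, cpgByChrom[[mch]])] <-
                config$mgmtLevel
        }
        snvs <- config$snvs
        focal <- genome$regions[
            GenomicRanges::mcols(genome$regions)$type == "focal"]
        recs <- list()
        readNo <- 0L
        arms <- genome$regions[
            GenomicRanges::mcols(genome$regions)$type == "arm"]
        for (ai in seq_along(arms)) {
            arm <- arms[ai]
            armId <- GenomicRanges::mcols(arm)$region_id
            state <- armStateOf(armId, config$copyStates)
            lambda <- GenomicRanges::width(arm) / config$cnvBinWidth *
                config$meanReadsPerBin * state / 2
            n <- stats::rpois(1, lambda)
            if (n == 0L) next
            ch <- as.character(GenomicRanges::seqnames(arm))
            chromLen <- config$chromLengths[[ch]]
            starts <- sample(BiocGenerics::start(arm):BiocGenerics::end(arm),
                             n, replace = TRUE)
            lens <- pmax(500L, as.integer(stats::rlnorm(n,
                        log(config$readLengthMedian),
                        config$readLengthSdlog)))
            ends <- pmin(starts + lens - 1L, chromLen)
            mids <- (starts + ends) %/% 2L
            ## focal copy state: thin reads whose midpoint hits the region
            keep <- rep(TRUE, n)
            for (fi in seq_along(focal)) {
                fId <- GenomicRanges::mcols(focal)$region_id[fi]
                fState <- if (fId %in% names(config$focalStates))
                    config$focalStates[[fId]] else state
                if (fState >= state) next
                if (as.character(GenomicRanges::seqnames(focal[fi])) != ch)
                    next
                inF <- mids >= BiocGenerics::start(focal[fi]) &
                       mids <= BiocGenerics::end(focal[fi])
                keep[inF] <- keep[inF] &
                    stats::runif(sum(inF)) < fState / state
            }
            starts <- starts[keep]; ends <- ends[keep]
            for (r in seq_along(starts)) {
                readNo <- readNo + 1L
                recs[[length(recs) + 1L]] <- simulateOneRead(
                    sprintf("read%06d", readNo), ch, starts[r], ends[r],
                    chromSeq, cpgByChrom, rateByChrom, snvs, config)
            }
        }
        ## planted fusions: chimeric reads with split alignments
        truthFusions <- list()
        for (fu in config$fusions) {
            geneGr <- genome$targets[match(fu$partners,
                GenomicRanges::mcols(genome$targets)$name)]
            segLen <- 800L
            ## junction breakpoints sit at each gene's midpoint
            mid <- (BiocGenerics::start(geneGr) +
                    BiocGenerics::end(geneGr)) %/% 2L
            segStart <- mid - segLen %/% 2L
            truthFusions[[length(truthFusions) + 1L]] <- list(
                partners = fu$partners,
                chroms = as.character(GenomicRanges::seqnames(geneGr)),
                junctions = lapply(seq_len(length(geneGr) - 1L), function(j)
                    c(posA = segStart[j] + segLen - 1L,
                      posB = segStart[j + 1L])))
            for (r in seq_len(fu$n_reads)) {
                readNo <- readNo + 1L
                jit <- sample(-20:20, length(geneGr), replace = TRUE)
                s0 <- segStart + jit
                qname <- sprintf("fusionread%03d_%06d",
                                 length(truthFusions), readNo)
                totalLen <- segLen * length(geneGr)
                for (j in seq_along(geneGr)) {
                    ch <- as.character(GenomicRanges::seqnames(geneGr))[j]
                    seqj <- substr(chromSeq[[ch]], s0[j],
                                   s0[j] + segLen - 1L)
                    pre <- segLen * (j - 1L)
                    post <- totalLen - pre - segLen
                    cig <- paste0(if (pre) paste0(pre, "S") else "",
                                  segLen, "M",
                                  if (post) paste0(post, "S") else "")
                    fullSeq <- paste0(
                        strrep("A", pre), seqj, strrep("A", post))
                    tags <- ""
                    if (j == 1L) {
                        mt <- readModTags(ch, s0[1L], s0[1L] + segLen - 1L,
                                          cpgByChrom, rateByChrom, config,
                                          isReverse = FALSE, qOffset = 0L,
                                          storedSeq = fullSeq)
                        tags <- mt
                    }
                    recs[[length(recs) + 1L]] <- data.frame(
                        qname = qname, flag = if (j == 1L) 0L else 2048L,
                        rname = ch, pos = s0[j], mapq = 60L, cigar = cig,
                        seq = fullSeq, tags = tags)
                }
            }
        }
        records <- do.call(rbind, recs)
        bam <- writeModBam(records, config$chromLengths, destBase)
        truth <- list(class_id = classId,
                      class_label = rownames(genome$classRates)[classId],
                      mgmt_level = config$mgmtLevel,
                      mgmt_status = if (config$mgmtLevel * 100 > 25)
                          "methylated" else "unmethylated",
                      copy_states = as.list(config$copyStates),
                      focal_states = as.list(config$focalStates),
                      snvs = snvs, fusions = truthFusions)
        list(bam = bam, truth = truth, genome = genome)
    })
}

#' Simulate alignment spans under planted copy states
#'
#' Lightweight companion to [simulateReads()] for copy-number validation at
#' scale: draws per-arm Poisson read counts scaled by the planted copy
#' states and returns the alignment spans as a GRanges (no sequences or
#' modification tags), directly consumable by [binCounts()].
#'
#' @param config a [simulationConfig()] (uses copyStates, meanReadsPerBin,
#'   cnvBinWidth, read length parameters).
#' @param genome optional [makeToyGenome()] result.
#' @param seed seed for this draw (defaults to the config seed).
#' @return GRanges of read spans with seqlengths set.
#' @export
simulateReadSpans <- function(config, genome = NULL, seed = config$seed) {
    if (is.null(genome)) genome <- makeToyGenome(config)
    withSeed(seed, {
        arms <- genome$regions[
            GenomicRanges::mcols(genome$regions)$type == "arm"]
        out <- list()
        for (ai in seq_along(arms)) {
            arm <- arms[ai]
            state <- armStateOf(GenomicRanges::mcols(arm)$region_id,
                                config$copyStates)
            lambda <- GenomicRanges::width(arm) / config$cnvBinWidth *
                config$meanReadsPerBin * state / 2
            n <- stats::rpois(1, lambda)
            if (n == 0L) next
            ch <- as.character(GenomicRanges::seqnames(arm))
            starts <- sample(BiocGenerics::start(arm):BiocGenerics::end(arm),
                             n, replace = TRUE)
            lens <- pmax(500L, as.integer(stats::rlnorm(n,
                        log(config$readLengthMedian),
                        config$readLengthSdlog)))
            out[[length(out) + 1L]] <- data.frame(chrom = ch, start = starts,
                end = pmin(starts + lens - 1L, config$chromLengths[[ch]]))
        }
        df <- do.call(rbind, out)
        GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                               seqlengths = config$chromLengths)
    })
}

## MM/ML tags for the CpGs a (sub)read covers; returns tab-joined tag text
## ("" when no CpG covered).
readModTags <- function(ch, start, end, cpgByChrom, rateByChrom, config,
                        isReverse, qOffset, storedSeq) {
    p <- cpgByChrom[[ch]]
    sel <- which(p >= start & p + 1L <= end)
    if (!length(sel)) return("")
    rates <- rateByChrom[[ch]][sel]
    meth <- stats::runif(length(sel)) < rates
    pTot <- ifelse(meth, stats::rbeta(length(sel), 20, 2),
                         stats::rbeta(length(sel), 2, 20))
    pH <- config$hmcFraction * pTot
    pM <- pTot - pH
    ## stored-SEQ offsets: the C for forward reads, the paired G for reverse
    off <- if (isReverse) (p[sel] + 1L) - start + 1L else p[sel] - start + 1L
    off <- off + qOffset
    tg <- modTagText(storedSeq, off, pM, pH, isReverse)
    if (is.null(tg)) return("")
    paste(tg, collapse = "\t")
}

simulateOneRead <- function(qname, ch, start, end, chromSeq, cpgByChrom,
                            rateByChrom, snvs, config) {
    seq <- substr(chromSeq[[ch]], start, end)
    ## plant SNV alt alleles at the configured VAF
    if (!is.null(snvs) && nrow(snvs)) {
        hit <- which(snvs$chrom == ch & snvs$pos >= start & snvs$pos <= end)
        for (i in hit) {
            if (stats::runif(1) < snvs$vaf[i])
                substr(seq, snvs$pos[i] - start + 1L,
                       snvs$pos[i] - start + 1L) <- snvs$alt[i]
        }
    }
    isRev <- stats::runif(1) < 0.5
    tags <- readModTags(ch, start, end, cpgByChrom, rateByChrom, config,
                        isReverse = isRev, qOffset = 0L, storedSeq = seq)
    data.frame(qname = qname, flag = if (isRev) 16L else 0L, rname = ch,
               pos = start, mapq = 60L,
               cigar = paste0(nchar(seq), "M"), seq = seq, tags = tags)
}
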