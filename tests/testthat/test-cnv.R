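## Binned coverage, log2 normalisation, changepoint segmentation and
## region-level event calls.

test_that("midpoint binning matches a brute-force count and conserves reads", {
    set.seed(21)
    n <- 400L
    spans <- GenomicRanges::GRanges(
        sample(c("chrA", "chrB"), n, replace = TRUE),
        IRanges::IRanges(start = sample.int(19000L, n), width = 900L))
    GenomeInfoDb::seqlevels(spans) <- c("chrA", "chrB")
    GenomeInfoDb::seqlengths(spans) <- c(chrA = 20000L, chrB = 20000L)
    bins <- binCounts(spans, binWidth = 1000L)
    expect_equal(sum(bins$count), n)       # every read lands in one bin
    ## brute force: midpoint falls inside the bin interval
    mid <- floor((GenomicRanges::start(spans) +
                  GenomicRanges::end(spans)) / 2)
    for (i in sample(length(bins), 25L)) {
        b <- bins[i]
        exp <- sum(GenomeInfoDb::seqnames(spans) ==
                       as.character(GenomeInfoDb::seqnames(b)) &
                   mid >= GenomicRanges::start(b) &
                   mid <= GenomicRanges::end(b))
        expect_equal(bins$count[i], exp)
    }
})

test_that("log2 normalisation uses the pseudocount and genome-wide median", {
    bins <- GenomicRanges::GRanges("chrA",
        IRanges::IRanges(start = seq(1L, 4001L, by = 1000L), width = 1000L),
        count = c(10L, 10L, 20L, 10L, 0L))
    norm <- normalizeBins(bins)
    med <- 10
    expect_equal(norm$log2_ratio,
                 log2((bins$count + 0.5) / (med + 0.5)), tolerance = 1e-12)
    expect_equal(norm$log2_ratio[1], 0)    # median bin maps to 0
    bins$count <- rep(0L, 5)
    expect_error(normalizeBins(bins), "no coverage")
})

test_that("exact segmentation matches exhaustive enumeration on short series", {
    ## brute-force optimal partitioning: try all 2^(n-1) changepoint sets
    bruteCost <- function(y, penalty) {
        n <- length(y)
        best <- Inf; bestK <- Inf
        for (mask in 0:(2^(n - 1) - 1)) {
            cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
            bounds <- c(0L, cuts, n)
            cost <- penalty * (length(bounds) - 1L)
            for (j in seq_len(length(bounds) - 1L)) {
                seg <- y[(bounds[j] + 1L):bounds[j + 1L]]
                cost <- cost + sum((seg - mean(seg))^2)
            }
            k <- length(bounds) - 1L
            if (cost < best - 1e-12 ||
                (abs(cost - best) <= 1e-12 && k < bestK)) {
                best <- cost; bestK <- k
            }
        }
        c(best, bestK)
    }
    set.seed(33)
    for (rep in 1:6) {
        n <- sample(6:12, 1)
        y <- rnorm(n, mean = rep(sample(c(-1, 0, 1), 3, replace = TRUE),
                                 length.out = n), sd = 0.3)
        for (pen in c(0.5, 2, 8)) {
            cps <- segmentSeries(y, penalty = pen)   # segment end indices
            from <- c(1L, utils::head(cps, -1L) + 1L)
            dpCost <- pen * length(cps) +
                sum(vapply(seq_along(cps), function(j) {
                    s <- y[from[j]:cps[j]]
                    sum((s - mean(s))^2)
                }, numeric(1)))
            bf <- bruteCost(y, pen)
            expect_equal(dpCost, bf[1], tolerance = 1e-9)
            expect_equal(length(cps), as.integer(bf[2]))
        }
    }
})

test_that("flat, stepped and whole-chromosome series segment as expected", {
    set.seed(44)
    flat <- rnorm(60, 0, 0.05)
    gain <- c(rnorm(20, 0, 0.05), rnorm(20, 0.58, 0.05), rnorm(20, 0, 0.05))
    loss <- rnorm(50, -1.0, 0.05)
    bins <- binsFromSeries(list(chrF = flat, chrG = gain, chrL = loss))
    segs <- segmentBins(bins)
    segF <- segs[GenomeInfoDb::seqnames(segs) == "chrF"]
    segG <- segs[GenomeInfoDb::seqnames(segs) == "chrG"]
    segL <- segs[GenomeInfoDb::seqnames(segs) == "chrL"]
    expect_equal(length(segF), 1L)
    expect_equal(segF$state, "neutral")
    expect_equal(length(segG), 3L)
    expect_equal(segG$state, c("neutral", "gain", "neutral"))
    ## step boundaries recovered within one bin
    expect_lte(abs(GenomicRanges::start(segG)[2] - 20001L), 1000L)
    expect_lte(abs(GenomicRanges::end(segG)[2] - 40000L), 1000L)
    expect_equal(length(segL), 1L)
    expect_equal(segL$state, "loss")
})

test_that("state thresholds are loss <= -0.35 and gain >= +0.30", {
    bins <- binsFromSeries(list(
        c1 = rep(-0.35, 10), c2 = rep(-0.34, 10),
        c3 = rep(0.30, 10),  c4 = rep(0.29, 10)))
    segs <- segmentBins(bins)
    st <- stats::setNames(segs$state,
                          as.character(GenomeInfoDb::seqnames(segs)))
    expect_equal(unname(st[c("c1", "c2", "c3", "c4")]),
                 c("loss", "neutral", "gain", "neutral"))
})

test_that("region events need 70% of bins and are called per arm", {
    lens <- c(chr1 = 40000L, chr7 = 40000L)
    regions <- armRegions(lens)
    ## chr7: uniform gain; chr1: only the p arm (first half) lost
    series <- list(
        chr1 = c(rep(-1, 20), rep(0, 20)),
        chr7 = rep(0.6, 40))
    bins <- binsFromSeries(list(chr1 = series$chr1 + rnorm(40, 0, 0.03),
                                chr7 = series$chr7 + rnorm(40, 0, 0.03)))
    GenomeInfoDb::seqlengths(bins) <- lens
    segs <- segmentBins(bins)
    ev <- callCNVEvents(bins, segs, regions)
    byId <- stats::setNames(ev$event, ev$region_id)
    expect_equal(unname(byId["chr7"]), "gain")
    expect_equal(unname(byId["7p"]), "gain")
    expect_equal(unname(byId["7q"]), "gain")
    expect_equal(unname(byId["1p"]), "loss")
    ## unaffected arm and the half-lost chromosome (70% rule) stay uncalled
    expect_false("1q" %in% ev$region_id)
    expect_false("chr1" %in% ev$region_id)
    expect_true(all(ev$fraction >= 0.70 & ev$fraction <= 1))
})

test_that("focal deletions use the deeper -0.8 cutoff and bin overlap", {
    lens <- c(chr9 = 40000L)
    y <- rep(0, 40); y[10:12] <- -1.2
    bins <- binsFromSeries(list(chr9 = y + rnorm(40, 0, 0.02)))
    GenomeInfoDb::seqlengths(bins) <- lens
    focal <- GenomicRanges::GRanges("chr9",
        IRanges::IRanges(9001L, 12000L), region_id = "FOCAL9",
        type = "focal")
    shallow <- binsFromSeries(list(chr9 = replace(rep(0, 40), 10:12, -0.5)))
    GenomeInfoDb::seqlengths(shallow) <- lens
    evDeep <- callCNVEvents(bins, segmentBins(bins),
                            c(armRegions(lens), focal))
    evShallow <- callCNVEvents(shallow, segmentBins(shallow),
                               c(armRegions(lens), focal))
    expect_equal(evDeep$event[evDeep$region_id == "FOCAL9"], "loss")
    expect_false("FOCAL9" %in% evShallow$region_id)
})

test_that("1p/19q codeletion requires loss of both arms", {
    lens <- c(chr1 = 40000L, chr19 = 40000L)
    both <- binsFromSeries(list(chr1 = c(rep(-1, 20), rep(0, 20)),
                                chr19 = c(rep(0, 20), rep(-1, 20))))
    oneOnly <- binsFromSeries(list(chr1 = c(rep(-1, 20), rep(0, 20)),
                                   chr19 = rep(0, 40)))
    GenomeInfoDb::seqlengths(both) <- lens
    GenomeInfoDb::seqlengths(oneOnly) <- lens
    evB <- callCNVEvents(both, segmentBins(both), armRegions(lens))
    evO <- callCNVEvents(oneOnly, segmentBins(oneOnly), armRegions(lens))
    expect_equal(evB$event[evB$region_id == "1p/19q"], "codeletion")
    expect_false("1p/19q" %in% evO$region_id)
})

test_that("simulated copy states are recovered from read spans", {
    cfg <- smallConfig(copyStates = c("1p" = 1L, "1q" = 1L, "7p" = 3L,
                                      "7q" = 3L, "10p" = 1L),
                       meanReadsPerBin = 40)
    g <- smallGenome()
    spans <- simulateReadSpans(cfg, g, seed = 77L)
    bins <- normalizeBins(binCounts(spans, binWidth = cfg$cnvBinWidth))
    ev <- callCNVEvents(bins, segmentBins(bins), g$regions)
    byId <- stats::setNames(ev$event, ev$region_id)
    expect_equal(unname(byId["chr1"]), "loss")
    expect_equal(unname(byId["chr7"]), "gain")
    expect_equal(unname(byId["10p"]), "loss")
    expect_false("chr9" %in% ev$region_id)
    expect_false("10q" %in% ev$region_id)
})

test_that("seg and bins files round-trip through text", {
    bins <- binsFromSeries(list(chrA = c(0, 0, 1, 1)))
    bins$count <- c(10L, 11L, 20L, 21L)
    segs <- segmentBins(bins)
    f1 <- tempfile(fileext = ".seg"); f2 <- tempfile(fileext = ".tsv")
    writeSegFile(segs, f1); writeBinsTsv(bins, f2)
    s <- read.table(f1, header = TRUE, sep = "\t")
    b <- read.table(f2, header = TRUE, sep = "\t")
    expect_equal(nrow(s), length(segs))
    expect_equal(s$seg.mean, segs$mean_log2, tolerance = 1e-4)
    expect_equal(b$count, bins$count)
})
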