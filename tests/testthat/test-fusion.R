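## Split-read footprint extraction and fusion candidate detection.

## footprints for `n` chimeric reads joining two loci at fixed breakpoints
chimericFootprints <- function(n, labelA = "GENEA", labelB = "GENEB",
                               chromA = "chr1", chromB = "chr7",
                               bpA = 12800L, bpB = 21500L, prefix = "fr",
                               jitter = 0L) {
    rows <- lapply(seq_len(n), function(i) {
        jA <- if (jitter) sample(-jitter:jitter, 1L) else 0L
        jB <- if (jitter) sample(-jitter:jitter, 1L) else 0L
        rbind(fpRow(paste0(prefix, i), labelA, chromA,
                    bpA + jA - 799L, bpA + jA, q = 1L),
              fpRow(paste0(prefix, i), labelB, chromB,
                    bpB + jB, bpB + jB + 799L, q = 801L,
                    primary = FALSE))
    })
    do.call(rbind, rows)
}

test_that("detection counts supporting reads exactly as a brute-force oracle", {
    set.seed(55)
    fps <- rbind(chimericFootprints(5L, prefix = "ab"),
                 chimericFootprints(3L, "GENEB", "GENEC", "chr7", "chr19",
                                    31000L, 9000L, prefix = "bc"),
                 chimericFootprints(2L, "GENEA", "GENEC", "chr1", "chr19",
                                    15000L, 9400L, prefix = "ac"),
                 fpRow("lone1", "GENEA", "chr1", 12000L, 12900L, q = 1L))
    cand <- detectFusions(fps, minSupport = 1L)
    got <- sort(stats::setNames(cand$n_support, cand$partners))
    expect_equal(got, bruteForcePairSupport(fps))
    ## with the default threshold only pairs with >= 3 reads survive
    def <- detectFusions(fps)
    expect_setequal(def$partners, c("GENEA::GENEB", "GENEB::GENEC"))
    expect_equal(def$n_support[def$partners == "GENEA::GENEB"], 5L)
})

test_that("two supporting reads are below the reporting threshold, three pass", {
    two <- detectFusions(chimericFootprints(2L))
    three <- detectFusions(chimericFootprints(3L))
    expect_equal(nrow(two), 0L)
    expect_equal(nrow(three), 1L)
    expect_equal(three$partners, "GENEA::GENEB")
    expect_equal(three$n_support, 3L)
    ## breakpoints are the cluster medians of the junction coordinates
    expect_equal(three$posA, 12800)
    expect_equal(three$posB, 21500)
    expect_equal(sort(strsplit(three$read_ids, ",")[[1]]),
                 c("fr1", "fr2", "fr3"))
})

test_that("distant junctions between the same partners form separate clusters", {
    near <- chimericFootprints(3L, prefix = "n")
    far <- chimericFootprints(3L, bpA = 12800L + 5000L, bpB = 21500L + 5000L,
                              prefix = "f")
    cand <- detectFusions(rbind(near, far))
    expect_equal(nrow(cand), 2L)
    expect_true(all(cand$partners == "GENEA::GENEB"))
    expect_setequal(round(cand$posA), c(12800, 17800))
    ## jitter within the 500 bp window keeps one cluster
    set.seed(9)
    jit <- chimericFootprints(6L, jitter = 100L, prefix = "j")
    candJ <- detectFusions(jit)
    expect_equal(nrow(candJ), 1L)
    expect_equal(candJ$n_support, 6L)
    expect_lte(abs(candJ$posA - 12800), 100)
})

test_that("pair orientation is canonical regardless of read direction", {
    ## same junction observed forward (A then B, plus strand) and from a
    ## reverse-complement read (B then A, minus strand)
    ab <- chimericFootprints(2L, prefix = "x")
    ba <- do.call(rbind, lapply(1:2, function(i)
        rbind(fpRow(paste0("y", i), "GENEB", "chr7", 21500L, 22299L,
                    q = 1L, strand = "-"),
              fpRow(paste0("y", i), "GENEA", "chr1", 12001L, 12800L,
                    q = 801L, strand = "-", primary = FALSE))))
    cand <- detectFusions(rbind(ab, ba))
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$partners, "GENEA::GENEB")
    expect_equal(cand$n_support, 4L)
    expect_equal(cand$posA, 12800)
    expect_equal(cand$posB, 21500)
})

test_that("nearby same-gene blocks never self-fuse; distant ones can", {
    ## two adjacent primary blocks within the same gene (e.g. a spliced or
    ## clipped alignment) must not produce GENEA::GENEA
    near <- do.call(rbind, lapply(1:3, function(i)
        rbind(fpRow(paste0("s", i), "GENEA", "chr1", 12001L, 12400L, q = 1L),
              fpRow(paste0("s", i), "GENEA", "chr1", 12500L, 12900L,
                    q = 401L))))
    expect_equal(nrow(detectFusions(near)), 0L)
    ## the same label two megabases away is a genuine rearrangement
    far <- do.call(rbind, lapply(1:3, function(i)
        rbind(fpRow(paste0("d", i), "elsewhere:chr1:1",
                    "chr1", 12001L, 12800L, q = 1L),
              fpRow(paste0("d", i), "elsewhere:chr1:1",
                    "chr1", 2012500L, 2013300L, q = 801L))))
    cand <- detectFusions(far)
    expect_equal(nrow(cand), 1L)
})

test_that("three-locus chimeras are reported as a multi-partner chain", {
    rows <- do.call(rbind, lapply(1:3, function(i)
        rbind(fpRow(paste0("c", i), "GENEA", "chr1", 12001L, 12800L, q = 1L),
              fpRow(paste0("c", i), "GENEB", "chr7", 21500L, 22299L,
                    q = 801L, primary = FALSE),
              fpRow(paste0("c", i), "GENEC", "chr19", 9000L, 9799L,
                    q = 1601L, primary = FALSE))))
    cand <- detectFusions(rows)
    chain <- cand[cand$n_partners == 3L, ]
    expect_equal(nrow(chain), 1L)
    expect_equal(chain$partners, "GENEA::GENEB::GENEC")
    expect_equal(chain$n_support, 3L)
    ## reads entering the chain from the other end collapse onto the same key
    revRows <- do.call(rbind, lapply(1:3, function(i)
        rbind(fpRow(paste0("r", i), "GENEC", "chr19", 9000L, 9799L, q = 1L),
              fpRow(paste0("r", i), "GENEB", "chr7", 21500L, 22299L,
                    q = 801L, primary = FALSE),
              fpRow(paste0("r", i), "GENEA", "chr1", 12001L, 12800L,
                    q = 1601L, primary = FALSE))))
    both <- detectFusions(rbind(rows, revRows))
    chain2 <- both[both$n_partners == 3L, ]
    expect_equal(chain2$partners, "GENEA::GENEB::GENEC")
    expect_equal(chain2$n_support, 6L)
})

test_that("planted simulator fusions are recovered near the true breakpoints", {
    g <- smallGenome()
    cfg <- smallConfig(fusions = list(list(partners = c("GENEA", "GENEB"),
                                           n_reads = 6L)))
    sim <- simulateReads(cfg, classId = 1L, destBase = tempfile("fus"),
                         genome = g)
    fps <- readFootprints(sim$bam, g$targets)
    cand <- detectFusions(fps)
    hit <- cand[cand$partners == "GENEA::GENEB", ]
    expect_equal(nrow(hit), 1L)
    expect_gte(hit$n_support, 3L)
    truth <- sim$truth$fusions[[1]]$junctions[[1]]
    expect_lte(abs(hit$posA - truth[["posA"]]), 50)
    expect_lte(abs(hit$posB - truth[["posB"]]), 50)
    ## no other fusion is reported from a fusion-free simulation
    none <- detectFusions(readFootprints(smallSim()$bam, g$targets))
    expect_equal(nrow(none), 0L)
})

test_that("fusion tables round-trip through TSV", {
    cand <- detectFusions(chimericFootprints(4L))
    f <- tempfile(fileext = ".tsv")
    writeFusionTsv(cand, f)
    back <- read.table(f, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    expect_equal(back$partners, cand$partners)
    expect_equal(back$n_support, cand$n_support)
})
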