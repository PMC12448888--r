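## Site summarisation, binarisation, the three classifier strategies and
## the multi-classifier consensus rule.

mkResult <- function(strategy, label, score, confident = NA) {
    r <- new("ClassifierResult", strategy = strategy, label = label,
             score = score, confident = FALSE, nSitesUsed = 100L,
             batchIndex = -1L)
    r@confident <- if (is.na(confident)) isConfident(r) else confident
    r
}

test_that("site summaries count methylated reads per site", {
    calls <- data.frame(read_id = c("a", "b", "c"), chrom = "chr1",
                        pos = 100L, strand = "+",
                        p_meth = c(0.9, 0.2, 0.8))
    s <- summarizeSites(calls, perReadThreshold = 0.5)
    expect_equal(s$n_reads, 3L)
    expect_equal(s$n_meth, 2L)
    expect_equal(s$fraction, 2 / 3)
    one <- summarizeSites(data.frame(read_id = "a", chrom = "chr1",
                                     pos = 1L, strand = "+", p_meth = 0.9))
    expect_equal(one$fraction, 1.0)
    expect_equal(nrow(summarizeSites(data.frame())), 0L)
})

test_that("binarisation applies the tie-methylated rule and panel filter", {
    panel <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(100L, 200L, 300L), width = 1L),
        site_index = 1:3)
    s <- data.frame(chrom = "chr1", pos = c(100L, 200L, 999L),
                    n_reads = 2L, n_meth = c(2L, 1L, 2L),
                    fraction = c(1.0, 0.5, 1.0))
    p <- binarize(s, panel)
    expect_s4_class(p, "BinaryProfile")
    expect_equal(nObserved(p), 2L)         # site 999 is off-panel
    expect_equal(unname(p@values[c("1", "2")]), c(1L, 1L))  # 0.5 ties to 1
    s$fraction[2] <- 0.49
    expect_equal(unname(binarize(s, panel)@values[["2"]]), 0L)
})

test_that("model construction validates classes and is deterministic", {
    rates <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                    dimnames = list(c("A", "B"), NULL))
    expect_error(trainReferenceModel(rates[1, , drop = FALSE], "centroid"),
                 "degenerate")
    expect_warning(trainReferenceModel(rbind(A = c(0.9, 0.1),
                                             B = c(0.9, 0.1)), "centroid"),
                   "identical")
    set.seed(7)
    bigRates <- matrix(sample(c(0.1, 0.9), 4 * 300, replace = TRUE), 4,
                       dimnames = list(paste0("c", 1:4), NULL))
    prof <- simulateBinaryProfile(bigRates, 2L, 120L, seed = 5L)
    for (s in c("forest", "perceptron", "centroid")) {
        m <- trainReferenceModel(bigRates, s, seed = 11L)
        r1 <- classifyProfile(prof, m)
        r2 <- classifyProfile(prof, m)
        expect_identical(score(r1), score(r2))
        expect_identical(classLabel(r1), classLabel(r2))
    }
})

test_that("all strategies recover the generating class on clean profiles", {
    set.seed(3)
    rates <- matrix(sample(c(0.1, 0.9), 4 * 400, replace = TRUE), 4,
                    dimnames = list(paste0("c", 1:4), NULL))
    for (s in c("forest", "perceptron", "centroid")) {
        m <- trainReferenceModel(rates, s, seed = 2L)
        ## profile drawn exactly from the class-3 centroid
        prof <- new("BinaryProfile", panelId = "panel",
                    values = stats::setNames(as.integer(rates[3, ] > 0.5),
                                             seq_len(400)),
                    nObserved = 400L)
        r <- classifyProfile(prof, m)
        expect_equal(classLabel(r), "c3")
        expect_true(r@confident)
    }
})

test_that("empty and very sparse profiles are handled", {
    set.seed(4)
    rates <- matrix(sample(c(0.1, 0.9), 4 * 400, replace = TRUE), 4,
                    dimnames = list(paste0("c", 1:4), NULL))
    empty <- new("BinaryProfile", panelId = "panel",
                 values = integer(), nObserved = 0L)
    sparse <- simulateBinaryProfile(rates, 1L, 10L, seed = 9L)
    for (s in c("forest", "perceptron", "centroid")) {
        m <- trainReferenceModel(rates, s, seed = 2L)
        r0 <- classifyProfile(empty, m)
        expect_true(is.na(classLabel(r0)))
        expect_equal(score(r0), 0)
        expect_false(r0@confident)
        r10 <- classifyProfile(sparse, m)   # sparse input still classifies
        expect_true(classLabel(r10) %in% rownames(rates))
        expect_equal(r10@nSitesUsed, 10L)
    }
})

test_that("confidence thresholds sit at 70, 0.8 and 0.2", {
    expect_true(isConfident(mkResult("forest", "A", 70.0)))
    expect_false(isConfident(mkResult("forest", "A", 69.99)))
    expect_true(isConfident(mkResult("centroid", "A", 0.8)))
    expect_false(isConfident(mkResult("centroid", "A", 0.79)))
    expect_true(isConfident(mkResult("perceptron", "A", 0.2)))
    expect_false(isConfident(mkResult("perceptron", "A", 0.19)))
    bad <- mkResult("forest", "A", 50); bad@strategy <- "mystery"
    expect_error(isConfident(bad), "unknown strategy")
})

test_that("consensus requires two confident concordant classifiers (exhaustive)", {
    strategies <- c("forest", "perceptron", "centroid")
    labels <- c("A", "B", "C")
    combos <- expand.grid(l1 = labels, l2 = labels, l3 = labels,
                          c1 = c(TRUE, FALSE), c2 = c(TRUE, FALSE),
                          c3 = c(TRUE, FALSE), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
        co <- combos[i, ]
        labs <- c(co$l1, co$l2, co$l3)
        conf <- c(co$c1, co$c2, co$c3)
        res <- lapply(1:3, function(j)
            mkResult(strategies[j], labs[j], 999, confident = conf[j]))
        d <- consensusCall(res)
        ## independent oracle: any label carried by >= 2 confident results
        tab <- table(labs[conf])
        expClassified <- length(tab) > 0 && max(tab) >= 2
        expect_equal(consensusStatus(d) == "classified", expClassified)
        if (expClassified) {
            expect_equal(classLabel(d), names(tab)[which.max(tab)])
            expect_gte(length(supportingStrategies(d)), 2L)
        }
    }
    expect_error(consensusCall(list(mkResult("forest", "A", 99),
                                    mkResult("forest", "A", 99))),
                 "one result per strategy")
})

test_that("recovery improves with the number of observed sites", {
    set.seed(12)
    rates <- matrix(sample(c(0.1, 0.9), 6 * 800, replace = TRUE), 6,
                    dimnames = list(paste0("c", 1:6), NULL))
    m <- trainReferenceModel(rates, "centroid", seed = 3L)
    recovery <- vapply(c(10L, 50L, 200L, 500L), function(ns) {
        hits <- vapply(1:30, function(r) {
            cls <- (r %% 6L) + 1L
            p <- simulateBinaryProfile(rates, cls, ns, seed = 1000L + r)
            classLabel(classifyProfile(p, m)) == rownames(rates)[cls]
        }, logical(1))
        mean(hits)
    }, numeric(1))
    expect_gte(recovery[2], recovery[1] - 0.05)
    expect_gte(recovery[4], recovery[1])
    expect_gte(recovery[4], 0.95)
})
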