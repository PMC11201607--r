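test_that("MethylCounts validates counts and positions", {
    sd1 <- data.frame(group = "a", row.names = "s1")
    mc <- MethylCounts(c(100L, 150L), matrix(c(3, 5), 2, 1),
                       matrix(c(10, 9), 2, 1), sd1)
    expect_equal(unname(rawFractions(mc)[1, 1]), 0.3)
    expect_error(
        MethylCounts(c(100L, 150L), matrix(c(11, 5), 2, 1),
                     matrix(c(10, 9), 2, 1), sd1),
        "exceed depth")
    expect_error(
        MethylCounts(c(100L, 100L), matrix(c(3, 5), 2, 1),
                     matrix(c(10, 9), 2, 1), sd1),
        "strictly increasing")
})

test_that("NA and zero-depth entries become the missing convention", {
    mc <- MethylCounts(c(10L, 20L, 30L),
                       matrix(c(NA, 2, 1), 3, 1),
                       matrix(c(5, 0, 4), 3, 1),
                       data.frame(group = "a", row.names = "s1"))
    expect_equal(unname(methReads(mc)[, 1]), c(0, 0, 1))
    expect_equal(unname(totalReads(mc)[, 1]), c(0, 0, 4))
    expect_equal(unname(missingMask(mc)[, 1]), c(TRUE, TRUE, FALSE))
    expect_true(all(is.na(rawFractions(mc)[1:2, 1])))
})

test_that("count table round trip is bit exact including the mask", {
    sim <- simulateExample1(T = 60, nGroup1 = 2, nGroup2 = 3, seed = 4,
                            depth = depthModel("nbinom", mu = 8,
                                               size = 1))
    mc <- maskAtRandom(sim$counts, 0.3, seed = 2)$counts
    tf <- tempfile(); mf <- tempfile()
    writeCountTable(mc, tf, mf)
    back <- readCountTable(tf, mf)
    expect_identical(unname(methReads(back)), unname(methReads(mc)))
    expect_identical(unname(totalReads(back)), unname(totalReads(mc)))
    expect_identical(unname(missingMask(back)), unname(missingMask(mc)))
    expect_identical(positionsOf(back), positionsOf(mc))
    expect_identical(as.character(sampleGroups(back)),
                     as.character(sampleGroups(mc)))
})

test_that("count table reader rejects malformed input", {
    tf <- tempfile(); mf <- tempfile()
    writeLines(c("chrom\tpos\ts1.y\ts1.n", "chr1\t10\t11\t10"), tf)
    writeLines(c("sample_id\tgroup", "s1\ta"), mf)
    expect_error(readCountTable(tf, mf), "y > n at position 10")
    writeLines(c("chrom\tpos\ts1.y\ts1.n",
                 "chr1\t10\t1\t5", "chr1\t10\t2\t5"), tf)
    expect_error(readCountTable(tf, mf), "duplicate position")
    writeLines(c("chrom\tpos\ts1.y\ts1.n", "chr1\t10\t1\t5"), tf)
    writeLines(c("sample_id\tgroup", "s2\ta"), mf)
    expect_error(readCountTable(tf, mf), "sample mismatch")
})

test_that("bedGraph-like per-sample files merge by position", {
    f1 <- tempfile(); f2 <- tempfile()
    writeLines(c("chr1\t9\t10\t3\t10", "chr1\t19\t20\t1\t5"), f1)
    writeLines(c("chr1\t9\t10\t2\t8", "chr1\t29\t30\t4\t4"), f2)
    sd2 <- data.frame(group = c("a", "b"), row.names = c("s1", "s2"))
    mc <- readBedGraphs(c(s1 = f1, s2 = f2), sd2)
    expect_equal(positionsOf(mc), c(10L, 20L, 30L))
    expect_equal(unname(methReads(mc)), rbind(c(3, 2), c(1, 0), c(0, 4)))
    expect_equal(unname(missingMask(mc)),
                 rbind(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, FALSE)))
})

test_that("DMC BED output follows the 0-based half-open convention", {
    mc <- tinyCounts(TT = 3, M = 2, groups = c("a", "b"))
    cd <- array(0.6, dim = c(3, 2, 8))
    cd[, 1, ] <- 0   # baseline curve 0; contrast draws all +0.6
    res <- callDMCs(manualFit(cd, mc), alpha = 0.05)
    tf <- tempfile()
    writeDmcBed(res, tf)
    lines <- readLines(tf)
    expect_match(lines[1], "^#chrom")
    fields <- strsplit(lines[2], "\t")[[1]]
    expect_equal(as.integer(fields[3]) - as.integer(fields[2]), 1L)
    expect_equal(as.integer(fields[2]), positionsOf(mc)[1] - 1L)
    expect_equal(fields[8], "1")
    expect_equal(fields[9], "hyper")
    # empty result -> header-only file
    res0 <- res
    res0@pos <- res@pos[0]
    res0@estimate <- res@estimate[0, , drop = FALSE]
    res0@lower <- res@lower[0, , drop = FALSE]
    res0@upper <- res@upper[0, , drop = FALSE]
    res0@dmc <- res@dmc[0, , drop = FALSE]
    res0@direction <- res@direction[0, , drop = FALSE]
    writeDmcBed(res0, tf)
    expect_length(readLines(tf), 1L)
})

test_that("partitioning covers 1..T with the degenerate-tail merge", {
    p1 <- partitionRegions(1200L, size = 500L)
    expect_equal(IRanges::start(p1@ranges), c(1L, 501L, 1001L))
    expect_equal(IRanges::end(p1@ranges), c(500L, 1000L, 1200L))
    p2 <- partitionRegions(400L, size = 500L)
    expect_length(p2@ranges, 1L)
    # remainder of 1 position is below the resolution -> merged
    p3 <- partitionRegions(1001L, size = 500L, resolution = 30L)
    expect_length(p3@ranges, 2L)
    expect_equal(IRanges::end(p3@ranges)[2L], 1001L)
    expect_error(partitionRegions(100L, size = 40L, resolution = 30L),
                 "twice the resolution")
})

test_that("partition ranges reassemble to 1..T for random T and size", {
    set.seed(7)
    for (rep in 1:25) {
        TT <- sample(80:4000, 1)
        size <- sample(seq(60L, 900L, by = 20L), 1)
        part <- partitionRegions(TT, size = size, resolution = 30L)
        idx <- unlist(lapply(seq_along(part@ranges),
                             function(k) regionIndices(part, k)))
        expect_identical(idx, seq_len(TT))
        expect_true(all(IRanges::width(part@ranges) >= 30L |
                        length(part@ranges) == 1L))
    }
})
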