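test_that("spline basis has the right shape and full rank", {
    set.seed(1)
    pos <- sort(sample.int(1e5, 500))
    b <- splineBasis(pos, p = 30)
    X <- basisMatrix(b)
    expect_equal(dim(X), c(500L, 30L))
    expect_true(all(is.finite(X)))
    expect_equal(qr(X)$rank, 30L)
    expect_error(splineBasis(pos[1:20], p = 30), "smaller resolution")
})

test_that("basis is evaluated at coordinates, not ranks", {
    even <- seq(1, 397, by = 4)
    b1 <- splineBasis(even, p = 6)
    b2 <- splineBasis(seq_along(even), p = 6)
    # uniform spacing: coordinate basis reduces to the index basis
    expect_equal(basisMatrix(b1), basisMatrix(b2), tolerance = 1e-12)
    # same ordering, uneven gaps: different basis
    set.seed(2)
    uneven <- cumsum(sample(c(1, 2, 40), 100, replace = TRUE))
    b3 <- splineBasis(uneven, p = 6)
    b4 <- splineBasis(seq_along(uneven), p = 6)
    expect_gt(max(abs(basisMatrix(b3) - basisMatrix(b4))), 0)
})

test_that("design layout counts columns and honors the baseline constraint", {
    mc <- tinyCounts(TT = 60, M = 21,
                     groups = rep(c("g1", "g2"), c(8, 13)))
    basis <- splineBasis(positionsOf(mc), p = 30)
    lay <- designLayout(basis, mc, depthCovariate = TRUE)
    # gamma0 + (G-1) contrasts + M individual blocks, p columns each,
    # plus q covariate columns: (G + M) p + q with delta_1 dropped
    expect_equal(lay@npar, (2L + 21L) * 30L + 1L)
    expect_false(any(grepl("delta.g1", names(lay@blocks))))
    types <- vapply(lay@blocks, `[[`, "", "type")
    expect_equal(sum(types == "delta"), 1L)
    expect_equal(sum(types == "upsilon"), 21L)
    # single group: no delta blocks at all
    mc1 <- tinyCounts(TT = 60, M = 3, groups = rep("only", 3))
    lay1 <- designLayout(splineBasis(positionsOf(mc1), p = 10), mc1)
    expect_false(any(vapply(lay1@blocks, `[[`, "", "type") == "delta"))
    expect_error(designLayout(basis, mc, covariates = "nope"),
                 "unknown covariate")
})

test_that("depth covariate is log(n+1), zero at missing entries", {
    mc <- MethylCounts(c(5L, 9L, 14L),
                       matrix(c(1, 0, 2), 3, 1),
                       matrix(c(4, 0, 6), 3, 1),
                       data.frame(group = "a", row.names = "s1"))
    lay <- designLayout(splineBasis(positionsOf(mc), p = 2), mc,
                        depthCovariate = TRUE)
    d <- methylFR:::etaDesign(lay, mc, 1L)
    expect_equal(d[, 1], log(c(4, 0, 6) + 1))
    expect_equal(d[2, 1], 0)
})

test_that("linear predictor equals the blockwise sum computed directly", {
    mc <- tinyCounts(TT = 30, M = 5, groups = c("a", "a", "b", "b", "b"),
                     seed = 3)
    SummarizedExperiment::colData(mc)$age <- c(31, 55, 42, 60, 24)
    basis <- splineBasis(positionsOf(mc), p = 5)
    lay <- designLayout(basis, mc, depthCovariate = TRUE,
                        covariates = "age")
    set.seed(4)
    for (rep in 1:5) {
        theta <- rnorm(lay@npar, 0, 0.4)
        lp <- linearPredictor(theta, lay, mc)
        X <- basisMatrix(basis)
        grp <- as.integer(sampleGroups(mc))
        for (i in seq_len(5)) {
            expected <- X %*% theta[lay@blocks[["gamma0"]]$cols]
            if (grp[i] == 2L)
                expected <- expected + X %*% theta[lay@blocks[["delta.b"]]$cols]
            expected <- expected +
                X %*% theta[lay@blocks[[paste0("upsilon.s", i)]]$cols] +
                methylFR:::etaDesign(lay, mc, i) %*%
                    theta[lay@blocks[["eta"]]$cols]
            expect_equal(lp[, i], as.vector(expected), tolerance = 1e-12)
        }
    }
})

test_that("relabeling the baseline group leaves fitted levels invariant", {
    mc <- tinyCounts(TT = 40, M = 6, depth = 15, seed = 5)
    # exchangeable prior scales so the objective is symmetric in groups
    pr <- priorSpec(tau = 1, tauBaseline = 1)
    fitFor <- function(baseline) {
        cd <- as.data.frame(SummarizedExperiment::colData(mc))
        cd$group <- relevel(factor(cd$group), baseline)
        mc2 <- MethylCounts(positionsOf(mc), methReads(mc),
                            totalReads(mc), cd)
        lay <- designLayout(splineBasis(positionsOf(mc2), p = 4), mc2,
                            depthCovariate = FALSE)
        th <- initializeState(mc2, lay, pr, sweeps = 2000L)
        fittedBeta(th, lay, mc2)
    }
    # invariant up to the coordinate-descent convergence tolerance
    expect_equal(fitFor("a"), fitFor("b"), tolerance = 1e-3)
})
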