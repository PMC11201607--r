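test_that("chain arithmetic and reproducibility hold", {
    cfg <- chainConfig(nIter = 15000, burnin = 5000, thin = 10, seed = 1)
    expect_equal(keptDraws(cfg), 1000L)
    expect_error(chainConfig(nIter = 100, burnin = 200), "exceed")
    mc <- tinyCounts(TT = 30, M = 4, depth = 15, seed = 2)
    cfg2 <- chainConfig(nIter = 300, burnin = 100, thin = 2, seed = 9)
    d1 <- runChain(mc, config = cfg2, p = 4)
    d2 <- runChain(mc, config = cfg2, p = 4)
    expect_identical(drawMatrix(d1), drawMatrix(d2))
    expect_equal(nrow(drawMatrix(d1)), keptDraws(cfg2))
    expect_true(all(dim(groupCurves(d1)) == c(30, 2, 100)))
})

test_that("an overwhelming prior pins a block at zero", {
    mc <- tinyCounts(TT = 25, M = 4, depth = 25, seed = 3)
    lay <- designLayout(splineBasis(positionsOf(mc), 3), mc,
                        depthCovariate = FALSE)
    pr <- priorSpec(tau = 1e-7, tauBaseline = 5)
    d <- runChain(mc, lay, pr,
                  chainConfig(nIter = 200, burnin = 100, thin = 1,
                              seed = 4))
    deltaCols <- lay@blocks[["delta.b"]]$cols
    expect_lt(max(abs(drawMatrix(d)[, deltaCols])), 1e-5)
})

test_that("a zero-information block's conditional is its prior", {
    mc <- MethylCounts(c(3L, 8L, 15L, 22L), matrix(0, 4, 2),
                       matrix(0, 4, 2),
                       data.frame(group = c("a", "b"),
                                  row.names = c("s1", "s2")))
    lay <- designLayout(splineBasis(positionsOf(mc), 2), mc,
                        depthCovariate = FALSE)
    pr <- priorSpec(tau = 0.3)
    set.seed(1)
    theta <- rnorm(lay@npar, 0, 0.2)
    cond <- gaussianApproxConditional("delta.b", theta, mc, lay, pr)
    expect_equal(cond$mean, rep(0, 2), tolerance = 1e-9)
    expect_equal(cond$precision, diag(1 / 0.3^2, 2), tolerance = 1e-9)
})

test_that("near-quadratic conditionals make the mode start-independent", {
    # huge depth: the block conditional is essentially Gaussian, so the
    # converged mode must not depend on the starting point
    mc <- tinyCounts(TT = 20, M = 2, depth = 5000, groups = c("a", "a"),
                     seed = 5)
    lay <- designLayout(splineBasis(positionsOf(mc), 3), mc,
                        depthCovariate = FALSE)
    pr <- priorSpec(tau = 2, tauBaseline = 2)
    set.seed(6)
    t1 <- rnorm(lay@npar, 0, 0.1)
    t2 <- t1; t2[lay@blocks[["gamma0"]]$cols] <- rnorm(3, 0, 1)
    c1 <- gaussianApproxConditional("gamma0", t1, mc, lay, pr)
    c2 <- gaussianApproxConditional("gamma0", t2, mc, lay, pr)
    expect_equal(c1$mean, c2$mean, tolerance = 1e-6)
})

test_that("gibbsSweep redraws only the named block", {
    mc <- tinyCounts(TT = 20, M = 4, depth = 10, seed = 7)
    lay <- designLayout(splineBasis(positionsOf(mc), 3), mc)
    pr <- priorSpec(tau = 0.4)
    set.seed(8)
    theta <- rnorm(lay@npar, 0, 0.2)
    out <- gibbsSweep(theta, "upsilon.s2", mc, lay, pr)
    changed <- which(out != theta)
    expect_true(all(changed %in% lay@blocks[["upsilon.s2"]]$cols))
    expect_gt(length(changed), 0)
})

test_that("partitioned fit is reproducible and worker-count invariant", {
    sim <- simulateExample1(T = 160, nGroup1 = 3, nGroup2 = 3, seed = 9)
    cfg <- chainConfig(nIter = 400, burnin = 150, thin = 5, seed = 17)
    f1 <- runPartitioned(sim$counts, p = 8, config = cfg,
                         partitionSize = 80, workers = 1L)
    f2 <- runPartitioned(sim$counts, p = 8, config = cfg,
                         partitionSize = 80, workers = 2L)
    expect_identical(drawMatrix(f1@results[[1L]]),
                     drawMatrix(f2@results[[1L]]))
    expect_identical(posteriorMeans(f1), posteriorMeans(f2))
    # a single partition reproduces runChain under the derived seed
    f3 <- runPartitioned(sim$counts, p = 8, config = cfg,
                         partitionSize = 200)
    cfg1 <- cfg; cfg1@seed <- methylFR:::partitionSeed(17, 1L)
    d <- runChain(sim$counts, prior = f3@prior, config = cfg1, p = 8)
    expect_identical(drawMatrix(f3@results[[1L]]), drawMatrix(d))
})

test_that("posterior mean levels smooth within the raw group range", {
    sim <- simulateExample2(T = 120, nPerGroup = 4, nDmrs = 1,
                            lenRange = c(15, 25), seed = 10,
                            depth = depthModel("uniform", lo = 40,
                                               hi = 60))
    cfg <- chainConfig(nIter = 800, burnin = 300, thin = 5, seed = 2)
    fit <- runPartitioned(sim$counts, p = 10, config = cfg)
    pm <- posteriorMeans(fit)
    expect_true(all(pm > 0 & pm < 1))
    f <- rawFractions(sim$counts)
    grp <- sampleGroups(sim$counts)
    # at high depth the groupwise posterior means should rarely leave
    # the envelope of raw group fractions by more than a little
    for (g in levels(grp)) {
        gm <- rowMeans(pm[, grp == g, drop = FALSE])
        lo <- apply(f[, grp == g, drop = FALSE], 1, min)
        hi <- apply(f[, grp == g, drop = FALSE], 1, max)
        expect_gt(mean(gm >= lo - 0.08 & gm <= hi + 0.08), 0.85)
    }
})

test_that("masked sites are imputed near the neighbouring fit", {
    sim <- simulateExample1(T = 250, nGroup1 = 4, nGroup2 = 4,
                            noiseSd = 0.1, seed = 11)
    masked <- maskAtRandom(sim$counts, 0.2, seed = 3)
    cfg <- chainConfig(nIter = 800, burnin = 300, thin = 5, seed = 5)
    fit <- runPartitioned(masked$counts, p = 15, config = cfg)
    pm <- posteriorMeans(fit)
    cells <- masked$maskedCells
    truthCurve <- ifelse(as.integer(sampleGroups(sim$counts))[cells[, 2]] == 1L,
                         sim$truth@group1[cells[, 1]],
                         sim$truth@group2[cells[, 1]])
    imputed <- pm[cells]
    expect_true(all(imputed > 0 & imputed < 1))
    expect_lt(sqrt(mean((imputed - truthCurve)^2)), 0.2)
})

test_that("the inverse-gamma prior variant runs and adapts block scales", {
    sim <- simulateExample2(T = 140, nPerGroup = 3, nDmrs = 1,
                            effectRange = c(0.4, 0.5), seed = 12)
    pr <- priorSpec("inverse_gamma", tau = 0.1, a = 2.5, b = 0.1)
    cfg <- chainConfig(nIter = 500, burnin = 200, thin = 3, seed = 6)
    d <- runChain(sim$counts, prior = pr, config = cfg, p = 8)
    expect_equal(nrow(drawMatrix(d)), keptDraws(cfg))
    expect_true(all(is.finite(drawMatrix(d))))
})
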