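test_that("all generators respect count and truth invariants", {
    gens <- list(
        function(s) simulateExample1(T = 120, nGroup1 = 3, nGroup2 = 4,
                                     seed = s),
        function(s) simulateExample2(T = 150, nPerGroup = 3, nDmrs = 3,
                                     seed = s),
        function(s) simulateExample3(T = 150, nPerGroup = 3, nDmrs = 1,
                                     sizeRange = c(20, 40), seed = s),
        function(s) simulateExample4(T = 150, nBumps = 2,
                                     groupSizes = c(3, 4),
                                     lenRange = c(10, 25), seed = s))
    for (gen in gens) {
        sim <- gen(5)
        y <- methReads(sim$counts); n <- totalReads(sim$counts)
        expect_true(all(y <= n))
        expect_true(all(y >= 0))
        expect_true(validObject(sim$truth))
        # curves differ only inside DMRs
        diff <- abs(sim$truth@group1 - sim$truth@group2) > 1e-12
        expect_true(all(diff == sim$truth@dmc | !diff))
        expect_false(any(diff & !sim$truth@dmc))
        # fixed seed reproduces everything
        sim2 <- gen(5)
        expect_identical(methReads(sim$counts), methReads(sim2$counts))
        expect_identical(sim$truth@dmrs, sim2$truth@dmrs)
    }
})

test_that("noise-free, effect-free data reduce to the baseline curve", {
    sim <- simulateExample1(T = 80, nGroup1 = 2, nGroup2 = 2,
                            noiseSd = 0,
                            dmrSpec = data.frame(start = integer(),
                                                 end = integer(),
                                                 effect = numeric()),
                            seed = 3)
    expect_identical(sim$truth@group1, sim$truth@group2)
    f <- rawFractions(sim$counts)
    n <- totalReads(sim$counts)
    # y = floor(beta * n): raw levels within 1/n of the curve
    obs <- !is.na(f)
    err <- abs(f - sim$truth@group1)[obs]
    expect_true(all(err <= 1 / n[obs] + 1e-12))
})

test_that("the HMM generator with identity transitions is constant", {
    sim <- simulateExample3(T = 100, nPerGroup = 2, nDmrs = 0,
                            selfTrans = 1, seed = 4)
    expect_equal(length(unique(sim$truth@group1)), 1L)
    # default sticky chain has 8 distinct levels
    sim8 <- simulateExample3(T = 600, nPerGroup = 2, nDmrs = 0, seed = 4)
    states <- (2 * (1:8) - 1) / 16
    expect_true(all(sim8$truth@group1 %in% states))
})

test_that("the AR(1) noise generator has the configured autocorrelation", {
    set.seed(9)
    x <- methylFR:::arNoise(40000, phi = 0.21, sigma = 0.2)
    expect_equal(cor(x[-1], x[-length(x)]), 0.21, tolerance = 0.03)
    expect_equal(sd(x), 0.2 / sqrt(1 - 0.21^2), tolerance = 0.01)
})

test_that("masking flags the requested fraction and zeroes the likelihood", {
    sim <- simulateExample2(T = 200, nPerGroup = 3, nDmrs = 2, seed = 6)
    m0 <- maskAtRandom(sim$counts, 0)
    expect_identical(methReads(m0$counts), methReads(sim$counts))
    mk <- maskAtRandom(sim$counts, 0.63, seed = 1)
    frac <- mean(missingMask(mk$counts)) - mean(missingMask(sim$counts))
    expect_equal(frac, 0.63 * mean(!missingMask(sim$counts)),
                 tolerance = 0.01)
    expect_error(maskAtRandom(sim$counts, 1), "fraction")
    # the masked object's likelihood equals a dbinom sum over the
    # remaining observed cells only
    lay <- designLayout(splineBasis(positionsOf(mk$counts), 5),
                        mk$counts, depthCovariate = FALSE)
    set.seed(2)
    theta <- rnorm(lay@npar, 0, 0.3)
    lp <- linearPredictor(theta, lay, mk$counts)
    y <- methReads(mk$counts); n <- totalReads(mk$counts)
    obs <- n > 0
    oracle <- sum(dbinom(y[obs], n[obs], plogis(lp[obs]), log = TRUE)) -
        sum(lchoose(n[obs], y[obs]))
    expect_equal(logLikelihood(theta, mk$counts, lay), oracle,
                 tolerance = 1e-10)
})

test_that("depth models draw from the advertised distributions", {
    set.seed(11)
    u <- drawDepths(depthModel("uniform", lo = 15, hi = 45), 2000, 2)
    expect_true(all(u >= 15 & u <= 45 & u == round(u)))
    p <- drawDepths(depthModel("poisson", lambda = 30), 4000, 1)
    expect_equal(mean(p), 30, tolerance = 0.5)
    nb <- drawDepths(depthModel("nbinom", mu = 30, size = 5), 4000, 1)
    expect_equal(mean(nb), 30, tolerance = 1.5)
    expect_gt(var(nb), 30)   # overdispersed
    e <- drawDepths(depthModel("empirical", table = c(3, 7, 11)), 500, 1)
    expect_true(all(e %in% c(3, 7, 11)))
    expect_error(depthModel("empirical"), "depth table")
})
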