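test_that("log-likelihood matches its closed form at zero parameters", {
    # two sites: one observed (y=1, n=2), one missing
    mc2 <- MethylCounts(c(5L, 9L), matrix(c(1, 0), 2, 1),
                        matrix(c(2, 0), 2, 1),
                        data.frame(group = "a", row.names = "s1"))
    lay2 <- designLayout(splineBasis(c(5, 9), 2), mc2,
                         depthCovariate = FALSE)
    theta <- rep(0, lay2@npar)
    # observed site contributes 1*0 - 2 log 2; missing site contributes 0
    expect_equal(logLikelihood(theta, mc2, lay2), -2 * log(2))
    set.seed(1)
    theta <- rnorm(lay2@npar)
    mc3 <- MethylCounts(c(5L, 9L), matrix(0, 2, 1), matrix(0, 2, 1),
                        data.frame(group = "a", row.names = "s1"))
    expect_equal(logLikelihood(theta, mc3, lay2), 0)
})

test_that("log-likelihood equals the binomial log-pmf sum minus its constant", {
    set.seed(11)
    for (rep in 1:20) {
        TT <- sample(8:25, 1); M <- sample(2:4, 1)
        mc <- tinyCounts(TT = TT, M = M, depth = sample(5:40, 1),
                         groups = rep(c("a", "b"), length.out = M),
                         seed = rep + 100)
        lay <- designLayout(splineBasis(positionsOf(mc), p = 3), mc,
                            depthCovariate = sample(c(TRUE, FALSE), 1))
        theta <- rnorm(lay@npar, 0, 0.5)
        lp <- linearPredictor(theta, lay, mc)
        y <- methReads(mc); n <- totalReads(mc)
        oracle <- sum(dbinom(y, n, plogis(lp), log = TRUE)) -
            sum(lchoose(n, y))
        expect_equal(logLikelihood(theta, mc, lay), oracle,
                     tolerance = 1e-10)
    }
})

test_that("empirical-Bayes tau is the mean across-sample sd of raw levels", {
    # hand-computed small case
    y <- rbind(c(2, 4, 6), c(1, 1, 1))
    n <- matrix(10, 2, 3)
    mc <- MethylCounts(c(10L, 20L), y, n,
                       data.frame(group = c("a", "a", "b"),
                                  row.names = paste0("s", 1:3)))
    expect_equal(estimateTau(mc)@tau,
                 mean(c(sd(c(0.2, 0.4, 0.6)), sd(c(0.1, 0.1, 0.1)))))
    # zero variance floors at the constant
    mcc <- MethylCounts(c(10L, 20L), matrix(5, 2, 3), matrix(10, 2, 3),
                        data.frame(group = c("a", "a", "b"),
                                   row.names = paste0("s", 1:3)))
    expect_equal(estimateTau(mcc)@tau, 0.01)
    # all missing errors
    mcm <- MethylCounts(c(10L, 20L), matrix(0, 2, 3), matrix(0, 2, 3),
                        data.frame(group = c("a", "a", "b"),
                                   row.names = paste0("s", 1:3)))
    expect_error(estimateTau(mcm), "missing")
})

test_that("the smooth-baseline generator with 0.18 noise yields tau near 0.18", {
    sim <- simulateExample1(T = 800, seed = 21)
    tau <- estimateTau(sim$counts)@tau
    # site noise 0.18 plus binomial sampling at depth ~30
    expect_gt(tau, 0.15)
    expect_lt(tau, 0.27)
})

test_that("quasi-IRLS initializer matches a dense penalized-IRLS oracle", {
    mc <- tinyCounts(TT = 10, M = 1, depth = 12, groups = "a", seed = 8)
    basis <- splineBasis(positionsOf(mc), p = 2)
    lay <- designLayout(basis, mc, depthCovariate = FALSE)
    pr <- priorSpec(tau = 0.7, tauBaseline = 2)
    th <- initializeState(mc, lay, pr, sweeps = 500L)
    # oracle: full Newton on the stacked design [X | X] with the
    # blockwise ridge penalty
    X <- basisMatrix(basis)
    D <- cbind(X, X)
    P <- diag(c(rep(1 / 2^2, 2), rep(1 / 0.7^2, 2)))
    y <- methReads(mc)[, 1]; n <- totalReads(mc)[, 1]
    b <- rep(0, 4)
    for (it in 1:200) {
        eta <- as.vector(D %*% b)
        mu <- plogis(eta)
        g <- crossprod(D, y - n * mu) - P %*% b
        H <- crossprod(D * (n * mu * (1 - mu)), D) + P
        step <- solve(H, g)
        b <- b + as.vector(step)
        if (max(abs(step)) < 1e-12) break
    }
    expect_equal(th, b, tolerance = 1e-6)
})

test_that("initializer is finite under separation and zero under no data", {
    mc <- tinyCounts(TT = 12, M = 2, depth = 9, groups = c("a", "b"))
    full <- MethylCounts(positionsOf(mc), totalReads(mc), totalReads(mc),
                         as.data.frame(SummarizedExperiment::colData(mc)))
    lay <- designLayout(splineBasis(positionsOf(full), 3), full)
    th <- initializeState(full, lay, priorSpec(tau = 0.5), sweeps = 100L)
    expect_true(all(is.finite(th)))
    empty <- MethylCounts(positionsOf(mc),
                          matrix(0, 12, 2), matrix(0, 12, 2),
                          as.data.frame(SummarizedExperiment::colData(mc)))
    lay0 <- designLayout(splineBasis(positionsOf(empty), 3), empty)
    th0 <- initializeState(empty, lay0, priorSpec(tau = 0.5),
                           sweeps = 20L)
    expect_equal(th0, rep(0, lay0@npar))
})

test_that("raising y at one site raises the fitted level there", {
    mc <- tinyCounts(TT = 15, M = 2, depth = 20, groups = c("a", "a"),
                     seed = 12)
    lay <- designLayout(splineBasis(positionsOf(mc), 4), mc,
                        depthCovariate = FALSE)
    pr <- priorSpec(tau = 0.5)
    y2 <- methReads(mc); y2[8, 1] <- y2[8, 1] + 6
    mc2 <- MethylCounts(positionsOf(mc), y2, totalReads(mc),
                        as.data.frame(SummarizedExperiment::colData(mc)))
    b1 <- fittedBeta(initializeState(mc, lay, pr, 200L), lay, mc)
    b2 <- fittedBeta(initializeState(mc2, lay, pr, 200L), lay, mc2)
    expect_gt(b2[8, 1], b1[8, 1])
})

test_that("likelihood depends on parameters only through the predictor", {
    mc <- tinyCounts(TT = 20, M = 2, depth = 10, groups = c("a", "a"),
                     seed = 13)
    lay <- designLayout(splineBasis(positionsOf(mc), 4), mc,
                        depthCovariate = FALSE)
    set.seed(14)
    theta <- rnorm(lay@npar, 0, 0.3)
    # shift gamma0 by c and every upsilon by -c: same predictor,
    # same likelihood
    cc <- rnorm(4, 0, 0.5)
    theta2 <- theta
    theta2[lay@blocks[["gamma0"]]$cols] <-
        theta2[lay@blocks[["gamma0"]]$cols] + cc
    for (nm in grep("upsilon", names(lay@blocks), value = TRUE))
        theta2[lay@blocks[[nm]]$cols] <-
            theta2[lay@blocks[[nm]]$cols] - cc
    expect_equal(logLikelihood(theta, mc, lay),
                 logLikelihood(theta2, mc, lay), tolerance = 1e-10)
})

test_that("inverse-gamma hyperparameters are positive and moment-matched", {
    sim <- simulateExample1(T = 150, nGroup1 = 3, nGroup2 = 3, seed = 6)
    lay <- designLayout(splineBasis(positionsOf(sim$counts), 10),
                        sim$counts)
    pr <- estimateInvGamma(sim$counts, lay)
    expect_s4_class(pr, "PriorSpec")
    expect_identical(pr@kind, "inverse_gamma")
    expect_gt(pr@a, 0); expect_gt(pr@b, 0)
})
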