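test_that("rss matches hand values and the oracle residual norm", {
    ## single entry: shat = 3, s0 = 1, r = 1, t = 1 -> (3 - 2)^2 = 1
    expect_equal(rss(matrix(c(3, 3), 1, 2), SiteParameters(1, 1), c(1, 1)), 2)
    expect_equal(rss(matrix(3, 1, 1), SiteParameters(1, 1), 1), 1)

    ## noise-free data at the true parameters -> 0
    t <- c(2, 4, 8)
    vals <- 0.4 + outer(c(0.01, -0.02), t)
    expect_equal(rss(vals, SiteParameters(c(0.01, -0.02), c(0.4, 0.4)), t), 0)

    ## equals the squared norm of the explicit design residual
    set.seed(50)
    for (rep in 1:20) {
        inst <- randomInstance()
        params <- randomParams(inst$n)
        sys <- buildDesignSystem(inst$vals, inst$ages)
        resid <- sys$y - sys$X %*% c(rates(params), startStates(params))
        expect_equal(rss(inst$vals, params, inst$ages), sum(resid^2),
                     tolerance = 1e-10)
    }
})

test_that("fitMC is a single exact site step and beats random perturbations", {
    set.seed(51)
    sim <- simulateMC(n = 30, m = 20, sigma = 0.05, seed = 51)
    me <- sim$experiment
    fit <- fitMC(me)
    expect_identical(fit@model, "MC")
    expect_identical(fit@iterations, 1L)
    expect_true(fit@converged)
    expect_equal(eAges(fit), ages(me))

    direct <- siteStep(me)
    expect_equal(rates(fit), rates(direct), tolerance = 1e-14)
    expect_equal(startStates(fit), startStates(direct), tolerance = 1e-14)

    ## optimality probe: 100 random parameter perturbations never improve RSS
    for (rep in 1:100) {
        eps <- rnorm(length(rates(fit)), 0, 0.01)
        probe <- SiteParameters(unname(rates(fit)) + eps,
                                unname(startStates(fit)) + rnorm(length(eps), 0, 0.1))
        expect_gte(rss(me, probe), fit@finalRSS)
    }

    ## zero-noise MC data: RSS is exactly zero, parameters exact
    sim0 <- simulateMC(n = 12, m = 9, sigma = 0, seed = 52)
    fit0 <- fitMC(sim0$experiment)
    expect_lt(fit0@finalRSS, 1e-20)
    expect_equal(rates(fit0), sim0$truth$rates, tolerance = 1e-10)
    expect_equal(startStates(fit0), sim0$truth$startStates, tolerance = 1e-10)
})

test_that("fitEPM: chronological truth is a fixed point on noiseless MC data", {
    sim <- simulateMC(n = 25, m = 15, sigma = 0, seed = 53)
    fit <- fitEPM(sim$experiment, deltaCEM = 1e-12)
    expect_true(fit@converged)
    expect_lt(fit@finalRSS, 1e-16 * 25 * 15)
    ## e-ages equal chronological ages up to the affine gauge; with this
    ## noiseless input the anchored frame reproduces them directly
    expect_equal(unname(eAges(fit)), unname(ages(sim$experiment)),
                 tolerance = 1e-8)
})

test_that("fitEPM drives noiseless pacemaker data to an exact fit", {
    sim <- simulateEPM(n = 40, m = 25, sigma = 0, seed = 54)
    fit <- fitEPM(sim$experiment, deltaCEM = 1e-14, maxIters = 200)
    nm <- prod(dim(sim$experiment))
    expect_lt(fit@finalRSS, 1e-16 * nm)
    fitted <- startStates(fit) + outer(unname(rates(fit)), unname(eAges(fit)))
    expect_equal(unname(fitted), unname(methLevels(sim$experiment)),
                 tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the RSS trace is non-increasing and the EPM fit nests below MC", {
    set.seed(55)
    for (rep in 1:10) {
        inst <- randomInstance(nMax = 15L, mMax = 12L)
        mc <- fitMC(inst$vals, inst$ages)
        epm <- fitEPM(inst$vals, inst$ages)
        expect_true(all(diff(rssTrace(epm)) <= 1e-10 * (1 + rssTrace(epm)[1])))
        roundingFloor <- 1e4 * .Machine$double.eps^2 * sum(inst$vals^2)
        expect_lte(epm@finalRSS,
                   mc@finalRSS * (1 + 1e-12) + roundingFloor)
        expect_identical(epm@finalRSS, rssTrace(epm)[length(rssTrace(epm))])
    }
})

test_that("the iteration cap is honored and reported as non-convergence", {
    sim <- simulateEPM(n = 30, m = 20, sigma = 0.05, seed = 56)
    fit <- fitEPM(sim$experiment, deltaCEM = 1e-300, maxIters = 3L)
    expect_identical(fit@iterations, 3L)
    expect_false(fit@converged)
    expect_length(rssTrace(fit), 6L)   # two half-steps per iteration
})

test_that("relative improvement mode converges on scale-inflated data", {
    sim <- simulateEPM(n = 20, m = 12, sigma = 0.05, seed = 57)
    big <- MethylationExperiment(methLevels(sim$experiment) * 1e6,
                                 ages = ages(sim$experiment))
    fit <- fitEPM(big, deltaCEM = 1e-10, improvement = "relative")
    expect_true(fit@converged)
})

test_that("the affine gauge leaves the RSS invariant to 1e-10", {
    set.seed(58)
    for (rep in 1:25) {
        inst <- randomInstance()
        params <- randomParams(inst$n)
        base <- rss(inst$vals, params, inst$ages)
        a <- runif(1, 0.1, 4) * sample(c(-1, 1), 1)
        b <- rnorm(1, 0, 10)
        gauged <- SiteParameters(rates(params) / a,
                                 startStates(params) - (b / a) * rates(params))
        transformed <- rss(inst$vals, gauged, a * inst$ages + b)
        expect_equal(transformed, base, tolerance = 1e-10)
    }
})

test_that("affineAlign recovers a known affine map", {
    set.seed(59)
    x <- rnorm(40)
    al <- affineAlign(x, 3 * x - 2)
    expect_equal(al$a, 3, tolerance = 1e-12)
    expect_equal(al$b, -2, tolerance = 1e-12)
    expect_equal(al$aligned, 3 * x - 2, tolerance = 1e-12)
    expect_error(affineAlign(rep(1, 5), rnorm(5)), "constant")
})
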