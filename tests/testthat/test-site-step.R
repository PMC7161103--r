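test_that("time moments match hand computation and reject degenerate ages", {
    tm <- computeTimeMoments(c(1, 2))
    expect_equal(tm@sumT, 3)
    expect_equal(tm@sumT2, 5)
    expect_equal(tm@lam, -1)   # 1 / (9 - 10)

    expect_error(computeTimeMoments(rep(4.2, 6)), "degenerate ages")
    expect_error(computeTimeMoments(3), "length >= 2")

    ## Lambda is strictly negative for any ages with two distinct values
    set.seed(30)
    for (rep in 1:50) {
        t <- rnorm(sample(2:20, 1)) * 10^sample(-2:2, 1)
        if (sd(t) == 0) next
        expect_lt(computeTimeMoments(t)@lam, 0)
    }
})

test_that("structured normal matrix and its Lambda-scaled inverse are exact", {
    set.seed(31)
    for (n in c(1L, 2L, 5L)) {
        m <- sample(3:12, 1)
        t <- runif(m, 0, 100)
        vals <- matrix(rnorm(n * m), n, m)
        nm <- assembleNormalMatrix(computeTimeMoments(t), n)
        dense <- expandNormalMatrix(nm)
        ## equals the oracle's explicit X'X
        sys <- buildDesignSystem(vals, t)
        expect_equal(dense, crossprod(sys$X), tolerance = 1e-12)
        ## inverse expansion: product with the forward expansion is identity
        expect_equal(dense %*% expandNormalInverse(nm), diag(2 * n),
                     tolerance = 1e-10)
    }
    ## t = (1, 2), n = 1 dense expansion is [[5, 3], [3, 2]]
    nm1 <- assembleNormalMatrix(computeTimeMoments(c(1, 2)), 1)
    expect_equal(expandNormalMatrix(nm1), matrix(c(5, 3, 3, 2), 2, 2))
})

test_that("closed-form site step agrees with the naive oracle on 200 random instances", {
    set.seed(32)
    worst <- 0
    for (rep in 1:200) {
        inst <- randomInstance()
        fast <- siteStep(inst$vals, inst$ages)
        naive <- solveMCNaive(buildDesignSystem(inst$vals, inst$ages))
        worst <- max(worst,
                     abs(rates(fast) - rates(naive)),
                     abs(startStates(fast) - startStates(naive)))
    }
    expect_lt(worst, 1e-8)
})

test_that("site step equals the per-site simple-regression identity to 1e-10", {
    set.seed(33)
    for (rep in 1:50) {
        inst <- randomInstance()
        fast <- siteStep(inst$vals, inst$ages)
        ref <- perSiteRegression(inst$vals, inst$ages)
        expect_equal(unname(rates(fast)), unname(ref$rates),
                     tolerance = 1e-10)
        expect_equal(unname(startStates(fast)), unname(ref$startStates),
                     tolerance = 1e-10)
    }
})

test_that("site step recovers exact lines and propagates degenerate-age errors", {
    t <- c(1, 2, 3)
    p <- siteStep(matrix(2 + 0.5 * t, 1, 3), t)
    expect_equal(unname(rates(p)), 0.5, tolerance = 1e-12)
    expect_equal(unname(startStates(p)), 2, tolerance = 1e-12)
    expect_error(siteStep(matrix(rnorm(6), 2, 3), c(1, 1, 1)),
                 "degenerate ages")
})

test_that("sites are estimated independently (block-diagonal decomposition)", {
    set.seed(34)
    inst <- randomInstance(nMax = 10L)
    if (inst$n < 2) inst <- list(vals = rbind(inst$vals, rnorm(inst$m)),
                                 ages = inst$ages, n = 2L, m = inst$m)
    full <- siteStep(inst$vals, inst$ages)
    drop1 <- siteStep(inst$vals[-1L, , drop = FALSE], inst$ages)
    expect_equal(unname(rates(full))[-1L], unname(rates(drop1)),
                 tolerance = 1e-12)
    expect_equal(unname(startStates(full))[-1L], unname(startStates(drop1)),
                 tolerance = 1e-12)
})

test_that("shifting all ages by c maps start states to s0 - c*r, rates unchanged", {
    set.seed(35)
    for (rep in 1:20) {
        inst <- randomInstance()
        shift <- rnorm(1, 0, 50)
        p0 <- siteStep(inst$vals, inst$ages)
        p1 <- siteStep(inst$vals, inst$ages + shift)
        expect_equal(rates(p1), rates(p0), tolerance = 1e-10)
        expect_equal(unname(startStates(p1)),
                     unname(startStates(p0) - shift * rates(p0)),
                     tolerance = 1e-8)
    }
})

test_that("instrumented multiplication count is exactly 2nm + 2m", {
    set.seed(36)
    for (n in c(1L, 3L, 17L, 100L)) {
        for (m in c(2L, 7L, 40L)) {
            t <- runif(m, 0, 100)
            p <- siteStep(matrix(rnorm(n * m), n, m), t)
            expect_identical(S4Vectors::metadata(p)$multiplications,
                             2L * n * m + 2L * m)
        }
    }
})
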