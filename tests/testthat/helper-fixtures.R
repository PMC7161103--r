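## Shared fixtures: all built programmatically, deterministic under set.seed.

## A small random instance with distinct ages and standard-normal levels.
randomInstance <- function(nMax = 20L, mMax = 15L) {
    n <- sample(seq_len(nMax), 1L)
    m <- sample(2:mMax, 1L)
    ages <- stats::rnorm(m)
    while (stats::sd(ages) == 0)
        ages <- stats::rnorm(m)
    list(vals = matrix(stats::rnorm(n * m), n, m), ages = ages, n = n, m = m)
}

## Random site parameters with at least one clearly non-zero rate.
randomParams <- function(n) {
    r <- stats::rnorm(n)
    r[1L] <- r[1L] + 2 * sign(r[1L] + 1e-9)
    SiteParameters(rates = r, startStates = stats::rnorm(n))
}

## Independent simple-regression closed form, per site.
perSiteRegression <- function(vals, ages) {
    r <- apply(vals, 1L, function(row) stats::cov(ages, row) / stats::var(ages))
    s0 <- rowMeans(vals) - r * mean(ages)
    list(rates = r, startStates = s0)
}

## Brute-force 1-D minimizer of the column-j RSS in t: Brent to locate the
## minimum, then a three-point parabolic vertex (function evaluations only)
## to beat Brent's sqrt(eps)-scale flatness limit near a quadratic minimum.
bruteForceTime <- function(vals, params, j, halfWidth = 1e3) {
    f <- function(t) sum((vals[, j] - (startStates(params) + rates(params) * t))^2)
    t0 <- stats::optimize(f, interval = c(-halfWidth, halfWidth),
                          tol = 1e-10)$minimum
    h <- 0.5
    f1 <- f(t0 - h); f2 <- f(t0); f3 <- f(t0 + h)
    denom <- f3 - 2 * f2 + f1
    if (denom <= 0) return(t0)   # numerically flat: fall back to Brent
    t0 - h * (f3 - f1) / (2 * denom)
}

## Write a MethylationExperiment + ages to temp files; returns the paths.
writeTempInput <- function(sim, ext = "tsv") {
    mat <- tempfile(fileext = paste0(".matrix.", ext))
    agesF <- tempfile(fileext = paste0(".ages.", ext))
    writeMethylationMatrix(sim$experiment, mat)
    writeAges(sim$experiment, agesF)
    list(matrix = mat, ages = agesF)
}
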