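## Seeded generators for the two generative models.
##
## Draw order is fixed and documented so runs are reproducible from the seed
## alone: (1) chronological ages, (2) rates, (3) start states, (4) per-
## individual dilation multipliers (pacemaker model only), (5) noise, drawn
## row-major (site by site). A degenerate dilation distribution that returns
## a constant without consuming random numbers (the default `NULL` for
## `simulateMC`) keeps the MC and EPM streams aligned.

.defaultRateDist <- function(n) {
    ## uniform on [-0.01, -0.001] U [0.001, 0.01]: a dead zone around zero
    ## keeps every site informative about time
    magnitude <- stats::runif(n, 0.001, 0.01)
    sign <- ifelse(stats::runif(n) < 0.5, -1, 1)
    sign * magnitude
}

.defaultStartDist <- function(n) stats::runif(n, 0.1, 0.9)

.defaultDilationDist <- function(m) stats::rlnorm(m, meanlog = 0, sdlog = 0.25)

.simulateCore <- function(n, m, ageRange, rateDist, startDist, dilationDist,
                          sigma, seed, clip, ages) {
    if (!is.numeric(n) || n < 1L || !is.numeric(m) || m < 2L)
        stop("need n >= 1 sites and m >= 2 individuals")
    if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
        stop("'sigma' must be a single non-negative number")
    if (is.null(seed) || !is.numeric(seed))
        stop("'seed' is required for reproducible simulation")
    n <- as.integer(n); m <- as.integer(m)
    set.seed(as.integer(seed))
    if (is.null(ages)) {
        if (length(ageRange) != 2L || diff(range(ageRange)) <= 0)
            stop("'ageRange' must span a non-degenerate interval")
        ages <- stats::runif(m, ageRange[1L], ageRange[2L])
    } else {
        if (length(ages) != m)
            stop("'ages' must have length m")
        ages <- as.numeric(ages)
    }
    rates <- rateDist(n)
    starts <- startDist(n)
    if (is.null(dilationDist)) {
        dilation <- rep(1, m)                 # no RNG consumed: MC model
    } else {
        dilation <- dilationDist(m)
        if (any(!is.finite(dilation)) || any(dilation <= 0))
            stop("dilation multipliers must be positive")
    }
    trueEAges <- dilation * ages
    expected <- starts + outer(rates, trueEAges)
    noise <- if (sigma > 0)
        matrix(stats::rnorm(n * m, 0, sigma), n, m, byrow = TRUE)
    else matrix(0, n, m)
    vals <- expected + noise
    if (clip)
        vals <- pmin(pmax(vals, 0), 1)
    siteIds <- paste0("cg", formatC(seq_len(n), width = 6, flag = "0"))
    indIds <- paste0("ind", formatC(seq_len(m), width = 4, flag = "0"))
    dimnames(vals) <- list(siteIds, indIds)
    me <- MethylationExperiment(vals, ages = stats::setNames(ages, indIds))
    truth <- list(rates = stats::setNames(rates, siteIds),
                  startStates = stats::setNames(starts, siteIds),
                  sigma = sigma,
                  chronoAges = stats::setNames(ages, indIds),
                  epigeneticAges = stats::setNames(trueEAges, indIds),
                  dilation = stats::setNames(dilation, indIds),
                  seed = as.integer(seed))
    list(experiment = me, truth = truth)
}

#' Simulate methylation data under the molecular-clock model
#'
#' Generates \eqn{\hat s_{ij} = s_i^0 + r_i t_j + \varepsilon_{ij}} with
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)} i.i.d., ages uniform over
#' `ageRange` (or fixed via `ages`), rates from `rateDist` and start states
#' from `startDist`. All draws come from one generator seeded with `seed`, in
#' the documented order (ages, rates, start states, noise row-major), so a
#' fixed seed reproduces the data exactly.
#'
#' Default distributions: ages uniform on \[0, 100\] years; rates uniform on
#' \eqn{\pm[0.001, 0.01]} level/year (a dead zone around zero keeps ages
#' identifiable); start states uniform on \[0.1, 0.9\]. Methylation values
#' are *not* clipped to \[0, 1\] unless `clip = TRUE`, because clipping
#' breaks the linear-Gaussian model the estimators assume.
#'
#' @param n,m number of sites and individuals.
#' @param ageRange length-2 numeric, the uniform support for chronological
#'   ages (ignored when `ages` is supplied).
#' @param rateDist,startDist functions of a count returning that many draws.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed (required).
#' @param clip clip the observed values to \[0, 1\]? Default `FALSE`.
#' @param ages optional explicit chronological ages (length m).
#' @return list with `experiment` (a [MethylationExperiment-class] carrying
#'   the chronological ages) and `truth` (named list: `rates`,
#'   `startStates`, `sigma`, `chronoAges`, `epigeneticAges`, `dilation`,
#'   `seed`).
#' @examples
#' sim <- simulateMC(n = 10, m = 8, sigma = 0, seed = 1)
#' max(abs(methLevels(sim$experiment) -
#'         (sim$truth$startStates + outer(sim$truth$rates, ages(sim$experiment)))))
#' @export
simulateMC <- function(n, m, ageRange = c(0, 100),
                       rateDist = .defaultRateDist,
                       startDist = .defaultStartDist,
                       sigma = 0.05, seed, clip = FALSE, ages = NULL) {
    .simulateCore(n, m, ageRange, rateDist, startDist,
                  dilationDist = NULL, sigma = sigma, seed = seed,
                  clip = clip, ages = ages)
}

#' Simulate methylation data under the epigenetic-pacemaker model
#'
#' As [simulateMC()], but each individual j receives a positive dilation
#' multiplier \eqn{c_j} and the data are generated from the true epigenetic
#' age \eqn{t^*_j = c_j t_j}: \eqn{\hat s_{ij} = s_i^0 + r_i t^*_j +
#' \varepsilon_{ij}}. All of an individual's sites share the same multiplier,
#' which is exactly the pacemaker property (pairwise rate ratios constant
#' within an individual). The returned experiment carries the chronological
#' ages — what a fitter observes — while `truth$epigeneticAges` holds
#' \eqn{t^*}.
#'
#' The default dilation distribution is log-normal with median 1
#' (`sdlog = 0.25`, i.e. typical dilations within ~±25%).
#'
#' @inheritParams simulateMC
#' @param dilationDist function of a count returning positive multipliers.
#' @return As [simulateMC()].
#' @examples
#' sim <- simulateEPM(n = 10, m = 8, sigma = 0, seed = 1)
#' range(sim$truth$dilation)
#' @export
simulateEPM <- function(n, m, ageRange = c(0, 100),
                        rateDist = .defaultRateDist,
                        startDist = .defaultStartDist,
                        dilationDist = .defaultDilationDist,
                        sigma = 0.05, seed, clip = FALSE, ages = NULL) {
    if (!is.function(dilationDist))
        stop("'dilationDist' must be a function of a count")
    .simulateCore(n, m, ageRange, rateDist, startDist,
                  dilationDist = dilationDist, sigma = sigma, seed = seed,
                  clip = clip, ages = ages)
}
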