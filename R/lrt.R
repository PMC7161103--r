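#' Likelihood-ratio test between the molecular-clock and pacemaker fits
#'
#' The MC model (epigenetic ages fixed at chronological ages) is nested in
#' the EPM model (m free time parameters). Under the Gaussian noise model the
#' profile log-likelihood ratio reduces to a function of the two residual
#' sums of squares, giving the statistic
#' \deqn{\chi^2 = n m \log(RSS_{MC} / RSS_{EPM})}
#' (natural logarithm), asymptotically chi-squared with degrees of freedom
#' equal to the number of freed parameters — the m individual ages.
#'
#' Nesting requires `rssEPM <= rssMC`; tiny numerical violations (relative
#' excess at most `1e-9`) are clamped to a ratio of 1, larger ones are
#' errors. A zero `rssEPM` (possible only for data the pacemaker model fits
#' exactly) yields `chi2 = Inf`, `p = 0` with a warning.
#'
#' @param rssMC,rssEPM positive residual sums of squares of the two fits.
#' @param n,m number of sites and individuals.
#' @param df degrees of freedom; defaults to `m`. Exposed for sensitivity
#'   analyses only.
#' @return An [LRTResult-class] object.
#' @examples
#' likelihoodRatioTest(rssMC = exp(1), rssEPM = 1, n = 10, m = 5)  # chi2 = 50
#' @seealso [compareModels()]
#' @export
likelihoodRatioTest <- function(rssMC, rssEPM, n, m, df = m) {
    stopifnot(length(rssMC) == 1L, length(rssEPM) == 1L,
              n >= 1L, m >= 1L, df >= 1L)
    if (!is.finite(rssMC) || rssMC <= 0)
        stop("rssMC must be a positive finite number (log undefined otherwise)")
    if (!is.finite(rssEPM) || rssEPM < 0)
        stop("rssEPM must be a non-negative finite number")
    if (rssEPM > rssMC) {
        if ((rssEPM - rssMC) / rssMC > 1e-9)
            stop("nesting violated: rssEPM exceeds rssMC by more than ",
                 "1e-9 relative (the EPM optimum cannot be worse than MC)")
        rssEPM <- rssMC   # clamp tiny numerical violation to ratio 1
    }
    if (rssEPM == 0) {
        warning("rssEPM is exactly zero: perfect pacemaker fit; ",
                "chi2 reported as Inf with p = 0")
        chi2 <- Inf
        p <- 0
    } else {
        chi2 <- n * m * log(rssMC / rssEPM)
        p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
    }
    new("LRTResult", chi2 = chi2, df = as.integer(df), pValue = p,
        rssMC = rssMC, rssEPM = rssEPM, n = as.integer(n), m = as.integer(m))
}

#' Fit both models and test the pacemaker against the clock
#'
#' Runs [fitMC()] and [fitEPM()] on the same data and summarizes them with
#' [likelihoodRatioTest()].
#'
#' When both residual sums of squares fall below the floating-point rounding
#' floor for the data — `1e4 * eps^2 * sum(values^2)`, the magnitude a sum of
#' squared rounding errors can reach on an exactly-representable fit — the
#' two fits are numerically indistinguishable perfect fits and their ratio
#' carries no information; the test then reports `chi2 = 0`, `p = 1` rather
#' than a ratio of rounding noise. This only triggers on data the clock
#' model fits exactly (e.g. noiseless simulations).
#'
#' @param x a [MethylationExperiment-class] with ages attached.
#' @param deltaCEM,maxIters,improvement forwarded to [fitEPM()].
#' @param ... passed between methods.
#' @return An [LRTResult-class] object.
#' @examples
#' sim <- simulateEPM(n = 60, m = 30, sigma = 0.02, seed = 11)
#' compareModels(sim$experiment)
#' @rdname compareModels
#' @export
setMethod("compareModels", "MethylationExperiment",
    function(x, deltaCEM = 1e-6, maxIters = 100L,
             improvement = c("absolute", "relative"), ...) {
        improvement <- match.arg(improvement)
        mc <- fitMC(x)
        epm <- fitEPM(x, deltaCEM = deltaCEM, maxIters = maxIters,
                      improvement = improvement)
        floor <- 1e4 * .Machine$double.eps^2 * sum(methLevels(x)^2)
        if (mc@finalRSS <= floor && epm@finalRSS <= floor)
            return(new("LRTResult", chi2 = 0, df = ncol(x), pValue = 1,
                       rssMC = mc@finalRSS, rssEPM = epm@finalRSS,
                       n = nrow(x), m = ncol(x)))
        likelihoodRatioTest(mc@finalRSS, epm@finalRSS,
                            n = nrow(x), m = ncol(x))
    })
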