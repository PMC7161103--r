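#' Residual sum of squares of the linear methylation model
#'
#' Evaluates \eqn{\sum_i \sum_j (\hat s_{ij} - (s_i^0 + r_i t_j))^2}, the
#' objective both fits minimize (under i.i.d. Gaussian noise, minimizing it
#' is equivalent to maximizing the likelihood).
#'
#' @param x a [MethylationExperiment-class] or numeric sites-x-individuals
#'   matrix.
#' @param params a [SiteParameters-class].
#' @param ages numeric vector of ages/epigenetic ages (length m); defaults to
#'   `ages(x)` for an experiment.
#' @param ... passed between methods.
#' @return A single non-negative number.
#' @rdname rss
#' @export
setMethod("rss", signature(x = "matrix", params = "SiteParameters"),
    function(x, params, ages, ...) {
        stopifnot(nrow(x) == length(params), ncol(x) == length(ages))
        fitted <- params@startStates + outer(params@rates, as.numeric(ages))
        sum((x - fitted)^2)
    })

#' @rdname rss
#' @export
setMethod("rss", signature(x = "MethylationExperiment",
                           params = "SiteParameters"),
    function(x, params, ages, ...) {
        if (missing(ages))
            ages <- .agesOf(x)
        rss(methLevels(x), params, as.numeric(ages))
    })

.newFit <- function(model, params, eAges, chrono, trace, iterations,
                    converged) {
    new("EPMFit", model = model, params = params,
        eAges = eAges, chronoAges = chrono, rssTrace = trace,
        iterations = as.integer(iterations), converged = converged,
        finalRSS = trace[length(trace)])
}

#' Fit the molecular-clock model
#'
#' Single closed-form site step with the chronological ages held fixed: the
#' exact maximum-likelihood MC fit. The returned epigenetic ages equal the
#' input ages by definition of the model.
#'
#' @param x a [MethylationExperiment-class] with ages attached, or a numeric
#'   matrix (then `ages` is required).
#' @param ages numeric chronological ages (matrix method).
#' @param ... passed between methods.
#' @return An [EPMFit-class] with `model = "MC"`, `iterations = 1`,
#'   `converged = TRUE`.
#' @seealso [fitEPM()], [compareModels()]
#' @rdname fitMC
#' @export
setMethod("fitMC", signature(x = "matrix"),
    function(x, ages, ...) {
        ages <- as.numeric(ages)
        chrono <- stats::setNames(ages, colnames(x))
        params <- siteStep(x, ages)
        .newFit("MC", params, chrono, chrono,
                trace = rss(x, params, ages), iterations = 1L,
                converged = TRUE)
    })

#' @rdname fitMC
#' @export
setMethod("fitMC", signature(x = "MethylationExperiment"),
    function(x, ...) {
        fitMC(methLevels(x), ages(x))
    })

#' Fit the epigenetic-pacemaker model by conditional maximization
#'
#' Alternates the two exact conditional minimizers of the residual sum of
#' squares — the closed-form site step (rates and start states given ages)
#' and the closed-form time step (epigenetic ages given site parameters) —
#' starting from the chronological ages. Because each half-step is an exact
#' conditional minimizer, the RSS is non-increasing along the whole
#' trajectory and the iteration converges to a critical point of the
#' likelihood surface.
#'
#' Iteration stops when the RSS improvement over one full iteration drops to
#' `deltaCEM` or below (absolute by default, or relative to the current RSS),
#' or at `maxIters`. The trace records the RSS after every half-step.
#'
#' The fitted model is invariant under the affine reparameterization
#' \eqn{(t, r, s^0) \to (a t + b,\ r / a,\ s^0 - (b/a) r)}; the reported
#' epigenetic ages live in the frame anchored by the chronological-age
#' initialization, so comparisons with external truth should be done after
#' affine alignment (see [affineAlign()]) or via correlation.
#'
#' @param x a [MethylationExperiment-class] with ages attached, or a numeric
#'   matrix (then `ages` is required).
#' @param ages numeric chronological ages (matrix method).
#' @param deltaCEM positive stopping threshold on per-iteration RSS
#'   improvement (default `1e-6`).
#' @param maxIters maximum number of full iterations (default 100).
#' @param improvement `"absolute"` (default) or `"relative"` — how the RSS
#'   decrease is compared with `deltaCEM`.
#' @param ... passed between methods.
#' @return An [EPMFit-class] with `model = "EPM"`.
#' @examples
#' sim <- simulateEPM(n = 50, m = 25, sigma = 0.02, seed = 7)
#' fit <- fitEPM(sim$experiment)
#' cor(eAges(fit), sim$truth$epigeneticAges)
#' @rdname fitEPM
#' @export
setMethod("fitEPM", signature(x = "matrix"),
    function(x, ages, deltaCEM = 1e-6, maxIters = 100L,
             improvement = c("absolute", "relative"), ...) {
        improvement <- match.arg(improvement)
        if (!is.numeric(deltaCEM) || length(deltaCEM) != 1L || deltaCEM <= 0)
            stop("'deltaCEM' must be a single positive number")
        if (!is.numeric(maxIters) || length(maxIters) != 1L || maxIters < 1)
            stop("'maxIters' must be a positive integer")
        maxIters <- as.integer(maxIters)
        ages <- as.numeric(ages)
        chrono <- stats::setNames(ages, colnames(x))

        t_cur <- ages
        trace <- numeric(0)
        prevRSS <- Inf
        converged <- FALSE
        iter <- 0L
        params <- NULL
        repeat {
            iter <- iter + 1L
            params <- tryCatch(
                siteStep(x, t_cur),
                error = function(e) stop("site step failed at iteration ",
                                         iter, ": ", conditionMessage(e)))
            trace <- c(trace, rss(x, params, t_cur))
            t_cur <- tryCatch(
                as.numeric(timeStep(x, params)),
                error = function(e) stop("time step failed at iteration ",
                                         iter, ": ", conditionMessage(e)))
            curRSS <- rss(x, params, t_cur)
            trace <- c(trace, curRSS)
            gain <- prevRSS - curRSS
            if (improvement == "relative" && is.finite(prevRSS))
                gain <- gain / max(curRSS, .Machine$double.xmin)
            if (is.finite(prevRSS) && gain <= deltaCEM) {
                converged <- TRUE
                break
            }
            if (iter >= maxIters)
                break
            prevRSS <- curRSS
        }
        eAges <- stats::setNames(t_cur, colnames(x))
        .newFit("EPM", params, eAges, chrono, trace, iter, converged)
    })

#' @rdname fitEPM
#' @export
setMethod("fitEPM", signature(x = "MethylationExperiment"),
    function(x, deltaCEM = 1e-6, maxIters = 100L,
             improvement = c("absolute", "relative"), ...) {
        fitEPM(methLevels(x), ages(x), deltaCEM = deltaCEM,
               maxIters = maxIters, improvement = improvement)
    })

#' Optimal affine alignment of one vector onto another
#'
#' Least-squares fit of `a * x + b` to `reference`; used to compare estimated
#' epigenetic ages with ground truth, since the pacemaker likelihood is flat
#' along the affine gauge of the time axis.
#'
#' @param x numeric vector to align.
#' @param reference numeric vector of the same length.
#' @return list with `aligned` (the transformed `x`), `a`, `b`.
#' @export
affineAlign <- function(x, reference) {
    stopifnot(length(x) == length(reference), length(x) >= 2L)
    vx <- stats::var(x)
    if (vx == 0)
        stop("cannot align a constant vector")
    a <- stats::cov(x, reference) / vx
    b <- mean(reference) - a * mean(x)
    list(aligned = a * x + b, a = a, b = b)
}
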