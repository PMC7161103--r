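## Closed-form site step.
##
## For fixed times t, minimizing the RSS over (r_i, s0_i) is ordinary least
## squares against a highly structured design: the normal matrix X'X is built
## from four n x n diagonal blocks diag(sum t^2), diag(sum t), diag(sum t),
## diag(m), and its inverse factors through the single scalar
## Lambda = 1 / ((sum t)^2 - m sum t^2). Multiplying out the projector
## (X'X)^{-1} X' shows each of its rows is a length-m band whose entries
## depend only on the column position within the band:
##   upper (rate) band:        u_j = -m t_j + sum t
##   lower (start-state) band: l_j = t_j sum t - sum t^2
## so the whole solve collapses to two banded dot products per site,
##   r_i  = Lambda * sum_j u_j shat_ij,   s0_i = Lambda * sum_j l_j shat_ij,
## with no matrix ever formed: O(nm) time and space.

#' Sufficient statistics of the age vector
#'
#' Computes \eqn{\sum t_j}, \eqn{\sum t_j^2}, \eqn{m} and the scalar
#' \eqn{\Lambda = 1/((\sum t)^2 - m \sum t^2)} that factors the inverse normal
#' matrix. \eqn{\Lambda} is strictly negative whenever at least two ages
#' differ (Cauchy--Schwarz); all-equal ages make the site step unsolvable and
#' are rejected.
#'
#' @param ages numeric vector of length >= 2.
#' @return A [TimeMoments-class] object.
#' @examples
#' computeTimeMoments(c(1, 2))  # Lambda = 1/(9 - 10) = -1
#' @export
computeTimeMoments <- function(ages) {
    ages <- as.numeric(ages)
    if (length(ages) < 2L || anyNA(ages) || any(!is.finite(ages)))
        stop("ages must be a finite numeric vector of length >= 2")
    m <- length(ages)
    sumT <- sum(ages)
    sumT2 <- sum(ages * ages)
    denom <- sumT * sumT - m * sumT2
    if (denom >= 0)
        stop("degenerate ages: Lambda undefined (all ages equal)")
    new("TimeMoments", sumT = sumT, sumT2 = sumT2, m = as.integer(m),
        lam = 1 / denom)
}

#' Structured description of the MC normal equations
#'
#' Returns the four diagonal scalars that fully describe the 2n x 2n normal
#' matrix `X'X` (`A = sum t^2`, `B = C = sum t`, `D = m`) and, via
#' [expandNormalMatrix()] / [expandNormalInverse()], their dense expansions
#' for inspection and testing. The fast path never materializes either
#' matrix.
#'
#' @param moments a [TimeMoments-class] object.
#' @param n number of sites.
#' @return An object of class `"NormalEquations"`: a list with fields
#'   `A`, `B`, `D`, `lam`, `n`.
#' @examples
#' nm <- assembleNormalMatrix(computeTimeMoments(c(1, 2)), n = 1)
#' expandNormalMatrix(nm)            # [[5, 3], [3, 2]]
#' expandNormalMatrix(nm) %*% expandNormalInverse(nm)  # identity
#' @rdname assembleNormalMatrix
#' @export
assembleNormalMatrix <- function(moments, n) {
    stopifnot(is(moments, "TimeMoments"), n >= 1)
    structure(list(A = moments@sumT2, B = moments@sumT,
                   D = as.numeric(moments@m), lam = moments@lam,
                   n = as.integer(n)),
              class = "NormalEquations")
}

#' @rdname assembleNormalMatrix
#' @param x a `"NormalEquations"` object.
#' @export
expandNormalMatrix <- function(x) {
    stopifnot(inherits(x, "NormalEquations"))
    n <- x$n
    I <- diag(n)
    rbind(cbind(x$A * I, x$B * I),
          cbind(x$B * I, x$D * I))
}

#' @rdname assembleNormalMatrix
#' @export
expandNormalInverse <- function(x) {
    stopifnot(inherits(x, "NormalEquations"))
    n <- x$n
    I <- diag(n)
    x$lam * rbind(cbind(-x$D * I, x$B * I),
                  cbind(x$B * I, -x$A * I))
}

#' Band coefficients of the structured projector
#'
#' The projector `(X'X)^{-1} X'` consists of two stacked banded matrices whose
#' row for site `k` is non-zero only on the m-wide column band of that site,
#' with entries depending solely on the position `j` within the band. This
#' returns the two shared length-m coefficient vectors (before the final
#' \eqn{\Lambda} scaling): `upper[j] = -m t_j + sum t` (rate rows) and
#' `lower[j] = t_j sum t - sum t^2` (start-state rows).
#'
#' @param moments a [TimeMoments-class].
#' @param ages the numeric age vector the moments were computed from.
#' @return list with numeric vectors `upper` and `lower` and the
#'   multiplication count `mults` (`2m`) spent computing them.
#' @export
projectionBand <- function(moments, ages) {
    stopifnot(is(moments, "TimeMoments"), length(ages) == moments@m)
    ages <- as.numeric(ages)
    m <- moments@m
    upper <- -(m * ages) + moments@sumT          # m scalar multiplications
    lower <- ages * moments@sumT - moments@sumT2 # m scalar multiplications
    list(upper = upper, lower = lower, mults = 2L * m)
}

.siteStepCore <- function(vals, ages) {
    moments <- computeTimeMoments(ages)
    band <- projectionBand(moments, ages)
    ## Two banded matrix-vector products: m multiplications per site each,
    ## accumulated in ascending j (column) order for bit-reproducibility.
    rawRates <- as.numeric(vals %*% band$upper)   # n*m multiplications
    rawStarts <- as.numeric(vals %*% band$lower)  # n*m multiplications
    n <- nrow(vals); m <- ncol(vals)
    list(rates = moments@lam * rawRates,
         startStates = moments@lam * rawStarts,
         mults = band$mults + 2L * n * m)
}

#' Closed-form site step: per-site rates and start states
#'
#' Solves, for fixed ages, the least-squares problem over all per-site rates
#' \eqn{r_i} and start states \eqn{s_i^0} in O(nm) time and space using the
#' structured normal-equations inverse — no design matrix is built, no matrix
#' is multiplied or inverted. The result is the exact minimizer of the
#' residual sum of squares for the given ages (identical, up to floating
#' point, to the naive oracle [solveMCNaive()]).
#'
#' The instrumented count of scalar multiplications — `2nm` for the two
#' banded products plus `2m` for the shared band coefficients — is stored in
#' `metadata(result)$multiplications`; the trailing `2n` \eqn{\Lambda}
#' rescalings and the moment sums are outside the counter's scope (the scalar
#' \eqn{\Lambda} is deliberately applied once after accumulation).
#'
#' @param x a [MethylationExperiment-class] or numeric sites-x-individuals
#'   matrix.
#' @param ages numeric ages; defaults to `ages(x)` for an experiment.
#' @param ... passed between methods.
#' @return A [SiteParameters-class] with `metadata()$multiplications` set.
#' @examples
#' ## two-point line through (1, 1) and (2, 3): rate 2, start state -1
#' siteStep(matrix(c(1, 3), 1, 2), ages = c(1, 2))
#' @rdname siteStep
#' @export
setMethod("siteStep", signature(x = "matrix"),
    function(x, ages, ...) {
        stopifnot(is.numeric(x), ncol(x) == length(ages))
        core <- .siteStepCore(x, as.numeric(ages))
        out <- SiteParameters(rates = core$rates,
                              startStates = core$startStates,
                              siteIds = rownames(x))
        S4Vectors::metadata(out)$multiplications <- core$mults
        out
    })

#' @rdname siteStep
#' @export
setMethod("siteStep", signature(x = "MethylationExperiment"),
    function(x, ages, ...) {
        if (missing(ages))
            ages <- .agesOf(x)
        siteStep(methLevels(x), as.numeric(ages))
    })
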