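## Closed-form time step.
##
## For fixed site parameters, the RSS is a separable quadratic in each t_j:
## only the column-j residuals involve t_j, so setting the derivative of
##   S_j(t) = sum_i (shat_ij - s0_i - r_i t)^2
## to zero gives the unique minimizer
##   t_j = sum_i r_i (shat_ij - s0_i) / sum_i r_i^2 .
## With sum r^2 computed once, this is nm + n multiplications for all m ages.

#' Closed-form time step: per-individual epigenetic ages
#'
#' Given fixed per-site rates and start states, returns for each individual
#' the unique age minimizing its column of the residual sum of squares:
#' \eqn{t_j = \sum_i r_i(\hat s_{ij} - s_i^0) / \sum_i r_i^2}. Estimates are
#' returned as-is — negative or super-chronological epigenetic ages are
#' meaningful (age deceleration / acceleration) and no bounds are imposed.
#'
#' Requires at least one non-zero rate; a vanishing \eqn{\sum_i r_i^2}
#' (including numerical underflow below `1e-300`) makes the ages
#' unidentifiable and is an error.
#'
#' The instrumented scalar-multiplication count (`nm` per-entry products plus
#' `n` for the \eqn{\sum r_i^2} preprocessing) is attached as
#' `attr(result, "multiplications")`.
#'
#' @param x a [MethylationExperiment-class] or numeric sites-x-individuals
#'   matrix.
#' @param params a [SiteParameters-class] with one entry per site of `x`.
#' @param ... passed between methods.
#' @return Named numeric vector of epigenetic ages (length m), with attribute
#'   `"multiplications"`.
#' @examples
#' ## r = (1, 2), s0 = (1, 0), column (2, 2): t = (1*1 + 2*2) / (1 + 4) = 1
#' timeStep(matrix(c(2, 2), 2, 1), SiteParameters(c(1, 2), c(1, 0)))
#' @rdname timeStep
#' @export
setMethod("timeStep", signature(x = "matrix", params = "SiteParameters"),
    function(x, params, ...) {
        stopifnot(is.numeric(x), nrow(x) == length(params))
        r <- params@rates
        s0 <- params@startStates
        sumR2 <- sum(r * r)                      # n multiplications
        if (!is.finite(sumR2) || sumR2 < 1e-300)
            stop("times unidentifiable: all rates zero")
        ## numerator_j = sum_i r_i (shat_ij - s0_i): n*m multiplications
        num <- as.numeric(crossprod(x - s0, r))
        eAges <- num / sumR2
        names(eAges) <- colnames(x)
        attr(eAges, "multiplications") <- length(r) * ncol(x) + length(r)
        eAges
    })

#' @rdname timeStep
#' @export
setMethod("timeStep", signature(x = "MethylationExperiment",
                                params = "SiteParameters"),
    function(x, params, ...) {
        timeStep(methLevels(x), params)
    })
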