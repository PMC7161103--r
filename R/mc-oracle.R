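## Naive molecular-clock solver via an explicit design matrix.
##
## The MC objective  RSS = sum_{i,j} (shat_ij - (s0_i + r_i t_j))^2  is an
## ordinary least-squares problem in beta = (r_1..r_n, s0_1..s0_n): each
## (site i, individual j) residual contributes one row of an (nm) x 2n design
## matrix with t_j at column i and 1 at column n+i. This module materializes
## that system and solves it with a stable QR factorization. It exists as the
## correctness oracle for the closed-form site step (which never forms any
## matrix) and is deliberately memory-naive, so it is gated to small inputs.

.NAIVE_MAX_ENTRIES <- 1e6

#' Build the explicit MC design system
#'
#' Constructs the dense (nm) x 2n design matrix `X` and response `y`
#' (row order: site-major, individual-minor; row for pair (i, j) has `t_j` at
#' column `i`, 1 at column `n + i`, zeros elsewhere; `y` holds the flattened
#' methylation levels).
#'
#' @param x a [MethylationExperiment-class] or numeric sites-x-individuals
#'   matrix.
#' @param ages numeric ages (defaults to `ages(x)` for an experiment).
#' @return list with elements `X` (matrix), `y` (numeric), `n`, `m`.
#' @seealso [solveMCNaive()], [siteStep()]
#' @export
buildDesignSystem <- function(x, ages = NULL) {
    if (is(x, "MethylationExperiment")) {
        if (is.null(ages)) ages <- .agesOf(x)
        x <- methLevels(x)
    }
    stopifnot(is.matrix(x), is.numeric(ages), ncol(x) == length(ages))
    n <- nrow(x); m <- ncol(x)
    if (n * m > .NAIVE_MAX_ENTRIES)
        stop("naive design system gated to n*m <= 1e6 entries; ",
             "use the closed-form siteStep() for larger inputs")
    ages <- as.numeric(ages)
    X <- matrix(0, nrow = n * m, ncol = 2L * n)
    for (i in seq_len(n)) {
        rows <- (i - 1L) * m + seq_len(m)
        X[rows, i] <- ages
        X[rows, n + i] <- 1
    }
    y <- as.numeric(t(x))   # site-major, individual-minor
    list(X = X, y = y, n = n, m = m)
}

#' Solve the MC model from the explicit design system
#'
#' Computes the least-squares minimizer of the MC residual sum of squares via
#' a QR factorization of the full design matrix (numerically stable, same
#' minimizer as the normal-equations form). Used only as a test oracle and
#' through the CLI's hidden naive engine.
#'
#' @param system a list as returned by [buildDesignSystem()].
#' @return A [SiteParameters-class]: first-half coefficients are the rates,
#'   second-half the start states.
#' @export
solveMCNaive <- function(system) {
    stopifnot(is.list(system), is.matrix(system$X), is.numeric(system$y))
    n <- system$n
    qrX <- qr(system$X)
    if (qrX$rank < ncol(system$X))
        stop("degenerate ages: design matrix is rank deficient ",
             "(ages all equal?)")
    beta <- qr.coef(qrX, system$y)
    SiteParameters(rates = beta[seq_len(n)],
                   startStates = beta[n + seq_len(n)])
}
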