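#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<-
NULL

#' MethylationExperiment: a sites-by-individuals methylation matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' assay named `"methyl"` (rows = CpG sites, columns = individuals) and,
#' optionally, a numeric `age` column in `colData` with each individual's
#' chronological age. The models fitted by this package place no constraint on
#' the methylation values themselves (they are modelled as linear in age with
#' Gaussian noise), so values outside \[0, 1\] are permitted.
#'
#' Validity requires a complete (no `NA`/`NaN`) numeric assay with at least one
#' site and two individuals, unique non-empty site and individual identifiers,
#' and, when present, finite non-missing ages.
#'
#' @seealso [MethylationExperiment()] for construction,
#'   [readMethylationMatrix()] for delimited-text input.
#' @exportClass MethylationExperiment
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    if (!("methyl" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'methyl' is required")
    vals <- SummarizedExperiment::assay(object, "methyl")
    if (!is.numeric(vals))
        msg <- c(msg, "assay 'methyl' must be numeric")
    if (anyNA(vals) || (is.numeric(vals) && any(!is.finite(vals))))
        msg <- c(msg, "assay 'methyl' must be complete and finite (no missing entries)")
    if (nrow(object) < 1L)
        msg <- c(msg, "at least one site (row) is required")
    if (ncol(object) < 2L)
        msg <- c(msg, "at least two individuals (columns) are required")
    rn <- rownames(object); cn <- colnames(object)
    if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
        msg <- c(msg, "site ids (rownames) must be present, non-empty and unique")
    if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
        msg <- c(msg, "individual ids (colnames) must be present, non-empty and unique")
    if ("age" %in% colnames(SummarizedExperiment::colData(object))) {
        a <- SummarizedExperiment::colData(object)$age
        if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
            msg <- c(msg, "colData 'age' must be finite numeric with no missing values")
    }
    if (length(msg)) msg else TRUE
})

#' SiteParameters: per-site rate and start state
#'
#' Holds the fitted molecular-clock parameters for each CpG site: the
#' methylation rate \eqn{r_i} (level change per unit time) and the start state
#' \eqn{s_i^0} (expected level at time 0). The `metadata()` list carries
#' fitting diagnostics, notably `multiplications`, the instrumented count of
#' scalar multiplications spent by the closed-form site step.
#'
#' @slot rates numeric vector of per-site rates.
#' @slot startStates numeric vector of per-site start states.
#' @slot siteIds character vector of site identifiers.
#' @seealso [siteStep()], [rates()], [startStates()]
#' @exportClass SiteParameters
setClass("SiteParameters",
    contains = "Annotated",
    representation(rates = "numeric", startStates = "numeric",
                   siteIds = "character"))

setValidity("SiteParameters", function(object) {
    msg <- character()
    n <- length(object@rates)
    if (length(object@startStates) != n)
        msg <- c(msg, "rates and startStates must have equal length")
    if (length(object@siteIds) && length(object@siteIds) != n)
        msg <- c(msg, "siteIds length must match rates")
    if (anyNA(object@rates) || any(!is.finite(object@rates)) ||
        anyNA(object@startStates) || any(!is.finite(object@startStates)))
        msg <- c(msg, "rates and startStates must be finite")
    if (length(msg)) msg else TRUE
})

#' TimeMoments: sufficient statistics of the age vector for the site step
#'
#' The closed-form site step needs only three reductions of the age vector
#' \eqn{t}: \eqn{\sum_j t_j}, \eqn{\sum_j t_j^2} and \eqn{m}, plus the scalar
#' \eqn{\Lambda = 1 / ((\sum_j t_j)^2 - m \sum_j t_j^2)} that factors the
#' inverse of the normal matrix. By the Cauchy--Schwarz inequality
#' \eqn{(\sum t)^2 < m \sum t^2} strictly whenever the ages are not all equal,
#' so \eqn{\Lambda} is finite and negative; all-equal ages are rejected.
#'
#' @slot sumT numeric(1), \eqn{\sum_j t_j}.
#' @slot sumT2 numeric(1), \eqn{\sum_j t_j^2}.
#' @slot m integer(1), number of individuals.
#' @slot lam numeric(1), the scalar \eqn{\Lambda} (strictly negative).
#' @seealso [computeTimeMoments()], [assembleNormalMatrix()]
#' @exportClass TimeMoments
setClass("TimeMoments",
    representation(sumT = "numeric", sumT2 = "numeric", m = "integer",
                   lam = "numeric"))

setValidity("TimeMoments", function(object) {
    msg <- character()
    for (s in c("sumT", "sumT2", "lam"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a finite scalar", s))
    if (length(object@m) != 1L || object@m < 2L)
        msg <- c(msg, "'m' must be a single integer >= 2")
    if (length(object@lam) == 1L && is.finite(object@lam) && object@lam >= 0)
        msg <- c(msg, "'lam' must be strictly negative (ages not all equal)")
    if (length(msg)) msg else TRUE
})

#' SiteSelection: sites ranked by Pearson correlation with age
#'
#' Result of [selectSites()]: the indices (into the originating
#' `MethylationExperiment`) of the kept sites, ordered by decreasing absolute
#' (or signed, if requested) Pearson correlation between the site's
#' methylation levels and the individuals' ages. Zero-variance sites are never
#' eligible because their correlation is undefined.
#'
#' @slot indices integer vector of kept site indices (original row order ties).
#' @slot correlations numeric vector of the corresponding Pearson correlations.
#' @slot siteIds character vector of kept site identifiers.
#' @slot signed logical(1); whether ranking used signed rather than absolute
#'   correlation.
#' @exportClass SiteSelection
setClass("SiteSelection",
    representation(indices = "integer", correlations = "numeric",
                   siteIds = "character", signed = "logical"))

setValidity("SiteSelection", function(object) {
    msg <- character()
    k <- length(object@indices)
    if (anyDuplicated(object@indices))
        msg <- c(msg, "site indices must be unique")
    if (length(object@correlations) != k || length(object@siteIds) != k)
        msg <- c(msg, "indices, correlations and siteIds must have equal length")
    if (any(abs(object@correlations) > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    key <- if (isTRUE(object@signed)) object@correlations else abs(object@correlations)
    if (k > 1L && any(diff(key) > 1e-12))
        msg <- c(msg, "sites must be sorted by decreasing correlation rank")
    if (length(msg)) msg else TRUE
})

#' EPMFit: a converged molecular-clock or pacemaker fit
#'
#' Container for the result of [fitMC()] or [fitEPM()]: the per-site
#' parameters, the per-individual estimated epigenetic ages (for an MC fit
#' these are the input chronological ages), the residual-sum-of-squares trace
#' recorded after every conditional half-step, and convergence metadata.
#' The trace is non-increasing by construction because each half-step is an
#' exact conditional minimizer of the RSS.
#'
#' @slot model character(1), `"MC"` or `"EPM"`.
#' @slot params a [SiteParameters-class] object.
#' @slot eAges named numeric vector of estimated epigenetic ages.
#' @slot chronoAges named numeric vector of the input chronological ages.
#' @slot rssTrace numeric vector, RSS after each half-step.
#' @slot iterations integer(1), full CEM iterations performed.
#' @slot converged logical(1), whether the improvement threshold was reached
#'   before the iteration cap.
#' @slot finalRSS numeric(1), the last entry of `rssTrace`.
#' @seealso [fitMC()], [fitEPM()], [ageAcceleration()]
#' @exportClass EPMFit
setClass("EPMFit",
    contains = "Annotated",
    representation(model = "character", params = "SiteParameters",
                   eAges = "numeric", chronoAges = "numeric",
                   rssTrace = "numeric", iterations = "integer",
                   converged = "logical", finalRSS = "numeric"))

setValidity("EPMFit", function(object) {
    msg <- character()
    if (!(object@model %in% c("MC", "EPM")))
        msg <- c(msg, "model must be 'MC' or 'EPM'")
    if (length(object@eAges) != length(object@chronoAges))
        msg <- c(msg, "eAges and chronoAges must have equal length")
    if (length(object@rssTrace) < 1L || any(object@rssTrace < -1e-12))
        msg <- c(msg, "rssTrace must be non-empty and non-negative")
    if (any(diff(object@rssTrace) > 1e-8 * (1 + object@rssTrace[1L])))
        msg <- c(msg, "rssTrace must be non-increasing")
    if (length(object@finalRSS) != 1L ||
        abs(object@finalRSS - object@rssTrace[length(object@rssTrace)]) >
            1e-12 * (1 + abs(object@finalRSS)))
        msg <- c(msg, "finalRSS must equal the last rssTrace entry")
    if (length(msg)) msg else TRUE
})

#' LRTResult: likelihood-ratio test between the MC and EPM fits
#'
#' The molecular clock is nested in the pacemaker model (fix every epigenetic
#' age at its chronological value), so the models are compared with a
#' likelihood-ratio test. Under the Gaussian noise model the statistic reduces
#' to \eqn{\chi^2 = nm \log(RSS_{MC} / RSS_{EPM})} with degrees of freedom
#' equal to the number of time parameters freed under the pacemaker model,
#' i.e. the number of individuals \eqn{m}.
#'
#' @slot chi2 numeric(1), the test statistic (can be `Inf` when the EPM fit is
#'   exact).
#' @slot df integer(1), degrees of freedom.
#' @slot pValue numeric(1), upper-tail chi-squared probability.
#' @slot rssMC,rssEPM numeric(1), the two residual sums of squares.
#' @slot n,m integer(1), number of sites and individuals.
#' @seealso [likelihoodRatioTest()], [compareModels()]
#' @exportClass LRTResult
setClass("LRTResult",
    representation(chi2 = "numeric", df = "integer", pValue = "numeric",
                   rssMC = "numeric", rssEPM = "numeric",
                   n = "integer", m = "integer"))

setValidity("LRTResult", function(object) {
    msg <- character()
    if (length(object@chi2) != 1L || (is.finite(object@chi2) && object@chi2 < -1e-9))
        msg <- c(msg, "chi2 must be a single non-negative number")
    if (length(object@df) != 1L || object@df < 1L)
        msg <- c(msg, "df must be a single positive integer")
    if (length(object@pValue) != 1L || object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
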