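#' Construct a MethylationExperiment
#'
#' Builds the package's central container from a sites-by-individuals numeric
#' matrix and, optionally, a vector of chronological ages. Row and column
#' names of `values` supply the identifiers; `siteIds` / `individualIds`
#' override them.
#'
#' @param values numeric matrix, n sites (rows) by m individuals (columns),
#'   complete (no missing entries).
#' @param ages optional numeric vector of length m with each individual's
#'   chronological age (any real time unit; 0 and negative values, e.g.
#'   gestational ages, are allowed). May be named, in which case names must
#'   match the individual ids and are used to align the vector.
#' @param siteIds,individualIds optional character identifiers; default to the
#'   dimnames of `values`, or `site1..n` / `ind1..m` when absent.
#'
#' @return A [MethylationExperiment-class] object.
#' @examples
#' vals <- matrix(runif(6), 2, 3)
#' me <- MethylationExperiment(vals, ages = c(10, 20, 30))
#' methLevels(me)
#' ages(me)
#' @export
MethylationExperiment <- function(values, ages = NULL, siteIds = NULL,
                                  individualIds = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(siteIds))
        siteIds <- rownames(values)
    if (is.null(siteIds))
        siteIds <- paste0("site", seq_len(nrow(values)))
    if (is.null(individualIds))
        individualIds <- colnames(values)
    if (is.null(individualIds))
        individualIds <- paste0("ind", seq_len(ncol(values)))
    dimnames(values) <- list(as.character(siteIds), as.character(individualIds))
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(ages)) {
        ages <- alignAges(ages, colnames(values))
        cd$age <- unname(ages)
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(methyl = values), colData = cd)
    new("MethylationExperiment", se)
}

## Accessor alias for use inside methods whose own formal argument is named
## `ages` (the formal would otherwise shadow the generic).
.agesOf <- function(x, required = TRUE) ages(x, required = required)

## Reorder a possibly-named age vector to a given id order; unnamed vectors
## are taken to be in order already.
alignAges <- function(ages, ids) {
    if (!is.numeric(ages))
        stop("'ages' must be numeric")
    if (!is.null(names(ages))) {
        missing <- setdiff(ids, names(ages))
        if (length(missing))
            stop("ages missing for individual(s): ",
                 paste(missing, collapse = ", "))
        ages <- ages[ids]
    } else if (length(ages) != length(ids)) {
        stop(sprintf("'ages' has length %d but there are %d individuals",
                     length(ages), length(ids)))
    }
    stats::setNames(as.numeric(ages), ids)
}

#' Access the methylation matrix
#'
#' Returns the sites-by-individuals matrix of observed methylation levels.
#'
#' @param x a [MethylationExperiment-class].
#' @param ... ignored.
#' @return numeric matrix with site rownames and individual colnames.
#' @rdname methLevels
#' @export
setMethod("methLevels", "MethylationExperiment", function(x, ...) {
    SummarizedExperiment::assay(x, "methyl")
})

#' Chronological ages of the individuals
#'
#' Gets or sets the `age` column of `colData`. The getter errors when no ages
#' have been attached (models cannot be fitted without them).
#'
#' @param x a [MethylationExperiment-class].
#' @param value numeric vector of ages (optionally named by individual id).
#' @param required logical(1); if `FALSE` the getter returns `NULL` instead of
#'   erroring when ages are absent.
#' @param ... ignored.
#' @return Named numeric vector of ages, in column order.
#' @rdname ages
#' @export
setMethod("ages", "MethylationExperiment", function(x, required = TRUE, ...) {
    cd <- SummarizedExperiment::colData(x)
    if (!("age" %in% colnames(cd))) {
        if (required)
            stop("no ages attached; use ages(x) <- ... or readAges()")
        return(NULL)
    }
    stats::setNames(as.numeric(cd$age), colnames(x))
})

#' @rdname ages
#' @export
setReplaceMethod("ages", "MethylationExperiment", function(x, value) {
    value <- alignAges(value, colnames(x))
    SummarizedExperiment::colData(x)$age <- unname(value)
    validObject(x)
    x
})

setMethod("show", "MethylationExperiment", function(object) {
    cat(sprintf("MethylationExperiment: %d sites x %d individuals\n",
                nrow(object), ncol(object)))
    a <- ages(object, required = FALSE)
    if (is.null(a)) {
        cat("  ages: <not attached>\n")
    } else {
        cat(sprintf("  ages: range [%.4g, %.4g]\n", min(a), max(a)))
    }
    v <- methLevels(object)
    cat(sprintf("  methylation levels: range [%.4g, %.4g]\n", min(v), max(v)))
})

#' Constructor for SiteParameters
#'
#' @param rates numeric vector of per-site rates \eqn{r_i}.
#' @param startStates numeric vector of per-site start states \eqn{s_i^0}.
#' @param siteIds optional character identifiers.
#' @return A [SiteParameters-class] object.
#' @examples
#' SiteParameters(rates = c(0.01, -0.02), startStates = c(0.5, 0.8))
#' @export
SiteParameters <- function(rates, startStates, siteIds = character()) {
    if (is.null(siteIds))
        siteIds <- character()
    new("SiteParameters", rates = as.numeric(rates),
        startStates = as.numeric(startStates),
        siteIds = as.character(siteIds))
}

#' Accessors for SiteParameters
#'
#' @param x a [SiteParameters-class] object.
#' @param ... ignored.
#' @return `rates()` and `startStates()` return numeric vectors, named by site
#'   id when ids are present.
#' @rdname SiteParameters-accessors
#' @export
setMethod("rates", "SiteParameters", function(x, ...) {
    out <- x@rates
    if (length(x@siteIds)) names(out) <- x@siteIds
    out
})

#' @rdname SiteParameters-accessors
#' @export
setMethod("startStates", "SiteParameters", function(x, ...) {
    out <- x@startStates
    if (length(x@siteIds)) names(out) <- x@siteIds
    out
})

setMethod("length", "SiteParameters", function(x) length(x@rates))

setMethod("show", "SiteParameters", function(object) {
    n <- length(object)
    cat(sprintf("SiteParameters for %d site%s\n", n, if (n == 1L) "" else "s"))
    if (n) {
        cat(sprintf("  rates:        median %.4g, range [%.4g, %.4g]\n",
                    stats::median(object@rates), min(object@rates),
                    max(object@rates)))
        cat(sprintf("  start states: median %.4g, range [%.4g, %.4g]\n",
                    stats::median(object@startStates), min(object@startStates),
                    max(object@startStates)))
    }
    mults <- S4Vectors::metadata(object)$multiplications
    if (!is.null(mults))
        cat(sprintf("  site-step scalar multiplications: %d\n", mults))
})

#' Accessors for EPMFit objects
#'
#' `eAges()` returns the estimated epigenetic ages; `rssTrace()` the residual
#' sum of squares after each conditional half-step; `ageAcceleration()` the
#' difference between epigenetic and chronological age (positive values mean
#' the individual's methylome looks older than its chronological age).
#'
#' @param x an [EPMFit-class] object.
#' @param ... ignored.
#' @return Numeric vectors; `rates(x)`/`startStates(x)` delegate to the
#'   embedded [SiteParameters-class].
#' @rdname EPMFit-accessors
#' @export
setMethod("eAges", "EPMFit", function(x, ...) x@eAges)

#' @rdname EPMFit-accessors
#' @export
setMethod("rssTrace", "EPMFit", function(x, ...) x@rssTrace)

#' @rdname EPMFit-accessors
#' @export
setMethod("ageAcceleration", "EPMFit", function(x, ...) {
    x@eAges - x@chronoAges
})

#' @rdname EPMFit-accessors
#' @export
setMethod("rates", "EPMFit", function(x, ...) rates(x@params))

#' @rdname EPMFit-accessors
#' @export
setMethod("startStates", "EPMFit", function(x, ...) startStates(x@params))

#' @rdname EPMFit-accessors
#' @param object an [EPMFit-class] object.
#' @export
setMethod("siteParameters", "EPMFit", function(x, ...) x@params)

setMethod("show", "EPMFit", function(object) {
    cat(sprintf("%s fit: %d sites, %d individuals\n", object@model,
                length(object@params), length(object@eAges)))
    cat(sprintf("  final RSS: %.6g after %d iteration%s (%s)\n",
                object@finalRSS, object@iterations,
                if (object@iterations == 1L) "" else "s",
                if (object@converged) "converged" else "iteration cap reached"))
    if (object@model == "EPM") {
        acc <- ageAcceleration(object)
        cat(sprintf("  age acceleration: median %.4g, range [%.4g, %.4g]\n",
                    stats::median(acc), min(acc), max(acc)))
    }
})

setMethod("show", "TimeMoments", function(object) {
    cat(sprintf("TimeMoments: m = %d, sum(t) = %.6g, sum(t^2) = %.6g, Lambda = %.6g\n",
                object@m, object@sumT, object@sumT2, object@lam))
})

setMethod("show", "SiteSelection", function(object) {
    k <- length(object@indices)
    cat(sprintf("SiteSelection: %d site%s ranked by %s Pearson correlation with age\n",
                k, if (k == 1L) "" else "s",
                if (object@signed) "signed" else "absolute"))
    if (k)
        cat(sprintf("  |r| range: [%.4g, %.4g]\n",
                    min(abs(object@correlations)), max(abs(object@correlations))))
})

setMethod("show", "LRTResult", function(object) {
    cat("Likelihood-ratio test: molecular clock (null) vs epigenetic pacemaker\n")
    cat(sprintf("  RSS_MC = %.6g, RSS_EPM = %.6g (n = %d sites, m = %d individuals)\n",
                object@rssMC, object@rssEPM, object@n, object@m))
    cat(sprintf("  chi-squared = %.6g on %d df, p = %.4g\n",
                object@chi2, object@df, object@pValue))
})
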