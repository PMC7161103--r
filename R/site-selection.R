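#' Select the sites most correlated with age
#'
#' Ranks sites by the Pearson correlation between their methylation levels
#' and the individuals' ages and keeps the top `k`. By default the absolute
#' correlation is used: sites that demethylate with age are as informative as
#' sites that methylate, and the models permit negative rates. Zero-variance
#' (constant) sites have undefined correlation and are never eligible. Ties
#' are broken by original site order, making the selection deterministic.
#'
#' Practical fits of methylation clocks typically restrict to a modest panel
#' of age-associated CpGs (on the order of 1000) selected exactly this way.
#'
#' @param x a [MethylationExperiment-class] or numeric matrix
#'   (sites x individuals).
#' @param ages numeric ages; taken from `ages(x)` when `x` is a
#'   `MethylationExperiment` and `ages` is missing.
#' @param k number of sites to keep; when `k` exceeds the number of eligible
#'   sites all eligible sites are returned.
#' @param signed logical(1); if `TRUE`, rank by signed correlation
#'   (largest positive first) instead of absolute value.
#' @param ... passed between methods.
#' @return A [SiteSelection-class] object.
#' @seealso [applySelection()]
#' @examples
#' sim <- simulateMC(n = 20, m = 15, seed = 1)
#' sel <- selectSites(sim$experiment, k = 5)
#' sel
#' @rdname selectSites
#' @export
setMethod("selectSites", signature(x = "matrix"),
    function(x, ages, k, signed = FALSE, ...) {
        stopifnot(is.numeric(x), is.numeric(ages), ncol(x) == length(ages))
        if (!is.numeric(k) || length(k) != 1L || k < 1)
            stop("'k' must be a single positive integer")
        k <- as.integer(k)
        sds <- apply(x, 1L, stats::sd)
        eligible <- which(sds > 0)
        if (!length(eligible))
            stop("all sites have zero variance; correlation with age is undefined")
        if (stats::sd(ages) == 0)
            stop("degenerate ages: all equal, correlation undefined")
        cors <- as.numeric(stats::cor(t(x[eligible, , drop = FALSE]), ages))
        key <- if (signed) cors else abs(cors)
        ord <- order(-key, eligible)          # ties: original site order
        keep <- ord[seq_len(min(k, length(ord)))]
        idx <- eligible[keep]
        ids <- rownames(x)
        new("SiteSelection", indices = idx, correlations = cors[keep],
            siteIds = if (is.null(ids)) as.character(idx) else ids[idx],
            signed = isTRUE(signed))
    })

#' @rdname selectSites
#' @export
setMethod("selectSites", signature(x = "MethylationExperiment"),
    function(x, ages, k, signed = FALSE, ...) {
        if (missing(ages))
            ages <- .agesOf(x)
        selectSites(methLevels(x), as.numeric(ages), k, signed = signed)
    })

#' Subset an experiment to the selected sites
#'
#' @param x a [MethylationExperiment-class].
#' @param selection a [SiteSelection-class] produced from `x`.
#' @return `x` restricted to the selected sites, in ranked order.
#' @export
applySelection <- function(x, selection) {
    stopifnot(is(x, "MethylationExperiment"), is(selection, "SiteSelection"))
    if (any(selection@indices > nrow(x)))
        stop("selection indices exceed the number of sites in 'x'")
    x[selection@indices, ]
}

#' Serialize selection metadata to JSON
#'
#' Writes a sidecar recording `k`, the ranking mode and the per-site
#' correlations, sufficient to audit or re-apply a selection.
#'
#' @param selection a [SiteSelection-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeSelectionJSON <- function(selection, path) {
    stopifnot(is(selection, "SiteSelection"))
    jsonlite::write_json(
        list(k = length(selection@indices),
             ranking = if (selection@signed) "signed" else "absolute",
             sites = data.frame(site_id = selection@siteIds,
                                index = selection@indices,
                                correlation = selection@correlations)),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
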