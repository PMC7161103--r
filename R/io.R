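## Delimiter detection: .csv => comma, anything else (.tsv/.txt) => tab.
detectSep <- function(path, sep = c("auto", "tab", "comma")) {
    sep <- match.arg(sep)
    switch(sep,
        tab = "\t",
        comma = ",",
        auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t")
}

#' Read a delimited methylation matrix
#'
#' Reads a tab- or comma-delimited table with a header row of identifiers and
#' a first column of identifiers into a [MethylationExperiment-class] in the
#' canonical sites-by-individuals orientation. When the file stores
#' individuals as rows, pass `orientation = "individuals_by_sites"` and the
#' table is transposed on read.
#'
#' Missing, empty or non-numeric cells are hard errors that name the first
#' offending (row id, column id) pair; the linear-Gaussian model underlying
#' the fits sums over every (site, individual) pair, so incomplete matrices
#' are rejected rather than imputed.
#'
#' @param path path to the delimited file.
#' @param orientation `"sites_by_individuals"` (default) or
#'   `"individuals_by_sites"`.
#' @param sep `"auto"` (by extension: `.csv` is comma, otherwise tab),
#'   `"tab"` or `"comma"`.
#' @return A [MethylationExperiment-class] (without ages attached).
#' @seealso [readAges()], [writeMethylationMatrix()]
#' @export
readMethylationMatrix <- function(path,
        orientation = c("sites_by_individuals", "individuals_by_sites"),
        sep = c("auto", "tab", "comma")) {
    orientation <- match.arg(orientation)
    delim <- detectSep(path, sep)
    raw <- utils::read.table(path, header = TRUE, sep = delim,
                             row.names = NULL, check.names = FALSE,
                             colClasses = "character", quote = "\"",
                             comment.char = "", stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("matrix file must have an id column plus at least one data column")
    rowIds <- raw[[1L]]
    colIds <- colnames(raw)[-1L]
    if (anyDuplicated(rowIds))
        stop("duplicate row id(s): ",
             paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
    if (anyDuplicated(colIds))
        stop("duplicate column id(s): ",
             paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
    cells <- as.matrix(raw[, -1L, drop = FALSE])
    blank <- !nzchar(trimws(cells)) | is.na(cells)
    if (any(blank)) {
        hit <- which(blank, arr.ind = TRUE)[1L, ]
        stop(sprintf("missing cell at row '%s', column '%s'",
                     rowIds[hit[1L]], colIds[hit[2L]]))
    }
    vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
    if (anyNA(vals)) {
        hit <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                     cells[hit[1L], hit[2L]], rowIds[hit[1L]], colIds[hit[2L]]))
    }
    dimnames(vals) <- list(rowIds, colIds)
    if (orientation == "individuals_by_sites")
        vals <- t(vals)
    MethylationExperiment(vals)
}

#' Read chronological ages aligned to a methylation matrix
#'
#' Reads a two-column delimited file (individual id, age) and returns the ages
#' reordered to the column order of `x`. Every individual in `x` must appear
#' exactly once; individuals in the file that are absent from `x` are dropped
#' with a warning.
#'
#' @param path path to the two-column file (header optional: a non-numeric
#'   second field on line one is treated as a header).
#' @param x a [MethylationExperiment-class] giving the required individuals
#'   and their order.
#' @param sep as in [readMethylationMatrix()].
#' @return Named numeric vector of ages in `colnames(x)` order.
#' @export
readAges <- function(path, x, sep = c("auto", "tab", "comma")) {
    stopifnot(is(x, "MethylationExperiment"))
    delim <- detectSep(path, sep)
    tab <- utils::read.table(path, header = FALSE, sep = delim,
                             colClasses = "character", quote = "\"",
                             comment.char = "", stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
        stop("age file must have two columns: individual id, age")
    if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab[1L, 2L]))))
        tab <- tab[-1L, , drop = FALSE]   # header row
    ids <- tab[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate individual id(s) in age file: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- suppressWarnings(as.numeric(tab[[2L]]))
    if (anyNA(vals))
        stop("non-numeric age for individual(s): ",
             paste(ids[is.na(vals)], collapse = ", "))
    wanted <- colnames(x)
    missing <- setdiff(wanted, ids)
    if (length(missing))
        stop("age file lacks individual(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(ids, wanted)
    if (length(extra))
        warning("dropping ", length(extra),
                " individual(s) absent from the matrix: ",
                paste(extra, collapse = ", "))
    stats::setNames(vals[match(wanted, ids)], wanted)
}

#' Read a methylation matrix together with its age table
#'
#' Convenience wrapper: [readMethylationMatrix()] followed by [readAges()],
#' returning a fit-ready object.
#'
#' @inheritParams readMethylationMatrix
#' @param agesPath path to the two-column age file.
#' @return A [MethylationExperiment-class] with ages attached.
#' @export
readMethylationExperiment <- function(path, agesPath,
        orientation = c("sites_by_individuals", "individuals_by_sites"),
        sep = c("auto", "tab", "comma")) {
    me <- readMethylationMatrix(path, orientation = orientation, sep = sep)
    ages(me) <- readAges(agesPath, me, sep = sep)
    me
}

#' Write a methylation matrix / age table to delimited text
#'
#' Values are serialized with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-for-bit.
#'
#' @param x a [MethylationExperiment-class].
#' @param path output file path (`.csv` selects comma under `sep = "auto"`).
#' @param sep as in [readMethylationMatrix()].
#' @return `path`, invisibly.
#' @rdname writeMethylationMatrix
#' @export
writeMethylationMatrix <- function(x, path, sep = c("auto", "tab", "comma")) {
    stopifnot(is(x, "MethylationExperiment"))
    delim <- detectSep(path, sep)
    vals <- methLevels(x)
    out <- cbind(site_id = rownames(vals),
                 as.data.frame(formatC(vals, digits = 17, format = "g"),
                               check.names = FALSE, optional = TRUE))
    utils::write.table(out, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeMethylationMatrix
#' @param ageVector optional named numeric vector; defaults to `ages(x)`.
#' @export
writeAges <- function(x, path, ageVector = NULL,
                      sep = c("auto", "tab", "comma")) {
    delim <- detectSep(path, sep)
    if (is.null(ageVector))
        ageVector <- ages(x)
    out <- data.frame(individual_id = names(ageVector),
                      age = formatC(ageVector, digits = 17, format = "g"))
    utils::write.table(out, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
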