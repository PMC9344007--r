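#' Read spectra from CSV
#'
#' Two dialects are supported, both plain comma-separated text with an
#' optional `#` comment header:
#' \describe{
#'   \item{two-column}{columns `wavenumber,intensity`; one spectrum per file,
#'     named after the file.}
#'   \item{matrix}{first column `wavenumber`, one column per sample; shared
#'     axis.}
#' }
#' Rows are sorted by wavenumber if needed (a descending export is common in
#' Raman software); duplicated wavenumbers, ragged rows and non-numeric cells
#' are errors that name the offending row/column. No partial result is ever
#' returned.
#'
#' @param path file to read.
#' @param dialect `"auto"` (default: two-column iff exactly the columns
#'   `wavenumber,intensity`), `"two-column"` or `"matrix"`.
#' @return a [SpectrumSet-class] (no concentration/group metadata; see
#'   [attachMetadata()]).
#' @seealso [writeSpectra()], [readSampleMetadata()]
#' @export
readSpectra <- function(path, dialect = c("auto", "two-column", "matrix")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path))
        stop("file not found: ", path)
    nf <- utils::count.fields(path, sep = ",", comment.char = "#")
    if (length(unique(nf)) > 1L)
        stop("ragged matrix in ", path, ": rows have ",
             paste(unique(nf), collapse = ", "), " fields")
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
    if (ncol(df) < 1L)
        stop("no columns found in ", path)
    if (dialect == "auto")
        dialect <- if (identical(tolower(names(df)),
                                 c("wavenumber", "intensity")))
            "two-column" else "matrix"
    if (dialect == "two-column" && ncol(df) != 2L)
        stop("two-column dialect expects exactly 2 columns, found ", ncol(df))
    num <- lapply(seq_along(df), function(j) {
        v <- suppressWarnings(as.numeric(df[[j]]))
        bad <- which(is.na(v) & !(trimws(df[[j]]) %in% c("NA", "")))
        blank <- which(trimws(df[[j]]) == "" | is.na(df[[j]]))
        bad <- sort(unique(c(bad, blank)))
        if (length(bad))
            stop("non-numeric value '", df[[j]][bad[1]], "' at data row ",
                 bad[1], ", column '", names(df)[j], "' of ", path)
        v
    })
    wn <- num[[1]]
    ints <- if (ncol(df) > 1L)
        do.call(cbind, num[-1]) else matrix(numeric(0), length(wn), 0L)
    if (anyDuplicated(wn))
        stop("duplicated wavenumbers in ", path)
    if (length(wn) && is.unsorted(wn)) {
        o <- order(wn)
        if (all(o == rev(seq_along(wn))))
            message("wavenumber axis is descending; reversing")
        else
            message("wavenumber axis is unordered; sorting")
        wn <- wn[o]
        ints <- ints[o, , drop = FALSE]
    }
    ids <- if (dialect == "two-column")
        sub("\\.[^.]*$", "", basename(path)) else names(df)[-1]
    if (length(wn) == 0L)
        return(SpectrumSet(matrix(numeric(0), 0L, 0L), numeric(0)))
    SpectrumSet(ints, wn, sampleIds = ids)
}

#' Write a SpectrumSet to matrix CSV
#'
#' Writes `wavenumber` plus one column per sample, at full double precision so
#' that `readSpectra(writeSpectra(x))` reproduces the values exactly. An empty
#' set yields a header-only file.
#'
#' @param set a [SpectrumSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(set, path) {
    stopifnot(is(set, "SpectrumSet"))
    methods::validObject(set)
    header <- paste(c("wavenumber", colnames(set)), collapse = ",")
    fmt <- function(x) sub("^\\s+", "", sprintf("%.17g", x))
    rows <- if (nrow(set) > 0L) {
        cells <- cbind(fmt(wavenumbers(set)),
                       if (ncol(set) > 0L) apply(intensities(set), 2, fmt))
        apply(matrix(cells, nrow = nrow(set)), 1, paste, collapse = ",")
    } else character(0)
    con <- tryCatch(file(path, "w"), error = function(e)
        stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
    on.exit(close(con))
    writeLines(c(header, rows), con)
    invisible(path)
}

#' Read a sample-metadata table
#'
#' Expects columns `sample_id,concentration,unit,group` (`unit` and `group`
#' optional). Used with [attachMetadata()] to annotate spectra read from a
#' matrix CSV.
#'
#' @param path CSV file.
#' @return a `data.frame`.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
    need <- c("sample_id", "concentration")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
    df$concentration <- suppressWarnings(as.numeric(df$concentration))
    df
}

#' Attach sample metadata to a SpectrumSet
#'
#' Joins by exact `sample_id` string match; spectra whose id is absent from
#' the metadata are an error (all missing ids are listed).
#'
#' @param set a [SpectrumSet-class].
#' @param meta a `data.frame` as returned by [readSampleMetadata()].
#' @return the annotated `SpectrumSet`.
#' @export
attachMetadata <- function(set, meta) {
    stopifnot(is(set, "SpectrumSet"), is.data.frame(meta))
    idx <- match(colnames(set), meta$sample_id)
    if (anyNA(idx))
        stop("sample ids missing from metadata: ",
             paste(colnames(set)[is.na(idx)], collapse = ", "))
    SummarizedExperiment::colData(set)$concentration <-
        meta$concentration[idx]
    if (!is.null(meta$group))
        SummarizedExperiment::colData(set)$group <-
            as.character(meta$group[idx])
    if (!is.null(meta$unit)) {
        u <- unique(meta$unit[idx])
        S4Vectors::metadata(set)$concentrationUnit <-
            if (length(u) == 1L) u else NA_character_
    }
    methods::validObject(set)
    set
}
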