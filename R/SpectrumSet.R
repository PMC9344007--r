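#' Construct a SpectrumSet
#'
#' Builds a [SpectrumSet-class] from an intensity matrix (wavenumber points in
#' rows, samples in columns) or a single intensity vector. A wavenumber axis
#' given in descending order is reversed (with the intensity rows kept
#' paired); a non-monotone axis is an error.
#'
#' @param intensities numeric matrix (rows = wavenumber points, columns =
#'   samples) or a vector for a single spectrum.
#' @param wavenumbers numeric vector of Raman shifts in cm\eqn{^{-1}}, one per
#'   row of `intensities`.
#' @param sampleIds character vector of sample labels; defaults to the column
#'   names of `intensities` or `"sample_1"`, ... .
#' @param concentrations optional per-sample analyte concentrations
#'   (non-negative; `NA` allowed).
#' @param groups optional per-sample replicate-group labels.
#' @param unit concentration unit recorded in the object metadata
#'   (e.g. `"ug/mL"`, `"ug/g"`).
#' @return a `SpectrumSet`.
#' @examples
#' s <- SpectrumSet(matrix(rnorm(20), 10, 2), wavenumbers = 551:560)
#' wavenumbers(s)
#' @export
SpectrumSet <- function(intensities, wavenumbers,
                        sampleIds = NULL, concentrations = NULL,
                        groups = NULL, unit = NA_character_) {
    if (is.vector(intensities))
        intensities <- matrix(intensities, ncol = 1L)
    intensities <- as.matrix(intensities)
    storage.mode(intensities) <- "double"
    wavenumbers <- as.numeric(wavenumbers)
    if (length(wavenumbers) != nrow(intensities))
        stop("length of 'wavenumbers' (", length(wavenumbers),
             ") does not match the number of intensity rows (",
             nrow(intensities), ")")
    if (length(wavenumbers) >= 2L && all(diff(wavenumbers) < 0)) {
        message("wavenumber axis is descending; reversing")
        wavenumbers <- rev(wavenumbers)
        intensities <- intensities[rev(seq_len(nrow(intensities))), ,
                                   drop = FALSE]
    }
    if (is.null(sampleIds))
        sampleIds <- colnames(intensities)
    if (is.null(sampleIds) && ncol(intensities) > 0L)
        sampleIds <- paste0("sample_", seq_len(ncol(intensities)))
    colnames(intensities) <- sampleIds
    rownames(intensities) <- NULL
    cd <- S4Vectors::DataFrame(
        sample_id = as.character(sampleIds %||% character(0)),
        row.names = sampleIds
    )
    cd$concentration <- if (is.null(concentrations))
        rep(NA_real_, ncol(intensities)) else as.numeric(concentrations)
    cd$group <- if (is.null(groups))
        rep(NA_character_, ncol(intensities)) else as.character(groups)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensities),
        rowData = S4Vectors::DataFrame(wavenumber = wavenumbers),
        colData = cd,
        metadata = list(concentrationUnit = unit)
    )
    methods::new("SpectrumSet", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname SpectrumSet
#' @export
setMethod("wavenumbers", "SpectrumSet", function(x)
    SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname SpectrumSet
#' @export
setMethod("intensities", "SpectrumSet", function(x)
    SummarizedExperiment::assay(x, "intensity"))

#' @rdname SpectrumSet
#' @export
setMethod("concentrations", "SpectrumSet", function(x)
    SummarizedExperiment::colData(x)$concentration)

#' @rdname SpectrumSet
#' @export
setMethod("replicateGroups", "SpectrumSet", function(x)
    SummarizedExperiment::colData(x)$group)

#' @rdname SpectrumSet
#' @export
setMethod("concentrationUnit", "SpectrumSet", function(x)
    S4Vectors::metadata(x)$concentrationUnit)

setMethod("show", "SpectrumSet", function(object) {
    wn <- wavenumbers(object)
    cat("SpectrumSet with", ncol(object), "spectra of", nrow(object),
        "points\n")
    if (nrow(object) > 0)
        cat("  axis:", min(wn), "-", max(wn), "cm^-1\n")
    conc <- concentrations(object)
    if (any(!is.na(conc)))
        cat("  concentrations:", paste(format(sort(unique(conc[!is.na(conc)])),
            trim = TRUE), collapse = ", "),
            concentrationUnit(object), "\n")
})

#' Intensity at the axis point nearest a wavenumber
#'
#' Convenience accessor for calibration work: returns, for every sample, the
#' intensity at the grid point closest to `at` (e.g. the 1379 cm\eqn{^{-1}}
#' quantitation band of thiram).
#'
#' @param set a [SpectrumSet-class].
#' @param at target wavenumber in cm\eqn{^{-1}}.
#' @return named numeric vector, one value per sample.
#' @export
peakHeight <- function(set, at) {
    stopifnot(is(set, "SpectrumSet"), length(at) == 1L, is.finite(at))
    i <- which.min(abs(wavenumbers(set) - at))
    intensities(set)[i, ]
}
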