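#' @rdname SpectrumSet
#' @param x a `SpectrumSet` (or other object with methods below).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectrumSet
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname SpectrumSet
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname SpectrumSet
#' @export
setGeneric("replicateGroups", function(x) standardGeneric("replicateGroups"))

#' @rdname SpectrumSet
#' @export
setGeneric("concentrationUnit", function(x) standardGeneric("concentrationUnit"))

#' @rdname KPCAModel-class
#' @param x a fitted model object.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname KPCAModel-class
#' @export
setGeneric("explainedRatio", function(x) standardGeneric("explainedRatio"))

#' @rdname SplitResult-class
#' @param x a `SplitResult`.
#' @export
setGeneric("calibrationIds", function(x) standardGeneric("calibrationIds"))

#' @rdname SplitResult-class
#' @export
setGeneric("predictionIds", function(x) standardGeneric("predictionIds"))

#' @rdname SplitResult-class
#' @export
setGeneric("distancesLog", function(x) standardGeneric("distancesLog"))

#' @rdname CalibrationCurve-class
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
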