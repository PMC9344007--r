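#' @import methods
#' @importFrom stats coef fitted lm lm.fit predict sd var
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SpectrumSet: a collection of Raman spectra on a shared wavenumber axis
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] with an
#' `"intensity"` assay whose rows are wavenumber points (cm\eqn{^{-1}},
#' strictly ascending, recorded in `rowData(x)$wavenumber`) and whose columns
#' are samples. Per-sample analyte concentration and replicate-group labels
#' live in `colData`; the concentration unit is kept in
#' `metadata(x)$concentrationUnit`.
#'
#' Validity requires: a numeric, finite, strictly ascending wavenumber axis of
#' length at least 2 (an empty set with zero samples and zero rows is
#' permitted), all-finite intensities (negative values are allowed, e.g. after
#' derivative or baseline steps), and non-negative concentrations where
#' present.
#'
#' @seealso [SpectrumSet()] for the constructor, [readSpectra()],
#'   [generateStudy()]
#' @aliases SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

.validSpectrumSet <- function(object) {
    msg <- NULL
    if (!("intensity" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'intensity' is missing")
    if (ncol(object) == 0L && nrow(object) == 0L)
        return(TRUE)
    wn <- SummarizedExperiment::rowData(object)$wavenumber
    if (is.null(wn))
        return("rowData must contain a 'wavenumber' column")
    if (!is.numeric(wn) || any(!is.finite(wn)))
        msg <- c(msg, "wavenumbers must be numeric and finite")
    if (length(wn) < 2L)
        msg <- c(msg, "a spectrum needs at least 2 wavenumber points")
    if (length(wn) >= 2L && any(diff(wn) <= 0))
        msg <- c(msg, "wavenumbers must be strictly ascending")
    ints <- SummarizedExperiment::assay(object, "intensity")
    if (any(!is.finite(ints)))
        msg <- c(msg, "intensities must all be finite")
    conc <- SummarizedExperiment::colData(object)$concentration
    if (!is.null(conc) && any(!is.na(conc) & conc < 0))
        msg <- c(msg, "concentrations must be non-negative")
    if (is.null(msg)) TRUE else msg
}

setValidity("SpectrumSet", .validSpectrumSet)

#' Fitted kernel principal component analysis model
#'
#' Holds the training feature matrix, the kernel and its width \eqn{\sigma},
#' the raw and double-centered Gram matrices, the retained eigenvalues
#' \eqn{\lambda_k} (descending, non-negative), the coefficient vectors
#' \eqn{\alpha_k} scaled so that \eqn{\lambda_k (\alpha_k \cdot \alpha_k) = 1}
#' (unit-norm feature-space eigenvectors), the training scores and the
#' per-component explained-variance ratios.
#'
#' @slot trainingFeatures numeric matrix, samples in rows.
#' @slot kernel `"rbf"` or `"linear"`.
#' @slot sigma RBF width (same units as feature Euclidean distances;
#'   `NA` for the linear kernel).
#' @slot kernelMatrix,centeredKernel raw and centered M x M Gram matrices.
#' @slot eigenvalues retained eigenvalues, descending.
#' @slot coefficients M x k matrix of alpha vectors (columns).
#' @slot scores M x k matrix of training projections.
#' @slot explainedRatio fraction of total non-negative eigenvalue mass per
#'   retained component.
#' @seealso [kpcaFit()], [kpcaTransform()]
#' @aliases KPCAModel-class
#' @exportClass KPCAModel
setClass("KPCAModel",
    representation(
        trainingFeatures = "matrix",
        kernel = "character",
        sigma = "numeric",
        kernelMatrix = "matrix",
        centeredKernel = "matrix",
        eigenvalues = "numeric",
        coefficients = "matrix",
        scores = "matrix",
        explainedRatio = "numeric"
    )
)

.validKPCAModel <- function(object) {
    msg <- NULL
    K <- object@kernelMatrix
    M <- nrow(K)
    if (M != ncol(K))
        msg <- c(msg, "kernel matrix must be square")
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
        msg <- c(msg, "kernel matrix must be symmetric")
    if (identical(object@kernel, "rbf") && M > 0 &&
        max(abs(diag(K) - 1)) > 1e-8)
        msg <- c(msg, "RBF kernel matrix must have unit diagonal")
    Kc <- object@centeredKernel
    if (M > 0 && max(abs(rowSums(Kc))) > 1e-9 * M * max(1, max(abs(K))))
        msg <- c(msg, "centered kernel rows must sum to 0")
    ev <- object@eigenvalues
    if (length(ev) > 1 && any(diff(ev) > 0))
        msg <- c(msg, "eigenvalues must be sorted descending")
    if (length(ev) > 0 && min(ev) < -1e-9 * max(abs(ev)))
        msg <- c(msg, "retained eigenvalues must be non-negative")
    if (is.null(msg)) TRUE else msg
}

setValidity("KPCAModel", .validKPCAModel)

#' Regression model mapping feature vectors to concentration
#'
#' Linear predictor \eqn{\hat y = X b + b_0} fitted either by NIPALS PLS1
#' (`method = "pls"`), ordinary least squares (`method = "mlr"`), or as the
#' intercept-only mean model (`method = "mean"`).
#'
#' @slot method `"pls"`, `"mlr"` or `"mean"`.
#' @slot coefficients regression coefficient vector (length = features).
#' @slot intercept scalar intercept.
#' @slot nLatent latent-variable count (PLS; 0 otherwise).
#' @slot xMeans,yMean centering statistics from the training data.
#' @seealso [plsFit()], [mlrFit()]
#' @aliases RegressionModel-class
#' @exportClass RegressionModel
setClass("RegressionModel",
    representation(
        method = "character",
        coefficients = "numeric",
        intercept = "numeric",
        nLatent = "integer",
        xMeans = "numeric",
        yMean = "numeric"
    )
)

#' Peak-intensity calibration curve
#'
#' Ordinary least-squares line \eqn{I = slope \cdot N + intercept} relating a
#' characteristic peak intensity \eqn{I} (a.u.) to analyte concentration
#' \eqn{N}, with goodness of fit \eqn{r^2} (squared Pearson correlation of
#' fitted vs observed, in \[0, 1\]).
#'
#' @slot slope a.u. per concentration unit.
#' @slot intercept a.u.
#' @slot rSquared coefficient of determination.
#' @slot n number of calibration points.
#' @seealso [fitCalibration()], [lod()]
#' @aliases CalibrationCurve-class
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
    representation(
        slope = "numeric",
        intercept = "numeric",
        rSquared = "numeric",
        n = "integer"
    )
)

.validCalibrationCurve <- function(object) {
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
        "rSquared must lie in [0, 1]" else TRUE
}

setValidity("CalibrationCurve", .validCalibrationCurve)

#' Result of a max-min calibration/prediction split
#'
#' @slot calibrationIds ordered ids selected into the calibration set.
#' @slot predictionIds remaining ids, in input order.
#' @slot distancesLog the selected distance at each pick (named by id):
#'   distance to the mean spectrum for the two seed picks, minimum distance to
#'   the current calibration set afterwards.
#' @seealso [maxminSplit()]
#' @aliases SplitResult-class
#' @exportClass SplitResult
setClass("SplitResult",
    representation(
        calibrationIds = "character",
        predictionIds = "character",
        distancesLog = "numeric"
    )
)

.validSplitResult <- function(object) {
    if (length(intersect(object@calibrationIds, object@predictionIds)) > 0)
        "calibration and prediction sets must be disjoint" else TRUE
}

setValidity("SplitResult", .validSplitResult)
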