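#' Preprocessing configuration
#'
#' Parameters for the spectral preprocessing chain: Savitzky-Golay smoothing,
#' baseline correction, Savitzky-Golay derivatives and feature-range
#' extraction. Defaults: window 9 points / polynomial order 3 (preserves
#' Raman peak heights better than a moving average at this bandwidth),
#' iterative-polynomial baseline of degree 5, derivative order 0 (off), and
#' the feature ranges 653-683, 705-728 and 847-872 cm\eqn{^{-1}}.
#'
#' @param smoothWindow odd integer window length (points).
#' @param smoothPolyorder polynomial order, < `smoothWindow`.
#' @param baselineMethod `"modpoly"` (iterative polynomial, default) or
#'   `"als"` (asymmetric least squares).
#' @param baselineDegree polynomial degree for modpoly.
#' @param baselineMaxIter,baselineTol modpoly iteration cap and relative
#'   convergence tolerance.
#' @param alsLambda,alsP ALS smoothness penalty and asymmetry weight.
#' @param derivativeOrder 0 (none), 1 or 2.
#' @param featureRanges list of closed `c(lo, hi)` wavenumber intervals,
#'   non-overlapping.
#' @return a validated `PreprocessConfig` list.
#' @export
preprocessConfig <- function(smoothWindow = 9L, smoothPolyorder = 3L,
                             baselineMethod = c("modpoly", "als"),
                             baselineDegree = 5L,
                             baselineMaxIter = 50L, baselineTol = 1e-4,
                             alsLambda = 3e4, alsP = 0.005,
                             derivativeOrder = 0L,
                             featureRanges = defaultFeatureRanges()) {
    baselineMethod <- match.arg(baselineMethod)
    smoothWindow <- as.integer(smoothWindow)
    smoothPolyorder <- as.integer(smoothPolyorder)
    if (smoothWindow %% 2L == 0L)
        stop("'smoothWindow' must be odd")
    if (smoothWindow <= smoothPolyorder)
        stop("'smoothWindow' must exceed 'smoothPolyorder'")
    if (!derivativeOrder %in% c(0L, 1L, 2L))
        stop("'derivativeOrder' must be 0, 1 or 2")
    .checkRanges(featureRanges)
    structure(list(
        smoothWindow = smoothWindow, smoothPolyorder = smoothPolyorder,
        baselineMethod = baselineMethod, baselineDegree = baselineDegree,
        baselineMaxIter = as.integer(baselineMaxIter),
        baselineTol = baselineTol,
        alsLambda = alsLambda, alsP = alsP,
        derivativeOrder = as.integer(derivativeOrder),
        featureRanges = featureRanges
    ), class = "PreprocessConfig")
}

#' @rdname preprocessConfig
#' @export
defaultFeatureRanges <- function() {
    list(c(653, 683), c(705, 728), c(847, 872))
}

.checkRanges <- function(ranges) {
    stopifnot(is.list(ranges), length(ranges) >= 1L)
    for (r in ranges)
        if (length(r) != 2L || !is.numeric(r) || r[1] > r[2])
            stop("each feature range must be a numeric c(lo, hi) with ",
                 "lo <= hi")
    o <- order(vapply(ranges, `[`, numeric(1), 1L))
    sorted <- ranges[o]
    for (i in seq_len(length(sorted) - 1L))
        if (sorted[[i]][2] >= sorted[[i + 1L]][1])
            stop("feature ranges must not overlap")
    invisible(ranges)
}

#' Average spectra within replicate groups
#'
#' Returns one arithmetic-mean spectrum per group on the unchanged axis. The
#' per-group concentration is kept when it is constant within the group, `NA`
#' otherwise.
#'
#' @param set a [SpectrumSet-class].
#' @param by per-sample group labels; defaults to `replicateGroups(set)`.
#' @return a `SpectrumSet` with one column per group.
#' @export
averageSpectra <- function(set, by = replicateGroups(set)) {
    stopifnot(is(set, "SpectrumSet"))
    if (ncol(set) == 0L)
        stop("cannot average an empty SpectrumSet")
    by <- as.character(by)
    if (length(by) != ncol(set) || anyNA(by))
        stop("'by' must provide a non-missing group label for every sample")
    groups <- unique(by)
    ints <- intensities(set)
    conc <- concentrations(set)
    m <- vapply(groups, function(g)
        rowMeans(ints[, by == g, drop = FALSE]), numeric(nrow(set)))
    gconc <- vapply(groups, function(g) {
        u <- unique(conc[by == g])
        if (length(u) == 1L) u else NA_real_
    }, numeric(1))
    SpectrumSet(m, wavenumbers(set), sampleIds = groups,
                concentrations = gconc, groups = groups,
                unit = concentrationUnit(set))
}

.applyColumns <- function(set, f) {
    out <- set
    ints <- intensities(set)
    SummarizedExperiment::assay(out, "intensity") <-
        matrix(apply(ints, 2, f), nrow = nrow(ints),
               dimnames = dimnames(ints))
    out
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing of every spectrum; the axis is
#' unchanged. Endpoints are handled by the filter's built-in polynomial
#' extrapolation rows; exactness guarantees (polynomials of degree
#' `<= polyorder` pass through unchanged) hold at interior points.
#'
#' @param set a [SpectrumSet-class].
#' @param window odd window length in points, `polyorder < window <= nrow(set)`.
#' @param polyorder fitting polynomial order.
#' @return the smoothed `SpectrumSet`.
#' @export
smoothSpectra <- function(set, window = 9L, polyorder = 3L) {
    stopifnot(is(set, "SpectrumSet"))
    window <- as.integer(window)
    polyorder <- as.integer(polyorder)
    if (window %% 2L == 0L)
        stop("'window' must be odd")
    if (window <= polyorder)
        stop("'window' must exceed 'polyorder'")
    if (window > nrow(set))
        stop("'window' exceeds the axis length")
    .applyColumns(set, function(y)
        signal::sgolayfilt(y, p = polyorder, n = window, m = 0))
}

#' Baseline estimation and correction
#'
#' `estimateBaseline()` returns the smooth background estimate;
#' `correctBaseline()` subtracts it. Two estimators:
#' \describe{
#'   \item{modpoly}{iterative polynomial fitting: fit a degree-`d` polynomial,
#'     clip the working spectrum to the fit wherever it lies above it, refit;
#'     stops when the fitted baseline changes by less than `baselineTol`
#'     (relative) or after `baselineMaxIter` iterations. Robust default for
#'     fluorescence backgrounds under narrow Raman bands.}
#'   \item{als}{asymmetric least squares (Whittaker smoother with asymmetric
#'     weights `alsP` above / `1 - alsP` below the estimate and second-order
#'     difference penalty `alsLambda`).}
#' }
#'
#' @param set a [SpectrumSet-class].
#' @param config a [preprocessConfig()].
#' @return a `SpectrumSet` of baselines (`estimateBaseline`) or of corrected
#'   spectra (`correctBaseline`).
#' @export
correctBaseline <- function(set, config = preprocessConfig()) {
    bl <- estimateBaseline(set, config)
    out <- set
    SummarizedExperiment::assay(out, "intensity") <-
        intensities(set) - intensities(bl)
    out
}

#' @rdname correctBaseline
#' @export
estimateBaseline <- function(set, config = preprocessConfig()) {
    stopifnot(is(set, "SpectrumSet"), inherits(config, "PreprocessConfig"))
    nu <- wavenumbers(set)
    f <- switch(config$baselineMethod,
        modpoly = function(y) .modpoly(nu, y, config$baselineDegree,
                                       config$baselineMaxIter,
                                       config$baselineTol),
        als = function(y) .alsBaseline(y, config$alsLambda, config$alsP))
    .applyColumns(set, f)
}

.modpoly <- function(nu, y, degree, maxIter, tol) {
    basis <- stats::poly(nu, degree = degree)
    work <- y
    fit <- rep(mean(y), length(y))
    for (i in seq_len(maxIter)) {
        coefs <- lm.fit(cbind(1, basis), work)
        new <- coefs$fitted.values
        delta <- sqrt(mean((new - fit)^2))
        fit <- new
        work <- pmin(work, fit)
        if (delta <= tol * max(1e-12, sqrt(mean(fit^2)))) break
    }
    fit
}

.alsBaseline <- function(y, lambda, p, nIter = 20L) {
    n <- length(y)
    D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                            diagonals = list(rep(1, n - 2L),
                                             rep(-2, n - 2L),
                                             rep(1, n - 2L)))
    P <- lambda * Matrix::crossprod(D)
    w <- rep(1, n)
    z <- y
    for (i in seq_len(nIter)) {
        W <- Matrix::Diagonal(n, w)
        z <- as.numeric(Matrix::solve(W + P, w * y))
        wNew <- ifelse(y > z, p, 1 - p)
        if (all(wNew == w)) break
        w <- wNew
    }
    z
}

#' Savitzky-Golay derivative with respect to wavenumber
#'
#' First- or second-order derivative computed with a Savitzky-Golay filter
#' (smoothing and differentiation in one least-squares step, since plain
#' differencing amplifies noise). A constant offset maps to zero under order
#' 1; a linear ramp maps to zero under order 2 — the classic use of
#' derivatives to remove constant and linearly sloped drift.
#'
#' @param set a [SpectrumSet-class] on an evenly spaced axis.
#' @param order derivative order, 1 or 2.
#' @param window,polyorder Savitzky-Golay parameters (see [smoothSpectra()]);
#'   `polyorder` must be at least `order`.
#' @return the differentiated `SpectrumSet` (units a.u. per
#'   cm\eqn{^{-1}}\eqn{{}^{order}}).
#' @export
derivativeSpectra <- function(set, order, window = 9L, polyorder = 3L) {
    stopifnot(is(set, "SpectrumSet"))
    if (!order %in% c(1L, 2L))
        stop("'order' must be 1 or 2")
    window <- as.integer(window)
    polyorder <- as.integer(polyorder)
    if (window %% 2L == 0L)
        stop("'window' must be odd")
    if (window <= polyorder || polyorder < order)
        stop("need order <= 'polyorder' < 'window'")
    steps <- diff(wavenumbers(set))
    if (max(steps) - min(steps) > 1e-8 * mean(steps))
        stop("derivatives require an evenly spaced wavenumber axis")
    ts <- mean(steps)
    .applyColumns(set, function(y)
        signal::sgolayfilt(y, p = polyorder, n = window, m = as.integer(order),
                           ts = ts))
}

#' Extract feature-range intensities
#'
#' Concatenates, in axis order, the intensities at points whose wavenumber
#' falls inside any of the closed intervals `ranges` (boundary points
#' included). Every range must intersect the axis.
#'
#' @param set a [SpectrumSet-class].
#' @param ranges list of `c(lo, hi)` intervals; default
#'   [defaultFeatureRanges()].
#' @return a samples x points feature matrix with the matching wavenumbers in
#'   `attr(, "wavenumbers")` and as column names.
#' @examples
#' cfg <- generatorConfig(noiseRsd = 0)
#' X <- extractRanges(generateSpectrum(cfg, 1))
#' dim(X)  # 1 x 81
#' @export
extractRanges <- function(set, ranges = defaultFeatureRanges()) {
    stopifnot(is(set, "SpectrumSet"))
    .checkRanges(ranges)
    nu <- wavenumbers(set)
    keep <- rep(FALSE, length(nu))
    for (r in ranges) {
        inside <- nu >= r[1] & nu <= r[2]
        if (!any(inside))
            stop("range [", r[1], ", ", r[2],
                 "] does not intersect the wavenumber axis")
        keep <- keep | inside
    }
    X <- t(intensities(set)[keep, , drop = FALSE])
    colnames(X) <- format(nu[keep], trim = TRUE)
    attr(X, "wavenumbers") <- nu[keep]
    X
}

#' Default preprocessing chain
#'
#' Applies, in order: optional replicate averaging, Savitzky-Golay smoothing,
#' baseline correction, and (if `derivativeOrder > 0`) the Savitzky-Golay
#' derivative. Range extraction is separate ([extractRanges()]) because it
#' changes the container from spectra to a feature matrix.
#'
#' @param set a [SpectrumSet-class].
#' @param config a [preprocessConfig()].
#' @param average average replicate groups first (default `FALSE`).
#' @return the preprocessed `SpectrumSet`.
#' @export
preprocessSpectra <- function(set, config = preprocessConfig(),
                              average = FALSE) {
    stopifnot(is(set, "SpectrumSet"), inherits(config, "PreprocessConfig"))
    if (average)
        set <- averageSpectra(set)
    set <- smoothSpectra(set, config$smoothWindow, config$smoothPolyorder)
    set <- correctBaseline(set, config)
    if (config$derivativeOrder > 0L)
        set <- derivativeSpectra(set, config$derivativeOrder,
                                 config$smoothWindow, config$smoothPolyorder)
    set
}
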