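#' NIPALS PLS1 regression
#'
#' Single-response partial least squares: X and y are column-centered, then
#' latent variables are extracted iteratively — weight vector
#' \eqn{w_a \propto E^\top f}, score \eqn{t_a = E w_a}, loading
#' \eqn{p_a = E^\top t_a / t_a^\top t_a}, response loading
#' \eqn{q_a = f^\top t_a / t_a^\top t_a} — with deflation of both blocks.
#' Regression coefficients are assembled as
#' \eqn{b = W (P^\top W)^{-1} q}, intercept \eqn{\bar y - \bar x^\top b}.
#' With the full number of latent variables on full-rank data, PLS1
#' predictions coincide with ordinary least squares. The algorithm is fully
#' deterministic. A constant response yields a zero coefficient vector (every
#' prediction is the training mean).
#'
#' @param X feature matrix, samples in rows.
#' @param y response (concentration) vector.
#' @param nLatent number of latent variables, `1 <= nLatent <=
#'   min(rank(X), n - 1)`.
#' @return a [RegressionModel-class].
#' @export
plsFit <- function(X, y, nLatent = 1L) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    n <- nrow(X)
    if (length(y) != n)
        stop("'y' must have one value per row of 'X'")
    nLatent <- as.integer(nLatent)
    xMeans <- colMeans(X)
    yMean <- mean(y)
    E <- sweep(X, 2, xMeans)
    f <- y - yMean
    rankX <- qr(E)$rank
    bound <- min(rankX, n - 1L)
    if (is.na(nLatent) || nLatent < 1L || nLatent > bound)
        stop("'nLatent' must lie in [1, ", bound,
             "] (min of rank(X) and n - 1)")
    W <- P <- matrix(0, ncol(X), nLatent)
    q <- numeric(nLatent)
    a <- 0L
    for (k in seq_len(nLatent)) {
        w <- drop(crossprod(E, f))
        nw <- sqrt(sum(w^2))
        if (nw < .Machine$double.eps^0.5) break  # no covariance left
        w <- w / nw
        t <- drop(E %*% w)
        tt <- sum(t^2)
        p <- drop(crossprod(E, t)) / tt
        qk <- sum(f * t) / tt
        E <- E - tcrossprod(t, p)
        f <- f - t * qk
        a <- k
        W[, k] <- w; P[, k] <- p; q[k] <- qk
    }
    b <- if (a == 0L) numeric(ncol(X)) else {
        Wa <- W[, seq_len(a), drop = FALSE]
        Pa <- P[, seq_len(a), drop = FALSE]
        drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
    }
    methods::new("RegressionModel",
                 method = "pls",
                 coefficients = stats::setNames(b, colnames(X)),
                 intercept = yMean - sum(xMeans * b),
                 nLatent = a,
                 xMeans = xMeans, yMean = yMean)
}

#' Multiple linear regression (ordinary least squares)
#'
#' Least-squares fit with intercept. Requires more samples than features and
#' a full-column-rank design; collinear or wide data should go through
#' [plsFit()] or KPCA score compression instead (the error says so).
#'
#' @param X feature matrix, samples in rows.
#' @param y response vector.
#' @return a [RegressionModel-class].
#' @export
mlrFit <- function(X, y) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    n <- nrow(X)
    if (length(y) != n)
        stop("'y' must have one value per row of 'X'")
    if (n <= ncol(X))
        stop("MLR needs more samples (", n, ") than features (", ncol(X),
             "); use PLS or KPCA scores instead")
    D <- cbind(`(Intercept)` = 1, X)
    qrD <- qr(D)
    if (qrD$rank < ncol(D))
        stop("design matrix is rank-deficient; use PLS or KPCA scores ",
             "instead")
    cf <- qr.coef(qrD, y)
    methods::new("RegressionModel",
                 method = "mlr",
                 coefficients = stats::setNames(cf[-1], colnames(X)),
                 intercept = unname(cf[1]),
                 nLatent = 0L,
                 xMeans = colMeans(X), yMean = mean(y))
}

.meanFit <- function(y) {
    methods::new("RegressionModel", method = "mean",
                 coefficients = numeric(0), intercept = mean(y),
                 nLatent = 0L, xMeans = numeric(0), yMean = mean(y))
}

#' Predict concentrations from a fitted regression model
#'
#' @param object a [RegressionModel-class].
#' @param newdata feature matrix (samples in rows) or vector.
#' @param ... ignored.
#' @return numeric vector of predicted concentrations.
#' @export
setMethod("predict", "RegressionModel", function(object, newdata, ...) {
    if (object@method == "mean") {
        n <- if (is.matrix(newdata)) nrow(newdata) else NROW(newdata)
        return(rep(object@intercept, n))
    }
    X <- if (is.vector(newdata)) matrix(newdata, nrow = 1L) else
        as.matrix(newdata)
    if (ncol(X) != length(object@coefficients))
        stop("feature dimension mismatch: ", ncol(X), " vs ",
             length(object@coefficients))
    drop(X %*% object@coefficients) + object@intercept
})

setMethod("show", "RegressionModel", function(object) {
    cat("Regression model (", object@method, ")", sep = "")
    if (object@method == "pls")
        cat(",", object@nLatent, "latent variable(s)")
    cat("\n  ", length(object@coefficients), "feature coefficient(s), ",
        "intercept ", format(object@intercept), "\n", sep = "")
})

.foldAssignment <- function(y, folds) {
    n <- length(y)
    if (is.null(folds))
        folds <- n  # leave-one-out
    folds <- as.integer(folds)
    if (is.na(folds) || folds < 2L || folds > n)
        stop("'folds' must lie in [2, ", n, "]")
    # contiguous blocks after sorting by y: deterministic, spans the range
    sizes <- rep(n %/% folds, folds) + c(rep(1L, n %% folds),
                                         rep(0L, folds - n %% folds))
    fold <- integer(n)
    fold[order(y)] <- rep(seq_len(folds), times = sizes)
    fold
}

#' Cross-validated root-mean-square error (RMSECV)
#'
#' \deqn{RMSECV = \sqrt{\frac{1}{n} \sum_i (\hat y_{(-i)} - y_i)^2}}
#' where \eqn{\hat y_{(-i)}} is the prediction of sample \eqn{i} by a model
#' fitted without its fold. Fold assignment is deterministic: samples are
#' sorted by `y` and cut into contiguous blocks, so every fold spans the
#' concentration range. Default is leave-one-out.
#'
#' @param X feature matrix, samples in rows.
#' @param y response vector.
#' @param method `"pls"`, `"mlr"` or `"mean"` (intercept-only baseline).
#' @param nLatent PLS latent variables.
#' @param folds number of folds; `NULL` = leave-one-out.
#' @return scalar RMSECV in concentration units.
#' @export
rmsecv <- function(X, y, method = c("pls", "mlr", "mean"), nLatent = 1L,
                   folds = NULL) {
    method <- match.arg(method)
    X <- as.matrix(X)
    y <- as.numeric(y)
    if (length(y) != nrow(X))
        stop("'y' must have one value per row of 'X'")
    fold <- .foldAssignment(y, folds)
    pred <- numeric(length(y))
    for (f in unique(fold)) {
        test <- fold == f
        model <- switch(method,
            pls = plsFit(X[!test, , drop = FALSE], y[!test], nLatent),
            mlr = mlrFit(X[!test, , drop = FALSE], y[!test]),
            mean = .meanFit(y[!test]))
        pred[test] <- if (method == "mean") model@intercept else
            predict(model, X[test, , drop = FALSE])
    }
    sqrt(mean((pred - y)^2))
}

#' Fit a peak-intensity calibration curve
#'
#' Ordinary least squares of intensity on concentration,
#' \eqn{I = slope \cdot N + intercept}, with \eqn{r^2} the squared Pearson
#' correlation of fitted vs observed intensities. Needs at least two points
#' at two distinct concentrations (two points give an exact line with
#' \eqn{r^2 = 1}).
#'
#' @param intensities peak heights (a.u.).
#' @param concentrations matching analyte concentrations.
#' @return a [CalibrationCurve-class].
#' @examples
#' fitCalibration(c(5700.9, 16180.5, 62756.5), c(0.1, 1.0, 5.0))
#' @export
fitCalibration <- function(intensities, concentrations) {
    I <- as.numeric(intensities)
    N <- as.numeric(concentrations)
    if (length(I) != length(N))
        stop("'intensities' and 'concentrations' differ in length")
    if (length(I) < 2L)
        stop("need at least 2 calibration points")
    if (length(unique(N)) < 2L)
        stop("need at least 2 distinct concentrations")
    fit <- lm(I ~ N)
    cf <- coef(fit)
    r2 <- stats::cor(fitted(fit), I)^2
    methods::new("CalibrationCurve",
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 rSquared = min(max(r2, 0), 1), n = length(I))
}

#' @rdname CalibrationCurve-class
#' @param object,x a `CalibrationCurve`.
#' @export
setMethod("coef", "CalibrationCurve", function(object, ...)
    c(intercept = object@intercept, slope = object@slope))

#' @rdname CalibrationCurve-class
#' @export
setMethod("rSquared", "CalibrationCurve", function(x) x@rSquared)

setMethod("show", "CalibrationCurve", function(object) {
    cat("Calibration curve: I =", format(object@slope), "* N +",
        format(object@intercept), "\n")
    cat("  r^2 =", format(object@rSquared), "on", object@n, "points\n")
})

#' Limit of detection from blank replicates
#'
#' Default rule: the blank mean plus three times the blank sample standard
#' deviation, converted to concentration through the calibration line and
#' floored at zero:
#' \deqn{LOD = \max\!\left(0, \frac{\bar I_{blank} + 3 s_{blank}
#'   - intercept}{slope}\right)}
#' The alternative `rule = "3s_only"` uses three times the blank signal
#' itself (\eqn{3 \bar I_{blank}}) as the detection threshold.
#'
#' @param blankIntensities replicate blank signals at the quantitation
#'   wavenumber (>= 3 values).
#' @param curve a [CalibrationCurve-class] with positive slope.
#' @param rule `"mean_plus_3sd"` (default) or `"3s_only"`.
#' @return LOD in concentration units.
#' @examples
#' curve <- fitCalibration(c(0, 50, 100), c(0, 1, 2))
#' lod(c(100, 100, 100), curve)  # 2
#' @export
lod <- function(blankIntensities, curve, rule = c("mean_plus_3sd",
                                                  "3s_only")) {
    rule <- match.arg(rule)
    stopifnot(is(curve, "CalibrationCurve"))
    b <- as.numeric(blankIntensities)
    if (length(b) < 3L)
        stop("need at least 3 blank replicates")
    if (curve@slope <= 0)
        stop("calibration slope must be positive")
    threshold <- switch(rule,
        mean_plus_3sd = mean(b) + 3 * sd(b),
        `3s_only` = 3 * mean(b))
    max(0, (threshold - curve@intercept) / curve@slope)
}

#' Relative standard deviation
#'
#' \eqn{RSD = 100 \cdot s / \bar x} (percent), with \eqn{s} the sample
#' standard deviation — the usual figure of merit for SERS substrate
#' uniformity across replicate peak intensities.
#'
#' @param values numeric vector (>= 2 values, non-zero mean).
#' @return RSD in percent.
#' @examples
#' rsd(c(9, 10, 11))  # 10
#' @export
rsd <- function(values) {
    v <- as.numeric(values)
    if (length(v) < 2L)
        stop("need at least 2 values")
    m <- mean(v)
    if (m == 0)
        stop("mean is zero; RSD undefined")
    100 * sd(v) / m
}

#' Detect Raman peaks
#'
#' Finds interior local maxima whose height, relative to the spectrum's
#' intensity range, exceeds `minProminence` (so the result is invariant to a
#' constant offset), enforces a minimum separation greedily from the tallest
#' candidate down, and refines each center by three-point parabolic
#' interpolation. Peaks are returned sorted by wavenumber; an empty
#' `data.frame` (e.g. for a flat spectrum) is valid output.
#'
#' @param set a single-sample [SpectrumSet-class] (or use `sample` to pick a
#'   column).
#' @param minProminence minimum relative height as a fraction of the
#'   intensity range (default 0.05).
#' @param minSeparation minimum center separation in cm\eqn{^{-1}}
#'   (default 20).
#' @param sample column index of the spectrum to analyse (default 1).
#' @return `data.frame(center, height)` sorted by center.
#' @export
detectPeaks <- function(set, minProminence = 0.05, minSeparation = 20,
                        sample = 1L) {
    stopifnot(is(set, "SpectrumSet"))
    y <- intensities(set)[, sample]
    nu <- wavenumbers(set)
    n <- length(y)
    rng <- max(y) - min(y)
    empty <- data.frame(center = numeric(0), height = numeric(0))
    if (n < 3L || rng == 0)
        return(empty)
    i <- 2:(n - 1L)
    isMax <- y[i] > y[i - 1L] & y[i] >= y[i + 1L]
    cand <- i[isMax & (y[i] - min(y)) / rng >= minProminence]
    if (!length(cand))
        return(empty)
    cand <- cand[order(y[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (j in cand)
        if (!length(kept) || all(abs(nu[j] - nu[kept]) >= minSeparation))
            kept <- c(kept, j)
    refine <- function(j) {
        a <- y[j - 1L]; b <- y[j]; c <- y[j + 1L]
        denom <- a - 2 * b + c
        delta <- if (denom == 0) 0 else 0.5 * (a - c) / denom
        step <- (nu[j + 1L] - nu[j - 1L]) / 2
        c(center = nu[j] + delta * step,
          height = b - 0.25 * (a - c) * delta)
    }
    out <- t(vapply(kept, refine, numeric(2)))
    out <- as.data.frame(out)
    out[order(out$center), , drop = FALSE]
}
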