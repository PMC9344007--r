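#' Radial-basis-function kernel
#'
#' \deqn{k(x, y) = \exp\!\left(-\|x - y\|^2 / 2\sigma^2\right)}
#' Symmetric, bounded in (0, 1\], with \eqn{k(x, x) = 1}; monotone increasing
#' in \eqn{\sigma} for fixed \eqn{x \ne y}.
#'
#' @param x,y numeric feature vectors of equal length.
#' @param sigma kernel width \eqn{\sigma > 0}, in the units of the feature
#'   Euclidean distances (raw intensity counts for unnormalized spectra —
#'   which is why useful widths for SERS intensities are in the thousands).
#' @return scalar kernel value.
#' @examples
#' rbfKernel(c(3, 4), c(0, 0), sigma = 5)  # exp(-0.5)
#' @export
rbfKernel <- function(x, y, sigma) {
    if (length(x) != length(y))
        stop("'x' and 'y' must have the same length")
    if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) ||
        sigma <= 0)
        stop("'sigma' must be a single positive number")
    exp(-sum((x - y)^2) / (2 * sigma^2))
}

.gramMatrix <- function(X, Y = X, kernel = "rbf", sigma = NULL) {
    X <- as.matrix(X); Y <- as.matrix(Y)
    if (ncol(X) != ncol(Y))
        stop("feature dimension mismatch: ", ncol(X), " vs ", ncol(Y))
    if (kernel == "linear")
        return(X %*% t(Y))
    if (is.null(sigma) || sigma <= 0)
        stop("'sigma' must be a single positive number")
    d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    d2[d2 < 0] <- 0
    exp(-d2 / (2 * sigma^2))
}

#' Double-center a kernel matrix
#'
#' Applies the centering correction that makes the implicitly mapped
#' features zero-mean in feature space:
#' \deqn{K_{\mu\nu} \rightarrow K_{\mu\nu}
#'   - \frac{1}{M}\Big(\sum_w K_{\mu w} + \sum_w K_{w\nu}\Big)
#'   + \frac{1}{M^2}\sum_{w,\tau} K_{w\tau}}
#' Equivalent to \eqn{H K H} with \eqn{H = I - \frac{1}{M} \mathbf{1}
#' \mathbf{1}^\top}; every row and column of the result sums to zero.
#'
#' @param K square symmetric kernel (Gram) matrix.
#' @return the centered matrix.
#' @examples
#' centerKernel(diag(2))  # matrix(c(.5, -.5, -.5, .5), 2)
#' @export
centerKernel <- function(K) {
    K <- as.matrix(K)
    if (nrow(K) != ncol(K))
        stop("'K' must be square (got ", nrow(K), " x ", ncol(K), ")")
    M <- nrow(K)
    rm <- rowMeans(K)
    cm <- colMeans(K)
    K - matrix(rm, M, M) - matrix(cm, M, M, byrow = TRUE) + mean(K)
}

#' Fit kernel principal component analysis
#'
#' Builds the Gram matrix of the training features, applies the centering
#' correction ([centerKernel()]), and eigendecomposes it. Coefficient vectors
#' \eqn{\alpha_k} are the eigenvectors rescaled so that
#' \eqn{\lambda_k (\alpha_k \cdot \alpha_k) = 1}, i.e. unit-norm eigenvectors
#' in feature space, which makes the projection sums well scaled. Components
#' with \eqn{\lambda_k \le 10^{-12} \lambda_{max}} carry no variance and are
#' dropped (with a warning if that truncates the request). Each coefficient
#' vector's sign is fixed so its largest-magnitude entry is positive, making
#' scores reproducible across platforms.
#'
#' Explained-variance ratios are \eqn{\lambda_k / \sum_j \lambda_j} over all
#' non-negative eigenvalues of the centered kernel.
#'
#' The `kernel = "linear"` variant (\eqn{k(x,y) = x^\top y}) reproduces
#' classical PCA scores exactly (up to component sign) and supports the
#' linear-PCA comparison baseline.
#'
#' @param X numeric matrix of training features, samples in rows (M >= 2), or
#'   a feature matrix from [extractRanges()].
#' @param sigma RBF width (ignored for the linear kernel).
#' @param nComponents number of components to retain (<= M).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return a [KPCAModel-class].
#' @seealso [kpcaTransform()], [sigmaSweep()]
#' @export
kpcaFit <- function(X, sigma = NULL, nComponents = 2L,
                    kernel = c("rbf", "linear")) {
    kernel <- match.arg(kernel)
    X <- as.matrix(X)
    M <- nrow(X)
    if (M < 2L)
        stop("need at least 2 training samples")
    nComponents <- as.integer(nComponents)
    if (is.na(nComponents) || nComponents < 1L || nComponents > M)
        stop("'nComponents' must lie in [1, ", M, "]")
    K <- .gramMatrix(X, X, kernel, sigma)
    Kc <- centerKernel(K)
    Kc <- (Kc + t(Kc)) / 2
    eig <- eigen(Kc, symmetric = TRUE)
    lambda <- eig$values
    lambdaMax <- max(lambda, 0)
    pos <- which(lambda > 1e-12 * max(lambdaMax, .Machine$double.eps))
    if (length(pos) < nComponents)
        warning("only ", length(pos), " components carry variance; ",
                "truncating from ", nComponents)
    k <- min(nComponents, length(pos))
    keep <- seq_len(k)
    lambdaKeep <- lambda[keep]
    alpha <- eig$vectors[, keep, drop = FALSE]
    if (k > 0) {
        alpha <- sweep(alpha, 2, sqrt(lambdaKeep), "/")
        flip <- vapply(seq_len(k), function(j) {
            v <- alpha[, j]
            sign(v[which.max(abs(v))])
        }, numeric(1))
        alpha <- sweep(alpha, 2, ifelse(flip == 0, 1, flip), "*")
    }
    scores <- Kc %*% alpha
    total <- sum(lambda[lambda > 0])
    ratio <- if (total > 0) lambdaKeep / total else numeric(k)
    if (k > 0) {
        colnames(alpha) <- colnames(scores) <- paste0("PC", seq_len(k))
        rownames(scores) <- rownames(X)
    }
    methods::new("KPCAModel",
                 trainingFeatures = X,
                 kernel = kernel,
                 sigma = if (kernel == "rbf") sigma else NA_real_,
                 kernelMatrix = K,
                 centeredKernel = Kc,
                 eigenvalues = lambdaKeep,
                 coefficients = alpha,
                 scores = scores,
                 explainedRatio = ratio)
}

#' Project new samples onto fitted kernel principal components
#'
#' Computes the test kernel rows \eqn{k(x_i, x)} against the training
#' samples, centers them against the *training* kernel statistics
#' \deqn{k'_{nj} = k_{nj} - \overline{k_{n\cdot}}
#'   - \overline{K_{\cdot j}} + \overline{K}}
#' and applies the projection \eqn{[v^k \cdot \Phi(x)] = \sum_i \alpha_i^k
#' k(x_i, x)}. Transforming the training matrix reproduces the training
#' scores.
#'
#' @param model a [KPCAModel-class].
#' @param Xnew matrix of new feature vectors (rows), with the training
#'   feature dimension.
#' @return a samples x components score matrix.
#' @export
kpcaTransform <- function(model, Xnew) {
    stopifnot(is(model, "KPCAModel"))
    Xnew <- if (is.vector(Xnew)) matrix(Xnew, nrow = 1L) else as.matrix(Xnew)
    if (ncol(Xnew) != ncol(model@trainingFeatures))
        stop("feature dimension mismatch: ", ncol(Xnew), " vs ",
             ncol(model@trainingFeatures))
    Kt <- .gramMatrix(Xnew, model@trainingFeatures, model@kernel,
                      model@sigma)
    K <- model@kernelMatrix
    Ktc <- Kt - matrix(rowMeans(Kt), nrow(Kt), ncol(Kt)) -
        matrix(colMeans(K), nrow(Kt), ncol(Kt), byrow = TRUE) + mean(K)
    s <- Ktc %*% model@coefficients
    rownames(s) <- rownames(Xnew)
    s
}

#' @rdname KPCAModel-class
#' @export
setMethod("scores", "KPCAModel", function(x) x@scores)

#' @rdname KPCAModel-class
#' @export
setMethod("explainedRatio", "KPCAModel", function(x) x@explainedRatio)

setMethod("show", "KPCAModel", function(object) {
    cat("KPCA model (", object@kernel, " kernel",
        if (object@kernel == "rbf") paste0(", sigma = ", object@sigma),
        ")\n", sep = "")
    cat("  ", nrow(object@trainingFeatures), "training samples,",
        ncol(object@coefficients), "retained components\n")
    if (length(object@explainedRatio))
        cat("  explained variance:",
            paste0(round(100 * object@explainedRatio, 1), "%",
                   collapse = ", "), "\n")
})

#' RMSECV across a grid of RBF kernel widths
#'
#' For every \eqn{\sigma} in the grid, cross-validates the full
#' KPCA-plus-regression chain: within each fold, KPCA is fitted on the
#' training part only, held-out samples are projected with
#' [kpcaTransform()], and the downstream regressor predicts their
#' concentrations. Reported RMSECV is
#' \eqn{\sqrt{\frac{1}{n}\sum_i (\hat y_{(-i)} - y_i)^2}}. Duplicate
#' \eqn{\sigma} values are deduplicated with a warning; a failure at one
#' \eqn{\sigma} is recorded as `NA` and the sweep continues.
#'
#' @param X calibration feature matrix (samples in rows).
#' @param y concentrations.
#' @param sigmas RBF widths to try (>= 2 values); the default grid
#'   \{1000, 5000, 8000, 10000\} suits raw-intensity feature scales.
#' @param nComponents kernel principal components fed to the regressor.
#' @param method downstream regressor, `"pls"` or `"mlr"`.
#' @param nLatent PLS latent variables (default `min(3, nComponents)`).
#' @param folds CV folds; `NULL` = leave-one-out.
#' @return `data.frame(sigma, rmsecv)` sorted by `sigma`.
#' @export
sigmaSweep <- function(X, y, sigmas = c(1000, 5000, 8000, 10000),
                       nComponents = 5L, method = c("pls", "mlr"),
                       nLatent = NULL, folds = NULL) {
    method <- match.arg(method)
    X <- as.matrix(X)
    if (length(y) != nrow(X))
        stop("'y' must have one value per row of 'X'")
    if (anyDuplicated(sigmas)) {
        warning("duplicate sigma values removed")
        sigmas <- unique(sigmas)
    }
    if (length(sigmas) < 2L)
        stop("need at least 2 sigma values")
    sigmas <- sort(sigmas)
    rmse <- vapply(sigmas, function(s) {
        tryCatch(
            .cvKpcaRegression(X, y, s, nComponents, method, nLatent, folds),
            error = function(e) {
                warning("sigma = ", s, " failed: ", conditionMessage(e))
                NA_real_
            })
    }, numeric(1))
    data.frame(sigma = sigmas, rmsecv = rmse)
}

.cvKpcaRegression <- function(X, y, sigma, nComponents, method, nLatent,
                              folds) {
    n <- nrow(X)
    fold <- .foldAssignment(y, folds)
    pred <- numeric(n)
    for (f in unique(fold)) {
        test <- fold == f
        fit <- kpcaFit(X[!test, , drop = FALSE], sigma = sigma,
                       nComponents = min(nComponents, sum(!test)))
        sTrain <- scores(fit)
        sTest <- kpcaTransform(fit, X[test, , drop = FALSE])
        model <- if (method == "pls")
            plsFit(sTrain, y[!test],
                   nLatent = min(nLatent %||% min(3L, ncol(sTrain)),
                                 ncol(sTrain), sum(!test) - 1L))
        else
            mlrFit(sTrain, y[!test])
        pred[test] <- predict(model, sTest)
    }
    sqrt(mean((pred - y)^2))
}
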