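#' Max-min calibration/prediction split
#'
#' Deterministic Kennard-Stone-style partitioning used to pick a calibration
#' set that spans the feature space:
#' \enumerate{
#'   \item Seed: compute the mean spectrum of all candidates and add the
#'     samples at minimum and maximum Euclidean distance from it.
#'   \item Iterate: for every remaining sample compute the minimum Euclidean
#'     distance to the current calibration set; add the sample with the
#'     largest such distance, then the one with the smallest (from the same
#'     per-iteration distance table; only one if a single slot remains).
#'   \item Stop when the calibration set reaches `nCal`; the rest form the
#'     prediction set.
#' }
#' All ties are broken by lowest input index, so the split is fully
#' deterministic. Each pick's distance is logged for audit.
#'
#' @param x a [SpectrumSet-class] (samples = columns, distance computed on
#'   the intensity vectors) or a numeric feature matrix with samples in rows.
#' @param nCal requested calibration-set size, `2 <= nCal <= n - 1`. Default:
#'   3:1 calibration:prediction, i.e. `round(0.75 * n)` clamped to that range.
#' @return a [SplitResult-class].
#' @examples
#' X <- matrix(c(0, 1, 2, 3, 10), ncol = 1)
#' maxminSplit(X, nCal = 4)  # calibration rows 4, 5, 1, 3
#' @export
maxminSplit <- function(x, nCal = NULL) {
    X <- if (is(x, "SpectrumSet")) t(intensities(x)) else as.matrix(x)
    n <- nrow(X)
    if (n < 3L)
        stop("need at least 3 samples to split")
    if (is.null(nCal))
        nCal <- min(max(2L, round(0.75 * n)), n - 1L)
    nCal <- as.integer(nCal)
    if (is.na(nCal) || nCal < 2L || nCal > n - 1L)
        stop("'nCal' must lie in [2, ", n - 1L, "]")
    ids <- rownames(X) %||% as.character(seq_len(n))
    mu <- colMeans(X)
    dMean <- sqrt(colSums((t(X) - mu)^2))
    cal <- integer(0)
    log <- numeric(0)
    pick <- function(cand, d, decreasing) {
        # ties -> lowest input index (order() is stable)
        cand[order(d, decreasing = decreasing)[1L]]
    }
    i1 <- pick(seq_len(n), dMean, FALSE)
    cal <- i1
    log <- dMean[i1]
    i2 <- pick(setdiff(seq_len(n), cal), dMean[-i1], TRUE)
    cal <- c(cal, i2)
    log <- c(log, dMean[i2])
    while (length(cal) < nCal) {
        rest <- setdiff(seq_len(n), cal)
        dCal <- vapply(rest, function(i)
            min(sqrt(colSums((t(X[cal, , drop = FALSE]) - X[i, ])^2))),
            numeric(1))
        iMax <- pick(rest, dCal, TRUE)
        cal <- c(cal, iMax)
        log <- c(log, dCal[match(iMax, rest)])
        if (length(cal) < nCal) {
            rest2 <- setdiff(rest, iMax)
            iMin <- pick(rest2, dCal[match(rest2, rest)], FALSE)
            cal <- c(cal, iMin)
            log <- c(log, dCal[match(iMin, rest)])
        }
    }
    pred <- setdiff(seq_len(n), cal)
    names(log) <- ids[cal]
    methods::new("SplitResult",
                 calibrationIds = ids[cal],
                 predictionIds = ids[pred],
                 distancesLog = log)
}

#' @rdname SplitResult-class
#' @export
setMethod("calibrationIds", "SplitResult", function(x) x@calibrationIds)

#' @rdname SplitResult-class
#' @export
setMethod("predictionIds", "SplitResult", function(x) x@predictionIds)

#' @rdname SplitResult-class
#' @export
setMethod("distancesLog", "SplitResult", function(x) x@distancesLog)

setMethod("show", "SplitResult", function(object) {
    cat("max-min split:", length(object@calibrationIds), "calibration /",
        length(object@predictionIds), "prediction samples\n")
    cat("  calibration:", paste(object@calibrationIds, collapse = ", "),
        "\n")
})
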