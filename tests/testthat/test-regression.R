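test_that("PLS1 handles exact, full-rank and degenerate responses", {
    # univariate exact linear relation, one latent variable
    x <- matrix(seq(1, 10), ncol = 1)
    m <- plsFit(x, 2 * x[, 1], nLatent = 1)
    expect_lt(max(abs(predict(m, x) - 2 * x[, 1])), 1e-10)
    # full latent variables on full-rank data equal OLS (oracle)
    set.seed(51)
    X <- matrix(rnorm(30), 10, 3)
    y <- rnorm(10)
    full <- plsFit(X, y, nLatent = 3)
    ols <- lm.fit(cbind(1, X), y)
    expect_equal(predict(full, X), ols$fitted.values, ignore_attr = TRUE,
                 tolerance = 1e-8)
    # constant response: nothing to extract, predictions are the mean
    const <- plsFit(X, rep(4, 10), nLatent = 2)
    expect_equal(unname(const@coefficients), rep(0, 3))
    expect_equal(predict(const, X), rep(4, 10), ignore_attr = TRUE)
    expect_error(plsFit(X, y, nLatent = 4), "\\[1, 3\\]")
})

test_that("MLR is exact on noiseless linear data and rejects bad designs", {
    x <- matrix(c(0, 1, 2, 3), ncol = 1)
    m <- mlrFit(x, 3 * x[, 1] + 1)
    expect_equal(unname(m@coefficients), 3)
    expect_equal(m@intercept, 1)
    set.seed(52)
    X <- matrix(rnorm(24), 8, 3)
    b <- c(2, -1, 0.5)
    y <- drop(X %*% b) + 4
    fit <- mlrFit(X, y)
    expect_lt(max(abs(predict(fit, X) - y)), 1e-10)
    expect_error(mlrFit(matrix(rnorm(12), 3, 4), rnorm(3)), "more samples")
    expect_error(mlrFit(cbind(X[, 1], X[, 1]), rnorm(8)), "rank")
})

test_that("RMSECV matches hand computations and estimator consistency", {
    x <- matrix(seq(0, 9), ncol = 1)
    expect_lt(rmsecv(x, 2 * x[, 1] + 1, method = "pls", nLatent = 1), 1e-9)
    # two samples, LOO, mean-only model: predictions swap -> RMSECV = 2
    expect_equal(rmsecv(matrix(c(1, 1), 2, 1), c(0, 2), method = "mean"), 2)
    # Monte-Carlo: with additive noise on a linear trend the LOO error
    # approaches the noise SD
    set.seed(53)
    n <- 150
    X <- matrix(runif(n, 0, 10), ncol = 1)
    y <- 3 * X[, 1] + rnorm(n, sd = 0.5)
    got <- rmsecv(X, y, method = "mlr")
    expect_gt(got, 0.5 * 0.75)
    expect_lt(got, 0.5 * 1.25)
    expect_error(rmsecv(X, y, folds = 1), "folds")
})

test_that("calibration fitting recovers the printed line from its own points", {
    # points generated by evaluating I = 11644 N + 4536.5
    curve <- fitCalibration(c(5700.9, 16180.5, 62756.5), c(0.1, 1.0, 5.0))
    expect_equal(unname(coef(curve)["slope"]), 11644)
    expect_equal(unname(coef(curve)["intercept"]), 4536.5)
    expect_equal(rSquared(curve), 1)
    # two distinct points give an exact line
    two <- fitCalibration(c(1, 3), c(0, 1))
    expect_equal(unname(coef(two)), c(1, 2))
    expect_equal(rSquared(two), 1)
    expect_error(fitCalibration(c(1, 2), c(1, 1)), "distinct")
    expect_error(fitCalibration(1, 1), "2 calibration points")
})

test_that("calibration fitting is scale-equivariant", {
    set.seed(54)
    N <- runif(10, 0.1, 5)
    I <- 100 * N + 20 + rnorm(10)
    base <- fitCalibration(I, N)
    for (c in c(0.5, 3, 1000)) {
        scaled <- fitCalibration(c * I, N)
        expect_equal(unname(coef(scaled)), c * unname(coef(base)))
        expect_equal(rSquared(scaled), rSquared(base))
    }
})

test_that("LOD follows the blank-mean-plus-3-SD rule", {
    curve50 <- fitCalibration(c(0, 50, 100), c(0, 1, 2))  # slope 50, int 0
    expect_equal(lod(c(100, 100, 100), curve50), 2.0)
    blanks <- c(90, 100, 110)  # mean 100, sd 10
    expect_equal(lod(blanks, curve50), (100 + 30) / 50)
    expect_equal(lod(blanks, curve50, rule = "3s_only"), 300 / 50)
    # floored at zero when the intercept exceeds the blank threshold
    high <- fitCalibration(c(1000, 1050, 1100), c(0, 1, 2))
    expect_equal(lod(c(10, 10, 10), high), 0)
    neg <- fitCalibration(c(100, 50, 0), c(0, 1, 2))
    expect_error(lod(blanks, neg), "positive")
    expect_error(lod(c(1, 2), curve50), "3 blank")
    # monotone non-decreasing in the blank SD
    lods <- vapply(c(0, 5, 10, 20), function(s)
        lod(c(100 - s, 100, 100 + s), curve50), numeric(1))
    expect_false(is.unsorted(lods))
})

test_that("RSD is 100 sd over mean", {
    expect_equal(rsd(c(9, 10, 11)), 10)
    expect_equal(rsd(c(5, 5, 5)), 0)
    expect_error(rsd(c(-1, 1)), "mean is zero")
    expect_error(rsd(3), "2 values")
})

test_that("peak detection matches the generator's band positions", {
    cfg <- quietConfig()
    s <- generateSpectrum(cfg, 1.0)
    pk <- detectPeaks(s)
    expect_equal(nrow(pk), 5L)
    expect_true(all(abs(pk$center - c(562, 929, 1146, 1379, 1514)) <= 2))
    expect_equal(pk$center[which.max(pk$height)], pk$center[4])
    # flat spectrum -> empty result
    flat <- SpectrumSet(rep(3, 100), seq(550, 649))
    expect_equal(nrow(detectPeaks(flat)), 0L)
    # parabolic refinement on a symmetric band off the grid
    nu <- seq(550, 1550, 1)
    g <- SpectrumSet(gaussProfile(nu, 12, 1000.3), nu)
    pg <- detectPeaks(g)
    expect_equal(nrow(pg), 1L)
    expect_lt(abs(pg$center - 1000.3), 0.5)
})

test_that("peak detection ignores constant offsets", {
    nu <- seq(550, 1550, 1)
    y <- voigtProfile(nu, 0.7, 50, 900, 10) +
        voigtProfile(nu, 0.7, 30, 1200, 10)
    p1 <- detectPeaks(SpectrumSet(y, nu))
    p2 <- detectPeaks(SpectrumSet(y + 1e4, nu))
    expect_equal(p1$center, p2$center)
    expect_equal(p2$height - p1$height, rep(1e4, 2))
})
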