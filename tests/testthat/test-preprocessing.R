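test_that("group averaging is the arithmetic mean on an unchanged axis", {
    s <- SpectrumSet(cbind(a = c(1, 3), b = c(3, 5)), c(550, 551),
                     groups = c("g", "g"), concentrations = c(1, 1))
    m <- averageSpectra(s)
    expect_equal(unname(intensities(m)[, 1]), c(2, 4))
    expect_equal(wavenumbers(m), c(550, 551))
    expect_equal(concentrations(m), 1)
    # single-member group is the identity
    s1 <- SpectrumSet(cbind(a = c(1, 3)), c(550, 551), groups = "g")
    expect_equal(intensities(averageSpectra(s1))[, 1],
                 unname(intensities(s1)[, 1]), ignore_attr = TRUE)
    # noiseless replicates are identical, so the mean equals any member
    cfg <- quietConfig()
    st <- generateStudy(cfg, 1.0, replicates = 4)
    mean4 <- averageSpectra(st)
    expect_equal(unname(intensities(mean4)[, 1]),
                 unname(intensities(st)[, 1]))
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
    nu <- seq(550, 650, 1)
    y <- 3 + 0.5 * nu - 0.002 * nu^2
    s <- SpectrumSet(y, nu)
    sm <- smoothSpectra(s, window = 5, polyorder = 2)
    interior <- 3:(length(nu) - 2)
    expect_equal(intensities(sm)[interior, 1], y[interior],
                 ignore_attr = TRUE, tolerance = 1e-9)
    # constant spectra are fixed points
    const <- SpectrumSet(rep(7, 101), nu)
    expect_equal(intensities(smoothSpectra(const))[, 1], rep(7, 101),
                 ignore_attr = TRUE)
    expect_error(smoothSpectra(s, window = 8), "odd")
    expect_error(smoothSpectra(s, window = 3, polyorder = 3), "polyorder")
})

test_that("smoothing reduces white-noise variance", {
    set.seed(31)
    nu <- seq(550, 1549, 1)
    reduced <- replicate(20, {
        y <- rnorm(length(nu))
        sm <- smoothSpectra(SpectrumSet(y, nu), window = 11, polyorder = 3)
        var(intensities(sm)[, 1]) < var(y)
    })
    expect_true(all(reduced))
})

test_that("baseline estimation recovers a pure synthetic background", {
    cfg <- quietConfig()
    nu <- wavenumberAxis(cfg)
    trueBaseline <- 2000 * exp(-(nu - 550) / 500) + 200
    s <- SpectrumSet(trueBaseline, nu)
    for (method in c("modpoly", "als")) {
        corr <- correctBaseline(s, preprocessConfig(baselineMethod = method))
        expect_lt(max(abs(intensities(corr)[, 1])), 0.01 * 2000)
    }
})

test_that("baseline correction preserves an isolated peak's height", {
    cfg <- singlePeakConfig()
    s <- generateSpectrum(cfg, 1.0)
    trueHeight <- 11644 + 4536.5
    corr <- correctBaseline(s)
    expect_equal(unname(peakHeight(corr, 1000)), trueHeight,
                 tolerance = 0.05)
    # zero in, zero out
    z <- SpectrumSet(rep(0, 1001), wavenumberAxis(cfg))
    expect_equal(max(abs(intensities(correctBaseline(z)))), 0)
})

test_that("derivatives remove constant and linear drift as calculus demands", {
    nu <- seq(550, 650, 1)
    const <- SpectrumSet(rep(5, 101), nu)
    expect_equal(max(abs(intensities(derivativeSpectra(const, 1)))), 0,
                 tolerance = 1e-10)
    ramp <- SpectrumSet(2 * nu, nu)
    d1 <- derivativeSpectra(ramp, 1)
    interior <- 5:97
    expect_equal(intensities(d1)[interior, 1], rep(2, length(interior)),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(max(abs(intensities(derivativeSpectra(ramp, 2)))), 0,
                 tolerance = 1e-8)
    expect_error(derivativeSpectra(ramp, 3), "order")
})

test_that("second derivative is invariant to adding a linear trend", {
    nu <- seq(550, 750, 1)
    base <- SpectrumSet(voigtProfile(nu, 0.5, 100, 650, 15), nu)
    trended <- SpectrumSet(voigtProfile(nu, 0.5, 100, 650, 15) +
                           3 * nu - 1000, nu)
    interior <- 5:197
    expect_equal(intensities(derivativeSpectra(trended, 2))[interior, 1],
                 intensities(derivativeSpectra(base, 2))[interior, 1],
                 tolerance = 1e-8)
})

test_that("range extraction keeps closed-interval points in axis order", {
    cfg <- quietConfig()
    s <- generateSpectrum(cfg, 1.0)
    X <- extractRanges(s)
    expect_equal(dim(X), c(1L, 81L))  # 31 + 24 + 26 inclusive points
    wn <- attr(X, "wavenumbers")
    expect_equal(sum(wn >= 653 & wn <= 683), 31L)
    expect_equal(sum(wn >= 705 & wn <= 728), 24L)
    expect_equal(sum(wn >= 847 & wn <= 872), 26L)
    expect_false(is.unsorted(wn))
    # one range covering the whole axis returns the full spectrum
    full <- extractRanges(s, list(c(550, 1550)))
    expect_equal(unname(full[1, ]), unname(intensities(s)[, 1]))
    expect_error(extractRanges(s, list(c(2000, 2100))),
                 "\\[2000, 2100\\]")
    expect_error(preprocessConfig(featureRanges = list(c(600, 700),
                                                       c(650, 800))),
                 "overlap")
})

test_that("every preprocessing step preserves axis and sample count", {
    cfg <- generatorConfig(seed = 17)
    st <- generateStudy(cfg, c(0.5, 2), replicates = 2)
    for (out in list(smoothSpectra(st), correctBaseline(st),
                     derivativeSpectra(st, 1), preprocessSpectra(st))) {
        expect_equal(wavenumbers(out), wavenumbers(st))
        expect_equal(ncol(out), ncol(st))
        expect_false(is.unsorted(wavenumbers(out)))
    }
})

test_that("the default chain recovers an isolated peak center within one step", {
    cfg <- singlePeakConfig()
    s <- generateSpectrum(cfg, 2.0)
    pp <- preprocessSpectra(s)
    pk <- detectPeaks(pp)
    expect_equal(nrow(pk), 1L)
    expect_lt(abs(pk$center - 1000), 1)
})
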