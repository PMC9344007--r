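test_that("pseudo-Voigt matches hand evaluation and its boundary cases", {
    # center: both terms peak, so V(omega) = alpha for any theta
    for (th in c(0, 0.3, 1))
        expect_equal(voigtProfile(1000, th, 2, 1000, 7), 2)
    # theta=0.5, alpha=2, omega=1000, gamma=10 at nu=1005:
    # exp(-ln2) + 100/125 = 0.5 + 0.8
    expect_equal(voigtProfile(1005, 0.5, 2, 1000, 10), 1.3)
    nu <- seq(900, 1100, 0.5)
    # theta boundaries reduce to the pure Gaussian / Lorentzian terms
    expect_equal(voigtProfile(nu, 1, 2, 1000, 10),
                 2 * exp(-4 * log(2) * (nu - 1000)^2 / 100))
    expect_equal(voigtProfile(nu, 0, 2, 1000, 10),
                 2 * 100 / ((nu - 1000)^2 + 100))
    expect_error(voigtProfile(1000, 0.5, 2, 1000, 0), "gamma")
    expect_error(voigtProfile(1000, 1.2, 2, 1000, 10), "theta")
})

test_that("Lorentzian peaks at 1/pi with gamma_L as half width", {
    for (g in c(1, 5, 20))
        expect_equal(lorentzProfile(1000, g, 1000), 1 / pi)
    expect_equal(lorentzProfile(1010, 10, 1000), 1 / (2 * pi))
    expect_error(lorentzProfile(1000, 0, 1000), "gammaL")
})

test_that("Gaussian form has the printed prefactor and half width", {
    expect_equal(gaussProfile(1000, 1, 1000), sqrt(log(2) / pi))
    # at omega + gamma_G the exponent is -ln2: half the center value
    expect_equal(gaussProfile(1010, 10, 1000),
                 gaussProfile(1000, 10, 1000) / 2)
    # 1/gamma_G prefactor: doubling the width halves the center value
    expect_equal(gaussProfile(1000, 20, 1000),
                 gaussProfile(1000, 10, 1000) / 2)
    expect_error(gaussProfile(1000, -1, 1000), "gammaG")
})

test_that("all line shapes are symmetric about their center", {
    for (d in c(0.5, 3, 11, 40)) {
        expect_equal(voigtProfile(1000 + d, 0.6, 2, 1000, 9),
                     voigtProfile(1000 - d, 0.6, 2, 1000, 9))
        expect_equal(lorentzProfile(1000 + d, 9, 1000),
                     lorentzProfile(1000 - d, 9, 1000))
        expect_equal(gaussProfile(1000 + d, 9, 1000),
                     gaussProfile(1000 - d, 9, 1000))
    }
})

test_that("noiseless generator pins the quantitation peak to the calibration line", {
    # single isolated peak: exact to machine precision
    cfg <- singlePeakConfig(baselineAmplitude = 0, baselineOffset = 0)
    s <- generateSpectrum(cfg, 1.0)
    expect_equal(unname(peakHeight(s, 1000)), 11644 * 1.0 + 4536.5)
    # thiram library: exact up to the small tails of neighbouring bands
    cfgT <- quietConfig()
    sT <- generateSpectrum(cfgT, 1.0)
    nu <- wavenumberAxis(cfgT)
    baselineAt <- cfgT$baselineAmplitude *
        exp(-(1379 - 550) / cfgT$baselineDecay) + cfgT$baselineOffset
    expect_equal(unname(peakHeight(sT, 1379)) - baselineAt, 16180.5,
                 tolerance = 0.005)
})

test_that("zero concentration with zero intercept and baseline gives a null spectrum", {
    cfg <- singlePeakConfig(baselineAmplitude = 0, baselineOffset = 0,
                            calibrationIntercept = 0)
    s <- generateSpectrum(cfg, 0)
    expect_true(all(intensities(s) == 0))
    expect_error(generateSpectrum(cfg, -0.1), "non-negative")
})

test_that("generation is reproducible under a fixed seed and leaves the RNG alone", {
    cfg <- generatorConfig(seed = 11)
    s1 <- generateSpectrum(cfg, 1)
    set.seed(99); before <- runif(1)
    s2 <- generateSpectrum(cfg, 1)
    expect_identical(intensities(s1), intensities(s2))
    set.seed(99)
    expect_identical(runif(1), before)
    st1 <- generateStudy(cfg, c(0.5, 1), 2)
    st2 <- generateStudy(cfg, c(0.5, 1), 2)
    expect_identical(intensities(st1), intensities(st2))
})

test_that("study layout follows the concentrations-by-replicates design", {
    cfg <- generatorConfig(peaks = epidermisPeaks(), unit = "ug/g", seed = 3)
    st <- generateStudy(cfg, c(0, 0.1, 0.5, 1.5, 10), replicates = 4)
    expect_equal(ncol(st), 20L)
    expect_equal(sort(unique(concentrations(st))), c(0, 0.1, 0.5, 1.5, 10))
    expect_equal(as.integer(table(replicateGroups(st))), rep(4L, 5))
    expect_equal(concentrationUnit(st), "ug/g")
    single <- generateStudy(cfg, 1.5, replicates = 1)
    expect_equal(ncol(single), 1L)
    expect_error(generateStudy(cfg, numeric(0)), "non-empty")
})

test_that("replicate peak intensities show the configured relative spread", {
    # 20 R6G replicates at the default 1.5% multiplicative noise:
    # observed RSD should fall in the Monte-Carlo bracket around 1.5%
    cfg <- generatorConfig(peaks = rhodaminePeaks(), noiseRsd = 0.015,
                           seed = 21)
    st <- generateStudy(cfg, 1.0, replicates = 20)
    observed <- rsd(peakHeight(st, 1362))
    expect_gt(observed, 0.9)
    expect_lt(observed, 2.3)
})

test_that("noiseless peak heights recover the calibration line to machine precision", {
    cfg <- singlePeakConfig(baselineAmplitude = 0, baselineOffset = 0)
    concs <- c(0.1, 0.5, 1, 2, 5)
    st <- generateStudy(cfg, concs, replicates = 1)
    curve <- fitCalibration(peakHeight(st, 1000), concentrations(st))
    expect_equal(unname(coef(curve)["slope"]), 11644, tolerance = 1e-10)
    expect_equal(unname(coef(curve)["intercept"]), 4536.5,
                 tolerance = 1e-10)
    expect_equal(rSquared(curve), 1)
})

test_that("a YAML config mirrors generatorConfig field-for-field", {
    f <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("axisStart: 600", "axisStop: 1400", "axisStep: 2",
                 "peaks: rhodamine", "noiseRsd: 0.02", "seed: 5"), f)
    cfg <- readGeneratorConfig(f)
    expect_equal(cfg$axisStart, 600)
    expect_equal(cfg$axisStep, 2)
    expect_equal(cfg$peaks$omega, c(1362, 1510))
    expect_equal(cfg$noiseRsd, 0.02)
    writeLines("axisStarp: 600", f)
    expect_error(readGeneratorConfig(f), "unknown generator config field")
})
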