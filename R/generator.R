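#' Configuration for the synthetic SERS spectrum generator
#'
#' Bundles everything [generateSpectrum()] and [generateStudy()] need: the
#' wavenumber axis, a pseudo-Voigt peak library, the calibration line tying
#' the quantitation band's clean height to concentration, a fluorescence
#' baseline, and the noise model.
#'
#' The clean (noise-free) spectrum at concentration \eqn{N} is
#' \deqn{I(\nu) = \sum_p V_p(\nu) + A e^{-(\nu - \nu_0)/\tau} + c}
#' where concentration-sensitive peaks are rescaled jointly so that the
#' quantitation band's height above baseline equals
#' `calibrationSlope * N + calibrationIntercept` exactly. Noise is
#' multiplicative Gaussian with relative standard deviation `noiseRsd`
#' (matching how SERS substrate variability is quoted as an RSD of peak
#' intensities), plus optional additive dark noise.
#'
#' @param axisStart,axisStop,axisStep wavenumber axis in cm\eqn{^{-1}}
#'   (defaults 550, 1550, 1 — a typical dispersive-Raman detection window).
#' @param peaks a peak library (see [peakParams()]); default [thiramPeaks()].
#' @param calibrationSlope,calibrationIntercept a.u. per concentration unit
#'   and a.u.; defaults 11644 and 4536.5.
#' @param baselineAmplitude,baselineDecay,baselineOffset fluorescence
#'   background: amplitude \eqn{A} (a.u.), exponential decay constant
#'   \eqn{\tau} (cm\eqn{^{-1}}) and constant offset \eqn{c} (a.u.).
#' @param noiseRsd relative standard deviation of the multiplicative
#'   intensity noise (fraction; default 0.015, the ~1.4-1.6% substrate
#'   repeatability regime).
#' @param darkNoiseSd additive Gaussian dark-noise SD in a.u. (default 0).
#' @param seed integer seed, or `NULL` to use the current RNG state; the
#'   generator never touches the global RNG when a seed is given.
#' @param unit concentration unit label (default `"ug/mL"`).
#' @return a `GeneratorConfig` (validated list).
#' @export
generatorConfig <- function(axisStart = 550, axisStop = 1550, axisStep = 1,
                            peaks = thiramPeaks(),
                            calibrationSlope = 11644,
                            calibrationIntercept = 4536.5,
                            baselineAmplitude = 2000,
                            baselineDecay = 500,
                            baselineOffset = 200,
                            noiseRsd = 0.015,
                            darkNoiseSd = 0,
                            seed = NULL,
                            unit = "ug/mL") {
    cfg <- structure(list(
        axisStart = axisStart, axisStop = axisStop, axisStep = axisStep,
        peaks = peaks,
        calibrationSlope = calibrationSlope,
        calibrationIntercept = calibrationIntercept,
        baselineAmplitude = baselineAmplitude,
        baselineDecay = baselineDecay,
        baselineOffset = baselineOffset,
        noiseRsd = noiseRsd, darkNoiseSd = darkNoiseSd,
        seed = seed, unit = unit
    ), class = "GeneratorConfig")
    .checkGeneratorConfig(cfg)
    cfg
}

.checkGeneratorConfig <- function(cfg) {
    stopifnot(inherits(cfg, "GeneratorConfig"))
    if (!(cfg$axisStart < cfg$axisStop))
        stop("'axisStart' must be below 'axisStop'")
    if (cfg$axisStep <= 0)
        stop("'axisStep' must be strictly positive")
    if (cfg$noiseRsd < 0)
        stop("'noiseRsd' must be non-negative")
    if (cfg$darkNoiseSd < 0)
        stop("'darkNoiseSd' must be non-negative")
    if (cfg$baselineDecay <= 0)
        stop("'baselineDecay' must be strictly positive")
    .checkPeakLibrary(cfg$peaks)
    if (any(cfg$peaks$sensitive) && sum(cfg$peaks$quant) != 1L)
        stop("generator needs exactly one sensitive peak flagged 'quant'")
    invisible(cfg)
}

#' @export
print.GeneratorConfig <- function(x, ...) {
    cat("SERS generator config\n")
    cat("  axis:", x$axisStart, "-", x$axisStop, "cm^-1, step",
        x$axisStep, "\n")
    cat("  peaks at:", paste(x$peaks$omega, collapse = ", "), "cm^-1\n")
    cat("  calibration: I =", x$calibrationSlope, "N +",
        x$calibrationIntercept, " [", x$unit, "]\n")
    cat("  noise RSD:", x$noiseRsd, " dark SD:", x$darkNoiseSd, "\n")
    invisible(x)
}

#' @rdname generatorConfig
#' @param cfg a `GeneratorConfig`.
#' @export
wavenumberAxis <- function(cfg) {
    .checkGeneratorConfig(cfg)
    seq(cfg$axisStart, cfg$axisStop, by = cfg$axisStep)
}

.baseline <- function(cfg, nu) {
    cfg$baselineAmplitude * exp(-(nu - cfg$axisStart) / cfg$baselineDecay) +
        cfg$baselineOffset
}

.cleanIntensity <- function(cfg, concentration, nu) {
    pk <- cfg$peaks
    target <- cfg$calibrationSlope * concentration + cfg$calibrationIntercept
    alpha <- pk$alpha
    if (any(pk$sensitive)) {
        scale <- target / pk$alpha[pk$quant]
        alpha[pk$sensitive] <- pk$alpha[pk$sensitive] * scale
    }
    y <- .baseline(cfg, nu)
    for (i in seq_len(nrow(pk)))
        if (alpha[i] > 0)
            y <- y + voigtProfile(nu, pk$theta[i], alpha[i], pk$omega[i],
                                  pk$gamma[i])
    y
}

.withSeed <- function(seed, code) {
    if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate one synthetic SERS spectrum
#'
#' Evaluates the clean pseudo-Voigt + baseline model at `concentration`, then
#' applies multiplicative noise (`sd = noiseRsd *` clean intensity) and
#' additive dark noise. With `noiseRsd = 0` and `darkNoiseSd = 0` the result
#' is a deterministic function of `(cfg, concentration)`.
#'
#' @param cfg a [generatorConfig()].
#' @param concentration analyte concentration (non-negative, in `cfg$unit`).
#' @param sampleId label for the generated spectrum.
#' @return a single-sample [SpectrumSet-class].
#' @examples
#' cfg <- generatorConfig(noiseRsd = 0)
#' s <- generateSpectrum(cfg, 1.0)
#' peakHeight(s, 1379)
#' @export
generateSpectrum <- function(cfg, concentration, sampleId = "sample_1") {
    .checkGeneratorConfig(cfg)
    if (!is.numeric(concentration) || length(concentration) != 1L ||
        is.na(concentration) || concentration < 0)
        stop("'concentration' must be a single non-negative number")
    nu <- wavenumberAxis(cfg)
    clean <- .cleanIntensity(cfg, concentration, nu)
    y <- .withSeed(cfg$seed, .addNoise(cfg, clean))
    SpectrumSet(y, nu, sampleIds = sampleId,
                concentrations = concentration, unit = cfg$unit)
}

.addNoise <- function(cfg, clean) {
    y <- clean
    if (cfg$noiseRsd > 0)
        y <- y * (1 + stats::rnorm(length(y), sd = cfg$noiseRsd))
    if (cfg$darkNoiseSd > 0)
        y <- y + stats::rnorm(length(y), sd = cfg$darkNoiseSd)
    y
}

#' Generate a replicated concentration study
#'
#' Produces `length(concentrations) * replicates` spectra with concentration
#' and replicate-group metadata attached — e.g. the residue design of five
#' levels \{0, 0.1, 0.5, 1.5, 10\} with four replicates each. With a non-NULL
#' `cfg$seed` the whole study is reproducible and the global RNG is left
#' untouched.
#'
#' @param cfg a [generatorConfig()].
#' @param concentrations non-empty numeric vector of levels (non-negative).
#' @param replicates spectra per level (>= 1).
#' @return a [SpectrumSet-class] with `concentration` and `group` columns.
#' @examples
#' cfg <- generatorConfig(peaks = epidermisPeaks(), unit = "ug/g", seed = 7)
#' generateStudy(cfg, c(0, 0.1, 0.5, 1.5, 10), replicates = 4)
#' @export
generateStudy <- function(cfg, concentrations, replicates = 4L) {
    .checkGeneratorConfig(cfg)
    if (length(concentrations) == 0L)
        stop("'concentrations' must be non-empty")
    if (any(is.na(concentrations) | concentrations < 0))
        stop("'concentrations' must be non-negative")
    replicates <- as.integer(replicates)
    if (is.na(replicates) || replicates < 1L)
        stop("'replicates' must be at least 1")
    nu <- wavenumberAxis(cfg)
    design <- expand.grid(rep = seq_len(replicates),
                          conc = concentrations)[, 2:1]
    ints <- .withSeed(cfg$seed, vapply(
        seq_len(nrow(design)),
        function(i) .addNoise(cfg, .cleanIntensity(cfg, design$conc[i], nu)),
        numeric(length(nu))
    ))
    ids <- sprintf("c%g_r%d", design$conc, design$rep)
    SpectrumSet(ints, nu, sampleIds = ids,
                concentrations = design$conc,
                groups = sprintf("c%g", design$conc),
                unit = cfg$unit)
}

#' Read a generator configuration from YAML
#'
#' The YAML mirrors [generatorConfig()] field-for-field (camelCase keys).
#' `peaks` may be the name of a built-in library (`"thiram"`, `"rhodamine"`,
#' `"epidermis"`) or a list of records with `theta`, `alpha`, `omega`,
#' `gamma`, `sensitive`, `quant`.
#'
#' @param path YAML file.
#' @return a `GeneratorConfig`.
#' @export
readGeneratorConfig <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    y <- yaml::read_yaml(path)
    if (!is.null(y$peaks)) {
        y$peaks <- if (is.character(y$peaks)) {
            switch(match.arg(y$peaks, c("thiram", "rhodamine", "epidermis")),
                   thiram = thiramPeaks(),
                   rhodamine = rhodaminePeaks(),
                   epidermis = epidermisPeaks())
        } else {
            do.call(rbind, lapply(y$peaks, function(p)
                data.frame(theta = p$theta, alpha = p$alpha,
                           omega = p$omega, gamma = p$gamma,
                           sensitive = isTRUE(p$sensitive),
                           quant = isTRUE(p$quant))))
        }
    }
    known <- names(formals(generatorConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown generator config field(s): ",
             paste(unknown, collapse = ", "))
    do.call(generatorConfig, y)
}
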