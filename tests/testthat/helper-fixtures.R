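# Shared fixtures: all synthetic, built in code.

quietConfig <- function(...) {
    generatorConfig(noiseRsd = 0, ...)
}

singlePeakConfig <- function(omega = 1000, gamma = 10, theta = 0.7, ...) {
    generatorConfig(
        peaks = peakParams(theta = theta, alpha = 1, omega = omega,
                           gamma = gamma, sensitive = TRUE, quant = TRUE),
        noiseRsd = 0, ...)
}

# log-spaced thiram concentration series over the linear calibration range
calibrationConcentrations <- function(n = 20) {
    exp(seq(log(0.1), log(5.0), length.out = n))
}
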