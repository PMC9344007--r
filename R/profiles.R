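#' Pseudo-Voigt line shape
#'
#' The pseudo-Voigt profile approximates the Gaussian/Lorentzian convolution
#' as a weighted sum of a Gaussian and a Lorentzian peak sharing one center
#' and width parameter:
#' \deqn{V(\nu) = \theta \alpha \exp\!\left[-4\ln 2\,(\nu-\omega)^2/\gamma^2\right]
#'   + (1-\theta)\,\alpha\,\gamma^2 / \left[(\nu-\omega)^2 + \gamma^2\right]}
#' where \eqn{\theta \in [0,1]} is the Gauss-Lorentz mixing coefficient,
#' \eqn{\alpha} the peak height, \eqn{\omega} the center (cm\eqn{^{-1}}) and
#' \eqn{\gamma} the half-width parameter (cm\eqn{^{-1}}). Note the convention
#' mismatch inherited from the field's common form: the Gaussian term treats
#' \eqn{\gamma} as a full width at half maximum (the \eqn{4\ln 2} factor)
#' while the Lorentzian term treats it as a half width at half maximum; the
#' formula is implemented verbatim rather than harmonized. At
#' \eqn{\nu = \omega} both terms peak and \eqn{V(\omega) = \alpha} for any
#' \eqn{\theta}.
#'
#' @param nu numeric vector of wavenumbers (cm\eqn{^{-1}}).
#' @param theta mixing coefficient in \[0, 1\]; 1 = pure Gaussian term,
#'   0 = pure Lorentzian term.
#' @param alpha peak height (a.u.), non-negative.
#' @param omega peak center (cm\eqn{^{-1}}).
#' @param gamma half-width parameter (cm\eqn{^{-1}}), strictly positive.
#' @return intensity vector, same length as `nu`.
#' @examples
#' voigtProfile(1005, theta = 0.5, alpha = 2, omega = 1000, gamma = 10) # 1.3
#' @export
voigtProfile <- function(nu, theta, alpha, omega, gamma) {
    stopifnot(is.numeric(nu), length(theta) == 1L, length(alpha) == 1L,
              length(omega) == 1L, length(gamma) == 1L)
    if (is.na(theta) || theta < 0 || theta > 1)
        stop("'theta' must lie in [0, 1]")
    if (is.na(alpha) || alpha < 0)
        stop("'alpha' must be non-negative")
    if (is.na(gamma) || gamma <= 0)
        stop("'gamma' must be strictly positive")
    d2 <- (nu - omega)^2
    theta * alpha * exp(-4 * log(2) * d2 / gamma^2) +
        (1 - theta) * alpha * gamma^2 / (d2 + gamma^2)
}

#' Lorentzian line shape
#'
#' \deqn{L(\nu) = \frac{1}{\pi} \frac{\gamma_L^2}{(\nu-\omega)^2 + \gamma_L^2}}
#' with \eqn{\gamma_L} the half width at half maximum. In this form the
#' numerator carries \eqn{\gamma_L^2} (not \eqn{\gamma_L}), so the profile is
#' not unit-area normalized: its peak value is \eqn{1/\pi} for every width.
#'
#' @param nu wavenumber vector (cm\eqn{^{-1}}).
#' @param gammaL half width at half maximum (cm\eqn{^{-1}}), > 0.
#' @param omega peak center (cm\eqn{^{-1}}).
#' @return intensity vector.
#' @export
lorentzProfile <- function(nu, gammaL, omega) {
    stopifnot(is.numeric(nu), length(gammaL) == 1L, length(omega) == 1L)
    if (is.na(gammaL) || gammaL <= 0)
        stop("'gammaL' must be strictly positive")
    (1 / pi) * gammaL^2 / ((nu - omega)^2 + gammaL^2)
}

#' Gaussian line shape
#'
#' \deqn{G(\nu) = \frac{1}{\gamma_G} \left(\frac{\ln 2}{\pi}\right)^{1/2}
#'   \exp\!\left[-\left(\frac{\nu-\omega}{\gamma_G}\right)^2 \ln 2\right]}
#' with \eqn{\gamma_G} the half width at half maximum of this form: at
#' \eqn{\nu = \omega \pm \gamma_G} the value is half the center value
#' \eqn{(\ln 2/\pi)^{1/2}/\gamma_G}.
#'
#' @param nu wavenumber vector (cm\eqn{^{-1}}).
#' @param gammaG half width at half maximum (cm\eqn{^{-1}}), > 0.
#' @param omega peak center (cm\eqn{^{-1}}).
#' @return intensity vector.
#' @export
gaussProfile <- function(nu, gammaG, omega) {
    stopifnot(is.numeric(nu), length(gammaG) == 1L, length(omega) == 1L)
    if (is.na(gammaG) || gammaG <= 0)
        stop("'gammaG' must be strictly positive")
    (1 / gammaG) * sqrt(log(2) / pi) *
        exp(-((nu - omega) / gammaG)^2 * log(2))
}

#' Pseudo-Voigt peak parameter records
#'
#' A peak library is a `data.frame` with one row per band and columns
#' `theta`, `alpha`, `omega`, `gamma`, `sensitive`, `quant`:
#' `sensitive` flags bands whose height scales with analyte concentration,
#' and exactly one sensitive band may be flagged `quant` — the quantitation
#' band whose clean height the generator pins to the calibration line (the
#' other sensitive bands keep their relative heights). `alpha` of
#' non-sensitive bands is an absolute height in a.u.; `alpha` of sensitive
#' bands only sets relative proportions.
#'
#' @param theta,alpha,omega,gamma pseudo-Voigt parameters, one per band (see
#'   [voigtProfile()]).
#' @param sensitive logical, concentration-sensitive flag.
#' @param quant logical, quantitation-band flag.
#' @return a peak-library `data.frame`.
#' @export
peakParams <- function(theta, alpha, omega, gamma,
                       sensitive = TRUE, quant = FALSE) {
    df <- data.frame(theta = theta, alpha = alpha, omega = omega,
                     gamma = gamma, sensitive = sensitive, quant = quant)
    .checkPeakLibrary(df)
    df
}

.checkPeakLibrary <- function(peaks) {
    stopifnot(is.data.frame(peaks),
              all(c("theta", "alpha", "omega", "gamma", "sensitive",
                    "quant") %in% names(peaks)))
    if (any(peaks$theta < 0 | peaks$theta > 1))
        stop("peak 'theta' values must lie in [0, 1]")
    if (any(peaks$alpha < 0))
        stop("peak 'alpha' values must be non-negative")
    if (any(peaks$gamma <= 0))
        stop("peak 'gamma' values must be strictly positive")
    if (any(peaks$quant & !peaks$sensitive))
        stop("the quantitation peak must be concentration-sensitive")
    if (sum(peaks$quant) > 1L)
        stop("at most one peak may be flagged 'quant'")
    invisible(peaks)
}

#' Built-in peak libraries
#'
#' Band centers follow the characteristic Raman bands of each system:
#' \describe{
#'   \item{`thiramPeaks()`}{562 (S-S stretch), 929 (C=S / C-N stretch), 1146
#'     and 1514 (C-N stretch, CH3 rocking), 1379 cm\eqn{^{-1}} (C-N stretch +
#'     CH3 symmetric deformation) — the strongest band and the quantitation
#'     band. Relative heights make 1379 dominant; all bands scale with
#'     concentration.}
#'   \item{`rhodaminePeaks()`}{R6G probe bands at 1362 (C-H in-plane bend,
#'     quantitation) and 1510 cm\eqn{^{-1}} (N-H in-plane bend), used for
#'     substrate uniformity/RSD studies.}
#'   \item{`epidermisPeaks()`}{fruit-epidermis bands at 750 (quantitation,
#'     concentration-sensitive), 830, 1165 and 1560 cm\eqn{^{-1}} (fixed
#'     matrix background bands).}
#' }
#'
#' @return a peak-library `data.frame` (see [peakParams()]).
#' @export
thiramPeaks <- function() {
    peakParams(theta = 0.7,
               alpha = c(0.45, 0.55, 0.50, 1.00, 0.65),
               omega = c(562, 929, 1146, 1379, 1514),
               gamma = 10,
               sensitive = TRUE,
               quant = c(FALSE, FALSE, FALSE, TRUE, FALSE))
}

#' @rdname thiramPeaks
#' @export
rhodaminePeaks <- function() {
    peakParams(theta = 0.7,
               alpha = c(1.00, 0.90),
               omega = c(1362, 1510),
               gamma = 10,
               sensitive = TRUE,
               quant = c(TRUE, FALSE))
}

#' @rdname thiramPeaks
#' @export
epidermisPeaks <- function() {
    peakParams(theta = 0.7,
               alpha = c(1.00, 3000, 2500, 2000),
               omega = c(750, 830, 1165, 1560),
               gamma = 10,
               sensitive = c(TRUE, FALSE, FALSE, FALSE),
               quant = c(TRUE, FALSE, FALSE, FALSE))
}
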