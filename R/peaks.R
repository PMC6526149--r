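#' Pseudo-Voigt line shape
#'
#' Weighted sum of a Gaussian and a Lorentzian sharing position and full
#' width at half maximum: `eta * G + (1 - eta) * L`, both normalized to unit
#' height so `height` is the actual peak maximum.
#'
#' @param x axis values (ppm).
#' @param position peak center (ppm).
#' @param height peak maximum (intensity units).
#' @param fwhm full width at half maximum (ppm), > 0.
#' @param gauss_fraction Gaussian weight eta in `[0, 1]`.
#' @return intensity at each `x`.
#' @export
pseudo_voigt <- function(x, position, height, fwhm, gauss_fraction) {
  u <- (x - position) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  height * (gauss_fraction * g + (1 - gauss_fraction) * l)
}

#' Analytic area of a pseudo-Voigt peak
#'
#' Gaussian part integrates to `h * w * sqrt(pi / (4 log 2))`, Lorentzian
#' part to `h * w * pi / 2`.
#'
#' @inheritParams pseudo_voigt
#' @return peak area in intensity x ppm units.
#' @export
pv_area <- function(height, fwhm, gauss_fraction) {
  height * fwhm * (gauss_fraction * sqrt(pi / (4 * log(2))) +
                     (1 - gauss_fraction) * pi / 2)
}

#' Define a pseudo-Voigt peak
#'
#' @inheritParams pseudo_voigt
#' @return a one-row `data.frame` with columns `position`, `height`, `fwhm`,
#'   `gauss_fraction`.
#' @export
pv_peak <- function(position, height, fwhm, gauss_fraction = 0.5) {
  stopifnot(fwhm > 0, height >= 0,
            gauss_fraction >= 0, gauss_fraction <= 1)
  data.frame(position = position, height = height, fwhm = fwhm,
             gauss_fraction = gauss_fraction)
}

#' Evaluate a pseudo-Voigt peak table on an axis
#'
#' @param x axis values.
#' @param peaks `data.frame` of [pv_peak()] rows.
#' @return summed intensity at each `x`.
#' @export
eval_peak_table <- function(x, peaks) {
  y <- numeric(length(x))
  for (k in seq_len(nrow(peaks))) {
    y <- y + pseudo_voigt(x, peaks$position[k], peaks$height[k],
                          peaks$fwhm[k], peaks$gauss_fraction[k])
  }
  y
}

# Discrete Hilbert transform of a real vector (periodic, FFT-based).
# Returns the quadrature component such that rotating the analytic signal
# a = y + 1i*H(y) by exp(1i*phi) mixes absorption into dispersion.
hilbert_transform <- function(y) {
  n <- length(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(stats::fft(y) * h, inverse = TRUE) / n)
}
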