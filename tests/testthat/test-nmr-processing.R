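test_that("process_fid zero fills, apodizes and produces the analytic linewidth", {
  fid <- lorentz_fid(offset_hz = 50, t2 = 0.3, n = 16384L)
  spec <- process_fid(fid, processing_params(zero_fill_to = 65536L,
                                             line_broadening = 0.5))
  expect_length(spec$intensity, 65536L)
  expect_true(all(is.finite(spec$intensity)))
  # closed-form width oracle: FWHM(Hz) = LB + 1/(pi*T2)
  fwhm_hz <- measure_fwhm(spec) * fid$spectrometer_freq
  expect_equal(fwhm_hz, 0.5 + 1 / (pi * 0.3), tolerance = 0.02)
  # line position: carrier ppm + offset/freq
  expect_equal(spec$axis[which.max(spec$intensity)],
               5.5 + 50 / 43.32, tolerance = 1e-3)
  # zero LB leaves the natural width
  spec0 <- process_fid(fid, processing_params(zero_fill_to = 65536L,
                                              line_broadening = 0))
  expect_equal(measure_fwhm(spec0) * 43.32, 1 / (pi * 0.3), tolerance = 0.02)
})

test_that("process_fid validates its inputs", {
  fid <- lorentz_fid(0, 0.1, n = 1024L)
  expect_error(process_fid(fid, processing_params(zero_fill_to = 512L)),
               "zero_fill_to")
  expect_error(new_fid(complex(real = numeric(0)), 1e-3), "2 points")
  empty <- new_fid(rep(0 + 0i, 16L), 1e-3)
  expect_error(process_fid(empty), "empty")
})

test_that("process_fid is linear in the FID", {
  set.seed(1)
  s1 <- complex(real = rnorm(256), imaginary = rnorm(256))
  s2 <- complex(real = rnorm(256), imaginary = rnorm(256))
  p <- processing_params(zero_fill_to = 512L)
  f <- function(s) process_fid(new_fid(s, 2e-3), p)$intensity
  expect_equal(f(2 * s1 - 3 * s2), 2 * f(s1) - 3 * f(s2), tolerance = 1e-10)
})

test_that("baseline_correct removes polynomials and preserves peak areas", {
  x <- seq(0, 11, length.out = 2048)
  # pure polynomial of the fitted order vanishes
  poly_spec <- new_spectrum(x, 2 + 0.5 * x - 0.03 * x^2)
  out <- baseline_correct(poly_spec, order = 2L)
  expect_lt(max(abs(out$intensity)), 1e-6 * max(abs(poly_spec$intensity)))
  # peak + constant offset: offset removed, area kept within 1%
  # (Gaussian shape: Lorentzian tails would legitimately leak into any
  # baseline estimate over a finite window)
  peak <- pseudo_voigt(x, 7.1, 10, 0.08, 1)
  sp <- new_spectrum(x, peak + 5)
  out <- baseline_correct(sp, order = 0L)
  expect_equal(trapz(x, out$intensity), trapz(x, peak), tolerance = 0.01)
  expect_lt(abs(median(out$intensity[abs(x - 7.1) > 1])), 1e-3)
  # flat zero spectrum unchanged
  z <- new_spectrum(x, rep(0, length(x)))
  expect_equal(baseline_correct(z, 1L)$intensity, z$intensity)
})

test_that("baseline_correct is idempotent", {
  set.seed(2)
  x <- seq(0, 11, length.out = 1024)
  y <- pseudo_voigt(x, 5, 8, 0.1, 0.3) + 1 + 0.2 * x + rnorm(1024, 0, 0.05)
  once <- baseline_correct(new_spectrum(x, y), order = 1L)
  twice <- baseline_correct(once, order = 1L)
  expect_lt(max(abs(twice$intensity - once$intensity)),
            1e-8 * max(abs(once$intensity)))
})

test_that("auto_phase recovers zero- and first-order phase errors", {
  x <- seq(0, 11, length.out = 2048)
  base <- synth_nmr_spectrum(c(oFNB = 0.5), axis = x)
  # already phased: correction within 1 degree of zero
  ph <- auto_phase(base)
  expect_lt(abs(ph$meta$phase[1]), 1)
  # 90-degree zero-order rotation recovered within 2 degrees
  rot <- synth_nmr_spectrum(c(oFNB = 0.5), axis = x, phase_error = 90)
  ph <- auto_phase(rot)
  expect_lt(abs(ph$meta$phase[1] - 90), 2)
  # two lines under a 30 deg/spectrum first-order gradient: peak maxima
  # restored within 1% of the unrotated heights
  two <- synth_nmr_spectrum(c(oFNB = 0.4, LiHMDS = 0.4), axis = x)
  cplx <- two$meta$complex
  frac <- (seq_along(x) - 1) / (length(x) - 1) - 0.5
  twisted <- two
  twisted$meta$complex <- cplx * exp(1i * (10 + 30 * frac) * pi / 180)
  twisted$intensity <- Re(twisted$meta$complex)
  ph <- auto_phase(twisted)
  for (pos in c(8.08, 0.08)) {
    idx <- which(abs(x - pos) < 0.3)
    expect_equal(max(ph$intensity[idx]), max(two$intensity[idx]),
                 tolerance = 0.01)
  }
  expect_error(auto_phase(new_spectrum(x, rep(0, length(x)))), "zero")
})

test_that("align_to_reference recovers and clamps interval shifts", {
  x <- seq(0, 11, length.out = 2048)
  ref <- new_spectrum(x, pseudo_voigt(x, 3.6, 10, 0.1, 0.4))
  expect_equal(align_to_reference(ref, ref, list(c(3, 4)))$meta$alignment_lags, 0L)
  # spectrum delayed by +7 grid points: reported correction is -7
  shifted <- new_spectrum(x, c(rep(0, 7), head(ref$intensity, -7)))
  al <- align_to_reference(shifted, ref, list(c(3, 4)), max_shift = 20L)
  expect_equal(al$meta$alignment_lags, -7L)
  idx <- which(x >= 3 & x <= 4)
  inner <- head(idx, -7)   # the last 7 points are edge-value fill
  expect_equal(al$intensity[inner], ref$intensity[inner], tolerance = 1e-8)
  # true shift beyond max_shift: clamped, with a warning
  big <- new_spectrum(x, c(rep(0, 12), head(ref$intensity, -12)))
  expect_warning(al <- align_to_reference(big, ref, list(c(3, 4)), max_shift = 5L),
                 "clamped")
  expect_equal(abs(al$meta$alignment_lags), 5L)
  expect_error(align_to_reference(ref, ref, list(c(10, 12))), "outside")
})

test_that("alignment preserves the total spectral integral", {
  x <- seq(0, 11, length.out = 2048)
  ref <- new_spectrum(x, pseudo_voigt(x, 3.6, 10, 0.1, 0.4) +
                        pseudo_voigt(x, 7.2, 6, 0.08, 0.6))
  shifted <- new_spectrum(x, c(rep(0, 5), head(ref$intensity, -5)))
  al <- align_to_reference(shifted, ref, list(c(3, 4.2), c(6.8, 7.6)),
                           max_shift = 10L)
  expect_equal(trapz(x, al$intensity), trapz(x, shifted$intensity),
               tolerance = 1e-3)
})

test_that("full preparation chain recovers positions and areas", {
  # synth spectrum with baseline, phase error and a global shift; the
  # chain (phase, baseline, align) restores peaks within one axis step
  # and areas within 2%
  x <- seq(-1, 11, length.out = 4096)
  dx <- diff(x)[1]
  truth <- synth_nmr_spectrum(c(oFNB = 0.6, LiHMDS = 0.8), axis = x)
  messy <- synth_nmr_spectrum(c(oFNB = 0.6, LiHMDS = 0.8), axis = x,
                              shift_error = 4 * dx, phase_error = 25,
                              baseline = c(0.4, 0.05))
  # offset spectra need an iterated preparation: the first phase pass
  # lands within a few degrees (the offset flattens the negative-area
  # objective), baseline removal then sharpens it for the second pass
  out <- auto_phase(messy)
  out <- baseline_correct(out, order = 1L)
  out <- auto_phase(out)
  out <- align_to_reference(out, truth, list(c(6.8, 8.6), c(-0.4, 0.6)),
                            max_shift = 20L)
  for (win in list(c(6.8, 8.6), c(-0.4, 0.6))) {
    idx <- which(x >= win[1] & x <= win[2])
    expect_lt(abs(x[idx][which.max(out$intensity[idx])] -
                    x[idx][which.max(truth$intensity[idx])]), 1.5 * dx)
    expect_equal(trapz(x[idx], out$intensity[idx]),
                 trapz(x[idx], truth$intensity[idx]), tolerance = 0.02)
  }
})
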