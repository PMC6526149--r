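# Shared oracles and builders, independent of the implementation paths
# they are used to check.

# trapezoid integral on a (possibly non-uniform) grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# complex FID of a single exponentially decaying sinusoid:
# offset_hz from the carrier, decay time t2 (s)
lorentz_fid <- function(offset_hz, t2, n = 8192L, dt = 2e-3, amp = 1) {
  t <- (seq_len(n) - 1) * dt
  new_fid(amp * exp(2i * pi * offset_hz * t - t / t2), dwell_time = dt)
}

# FWHM of the tallest line in a spectrum, by linear interpolation at
# half maximum on both flanks
measure_fwhm <- function(spec) {
  y <- spec$intensity
  x <- spec$axis
  i <- which.max(y)
  half <- y[i] / 2
  il <- max(which(y[1:i] <= half))
  ir <- i - 1 + min(which(y[i:length(y)] <= half))
  xl <- x[il] + (x[il + 1] - x[il]) * (half - y[il]) / (y[il + 1] - y[il])
  xr <- x[ir - 1] + (x[ir] - x[ir - 1]) * (half - y[ir - 1]) / (y[ir] - y[ir - 1])
  xr - xl
}

# default library handles, shared across tests
lib5 <- default_component_library()
models5 <- unname(lib5)
numap5 <- nu_map(lib5)
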