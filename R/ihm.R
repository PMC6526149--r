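#' Pure-component model for Indirect Hard Modeling
#'
#' A named analyte represented as a sum of pseudo-Voigt peaks.  The
#' relative peak areas are frozen when the model is built; a mixture fit
#' may rescale the whole component, shift it, and scale its width, but
#' never change the intra-component area ratios.
#'
#' @param name analyte identifier.
#' @param peaks `data.frame` of [pv_peak()] rows.
#' @param nu number of nuclei contributing to the modeled signal (the
#'   divisor in the area-to-concentration conversion), integer >= 1.
#' @param constraints list with elements `global_shift` (ppm, default
#'   0.05), `peak_shift` (ppm, default 0.01) and `width_scale`
#'   (`c(lo, hi)`, default `c(0.8, 1.25)`).
#' @return object of class `pure_component_model` with frozen
#'   `relative_areas` and the reference `area` at unit weight.
#' @export
pure_component_model <- function(name, peaks, nu,
                                 constraints = list()) {
  stopifnot(nrow(peaks) >= 1L, nu >= 1, nu == round(nu))
  areas <- pv_area(peaks$height, peaks$fwhm, peaks$gauss_fraction)
  total <- sum(areas)
  if (total <= 0) stop("model has zero total area", call. = FALSE)
  cons <- utils::modifyList(
    list(global_shift = 0.05, peak_shift = 0.01, width_scale = c(0.8, 1.25)),
    constraints)
  structure(list(name = name, peaks = peaks, nu = as.integer(nu),
                 relative_areas = areas / total, area = total,
                 constraints = cons),
            class = "pure_component_model")
}

#' @export
print.pure_component_model <- function(x, ...) {
  cat(sprintf("<component model> %s: %d peak(s), nu = %d, area = %.4g\n",
              x$name, nrow(x$peaks), x$nu, x$area))
  invisible(x)
}

#' Evaluate a pure-component model on an axis
#'
#' Renders a component at area weight `w`, global position shift `d`
#' (ppm), common width-scale factor `s` and optional per-peak shifts
#' `dk` — the same degrees of freedom the mixture fit adjusts.
#'
#' @param x ppm axis values.
#' @param model a [pure_component_model()].
#' @param w,d,s,dk component weight, global shift, width scale, per-peak
#'   shifts (scalar or one per peak).
#' @return intensity at each `x`.
#' @export
eval_component <- function(x, model, w = 1, d = 0, s = 1, dk = 0) {
  p <- model$peaks
  y <- numeric(length(x))
  if (length(dk) == 1L) dk <- rep(dk, nrow(p))
  for (k in seq_len(nrow(p))) {
    y <- y + pseudo_voigt(x, p$position[k] + d + dk[k], p$height[k],
                          p$fwhm[k] * s, p$gauss_fraction[k])
  }
  w * y
}

# Local maxima separated by at least `sep` points, strongest first.
pick_peaks <- function(y, n, sep = 5L) {
  n_pts <- length(y)
  cand <- which(y > c(-Inf, y[-n_pts]) & y >= c(y[-1L], -Inf))
  cand <- cand[order(y[cand], decreasing = TRUE)]
  sel <- integer(0)
  for (i in cand) {
    if (!length(sel) || min(abs(sel - i)) >= sep) sel <- c(sel, i)
    if (length(sel) == n) break
  }
  sort(sel)
}

#' Fit a pure-component model to a pure-analyte spectrum
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt) of `n_peaks`
#' pseudo-Voigt functions plus a linear baseline.  The relative areas of
#' the fitted peaks are frozen into the returned model.
#'
#' @param spec a pure-analyte `nmr_spectrum`.
#' @param n_peaks number of peaks to fit.
#' @param name analyte name for the returned model.
#' @param nu proton count for the returned model.
#' @param init_positions optional starting positions (ppm); peak-picked
#'   from the spectrum when missing.
#' @param constraints passed to [pure_component_model()].
#' @return a [pure_component_model()]; fit diagnostics in
#'   `attr(, "fit")` (`r_squared`, `residual_norm`).
#' @export
fit_pure_component <- function(spec, n_peaks, name = "component", nu = 1L,
                               init_positions = NULL, constraints = list()) {
  stopifnot(is_spectrum(spec), n_peaks >= 1L)
  x <- spec$axis; y <- spec$intensity
  if (max(abs(y)) == 0 || stats::sd(y) == 0)
    stop("flat spectrum: nothing to fit", call. = FALSE)
  if (is.null(init_positions)) {
    idx <- pick_peaks(y, n_peaks)
    if (length(idx) < n_peaks)
      stop("could not locate ", n_peaks, " peaks", call. = FALSE)
    init_positions <- x[idx]
  }
  dx <- stats::median(diff(x))
  h0 <- vapply(init_positions, function(p) max(y[abs(x - p) <= 5 * dx]), 0)
  w0 <- rep(10 * dx, n_peaks)
  span <- diff(range(x))
  # parameter layout: [pos, h, fwhm, eta] per peak, then 2 baseline coefs
  par0 <- c(rbind(init_positions, pmax(h0, 1e-6 * max(y)), w0, 0.5), 0, 0)
  lower <- c(rbind(init_positions - 0.2, 0, 2 * dx, 0), -Inf, -Inf)
  upper <- c(rbind(init_positions + 0.2, Inf, span / 2, 1), Inf, Inf)
  xm <- mean(x)
  fn <- function(p) {
    yh <- p[4 * n_peaks + 1] + p[4 * n_peaks + 2] * (x - xm)
    for (k in seq_len(n_peaks)) {
      q <- p[(4 * (k - 1) + 1):(4 * k)]
      yh <- yh + pseudo_voigt(x, q[1], q[2], q[3], q[4])
    }
    y - yh
  }
  fit <- minpack.lm::nls.lm(par0, lower, upper, fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ptol = 1e-12, ftol = 1e-12))
  if (fit$info == 0 || fit$info == 9)
    stop("pure-component fit did not converge (residual norm ",
         format(fit$deviance, digits = 4), ")", call. = FALSE)
  p <- fit$par
  peaks <- do.call(rbind, lapply(seq_len(n_peaks), function(k) {
    q <- p[(4 * (k - 1) + 1):(4 * k)]
    pv_peak(q[1], q[2], q[3], q[4])
  }))
  peaks <- peaks[order(peaks$position), ]
  rownames(peaks) <- NULL
  model <- pure_component_model(name, peaks, nu, constraints)
  r2 <- 1 - fit$deviance / sum((y - mean(y))^2)
  attr(model, "fit") <- list(r_squared = r2, residual_norm = fit$deviance,
                             baseline = p[4 * n_peaks + 1:2])
  model
}

#' Fit a constrained superposition of component models to a mixture
#' spectrum
#'
#' Minimizes the squared residual over, per component, a non-negative
#' area weight, a bounded global position shift, bounded per-peak shifts
#' and a bounded common width-scale factor, plus a jointly fitted
#' polynomial baseline.  Peak heights and the intra-component area ratios
#' stay fixed at the model values, so each component can only be scaled,
#' shifted and (uniformly) broadened as a whole.
#'
#' @param spec mixture `nmr_spectrum`.
#' @param models list of [pure_component_model()] objects whose peaks lie
#'   within the spectrum axis range.
#' @param baseline_order polynomial baseline order (default 2).
#' @param per_peak_shifts fit individual peak shifts within
#'   `constraints$peak_shift` (default `TRUE`; disable for speed in long
#'   campaign runs where the global shift suffices).
#' @param start optional warm-start parameter vector from a previous fit.
#' @param restarts extra deterministically jittered starts tried when the
#'   first fit leaves more than 5\% relative residual (default 2).
#' @return list of class `mixture_fit` with `weights`, `areas` (absolute
#'   integral per component, weight x width-scale x model reference area),
#'   `shifts`, `width_scales`, `peak_shifts`, `baseline_coeffs`,
#'   `residual_norm` and the raw parameter vector `par` (for warm starts).
#' @export
fit_mixture <- function(spec, models, baseline_order = 2L,
                        per_peak_shifts = TRUE, start = NULL, restarts = 2L) {
  stopifnot(is_spectrum(spec), length(models) >= 1L)
  if (!all(vapply(models, inherits, TRUE, "pure_component_model")))
    stop("`models` must be pure_component_model objects", call. = FALSE)
  x <- spec$axis; y <- spec$intensity
  rng <- range(x)
  for (m in models) {
    if (any(m$peaks$position < rng[1]) || any(m$peaks$position > rng[2]))
      stop("peaks of component '", m$name, "' fall outside the spectrum axis",
           call. = FALSE)
  }
  nc <- length(models)
  npk <- vapply(models, function(m) nrow(m$peaks), 0L)
  nb <- baseline_order + 1L
  # fit only where some component has support (dilated), plus a thinned
  # global sample so the baseline stays anchored in signal-free regions
  amp <- numeric(length(x))
  for (m in models) amp <- amp + eval_component(x, m)
  mask <- amp > 1e-4 * max(amp)
  r <- 12L
  mask <- as.logical(stats::filter(mask, rep(1, 2 * r + 1), sides = 2) > 0)
  mask[is.na(mask)] <- TRUE
  mask[seq(1L, length(x), by = 8L)] <- TRUE
  x_full <- x
  x <- x[mask]; y <- y[mask]
  xm <- mean(x_full); xs <- diff(rng) / 2
  xn <- (x - xm) / xs
  B <- vapply(seq_len(nb) - 1L, function(d) xn^d, numeric(length(x)))

  # index bookkeeping: per component (w, d, s), then per-peak shifts, then
  # baseline coefficients
  i_w <- seq_len(nc) * 3L - 2L
  i_d <- i_w + 1L
  i_s <- i_w + 2L
  i_pk <- if (per_peak_shifts) 3L * nc + seq_len(sum(npk)) else integer(0)
  i_b <- 3L * nc + length(i_pk) + seq_len(nb)
  pk_of <- rep(seq_len(nc), npk)

  model_eval <- function(p) {
    yh <- drop(B %*% p[i_b])
    for (c in seq_len(nc)) {
      dk <- if (per_peak_shifts) p[i_pk[pk_of == c]] else 0
      yh <- yh + eval_component(x, models[[c]], p[i_w[c]], p[i_d[c]],
                                p[i_s[c]], dk)
    }
    yh
  }
  fn <- function(p) y - model_eval(p)
  # analytic Jacobian of the residual (-d model / d theta)
  jac <- function(p) {
    J <- matrix(0, length(x), length(p))
    ln16 <- 4 * log(2)
    for (c in seq_len(nc)) {
      pk <- models[[c]]$peaks
      dks <- if (per_peak_shifts) p[i_pk[pk_of == c]] else rep(0, nrow(pk))
      w <- p[i_w[c]]; d <- p[i_d[c]]; s <- p[i_s[c]]
      base <- numeric(length(x)); d_pos <- numeric(length(x))
      d_scale <- numeric(length(x))
      for (k in seq_len(nrow(pk))) {
        f <- pk$fwhm[k] * s
        u <- (x - (pk$position[k] + d + dks[k])) / f
        g <- exp(-ln16 * u^2)
        l <- 1 / (1 + 4 * u^2)
        eta <- pk$gauss_fraction[k]
        v <- pk$height[k] * (eta * g + (1 - eta) * l)
        Dk <- pk$height[k] * (eta * g * 2 * ln16 * u +
                                (1 - eta) * 8 * u * l^2)
        base <- base + v
        d_pos_k <- Dk / f
        d_pos <- d_pos + d_pos_k
        d_scale <- d_scale + Dk * u / f * pk$fwhm[k]
        if (per_peak_shifts)
          J[, i_pk[pk_of == c][k]] <- -w * d_pos_k
      }
      J[, i_w[c]] <- -base
      J[, i_d[c]] <- -w * d_pos
      J[, i_s[c]] <- -w * d_scale
    }
    J[, i_b] <- -B
    J
  }

  lower <- numeric(3L * nc + length(i_pk) + nb)
  upper <- lower
  for (c in seq_len(nc)) {
    cs <- models[[c]]$constraints
    lower[i_w[c]] <- 0;                  upper[i_w[c]] <- Inf
    lower[i_d[c]] <- -cs$global_shift;   upper[i_d[c]] <- cs$global_shift
    lower[i_s[c]] <- cs$width_scale[1];  upper[i_s[c]] <- cs$width_scale[2]
    if (per_peak_shifts) {
      lower[i_pk[pk_of == c]] <- -cs$peak_shift
      upper[i_pk[pk_of == c]] <- cs$peak_shift
    }
  }
  lower[i_b] <- -Inf; upper[i_b] <- Inf

  if (is.null(start)) {
    # linear projection for starting weights
    A <- vapply(models, function(m) eval_component(x, m), numeric(length(x)))
    w0 <- tryCatch(pmax(stats::lm.fit(cbind(A, B), y)$coefficients[seq_len(nc)], 0),
                   error = function(e) rep(max(y) / max(A), nc))
    w0[!is.finite(w0)] <- 0
    start <- numeric(length(lower))
    start[i_w] <- w0
    start[i_s] <- 1
  }
  start <- pmin(pmax(start, lower), upper)

  run_fit <- function(p0) {
    minpack.lm::nls.lm(p0, lower, upper, fn, jac,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 400, ptol = 1e-12, ftol = 1e-12))
  }
  fit <- run_fit(start)
  energy <- sum(y^2)
  if (energy > 0 && fit$deviance / energy > 0.05^2 && restarts > 0L) {
    for (j in seq_len(restarts)) {
      alt <- start
      alt[i_d] <- pmin(pmax((-1)^j * 0.01 * j, lower[i_d]), upper[i_d])
      f2 <- run_fit(alt)
      if (f2$deviance < fit$deviance) fit <- f2
    }
  }
  p <- fit$par
  yh_full <- local({
    xn_f <- (x_full - xm) / xs
    Bf <- vapply(seq_len(nb) - 1L, function(d) xn_f^d, numeric(length(x_full)))
    yh <- drop(Bf %*% p[i_b])
    for (c in seq_len(nc)) {
      dk <- if (per_peak_shifts) p[i_pk[pk_of == c]] else 0
      yh + eval_component(x_full, models[[c]], p[i_w[c]], p[i_d[c]],
                          p[i_s[c]], dk) -> yh
    }
    yh
  })
  w <- p[i_w]; s <- p[i_s]
  areas <- w * s * vapply(models, function(m) m$area, 0)
  names(areas) <- names(w) <- vapply(models, function(m) m$name, "")
  structure(list(
    weights = w,
    areas = areas,
    shifts = stats::setNames(p[i_d], names(w)),
    width_scales = stats::setNames(s, names(w)),
    peak_shifts = if (per_peak_shifts) split(p[i_pk], pk_of) else NULL,
    baseline_coeffs = p[i_b],
    residual_norm = fit$deviance,
    par = p,
    fitted = yh_full),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture fit>\n")
  print(round(rbind(weight = x$weights, area = x$areas,
                    shift_ppm = x$shifts, width_scale = x$width_scales), 5))
  cat(sprintf("residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' One-point absolute calibration of the area-to-concentration factor
#'
#' Inverts the quantification relation `c = xi * A / nu` on a stream of
#' known concentration (in the plant: the pure o-FNB feed pumped through
#' the sensors at start-up), giving `xi = c * nu / A`.
#'
#' @param area absolute fitted integral A of the calibration analyte.
#' @param nu number of nuclei behind that integral.
#' @param known_conc known concentration of the calibration stream,
#'   mol L-1.
#' @param source optional label of the calibration stream.
#' @return object of class `calibration_factor` with element `xi` in
#'   (mol L-1) / (area per nucleus).
#' @export
calibrate_xi <- function(area, nu, known_conc, source = "oFNB") {
  if (!is.finite(area) || area <= 0) stop("`area` must be > 0", call. = FALSE)
  if (nu < 1) stop("`nu` must be >= 1", call. = FALSE)
  if (!is.finite(known_conc) || known_conc <= 0)
    stop("`known_conc` must be > 0", call. = FALSE)
  structure(list(xi = known_conc * nu / area,
                 source = list(analyte = source, conc = known_conc, nu = nu)),
            class = "calibration_factor")
}

#' @export
print.calibration_factor <- function(x, ...) {
  cat(sprintf("<calibration factor> xi = %.6g (mol/L per area/nucleus), from %s at %.3g mol/L\n",
              x$xi, x$source$analyte, x$source$conc))
  invisible(x)
}

#' Convert fitted component areas to molar concentrations
#'
#' Applies `c_i = xi * A_i / nu_i` per component.
#'
#' @param fit a [fit_mixture()] result (or a named numeric vector of
#'   areas).
#' @param xi a [calibrate_xi()] factor (or a bare positive number).
#' @param nu_map named integer vector analyte -> nucleus count.
#' @return named numeric vector of concentrations, mol L-1.
#' @export
quantify <- function(fit, xi, nu_map) {
  areas <- if (inherits(fit, "mixture_fit")) fit$areas else fit
  xival <- if (inherits(xi, "calibration_factor")) xi$xi else xi
  missing_nu <- setdiff(names(areas), names(nu_map))
  if (length(missing_nu))
    stop("no nucleus count configured for: ",
         paste(missing_nu, collapse = ", "), call. = FALSE)
  conc <- xival * areas / nu_map[names(areas)]
  pmax(conc, 0)
}
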