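#' Feed stream definition
#'
#' A reactant dissolved in THF, dosed at a mass flow rate.
#'
#' @param species `"aniline"`, `"LiHMDS"` or `"oFNB"`.
#' @param mass_flow kg h-1, >= 0.
#' @param conc solution concentration, mol L-1.
#' @param density solution density, kg L-1 (default 0.90, consistent with
#'   the 900 kg m-3 mixture density).
#' @return list of class `feed_stream`; `molar_flow` in mol h-1.
#' @export
feed_stream <- function(species = c("aniline", "LiHMDS", "oFNB"),
                        mass_flow, conc, density = 0.90) {
  species <- match.arg(species)
  stopifnot(mass_flow >= 0, conc >= 0, density > 0)
  structure(list(species = species, mass_flow = mass_flow, conc = conc,
                 density = density,
                 molar_flow = mass_flow / density * conc),
            class = "feed_stream")
}

#' Start-up feed set consistent with the pilot recipe
#'
#' o-FNB 5.60 kg/h at 0.63 mol/L, aniline 3.68 kg/h at 0.96 mol/L and
#' LiHMDS 6.89 kg/h at 1.10 mol/L (a 2.14 stoichiometric excess of the
#' base over the 2:1 requirement).
#'
#' @param u optional `c(u_aniline, u_LiHMDS, u_oFNB)` kg h-1 overriding
#'   the default mass flows.
#' @param conc_LiHMDS LiHMDS feed concentration (changes when the dosing
#'   tank is refilled with a new batch).
#' @return named list of three [feed_stream()]s.
#' @export
default_feeds <- function(u = c(3.68, 6.89, 5.60), conc_LiHMDS = 1.10) {
  list(aniline = feed_stream("aniline", u[1], 0.96),
       LiHMDS = feed_stream("LiHMDS", u[2], conc_LiHMDS),
       oFNB = feed_stream("oFNB", u[3], 0.63))
}

#' Plant / simulator parameters
#'
#' @param k_sat saturation constant of the conversion law
#'   `eta = excess / (excess + k_sat)` in the dimensionless LiHMDS excess.
#' @param moisture_sink LiHMDS molar flow lost to residual water,
#'   mol h-1.
#' @param mixing_eff multiplicative mixing efficiency on the conversion
#'   (1 = ideal; the true plant uses < 1, giving the nominal model a
#'   structural mismatch).
#' @param li_aniline_frac fraction of the unconverted aniline pool
#'   present as the lithiated intermediate at the outlet.
#' @param smoothing relative width of the soft-minimum limiting term in
#'   the conversion law (imperfect mixing blurs the switch between
#'   limiting reagents; 0 recovers a hard minimum).
#' @param rho_mixture reaction-mixture density, kg m-3 (default 900).
#' @param nmr_noise_sd,nir_noise_sd additive noise levels of the
#'   synthetic spectra (intensity / absorbance units).
#' @param delay_nir NIR sensor delay relative to NMR, s (default 120).
#' @param dt_nmr,dt_nir sampling intervals, s (defaults 15 and 160).
#' @param tau relaxation time constant of outlet concentrations after a
#'   set-point move, s (default 60: the short-residence-time tubular
#'   reactor settles quickly after flow changes).
#' @return list of class `plant_params`.
#' @export
plant_params <- function(k_sat = 0.05, moisture_sink = 0.3, mixing_eff = 1.0,
                         li_aniline_frac = 0.35, smoothing = 0.05,
                         rho_mixture = 900,
                         nmr_noise_sd = 0.12, nir_noise_sd = 0.002,
                         delay_nir = 120, dt_nmr = 15, dt_nir = 160,
                         tau = 60) {
  stopifnot(k_sat >= 0, moisture_sink >= 0, mixing_eff > 0, mixing_eff <= 1,
            rho_mixture > 0, nmr_noise_sd >= 0, nir_noise_sd >= 0)
  structure(as.list(environment()), class = "plant_params")
}

#' Parameters of the "true" plant
#'
#' Same structure as [plant_params()] but with a different saturation
#' constant, a larger moisture sink and a sub-unity mixing efficiency, so
#' that the nominal control model has both parametric and structural
#' mismatch against it.
#'
#' @param ... overrides passed to [plant_params()].
#' @export
true_plant_params <- function(...) {
  plant_params(k_sat = 0.12, moisture_sink = 0.5, mixing_eff = 0.92, ...)
}

#' Steady-state reactor model
#'
#' Stoichiometric 1:1:2 coupling of aniline and o-FNB by LiHMDS with a
#' moisture side sink and a saturating conversion law.  The LiHMDS molar
#' feed is first reduced by `moisture_sink`; the reaction extent is
#' `min(n_aniline, n_oFNB, n_LiHMDS_eff / 2) * mixing_eff * excess /
#' (excess + k_sat)` where `excess = n_LiHMDS_eff / (2 min(n_aniline,
#' n_oFNB))`.  A fixed fraction of the unconverted aniline pool leaves as
#' the lithiated intermediate.  Outlet concentrations are molar flows
#' over the volumetric flow `sum(u) / rho_mixture`.
#'
#' @param feeds named list of the three [feed_stream()]s
#'   (`aniline`, `LiHMDS`, `oFNB`).
#' @param params a [plant_params()].
#' @return object of class `outlet_state`: `concentrations` (mol m-3,
#'   names `aniline`, `oFNB`, `LiAniline`, `LiNDPA`, `LiHMDS`),
#'   `molar_flows` (mol h-1), `total_mass_flow` (kg h-1), `vol_flow`
#'   (m3 h-1).
#' @export
reactor_steady_state <- function(feeds, params = plant_params()) {
  for (nm in c("aniline", "LiHMDS", "oFNB"))
    if (is.null(feeds[[nm]])) stop("missing feed: ", nm, call. = FALSE)
  n_an <- feeds$aniline$molar_flow
  n_of <- feeds$oFNB$molar_flow
  n_li <- feeds$LiHMDS$molar_flow
  total_mass <- feeds$aniline$mass_flow + feeds$LiHMDS$mass_flow +
    feeds$oFNB$mass_flow
  if (total_mass <= 0) stop("zero total feed flow", call. = FALSE)
  n_li_eff <- max(n_li - params$moisture_sink, 0)
  pairmin <- min(n_an, n_of)
  if (pairmin > 0 && n_li_eff > 0) {
    excess <- n_li_eff / (2 * pairmin)
    eta <- params$mixing_eff * excess / (excess + params$k_sat)
    # imperfect mixing blurs the switch between limiting reagents: a
    # log-sum-exp soft minimum (always <= the hard minimum, so balances
    # stay feasible); width scales with the coupled aryl feeds
    sm <- params$smoothing %||% 0
    lim <- if (sm > 0) {
      w <- sm * (n_an + n_of) / 2
      m <- min(n_an, n_of, n_li_eff / 2)
      m - w * log(exp(-(n_an - m) / w) + exp(-(n_of - m) / w) +
                    exp(-(n_li_eff / 2 - m) / w))
    } else min(n_an, n_of, n_li_eff / 2)
    extent <- max(lim, 0) * eta
  } else extent <- 0
  unreacted_an <- n_an - extent
  li_remaining <- n_li_eff - 2 * extent
  li_an <- min(params$li_aniline_frac * unreacted_an, li_remaining)
  flows <- c(aniline = unreacted_an - li_an,
             oFNB = n_of - extent,
             LiAniline = li_an,
             LiNDPA = extent,
             LiHMDS = li_remaining - li_an)
  vol <- total_mass / params$rho_mixture      # m3 h-1
  structure(list(concentrations = flows / vol,
                 molar_flows = flows,
                 total_mass_flow = total_mass,
                 vol_flow = vol,
                 extent = extent),
            class = "outlet_state")
}

#' @export
print.outlet_state <- function(x, ...) {
  cat("<outlet state> mol/m3:\n")
  print(round(x$concentrations, 2))
  cat(sprintf("total mass flow %.3g kg/h\n", x$total_mass_flow))
  invisible(x)
}

#' Ground-truth plant response (with mismatch against the nominal model)
#'
#' Thin wrapper evaluating [reactor_steady_state()] under
#' [true_plant_params()]; used as the simulated "real" plant in
#' real-time-optimization experiments while the nominal model runs under
#' [plant_params()].
#'
#' @param feeds named list of [feed_stream()]s.
#' @param params_true a [plant_params()] for the true plant.
#' @return an `outlet_state`.
#' @export
true_plant <- function(feeds, params_true = true_plant_params()) {
  reactor_steady_state(feeds, params_true)
}

#' Synthesize a 43-MHz-like mixture NMR spectrum
#'
#' Superposes the pseudo-Voigt component models scaled so that each
#' component's area per nucleus equals its concentration divided by
#' `xi_true` (the simulated instrument's absolute response), then applies
#' an optional global ppm shift and zero-order phase rotation and adds
#' complex white noise.  The complex spectrum is stored in
#' `meta$complex`, so the standard processing chain (phasing, baseline,
#' alignment) applies.
#'
#' @param conc named concentrations, mol L-1 (names must exist in
#'   `library`).
#' @param library component library (default
#'   [default_component_library()]).
#' @param axis ppm axis (default 2048 points over -1..11 ppm).
#' @param noise_sd additive noise SD per channel.
#' @param shift_error global ppm shift applied to every peak.
#' @param phase_error zero-order phase error, degrees.
#' @param xi_true simulated area-per-nucleus response per mol L-1
#'   (default 1).
#' @param baseline optional length-2 `c(offset, slope)` baseline.
#' @return an NMR `nmr_spectrum`; ground truth in `meta$truth`.
#' @export
synth_nmr_spectrum <- function(conc, library = default_component_library(),
                               axis = seq(-1, 11, length.out = 2048),
                               noise_sd = 0, shift_error = 0, phase_error = 0,
                               xi_true = 1, baseline = c(0, 0)) {
  stopifnot(all(names(conc) %in% names(library)))
  y <- numeric(length(axis))
  for (nm in names(conc))
    y <- y + eval_component(axis, library[[nm]], w = conc[[nm]] / xi_true,
                            d = shift_error)
  y <- y + baseline[1] + baseline[2] * (axis - mean(axis))
  cplx <- complex(real = y, imaginary = hilbert_transform(y))
  if (phase_error != 0)
    cplx <- cplx * exp(1i * phase_error * pi / 180)
  if (noise_sd > 0)
    cplx <- cplx + complex(real = stats::rnorm(length(axis), 0, noise_sd),
                           imaginary = stats::rnorm(length(axis), 0, noise_sd))
  new_spectrum(axis, Re(cplx), domain = "nmr",
               meta = list(complex = cplx, truth = conc,
                           xi_true = xi_true,
                           shift_error = shift_error,
                           phase_error = phase_error))
}

#' Gaussian NIR band library of the process analytes
#'
#' Invented but spectroscopically plausible absorbance bands (center
#' cm-1, absorbance per mol L-1, Gaussian SD cm-1), concentrated in the
#' quantitatively usable 4611-8957 cm-1 region with overlap between the
#' aromatic species.
#'
#' @return named list per analyte of `data.frame(center, eps, width)`.
#' @export
nir_band_library <- function() {
  list(
    aniline = data.frame(center = c(5930, 8290), eps = c(0.150, 0.050),
                         width = c(150, 200)),
    oFNB = data.frame(center = c(6150, 4840), eps = c(0.120, 0.080),
                      width = c(90, 120)),
    LiHMDS = data.frame(center = c(5780, 8520), eps = c(0.060, 0.030),
                        width = c(250, 300)),
    LiAniline = data.frame(center = c(6690, 5210), eps = c(0.100, 0.070),
                           width = c(130, 160)),
    LiNDPA = data.frame(center = c(6010, 7610, 5010),
                        eps = c(0.090, 0.120, 0.060),
                        width = c(140, 180, 150)))
}

#' Synthesize an NIR absorbance spectrum
#'
#' Analyte-linear Gaussian bands plus a smooth background, multiplicative
#' scatter (random gain and offset, removable by SNV) and heteroscedastic
#' noise amplified in the flanking 12000-8975 and 4611-4000 cm-1 regions
#' (absorption/detector-noise dominated on the real instrument).  The
#' grid is 2074 points over 4000-12000 cm-1.
#'
#' @param conc named concentrations, mol L-1.
#' @param bands band library (default [nir_band_library()]).
#' @param noise_sd base absorbance noise SD.
#' @param scatter logical: apply random gain/offset.
#' @param wn wavenumber grid.
#' @return an NIR `nmr_spectrum`.
#' @export
synth_nir_spectrum <- function(conc, bands = nir_band_library(),
                               noise_sd = 0.002, scatter = TRUE,
                               wn = seq(4000, 12000, length.out = 2074)) {
  stopifnot(all(names(conc) %in% names(bands)))
  a <- 0.05 + 0.02 * (wn - 4000) / 8000          # gentle instrument background
  for (nm in names(conc)) {
    b <- bands[[nm]]
    for (k in seq_len(nrow(b)))
      a <- a + conc[[nm]] * b$eps[k] * exp(-(wn - b$center[k])^2 / (2 * b$width[k]^2))
  }
  # product-linked broad absorption at high wavenumbers (colored solution)
  if (!is.null(conc[["LiNDPA"]]))
    a <- a + conc[["LiNDPA"]] * 0.4 * exp(-(wn - 10800)^2 / (2 * 900^2))
  if (scatter) {
    gain <- exp(stats::rnorm(1, 0, 0.05))
    offset <- stats::rnorm(1, 0, 0.02)
    a <- gain * a + offset
  }
  if (noise_sd > 0) {
    amp <- 1 + 9 * (wn > 8975 | wn < 4611)
    a <- a + stats::rnorm(length(wn), 0, noise_sd) * amp
  }
  new_spectrum(wn, a, domain = "nir", meta = list(truth = conc))
}

#' Simulate a monitored campaign run
#'
#' Walks a set-point schedule through the true plant, relaxes outlet
#' concentrations first-order (time constant `params$tau`) after each
#' move, and emits timestamped synthetic NMR spectra every `dt_nmr`
#' seconds and NIR spectra every `dt_nir` seconds, the NIR sensor seeing
#' the composition `delay_nir` seconds earlier.  All randomness flows
#' through `seed`; ground-truth concentrations at both sensors are kept
#' for oracle checks.
#'
#' @param schedule `data.frame` with columns `time` (s, increasing),
#'   `u_aniline`, `u_LiHMDS`, `u_oFNB` (kg h-1) and optionally
#'   `conc_LiHMDS` (feed-batch concentration, mol L-1).
#' @param duration total simulated time, s.
#' @param params plant parameters of the generating (true) plant
#'   (default [true_plant_params()]).
#' @param seed RNG seed; identical seeds give identical bundles.
#' @param library NMR component library.
#' @param bands NIR band library.
#' @param run_id label attached to the bundle.
#' @return list of class `campaign_bundle`: `nmr` (`times`, `spectra`,
#'   `truth` matrix in mol L-1), `nir` (`times`, `X` absorbance matrix,
#'   `wn`, `truth`), plus `schedule`, `params`, `seed`, `run_id`.
#' @export
run_campaign <- function(schedule, duration = max(schedule$time) + 600,
                         params = true_plant_params(), seed = 1L,
                         library = default_component_library(),
                         bands = nir_band_library(), run_id = 1L) {
  stopifnot(all(diff(schedule$time) > 0))
  set.seed(seed)
  quant <- c("aniline", "oFNB", "LiAniline", "LiNDPA", "LiHMDS")
  dt <- 5                                   # integration grid, s
  tgrid <- seq(0, duration, by = dt)
  c_now <- NULL
  truth <- matrix(0, length(tgrid), length(quant),
                  dimnames = list(NULL, quant))
  for (i in seq_along(tgrid)) {
    row <- max(which(schedule$time <= tgrid[i]))
    sp <- schedule[row, ]
    feeds <- default_feeds(
      u = c(sp$u_aniline, sp$u_LiHMDS, sp$u_oFNB),
      conc_LiHMDS = if ("conc_LiHMDS" %in% names(sp)) sp$conc_LiHMDS else 1.10)
    c_ss <- reactor_steady_state(feeds, params)$concentrations[quant] / 1000
    if (is.null(c_now)) c_now <- c_ss
    c_now <- c_now + (c_ss - c_now) * (1 - exp(-dt / params$tau))
    truth[i, ] <- c_now
  }
  truth_at <- function(tt) {
    i <- pmin(pmax(round(tt / dt) + 1, 1), nrow(truth))
    truth[i, , drop = FALSE]
  }
  nmr_times <- seq(params$dt_nmr, duration, by = params$dt_nmr)
  nmr_truth <- truth_at(nmr_times)
  nmr_spectra <- lapply(seq_along(nmr_times), function(i) {
    synth_nmr_spectrum(nmr_truth[i, ], library = library,
                       noise_sd = params$nmr_noise_sd,
                       shift_error = stats::rnorm(1, 0, 0.005),
                       phase_error = stats::rnorm(1, 0, 3))
  })
  nir_times <- seq(params$delay_nir + params$dt_nir, duration,
                   by = params$dt_nir)
  nir_truth <- truth_at(nir_times - params$delay_nir)
  nir_list <- lapply(seq_along(nir_times), function(i) {
    synth_nir_spectrum(nir_truth[i, ], bands = bands,
                       noise_sd = params$nir_noise_sd)
  })
  wn <- nir_list[[1L]]$axis
  X <- do.call(rbind, lapply(nir_list, function(s) s$intensity))
  structure(list(
    nmr = list(times = nmr_times, spectra = nmr_spectra, truth = nmr_truth),
    nir = list(times = nir_times, X = X, wn = wn, truth = nir_truth),
    schedule = schedule, params = params, seed = seed, run_id = run_id),
    class = "campaign_bundle")
}

#' @export
print.campaign_bundle <- function(x, ...) {
  cat(sprintf("<campaign bundle> run %s: %d NMR spectra, %d NIR spectra, seed %d\n",
              x$run_id, length(x$nmr$times), nrow(x$nir$X), x$seed))
  invisible(x)
}

#' Default four-hold set-point schedule for one production run
#'
#' Four constant-flow holds of `hold` seconds each around the start-up
#' recipe, emulating the iterative step changes of a production day.
#'
#' @param hold hold length per set-point, s (default 600, the "about
#'   10 min to reach steady state" operating practice).
#' @param jitter relative set-point variation between holds.
#' @param seed seed for the set-point draws.
#' @return a schedule `data.frame` for [run_campaign()].
#' @export
default_schedule <- function(hold = 600, jitter = 0.12, seed = 1L) {
  set.seed(seed + 1000L)
  base <- c(3.68, 6.89, 5.60)
  n <- 4L
  u <- t(vapply(seq_len(n), function(i)
    base * (1 + stats::runif(3, -jitter, jitter)), numeric(3)))
  data.frame(time = (seq_len(n) - 1L) * hold,
             u_aniline = u[, 1], u_LiHMDS = u[, 2], u_oFNB = u[, 3])
}

#' Quantify every NMR spectrum of a campaign bundle
#'
#' Runs phasing, baseline correction and the constrained mixture fit on
#' each spectrum and converts areas to concentrations with the given
#' calibration factor, warm-starting each fit from the previous solution.
#'
#' @param bundle a [run_campaign()] bundle.
#' @param xi a [calibrate_xi()] factor (default the simulator truth,
#'   xi = 1).
#' @param library component library used for fitting.
#' @param per_peak_shifts passed to [fit_mixture()] (default `FALSE` for
#'   speed over long series).
#' @return a [conc_series()] of quantified concentrations (mol L-1).
#' @export
quantify_campaign <- function(bundle, xi = 1,
                              library = default_component_library(),
                              per_peak_shifts = FALSE) {
  models <- unname(library)
  nm <- vapply(models, function(m) m$name, "")
  numap <- nu_map(library)
  warm <- NULL
  vals <- matrix(NA_real_, length(bundle$nmr$times), length(nm),
                 dimnames = list(NULL, nm))
  for (i in seq_along(bundle$nmr$spectra)) {
    sp <- bundle$nmr$spectra[[i]]
    sp <- auto_phase(sp)
    sp <- baseline_correct(sp, order = 1L)
    fit <- fit_mixture(sp, models, per_peak_shifts = per_peak_shifts,
                       start = warm, restarts = 0L)
    warm <- fit$par
    vals[i, ] <- quantify(fit, xi, numap)[nm]
  }
  conc_series(bundle$nmr$times, vals,
              run_id = rep(bundle$run_id, length(bundle$nmr$times)))
}
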