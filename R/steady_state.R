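#' Concentration time series container
#'
#' @param timestamps seconds, strictly increasing (nominally 15-s spacing
#'   for the online NMR).
#' @param values numeric matrix (or data.frame) of concentrations in
#'   mol L-1, one column per analyte; `NA` marks failed fits.
#' @param steady optional logical steady flags (filled by
#'   [classify_steady()]).
#' @param run_id optional run (production day) label per point.
#' @return object of class `conc_series`.
#' @export
conc_series <- function(timestamps, values, steady = NULL, run_id = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("analyte", seq_len(ncol(values)))
  if (length(timestamps) != nrow(values))
    stop("length(timestamps) != nrow(values)", call. = FALSE)
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("concentrations must be >= 0 (or NA)", call. = FALSE)
  structure(list(timestamps = as.numeric(timestamps), values = values,
                 steady = steady, run_id = run_id),
            class = "conc_series")
}

#' @export
print.conc_series <- function(x, ...) {
  cat(sprintf("<concentration series> %d points x %d analyte(s), t = %.0f .. %.0f s",
              nrow(x$values), ncol(x$values),
              min(x$timestamps), max(x$timestamps)))
  if (!is.null(x$steady))
    cat(sprintf("; %d steady", sum(x$steady)))
  cat("\n")
  invisible(x)
}

#' Moving-window steady-state classification
#'
#' For each analyte, an ordinary least-squares line is fitted to a
#' centered window of `window` consecutive concentration values.  A point
#' is steady when, for every analyte jointly, the absolute slope is below
#' `slope_max` and the standard deviation of the fit residuals is below
#' `sd_max`.  Points whose window would run off either end of the series
#' (the first and last `(window-1)/2` points) are flagged transient.
#'
#' @param series a [conc_series()].
#' @param window odd window length (default 11 points).
#' @param slope_max slope threshold in mol L-1 h-1 (default 0.1).
#' @param sd_max residual-SD threshold in mol L-1 (default 0.01).
#' @return the series with logical `steady` flags filled in.
#' @export
classify_steady <- function(series, window = 11L, slope_max = 0.1,
                            sd_max = 0.01) {
  stopifnot(inherits(series, "conc_series"), window %% 2 == 1, window >= 3)
  ts <- series$timestamps
  n <- length(ts)
  if (n < window) stop("need at least ", window, " points", call. = FALSE)
  dts <- diff(ts)
  dt0 <- stats::median(dts)
  if (any(abs(dts - dt0) > 0.1 * dt0))
    warning("sampling jitter beyond 10%; proceeding on nominal spacing")
  half <- (window - 1L) %/% 2L
  t_hr <- (seq_len(window) - 1) * dt0 / 3600  # nominal spacing, hours
  tc <- t_hr - mean(t_hr)
  sxx <- sum(tc^2)
  vals <- series$values
  steady <- rep(FALSE, n)
  for (i in (half + 1L):(n - half)) {
    idx <- (i - half):(i + half)
    ok <- TRUE
    for (j in seq_len(ncol(vals))) {
      v <- vals[idx, j]
      if (anyNA(v)) { ok <- FALSE; break }
      slope <- sum(tc * (v - mean(v))) / sxx           # mol L-1 h-1
      resid <- v - mean(v) - slope * tc
      sd_res <- sqrt(sum(resid^2) / (window - 2L))
      if (abs(slope) >= slope_max || sd_res >= sd_max) { ok <- FALSE; break }
    }
    steady[i] <- ok
  }
  series$steady <- steady
  series
}

#' Moving-average smoothing of steady segments
#'
#' Each steady point is replaced by the trailing mean of the most recent
#' `block` steady values (fewer at the start of a steady segment history);
#' transient points are untouched.
#'
#' @param series a flagged [conc_series()].
#' @param block moving-average block size (default 6).
#' @return the smoothed series.
#' @export
smooth_steady <- function(series, block = 6L) {
  stopifnot(inherits(series, "conc_series"))
  if (is.null(series$steady))
    stop("run classify_steady() first", call. = FALSE)
  vals <- series$values
  out <- vals
  st_idx <- which(series$steady)
  for (pos in seq_along(st_idx)) {
    take <- st_idx[max(1L, pos - block + 1L):pos]
    out[st_idx[pos], ] <- colMeans(vals[take, , drop = FALSE])
  }
  series$values <- out
  series
}

#' Pair NIR acquisition times with steady NMR reference values
#'
#' The NIR sensor sits downstream of the NMR sensor; its residence-time
#' delay is compensated by matching each NIR timestamp `t` with the NMR
#' point nearest to `t - delay` (nearest neighbor; ties broken toward the
#' earlier NMR point).  A pair is formed only when that NMR point is
#' steady and the residual gap does not exceed `max_gap`; unmatched NIR
#' spectra remain in the transient test pool.
#'
#' @param nmr a flagged (and typically smoothed) [conc_series()].
#' @param nir_times NIR acquisition timestamps, seconds.
#' @param delay inter-sensor delay in seconds (default 120).
#' @param max_gap largest tolerated residual gap, seconds (default 15,
#'   one NMR sampling interval).
#' @return `data.frame` with one row per paired NIR spectrum:
#'   `nir_index`, `nir_time`, `nmr_index`, `nmr_time`, `gap`, plus one
#'   reference-concentration column per analyte; the applied delay in
#'   `attr(, "delay")` and the unpaired NIR indices in
#'   `attr(, "transient_pool")`.
#' @export
pair_references <- function(nmr, nir_times, delay = 120, max_gap = 15) {
  stopifnot(inherits(nmr, "conc_series"))
  if (is.null(nmr$steady))
    stop("run classify_steady() first", call. = FALSE)
  if (!any(nmr$steady)) warning("no steady NMR points; empty pairing")
  rows <- list()
  transient <- integer(0)
  for (i in seq_along(nir_times)) {
    target <- nir_times[i] - delay
    d <- abs(nmr$timestamps - target)
    j <- which(d == min(d))[1L]   # ties resolve to the earlier timestamp
    if (nmr$steady[j] && d[j] <= max_gap) {
      rows[[length(rows) + 1L]] <- data.frame(
        nir_index = i, nir_time = nir_times[i],
        nmr_index = j, nmr_time = nmr$timestamps[j], gap = d[j],
        run_id = if (!is.null(nmr$run_id)) nmr$run_id[j] else NA,
        as.list(nmr$values[j, ]))
    } else {
      transient <- c(transient, i)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(nir_index = integer(0), nir_time = numeric(0),
               nmr_index = integer(0), nmr_time = numeric(0),
               gap = numeric(0), run_id = integer(0))
  attr(out, "delay") <- delay
  attr(out, "transient_pool") <- transient
  out
}

#' Split paired samples into calibration and test sets by run
#'
#' @param pairs a [pair_references()] table carrying a `run_id` column.
#' @param calibration_runs run ids entering the calibration set.
#' @param test_run run id(s) held out as the test set.
#' @return list with `calibration`, `test` and a `counts` vector.
#' @export
split_by_run <- function(pairs, calibration_runs, test_run) {
  if (!"run_id" %in% names(pairs) || anyNA(pairs$run_id))
    stop("pairs must carry a run_id label", call. = FALSE)
  known <- unique(pairs$run_id)
  bad <- setdiff(calibration_runs, known)
  if (length(bad))
    stop("unknown run id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cal <- pairs[pairs$run_id %in% calibration_runs, , drop = FALSE]
  tst <- pairs[pairs$run_id %in% test_run, , drop = FALSE]
  if (!nrow(tst)) warning("empty test run")
  list(calibration = cal, test = tst,
       counts = c(calibration = nrow(cal), test = nrow(tst)))
}
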