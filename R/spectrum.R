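#' Construct a spectrum object
#'
#' The common currency of all spectral operations: a strictly monotone axis
#' (ppm for NMR, cm-1 for NIR) with one real intensity per axis point, plus
#' free-form acquisition metadata.  Axes are stored ascending regardless of
#' display convention.
#'
#' @param axis numeric axis values (ppm or cm-1), strictly monotone.
#' @param intensity numeric intensities, same length as `axis`.
#' @param domain `"nmr"` or `"nir"`.
#' @param meta named list of acquisition descriptors.  For NMR spectra the
#'   complex (pre-phase) spectrum may be kept in `meta$complex` so that
#'   [auto_phase()] can operate after Fourier transformation.
#' @return An object of class `nmr_spectrum` (used for both domains).
#' @export
new_spectrum <- function(axis, intensity, domain = c("nmr", "nir"),
                         meta = list()) {
  domain <- match.arg(domain)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop("`axis` and `intensity` must have the same length", call. = FALSE)
  if (length(axis) < 2L)
    stop("a spectrum needs at least two points", call. = FALSE)
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0)))
    stop("`axis` must be strictly monotone", call. = FALSE)
  if (any(d < 0)) {             # store ascending
    axis <- rev(axis)
    intensity <- rev(intensity)
    if (!is.null(meta$complex)) meta$complex <- rev(meta$complex)
  }
  structure(list(axis = axis, intensity = intensity,
                 domain = domain, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<%s spectrum> %d points, axis %.4g .. %.4g %s\n",
              toupper(x$domain), length(x$axis), min(x$axis), max(x$axis),
              if (x$domain == "nmr") "ppm" else "cm-1"))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "nmr_spectrum")

#' Construct a free induction decay (FID)
#'
#' Complex time-domain NMR signal as acquired by the spectrometer.
#'
#' @param samples complex vector of time-domain samples.
#' @param dwell_time sampling interval in seconds.
#' @param spectrometer_freq proton frequency in MHz (43.32 for the benchtop
#'   instrument emulated here).
#' @param center_ppm ppm value at the carrier (axis center) after transform.
#' @return An object of class `nmr_fid`.
#' @export
new_fid <- function(samples, dwell_time, spectrometer_freq = 43.32,
                    center_ppm = 5.5) {
  samples <- as.complex(samples)
  if (length(samples) < 2L) stop("FID needs at least 2 points", call. = FALSE)
  if (!is.finite(dwell_time) || dwell_time <= 0)
    stop("`dwell_time` must be > 0", call. = FALSE)
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0)
    stop("`spectrometer_freq` must be > 0", call. = FALSE)
  structure(list(samples = samples, dwell_time = dwell_time,
                 spectrometer_freq = spectrometer_freq,
                 center_ppm = center_ppm, n_points = length(samples)),
            class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<FID> %d points, dwell %.3g s, %.4g MHz\n",
              x$n_points, x$dwell_time, x$spectrometer_freq))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Supports a minimal JCAMP-DX dialect (`##XYDATA=(X++(Y..Y))` with AFFN
#' values, plus `(XY..XY)` pairs) and CSV with a header row
#' `axis,intensity`.
#'
#' @param path file path; format inferred from extension (`.jdx`/`.dx` vs
#'   `.csv`) unless `format` is given.
#' @param format `"auto"`, `"jcamp"` or `"csv"`.
#' @param domain passed to [new_spectrum()].
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "jcamp", "csv"),
                          domain = c("nmr", "nir")) {
  format <- match.arg(format)
  domain <- match.arg(domain)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm)$", path, ignore.case = TRUE))
      "jcamp" else "csv"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path)
    return(new_spectrum(tab[[1L]], tab[[2L]], domain = domain,
                        meta = list(source = path)))
  }
  read_jcamp(path, domain = domain)
}

# Minimal JCAMP-DX reader: FIRSTX/LASTX/NPOINTS + XYDATA=(X++(Y..Y)) with
# plain AFFN numbers, or PEAK/XYPOINTS pair tables.  Vendor compression
# (SQZ/DIF/DUP) is not supported.
read_jcamp <- function(path, domain = "nmr") {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub("^##[^=]*=\\s*", "", hit[[1L]])
  }
  num <- function(name) suppressWarnings(as.numeric(ldr(name)))
  start <- grep("^##(XYDATA|XYPOINTS|PEAK TABLE)=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no XYDATA/XYPOINTS block in ", path, call. = FALSE)
  start <- start[[1L]]
  endl <- grep("^##", lines)
  endl <- endl[endl > start]
  body <- lines[(start + 1L):(if (length(endl)) min(endl) - 1L else length(lines))]
  variant <- toupper(lines[[start]])
  yfac <- num("YFACTOR"); if (is.na(yfac)) yfac <- 1
  xfac <- num("XFACTOR"); if (is.na(xfac)) xfac <- 1
  toks <- lapply(strsplit(trimws(body), "[,;[:space:]]+"), function(v) v[nzchar(v)])
  if (grepl("X\\+\\+\\(Y\\.\\.Y\\)", variant)) {
    # first token of each line is the X start value; the rest are Y ordinates
    y <- unlist(lapply(toks, function(v) as.numeric(v[-1L])))
    firstx <- num("FIRSTX"); lastx <- num("LASTX"); np <- num("NPOINTS")
    if (is.na(np)) np <- length(y)
    axis <- seq(firstx, lastx, length.out = np) * xfac
    y <- y[seq_len(np)] * yfac
  } else {
    vals <- as.numeric(unlist(toks))
    axis <- vals[seq(1L, length(vals), by = 2L)] * xfac
    y <- vals[seq(2L, length(vals), by = 2L)] * yfac
  }
  new_spectrum(axis, y, domain = domain,
               meta = list(source = path, title = ldr("TITLE")))
}

#' Write a spectrum to disk
#'
#' @param spec an `nmr_spectrum`.
#' @param path output path; `.jdx` writes JCAMP-DX `(X++(Y..Y))`, anything
#'   else a two-column CSV `axis,intensity`.
#' @param title JCAMP title record.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, title = "flownmr spectrum") {
  stopifnot(is_spectrum(spec))
  if (grepl("\\.(jdx|dx)$", path, ignore.case = TRUE)) {
    n <- length(spec$axis)
    hdr <- c(
      paste0("##TITLE=", title),
      "##JCAMP-DX=4.24",
      paste0("##DATA TYPE=", if (spec$domain == "nmr") "NMR SPECTRUM" else "INFRARED SPECTRUM"),
      paste0("##XUNITS=", if (spec$domain == "nmr") "PPM" else "1/CM"),
      "##YUNITS=ARBITRARY UNITS",
      "##XFACTOR=1", "##YFACTOR=1",
      paste0("##FIRSTX=", format(spec$axis[1L], digits = 12)),
      paste0("##LASTX=", format(spec$axis[n], digits = 12)),
      paste0("##NPOINTS=", n),
      "##XYDATA=(X++(Y..Y))")
    idx <- split(seq_len(n), ceiling(seq_len(n) / 6))
    body <- vapply(idx, function(i) {
      paste(format(spec$axis[i[1L]], digits = 10),
            paste(format(spec$intensity[i], digits = 8), collapse = " "))
    }, character(1L))
    writeLines(c(hdr, body, "##END="), path)
  } else {
    utils::write.csv(data.frame(axis = spec$axis, intensity = spec$intensity),
                     path, row.names = FALSE)
  }
  invisible(path)
}
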