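#' Default pure-component model library for the lithiation system
#'
#' Pseudo-Voigt models of the five process analytes as they appear in
#' 43.32-MHz proton spectra of the THF-based reaction mixture: the
#' reactants aniline and 1-fluoro-2-nitrobenzene (o-FNB), the base LiHMDS
#' (trimethylsilyl singlet), the lithiated-aniline intermediate and the
#' product lithium 2-nitrodiphenylamine (Li-NDPA).  Heights are normalized
#' so that each component's total area equals its nucleus count `nu`; at
#' that normalization a component weight of `w` corresponds to an area per
#' nucleus of `w`, which is what the one-point calibration factor converts
#' to mol L-1.  Aromatic multiplets collapse to broad pseudo-Voigt lines
#' at this field strength, with substantial overlap between the three
#' aniline-derived species.
#'
#' @param components character vector selecting a subset (default: all
#'   five analytes).
#' @return named list of [pure_component_model()] objects.
#' @export
default_component_library <- function(components = c("aniline", "oFNB",
                                                     "LiHMDS", "LiAniline",
                                                     "LiNDPA")) {
  norm_peaks <- function(tbl, nu) {
    a <- pv_area(tbl$height, tbl$fwhm, tbl$gauss_fraction)
    tbl$height <- tbl$height * nu / sum(a)
    tbl
  }
  spec_tbl <- list(
    aniline = list(nu = 5L, peaks = rbind(      # C6H5-NH2 aromatic envelope
      pv_peak(7.02, 2.0, 0.060, 0.45),
      pv_peak(6.63, 3.0, 0.065, 0.50))),
    oFNB = list(nu = 4L, peaks = rbind(         # four aromatic H, ortho F/NO2
      pv_peak(8.08, 1.0, 0.060, 0.50),
      pv_peak(7.72, 1.0, 0.062, 0.50),
      pv_peak(7.28, 2.0, 0.080, 0.55))),
    LiHMDS = list(nu = 18L, peaks = rbind(      # (Si(CH3)3)2 singlet
      pv_peak(0.08, 1.0, 0.050, 0.40))),
    LiAniline = list(nu = 5L, peaks = rbind(    # ring shifted upfield on N-Li
      pv_peak(6.85, 2.0, 0.070, 0.50),
      pv_peak(6.25, 3.0, 0.070, 0.50))),
    LiNDPA = list(nu = 9L, peaks = rbind(       # nine aromatic H of product
      pv_peak(8.18, 1.0, 0.070, 0.50),
      pv_peak(7.45, 3.0, 0.090, 0.55),
      pv_peak(7.12, 3.0, 0.090, 0.55),
      pv_peak(6.70, 2.0, 0.080, 0.50))))
  unknown <- setdiff(components, names(spec_tbl))
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- lapply(components, function(nm) {
    s <- spec_tbl[[nm]]
    pure_component_model(nm, norm_peaks(s$peaks, s$nu), s$nu)
  })
  stats::setNames(out, components)
}

#' Nucleus counts of the default library
#'
#' @param library a component library as from [default_component_library()].
#' @return named integer vector analyte -> nu.
#' @export
nu_map <- function(library = default_component_library()) {
  vapply(library, function(m) m$nu, 0L)
}

#' Write / read a component model as a structured config file
#'
#' Plain DCF-style text (`schema`, `name`, `nu`, constraint bounds, and a
#' CSV peak table) so a model database can live as a directory of text
#' files and be versioned.
#'
#' @param model a [pure_component_model()].
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_component_model <- function(model, path) {
  stopifnot(inherits(model, "pure_component_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "schema: flownmr-component-1",
    paste0("name: ", model$name),
    paste0("nu: ", model$nu),
    paste0("global_shift: ", model$constraints$global_shift),
    paste0("peak_shift: ", model$constraints$peak_shift),
    paste0("width_scale: ", paste(model$constraints$width_scale, collapse = " ")),
    "peaks: position,height,fwhm,gauss_fraction"), con)
  utils::write.table(model$peaks, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_component_model
#' @export
read_component_model <- function(path) {
  lines <- readLines(path)
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^[^:]*:", "", hit[[1L]]))
  }
  if (!identical(field("schema"), "flownmr-component-1"))
    stop("unrecognized component model schema in ", path, call. = FALSE)
  hdr <- grep("^peaks:", lines)
  pk <- utils::read.csv(text = lines[(hdr + 1L):length(lines)],
                        header = FALSE,
                        col.names = c("position", "height", "fwhm",
                                      "gauss_fraction"))
  pure_component_model(
    field("name"), pk, as.integer(field("nu")),
    constraints = list(
      global_shift = as.numeric(field("global_shift")),
      peak_shift = as.numeric(field("peak_shift")),
      width_scale = as.numeric(strsplit(field("width_scale"), " +")[[1L]])))
}
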