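#' Read a CSV spectral table
#'
#' The package's CSV dialect for spectra: a header row, first column
#' `wavelength_nm`, each subsequent column one spectrum sampled at those
#' wavelengths. Wavelengths must be uniformly spaced.
#'
#' @param path CSV file path.
#' @param grid optional [spectral_grid()]; when given, every column is
#'   resampled onto it (nearest-endpoint extension outside the tabulated
#'   range).
#' @return a named list of [spectrum()] objects, one per column.
#' @export
read_spectra_csv <- function(path, grid = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2 || names(tab)[1] != "wavelength_nm") {
    stop("spectral CSV must have a 'wavelength_nm' first column and at least one spectrum column: ", path)
  }
  wl <- tab[[1]]
  steps <- diff(wl)
  if (any(abs(steps - steps[1]) > 1e-9) || steps[1] <= 0) {
    stop("wavelength_nm column must be strictly increasing and uniformly spaced: ", path)
  }
  src <- spectral_grid(wl[1], wl[length(wl)], steps[1])
  out <- lapply(tab[-1], function(v) spectrum(v, src))
  if (!is.null(grid)) out <- lapply(out, resample_spectrum, target = grid)
  out
}

#' Write spectra to the package CSV dialect
#'
#' @param spectra named list of [spectrum()] objects sharing one grid.
#' @param path output file.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  g <- spectra[[1]]$grid
  for (s in spectra) {
    if (!grids_identical(s$grid, g)) stop("all spectra must share one grid")
  }
  tab <- data.frame(wavelength_nm = g$wavelengths)
  nm <- names(spectra)
  if (is.null(nm)) nm <- paste0("spectrum_", seq_along(spectra))
  for (i in seq_along(spectra)) tab[[nm[i]]] <- spectra[[i]]$values
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "savelight")
  if (!nzchar(p)) stop("packaged table not found: ", file)
  p
}

#' CIE 1931 2-degree colour-matching functions
#'
#' Packaged standard-observer table (380--780 nm at 5 nm), resampled onto the
#' requested grid.
#'
#' @param grid a [spectral_grid()]; defaults to the package [master_grid()].
#' @return a list of class `cmf_set` with fields `grid`, `xbar`, `ybar`,
#'   `zbar` (each a numeric vector on `grid`).
#' @export
cie_cmfs <- function(grid = master_grid()) {
  tabs <- read_spectra_csv(extdata_path("cie1931_2deg_5nm.csv"), grid = grid)
  out <- structure(list(grid = grid,
                        xbar = tabs$xbar$values,
                        ybar = tabs$ybar$values,
                        zbar = tabs$zbar$values),
                   class = "cmf_set")
  if (any(out$xbar < 0) || any(out$ybar < 0) || any(out$zbar < 0)) {
    stop("colour-matching functions must be non-negative")
  }
  out
}

#' CIE standard illuminant D65
#'
#' Packaged relative spectral power distribution (380--780 nm at 5 nm,
#' normalised to 100 at 560 nm), resampled onto the requested grid.
#'
#' @inheritParams cie_cmfs
#' @return a [spectrum()].
#' @export
illuminant_d65 <- function(grid = master_grid()) {
  read_spectra_csv(extdata_path("illuminant_d65_5nm.csv"), grid = grid)$d65
}

#' An equal-energy (flat) illuminant
#' @inheritParams cie_cmfs
#' @return a [spectrum()] with all values 1.
#' @export
illuminant_equal_energy <- function(grid = master_grid()) {
  spectrum(rep(1, grid$n), grid)
}
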