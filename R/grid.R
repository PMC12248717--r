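#' Create a uniform wavelength grid
#'
#' A `spectral_grid` is the discretisation on which every spectrum, observer
#' table and illuminant in the package lives: uniformly spaced wavelengths in
#' nanometres including both endpoints. The package master grid is 400--780 nm
#' at 5 nm (77 bands); colorimetric integrals restrict themselves to the
#' 400--700 nm portion (see [reflectance_to_xyz()]).
#'
#' @param start_nm,stop_nm grid endpoints in nm; `start_nm < stop_nm`.
#' @param step_nm positive increment in nm; must divide `stop_nm - start_nm`
#'   exactly (to within floating tolerance).
#' @return an object of class `spectral_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm`, `n` and `wavelengths`.
#' @examples
#' g <- spectral_grid(400, 700, 10)
#' g$n                 # 31
#' head(g$wavelengths)
#' @export
spectral_grid <- function(start_nm, stop_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm))
  if (step_nm <= 0) {
    stop("step_nm must be positive, got ", step_nm)
  }
  if (!(start_nm < stop_nm)) {
    stop("start must be < stop (got start ", start_nm, ", stop ", stop_nm, ")")
  }
  span <- stop_nm - start_nm
  k <- span / step_nm
  if (abs(k - round(k)) > 1e-9) {
    stop("step_nm (", step_nm, ") must divide stop_nm - start_nm (", span,
         ") exactly")
  }
  n <- as.integer(round(k)) + 1L
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
         n = n,
         wavelengths = start_nm + step_nm * (seq_len(n) - 1)),
    class = "spectral_grid")
}

#' The package master wavelength grid (400--780 nm at 5 nm, 77 bands)
#' @return a [spectral_grid()]
#' @export
master_grid <- function() spectral_grid(400, 780, 5)

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %g-%g nm, step %g nm (%d samples)\n",
              x$start_nm, x$stop_nm, x$step_nm, x$n))
  invisible(x)
}

#' @export
format.spectral_grid <- function(x, ...) {
  sprintf("%g:%g:%g", x$start_nm, x$stop_nm, x$step_nm)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(c(a$start_nm, a$stop_nm, a$step_nm),
                   c(b$start_nm, b$stop_nm, b$step_nm), tolerance = 1e-9))
}

#' Construct a spectrum on a grid
#'
#' @param values numeric vector, one value per grid sample (reflectance or
#'   relative spectral power).
#' @param grid a [spectral_grid()].
#' @param extended logical flag recording that some values were produced by
#'   nearest-endpoint extension during resampling.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(values, grid, extended = FALSE) {
  stopifnot(inherits(grid, "spectral_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n) {
    stop("spectrum length (", length(values), ") must equal grid sample count (",
         grid$n, ")")
  }
  if (anyNA(values)) stop("spectrum values must not contain NA")
  structure(list(values = values, grid = grid, extended = isTRUE(extended)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> on %s nm, range [%.4g, %.4g]%s\n",
              format(x$grid), min(x$values), max(x$values),
              if (x$extended) " (endpoint-extended)" else ""))
  invisible(x)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation at the target wavelengths. Target samples outside the
#' source range are filled with the nearest source endpoint value and the
#' result is flagged `extended = TRUE`.
#'
#' @param spec a [spectrum()].
#' @param target a [spectral_grid()].
#' @return a [spectrum()] on `target`.
#' @examples
#' s <- spectrum(c(0, 1), spectral_grid(400, 500, 100))
#' resample_spectrum(s, spectral_grid(400, 500, 50))$values  # 0, 0.5, 1
#' @export
resample_spectrum <- function(spec, target) {
  stopifnot(inherits(spec, "spectrum"), inherits(target, "spectral_grid"))
  if (length(spec$values) == 0) stop("cannot resample an empty spectrum")
  if (grids_identical(spec$grid, target)) {
    return(spectrum(spec$values, target, extended = spec$extended))
  }
  wl_src <- spec$grid$wavelengths
  wl_tgt <- target$wavelengths
  out <- stats::approx(wl_src, spec$values, xout = wl_tgt, method = "linear",
                       rule = 2)$y
  ext <- any(wl_tgt < wl_src[1] - 1e-9 | wl_tgt > wl_src[length(wl_src)] + 1e-9)
  spectrum(out, target, extended = ext || spec$extended)
}

# Resample a matrix of spectra (rows = spectra, cols = source samples).
resample_matrix <- function(values, src_grid, target) {
  t(apply(values, 1, function(v) {
    stats::approx(src_grid$wavelengths, v, xout = target$wavelengths,
                  rule = 2)$y
  }))
}
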