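#' Hyperspectral reflectance cube
#'
#' @param values H x W x B array of reflectance values in \[0, clip_max\].
#' @param grid the [spectral_grid()] of the band axis.
#' @param clip_count number of samples clipped into range during
#'   reconstruction.
#' @return object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(values, grid, clip_count = 0L) {
  stopifnot(inherits(grid, "spectral_grid"))
  d <- dim(values)
  if (length(d) != 3) stop("cube values must be an H x W x B array")
  if (d[3] != grid$n) stop("cube has ", d[3], " bands but grid has ", grid$n)
  if (d[1] * d[2] == 0) stop("cube must have at least one pixel")
  structure(list(values = values, grid = grid,
                 height = d[1], width = d[2],
                 clip_count = as.integer(clip_count)),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  cat(sprintf("<hyperspectral_cube> %d x %d pixels, %d bands (%s nm), %d clipped samples\n",
              x$height, x$width, x$grid$n, format(x$grid), x$clip_count))
  invisible(x)
}

#' Reconstruct a hyperspectral cube from an RGB image
#'
#' Applies the calibration chain pixel-wise: dark subtraction, gamma
#' linearisation, polynomial colour correction, spectral transform, PCA
#' re-expansion, clipping into \[0, clip_max\]. Reconstruction is a pure
#' function of the 24-bit pixel value, so unique colours are evaluated once
#' and looked up (typical endoscopy frames contain far fewer unique colours
#' than pixels).
#'
#' @param image H x W x 3 array of 8-bit RGB values (alpha channels are
#'   rejected, not dropped).
#' @param bundle a [save_calibrate()] fit.
#' @return a [hyperspectral_cube()] with aggregated `clip_count`.
#' @export
rgb_image_to_cube <- function(image, bundle) {
  stopifnot(inherits(bundle, "save_calibration"))
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("image must be H x W x 3 (got ",
         paste(d, collapse = " x "),
         if (length(d) == 3 && d[3] == 4) "; drop the alpha channel explicitly" else "",
         ")")
  }
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  key <- px[, 1] * 65536 + px[, 2] * 256 + px[, 3]
  uk <- !duplicated(key)
  spectra_u <- predict(bundle, px[uk, , drop = FALSE], type = "spectra")
  idx <- match(key, key[uk])
  # clip_count must reflect every pixel, not just unique colours
  counts_u <- rowSums(
    spectra_from_scores_raw(bundle, px[uk, , drop = FALSE]) < 0 |
      spectra_from_scores_raw(bundle, px[uk, , drop = FALSE]) > bundle$clip_max)
  clip_count <- sum(counts_u[idx])
  sp <- spectra_u[idx, , drop = FALSE]
  cube <- array(sp, dim = c(d[1], d[2], bundle$grid$n))
  hyperspectral_cube(cube, bundle$grid, clip_count = clip_count)
}

# unclipped spectra for clip accounting
spectra_from_scores_raw <- function(bundle, rgb) {
  lin <- linearize_srgb(subtract_dark(rgb, bundle$dark_offset),
                        gamma_mode = bundle$gamma_mode, gamma = bundle$gamma)
  V <- expand_variables(lin, degree = bundle$degree)
  xyz <- apply_correction(bundle$correction, V)
  sc <- scores_from_xyz(bundle, xyz)
  sweep(sc %*% t(bundle$basis$components), 2, bundle$basis$mean_spectrum, "+")
}

#' Render a cube to white-light sRGB
#'
#' Integrates each pixel spectrum against an illuminant and the CIE 1931
#' observer, converts to linear sRGB and gamma-encodes, giving the
#' conventional white-light view of a reconstructed cube.
#'
#' @param cube a [hyperspectral_cube()].
#' @param illuminant,cmfs on the cube grid (defaults D65 / CIE 1931).
#' @return H x W x 3 array of 8-bit sRGB codes.
#' @export
render_wli <- function(cube, illuminant = illuminant_d65(cube$grid),
                       cmfs = cie_cmfs(cube$grid)) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  px <- matrix(cube$values, nrow = cube$height * cube$width)
  xyz <- reflectance_to_xyz(px, illuminant, cmfs)
  rgb <- xyz_to_linear_srgb(xyz) / 100
  out <- encode_srgb(pmin(pmax(rgb, 0), 1))
  array(out, dim = c(cube$height, cube$width, 3))
}

envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(size = 4L, what = "numeric"),
         "5" = list(size = 8L, what = "numeric"),
         stop("unsupported ENVI data type ", code,
              " (supported: 4 = float32, 5 = float64)"))
}

#' Write a cube in ENVI format (text header + band-sequential binary)
#'
#' Writes `<path>.hdr` (plain-text ENVI header carrying dimensions, band
#' wavelengths and the grid) and `<path>.dat` (band-sequential
#' little-endian floats). The default 64-bit data type round-trips values
#' bit-exactly; `data_type = 4` writes conventional 32-bit floats.
#'
#' @param cube a [hyperspectral_cube()].
#' @param path base path (extensions `.hdr`/`.dat` are appended).
#' @param data_type ENVI data type code: 5 = float64 (default), 4 = float32.
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path, data_type = 5) {
  stopifnot(inherits(cube, "hyperspectral_cube"))
  dt <- envi_dtype(data_type)
  hdr <- c(
    "ENVI",
    "description = { savelight reflectance cube }",
    paste0("samples = ", cube$width),
    paste0("lines = ", cube$height),
    paste0("bands = ", cube$grid$n),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", data_type),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("clip count = ", cube$clip_count),
    paste0("wavelength = { ",
           paste(format(cube$grid$wavelengths, trim = TRUE), collapse = ", "),
           " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: all pixels of band 1 (column-major within a band), then band 2, ...
  writeBin(as.vector(cube$values), con, size = dt$size, endian = "little")
  invisible(path)
}

parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  get1 <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?m)^", key, " *= *([^\n{]+)$"), txt,
                                 perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  wl <- regmatches(txt, regexec("wavelength *= *\\{([^}]*)\\}", txt))[[1]]
  list(samples = as.integer(get1("samples")),
       lines = as.integer(get1("lines")),
       bands = as.integer(get1("bands")),
       data_type = as.integer(get1("data type")),
       interleave = get1("interleave"),
       clip_count = as.integer(get1("clip count")),
       wavelengths = if (length(wl) >= 2) {
         as.numeric(strsplit(wl[2], ",")[[1]])
       } else NULL)
}

#' Read a cube written by [write_envi()]
#' @param path base path used when writing.
#' @return a [hyperspectral_cube()].
#' @export
read_envi <- function(path) {
  hdr <- parse_envi_header(readLines(paste0(path, ".hdr")))
  if (is.na(hdr$samples) || is.na(hdr$bands)) {
    stop("malformed ENVI header: ", path, ".hdr")
  }
  if (!identical(hdr$interleave, "bsq")) {
    stop("only bsq interleave is supported, got ", hdr$interleave)
  }
  dt <- envi_dtype(hdr$data_type)
  n <- hdr$samples * hdr$lines * hdr$bands
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = dt$what, n = n, size = dt$size,
                  endian = "little")
  if (length(vals) != n) stop("truncated ENVI data file: ", path, ".dat")
  wl <- hdr$wavelengths
  grid <- spectral_grid(wl[1], wl[length(wl)], wl[2] - wl[1])
  hyperspectral_cube(array(vals, dim = c(hdr$lines, hdr$samples, hdr$bands)),
                     grid,
                     clip_count = if (is.na(hdr$clip_count)) 0L else hdr$clip_count)
}

#' Read an RGB image file into an 8-bit H x W x 3 array
#'
#' @param path a PNG file.
#' @return H x W x 3 array of integer codes 0--255. Images with an alpha
#'   channel are rejected.
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) stop("greyscale image; expected 3 channels")
  if (dim(img)[3] == 4) stop("image has an alpha channel; remove it first")
  if (dim(img)[3] != 3) stop("expected 3 channels, got ", dim(img)[3])
  round(img * 255)
}

#' Write an 8-bit H x W x 3 array as PNG
#' @param image H x W x 3 array of codes 0--255.
#' @param path output file.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
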