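mat_to_json <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), data = as.vector(t(unclass(m))))
}

mat_from_json <- function(j) {
  # JSON has no integer/double distinction; everything numeric comes back as
  # double so round trips are identical()
  matrix(as.numeric(unlist(j$data)), nrow = j$nrow, ncol = j$ncol, byrow = TRUE)
}

#' Save a calibration fit to JSON
#'
#' Single JSON document embedding all matrices row-major, with term labels,
#' the wavelength grid and provenance. Numbers are written at full precision,
#' so [read_calibration()] reproduces the fit bit-exactly.
#'
#' @param bundle a [save_calibrate()] fit.
#' @param path output file.
#' @export
write_calibration <- function(bundle, path) {
  stopifnot(inherits(bundle, "save_calibration"))
  doc <- list(
    format = "savelight-calibration-1",
    grid = list(start_nm = bundle$grid$start_nm, stop_nm = bundle$grid$stop_nm,
                step_nm = bundle$grid$step_nm),
    degree = bundle$degree, n_components = bundle$n_components,
    gamma_mode = bundle$gamma_mode, gamma = bundle$gamma,
    rcond = bundle$rcond, clip_max = bundle$clip_max,
    dark_offset = bundle$dark_offset,
    term_labels_rgb = attr(bundle$correction, "term_labels"),
    term_labels_xyz = attr(bundle$transform, "term_labels"),
    correction = mat_to_json(bundle$correction),
    transform = mat_to_json(bundle$transform),
    mean_spectrum = bundle$basis$mean_spectrum,
    components = mat_to_json(bundle$basis$components),
    explained_variance_fraction = bundle$basis$explained_variance_fraction,
    scores = mat_to_json(bundle$basis$scores),
    white = bundle$white,
    patch_ids = bundle$patch_ids,
    reference_xyz = mat_to_json(bundle$reference_xyz),
    corrected_xyz = mat_to_json(bundle$corrected_xyz),
    naive_xyz = mat_to_json(bundle$naive_xyz),
    reference_spectra = mat_to_json(bundle$reference_spectra),
    provenance = bundle$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 17, pretty = TRUE)
  invisible(path)
}

#' Load a calibration fit written by [write_calibration()]
#' @param path JSON file.
#' @return a `save_calibration` object.
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "savelight-calibration-1")) {
    stop("not a savelight calibration file: ", path)
  }
  grid <- spectral_grid(as.numeric(doc$grid$start_nm),
                        as.numeric(doc$grid$stop_nm),
                        as.numeric(doc$grid$step_nm))
  C <- mat_from_json(doc$correction)
  rownames(C) <- c("X", "Y", "Z")
  colnames(C) <- doc$term_labels_rgb
  attr(C, "term_labels") <- doc$term_labels_rgb
  class(C) <- c("correction_matrix", class(C))
  M <- mat_from_json(doc$transform)
  colnames(M) <- doc$term_labels_xyz
  attr(M, "term_labels") <- doc$term_labels_xyz
  class(M) <- c("spectral_transform", class(M))
  basis <- structure(list(
    mean_spectrum = as.numeric(doc$mean_spectrum),
    components = mat_from_json(doc$components),
    explained_variance_fraction = as.numeric(doc$explained_variance_fraction),
    scores = mat_from_json(doc$scores), grid = grid), class = "pca_basis")
  ids <- doc$patch_ids
  named3 <- function(m, with_ids = FALSE) {
    dimnames(m) <- list(if (with_ids) ids, c("X", "Y", "Z"))
    m
  }
  rownames(basis$scores) <- ids
  white <- as.numeric(unlist(doc$white))
  names(white) <- c("X", "Y", "Z")
  ref_spectra <- mat_from_json(doc$reference_spectra)
  rownames(ref_spectra) <- ids
  structure(list(
    correction = C, transform = M, basis = basis, grid = grid, white = white,
    degree = as.numeric(doc$degree),
    n_components = as.numeric(doc$n_components),
    gamma_mode = doc$gamma_mode, gamma = as.numeric(doc$gamma),
    rcond = as.numeric(doc$rcond), clip_max = as.numeric(doc$clip_max),
    dark_offset = as.numeric(unlist(doc$dark_offset)),
    patch_ids = ids,
    reference_xyz = named3(mat_from_json(doc$reference_xyz), with_ids = TRUE),
    corrected_xyz = named3(mat_from_json(doc$corrected_xyz)),
    naive_xyz = named3(mat_from_json(doc$naive_xyz)),
    reference_spectra = ref_spectra,
    provenance = doc$provenance),
    class = "save_calibration")
}
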