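#' Subtract a dark-current offset from channel values
#'
#' Endoscopy cameras add a preset dark-current offset to every channel;
#' calibration removes it before gamma linearisation. Values are floored at
#' zero.
#'
#' @param rgb numeric vector, matrix (n x 3) or array of 8-bit channel values.
#' @param offset non-negative per-channel offset; scalar or length 3 (recycled
#'   across rows / the third array dimension).
#' @return same shape as `rgb`.
#' @export
subtract_dark <- function(rgb, offset) {
  if (any(offset < 0)) stop("dark offset must be non-negative")
  if (is.matrix(rgb) && length(offset) == ncol(rgb)) {
    out <- pmax(sweep(rgb, 2, offset, "-"), 0)
  } else if (length(dim(rgb)) == 3 && length(offset) == dim(rgb)[3]) {
    out <- rgb
    for (ch in seq_len(dim(rgb)[3])) {
      out[, , ch] <- pmax(rgb[, , ch] - offset[ch], 0)
    }
  } else {
    out <- pmax(rgb - offset, 0)
  }
  out
}

monomial_exponents <- function(degree) {
  # graded lexicographic: total degree ascending, then lexicographic with the
  # first variable strongest
  out <- list()
  for (d in 0:degree) {
    for (i in d:0) for (j in (d - i):0) {
      out[[length(out) + 1L]] <- c(i, j, d - i - j)
    }
  }
  do.call(rbind, out)
}

monomial_label <- function(e, vars) {
  if (all(e == 0)) return("1")
  parts <- character(0)
  for (v in 1:3) {
    if (e[v] > 0) {
      parts <- c(parts, if (e[v] == 1) vars[v] else paste0(vars[v], e[v]))
    }
  }
  paste0(parts, collapse = "")
}

#' Polynomial variable expansion of channel triples
#'
#' Builds the variable matrix of the colour-correction model: all monomials
#' of total degree at most `degree` in the three channels, plus an optional
#' constant column, in graded-lexicographic order. The full trivariate cubic
#' with constant has 20 terms; the cubic cap guards against overfitting a
#' 24-patch chart.
#'
#' @param x n x 3 matrix of (linearised) channel values; a length-3 vector is
#'   treated as one row.
#' @param degree polynomial degree, one of 1, 2, 3.
#' @param include_constant prepend a constant 1 column (default `TRUE`).
#' @param vars channel names used to label terms (default `c("r","g","b")`).
#' @return matrix with attribute `term_labels`.
#' @examples
#' colnames(expand_variables(c(0.2, 0.5, 0.8), degree = 1))
#' @export
expand_variables <- function(x, degree = 3, include_constant = TRUE,
                             vars = c("r", "g", "b")) {
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3, got ", degree)
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(m) != 3) stop("expected 3 channels, got ", ncol(m))
  ex <- monomial_exponents(degree)
  if (!include_constant) ex <- ex[-1, , drop = FALSE]
  V <- sapply(seq_len(nrow(ex)), function(t) {
    m[, 1]^ex[t, 1] * m[, 2]^ex[t, 2] * m[, 3]^ex[t, 3]
  })
  V <- matrix(V, nrow = nrow(m))
  labels <- apply(ex, 1, monomial_label, vars = vars)
  colnames(V) <- labels
  attr(V, "term_labels") <- labels
  V
}

check_term_labels <- function(a, b) {
  if (length(a) != length(b) || any(a != b)) {
    i <- which(a != b | is.na(a) | is.na(b))[1]
    stop("term labels disagree at position ", i, ": '", a[i], "' vs '", b[i], "'")
  }
}

#' Fit the colour-correction matrix C
#'
#' Least-squares fit of corrected tristimulus values to the expanded camera
#' variables, solved through the singular-value pseudo-inverse
#' (`C = XYZ' pinv(V')`): rank-deficient charts get the minimum-norm
#' solution.
#'
#' @param reference_xyz n x 3 matrix of reference XYZ triples (spectrometer
#'   side).
#' @param V variable matrix from [expand_variables()], n rows.
#' @param rcond singular-value cutoff for the pseudo-inverse.
#' @return 3 x n_terms matrix of class `correction_matrix` with attribute
#'   `term_labels`.
#' @export
fit_correction_matrix <- function(reference_xyz, V, rcond = 1e-10) {
  reference_xyz <- as.matrix(reference_xyz)
  V <- as.matrix(V)
  if (nrow(reference_xyz) != nrow(V)) {
    stop("row count mismatch: ", nrow(reference_xyz), " reference triples vs ",
         nrow(V), " variable rows")
  }
  if (all(V == 0)) stop("variable matrix is all zero; correction is degenerate")
  C <- t(reference_xyz) %*% pinv(t(V), rcond = rcond)
  rownames(C) <- c("X", "Y", "Z")
  colnames(C) <- colnames(V)
  attr(C, "term_labels") <- attr(V, "term_labels")
  class(C) <- c("correction_matrix", class(C))
  C
}

#' Apply a correction matrix to a variable matrix
#'
#' @param C a [fit_correction_matrix()] result.
#' @param V variable matrix whose term labels match `C`.
#' @return n x 3 matrix of corrected XYZ rows (not clipped).
#' @export
apply_correction <- function(C, V) {
  check_term_labels(attr(C, "term_labels"), attr(V, "term_labels"))
  out <- V %*% t(unclass(C))
  colnames(out) <- c("X", "Y", "Z")
  out
}

#' Principal-component basis of reflectance spectra
#'
#' Mean-centred PCA via singular value decomposition. Component signs are
#' fixed so that each component's largest-magnitude coefficient is positive;
#' explained-variance fractions are reported relative to the total variance.
#'
#' @param spectra n x bands matrix (rows are spectra) or list of [spectrum()]
#'   objects on one grid; n >= 2.
#' @param n_components number of components to keep (default 6, the number
#'   found to carry essentially all chart variance); at most
#'   `min(n - 1, bands)`.
#' @return object of class `pca_basis`: `mean_spectrum`, `components`
#'   (bands x k, orthonormal columns), `explained_variance_fraction` (length
#'   k, non-increasing), `scores` (n x k), `grid` (when available).
#' @export
pca_reflectance <- function(spectra, n_components = 6) {
  grid <- NULL
  if (is.list(spectra) && !is.data.frame(spectra)) {
    grid <- spectra[[1]]$grid
    spectra <- do.call(rbind, lapply(spectra, function(s) s$values))
  }
  X <- as.matrix(spectra)
  if (nrow(X) < 2) stop("need at least 2 spectra for PCA, got ", nrow(X))
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components > kmax) {
    stop("n_components (", n_components, ") exceeds min(n - 1, bands) = ", kmax)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  comp <- s$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest |coefficient| entry of each component positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  scores <- Xc %*% comp
  tot <- sum(s$d^2)
  evf <- if (tot > 0) s$d[seq_len(n_components)]^2 / tot else rep(0, n_components)
  structure(list(mean_spectrum = mu, components = comp,
                 explained_variance_fraction = evf,
                 scores = scores, grid = grid),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d components over %d bands; cumulative variance %.4f\n",
              ncol(x$components), length(x$mean_spectrum),
              sum(x$explained_variance_fraction)))
  invisible(x)
}

#' Fit the spectral transform M from PCA scores
#'
#' Least-squares regression of per-patch PCA scores on the polynomial
#' expansion of corrected colours (`M = Score' pinv(Vcolour')`), again
#' through the singular-value pseudo-inverse.
#'
#' @param scores n x k matrix of PCA scores.
#' @param v_colour n x n_terms variable matrix built from corrected XYZ rows.
#' @param rcond singular-value cutoff.
#' @return k x n_terms matrix of class `spectral_transform` with
#'   `term_labels`.
#' @export
fit_spectral_transform <- function(scores, v_colour, rcond = 1e-10) {
  scores <- as.matrix(scores)
  v_colour <- as.matrix(v_colour)
  if (nrow(scores) != nrow(v_colour)) {
    stop("row count mismatch: ", nrow(scores), " score rows vs ",
         nrow(v_colour), " variable rows")
  }
  M <- t(scores) %*% pinv(t(v_colour), rcond = rcond)
  colnames(M) <- colnames(v_colour)
  attr(M, "term_labels") <- attr(v_colour, "term_labels")
  class(M) <- c("spectral_transform", class(M))
  M
}

#' Similarity index between predicted and measured XYZ sets
#'
#' Defined in this package as `1 - RMSE / RMS(measured)`, clamped to \[0, 1\]:
#' 1 means perfect agreement, 0 means the error is as large as the reference
#' signal itself. The index quantifies the fit between spectrometer-derived
#' and algorithm-estimated tristimulus values; the exact formula is a package
#' definition.
#'
#' @param predicted,measured equal-size numeric vectors or matrices.
#' @return scalar in \[0, 1\].
#' @export
similarity_index <- function(predicted, measured) {
  p <- as.numeric(predicted)
  m <- as.numeric(measured)
  if (length(p) == 0 || length(m) == 0) stop("inputs must be non-empty")
  if (length(p) != length(m)) stop("predicted and measured sizes differ")
  rms <- sqrt(mean(m^2))
  if (rms == 0) return(if (all(p == 0)) 1 else 0)
  min(max(1 - sqrt(mean((p - m)^2)) / rms, 0), 1)
}

#' Reference colour chart
#'
#' Bundles the spectrometer side of a 24-patch colour checker: patch
#' reflectance spectra on one grid plus their tristimulus values under a
#' stated illuminant.
#'
#' @param spectra n x bands matrix of patch reflectances (rows in chart
#'   layout order).
#' @param grid the [spectral_grid()] of the columns.
#' @param patch_ids character patch labels (default `patch01...`).
#' @param illuminant,cmfs used to compute the stored reference XYZ (default
#'   D65 / CIE 1931 2 degree).
#' @return object of class `chart_reference`.
#' @export
chart_reference <- function(spectra, grid, patch_ids = NULL,
                            illuminant = illuminant_d65(grid),
                            cmfs = cie_cmfs(grid)) {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != grid$n) stop("spectra bands do not match grid")
  if (is.null(patch_ids)) patch_ids <- sprintf("patch%02d", seq_len(nrow(spectra)))
  xyz <- reflectance_to_xyz(spectra, illuminant, cmfs)
  rownames(spectra) <- rownames(xyz) <- patch_ids
  structure(list(spectra = spectra, grid = grid, patch_ids = patch_ids,
                 xyz = xyz, illuminant = illuminant, cmfs = cmfs),
            class = "chart_reference")
}

#' @export
print.chart_reference <- function(x, ...) {
  cat(sprintf("<chart_reference> %d patches on %s nm\n",
              length(x$patch_ids), format(x$grid)))
  invisible(x)
}

#' Read a chart reference from a CSV spectral table
#'
#' Accepts user-supplied measured chart spectra (e.g. a spectrometer dump of
#' an X-Rite chart) in the package CSV dialect: `wavelength_nm` first, one
#' column per patch.
#'
#' @param path CSV path.
#' @param grid target [spectral_grid()] (default [master_grid()]).
#' @inheritParams chart_reference
#' @return a [chart_reference()].
#' @export
read_chart_reference <- function(path, grid = master_grid(),
                                 illuminant = illuminant_d65(grid),
                                 cmfs = cie_cmfs(grid)) {
  specs <- read_spectra_csv(path, grid = grid)
  chart_reference(do.call(rbind, lapply(specs, `[[`, "values")), grid,
                  patch_ids = names(specs), illuminant = illuminant,
                  cmfs = cmfs)
}

#' Camera capture of a colour chart
#'
#' @param rgb n x 3 matrix of mean 8-bit channel values per patch (fractional
#'   values allowed, as patch-region averages are).
#' @param dark_offset per-channel dark-current constant (scalar or length 3).
#' @param patch_ids labels matching the chart layout order.
#' @return object of class `patch_capture`.
#' @export
patch_capture <- function(rgb, dark_offset = 0, patch_ids = NULL) {
  rgb <- as.matrix(rgb)
  if (ncol(rgb) != 3) stop("capture must have 3 channels")
  if (any(rgb < 0 | rgb > 255)) stop("capture values must lie in [0, 255]")
  if (any(dark_offset < 0)) stop("dark offset must be non-negative")
  if (is.null(patch_ids)) patch_ids <- sprintf("patch%02d", seq_len(nrow(rgb)))
  colnames(rgb) <- c("R", "G", "B")
  structure(list(rgb = rgb, dark_offset = rep(dark_offset, length.out = 3),
                 patch_ids = patch_ids),
            class = "patch_capture")
}

#' Read a patch capture from CSV (`patch_id,R,G,B`)
#' @param path CSV path.
#' @param dark_offset per-channel dark-current constant.
#' @return a [patch_capture()].
#' @export
read_patch_capture <- function(path, dark_offset = 0) {
  tab <- utils::read.csv(path)
  need <- c("patch_id", "R", "G", "B")
  if (!all(need %in% names(tab))) {
    stop("capture CSV needs columns patch_id,R,G,B: ", path)
  }
  patch_capture(as.matrix(tab[, c("R", "G", "B")]), dark_offset,
                patch_ids = as.character(tab$patch_id))
}

#' Calibrate a camera against a reference colour chart
#'
#' The central fit of the package. From one chart capture it estimates
#' everything needed to turn that camera's RGB values into reflectance
#' spectra:
#' \enumerate{
#'   \item dark-current subtraction and gamma linearisation of the captured
#'     patch means;
#'   \item the colour-correction matrix `C` mapping the degree-`degree`
#'     polynomial expansion of linear RGB to reference XYZ (least squares via
#'     pseudo-inverse);
#'   \item a mean-centred PCA basis of the chart reflectance spectra;
#'   \item the spectral transform `M` regressing patch PCA scores on the
#'     polynomial expansion of the corrected XYZ (scaled by 1/100 for
#'     conditioning of the cubic terms).
#' }
#' The fitted object predicts spectra for new RGB values ([predict.save_calibration()])
#' and drives whole-image reconstruction ([rgb_image_to_cube()]).
#'
#' @param capture a [patch_capture()].
#' @param chart a [chart_reference()] with matching patch order.
#' @param degree polynomial degree of the variable expansion (1--3, default 3).
#' @param n_components PCA components kept (default 6).
#' @param gamma_mode camera transfer curve: `"srgb"`, `"power"`, `"linear"`.
#' @param gamma exponent when `gamma_mode = "power"`.
#' @param rcond pseudo-inverse singular-value cutoff.
#' @param clip_max ceiling for reconstructed reflectance (default 1.2;
#'   reconstruction may overshoot 1 and is hard-clipped with a count).
#' @return an object of class `save_calibration`.
#' @examples
#' chart <- make_reference_chart()
#' cam <- make_camera_model("ideal")
#' cap <- simulate_capture(chart, cam)
#' fit <- save_calibrate(cap, chart, gamma_mode = "linear")
#' fit
#' @export
save_calibrate <- function(capture, chart, degree = 3, n_components = 6,
                           gamma_mode = c("srgb", "power", "linear"),
                           gamma = 2.2, rcond = 1e-10, clip_max = 1.2) {
  stopifnot(inherits(capture, "patch_capture"), inherits(chart, "chart_reference"))
  gamma_mode <- match.arg(gamma_mode)
  if (nrow(capture$rgb) != nrow(chart$spectra)) {
    stop("capture has ", nrow(capture$rgb), " patches but chart has ",
         nrow(chart$spectra))
  }
  if (!all(capture$patch_ids == chart$patch_ids)) {
    stop("capture and chart patch ids are not in the same order")
  }

  lin <- linearize_srgb(subtract_dark(capture$rgb, capture$dark_offset),
                        gamma_mode = gamma_mode, gamma = gamma)
  V <- expand_variables(lin, degree = degree)
  C <- fit_correction_matrix(chart$xyz, V, rcond = rcond)
  xyz_corrected <- apply_correction(C, V)

  basis <- pca_reflectance(chart$spectra, n_components = n_components)
  basis$grid <- chart$grid
  v_colour <- expand_variables(xyz_corrected / 100, degree = degree,
                               vars = c("x", "y", "z"))
  M <- fit_spectral_transform(basis$scores, v_colour, rcond = rcond)

  # naive camera colours (standard sRGB primaries), kept for before/after
  # comparison of the correction stage
  xyz_naive <- linear_srgb_to_xyz(lin)
  white <- illuminant_white(chart$illuminant, chart$cmfs)

  structure(list(
    correction = C, transform = M, basis = basis,
    grid = chart$grid, white = white,
    degree = degree, n_components = n_components,
    gamma_mode = gamma_mode, gamma = gamma, rcond = rcond,
    clip_max = clip_max, dark_offset = capture$dark_offset,
    patch_ids = chart$patch_ids,
    reference_xyz = chart$xyz, corrected_xyz = xyz_corrected,
    naive_xyz = xyz_naive, reference_spectra = chart$spectra,
    provenance = sprintf("savelight %s, fitted %s",
                         as.character(utils::packageVersion("savelight")),
                         format(Sys.time(), "%Y-%m-%d"))),
    class = "save_calibration")
}

#' @export
print.save_calibration <- function(x, ...) {
  cat("Camera-to-spectrum calibration\n")
  cat(sprintf("  patches: %d   polynomial degree: %d (%d terms)   PCA components: %d\n",
              length(x$patch_ids), x$degree, ncol(x$correction), x$n_components))
  cat(sprintf("  grid: %s nm   transfer: %s\n", format(x$grid), x$gamma_mode))
  de <- ciede2000(xyz_to_lab(x$corrected_xyz, x$white),
                  xyz_to_lab(x$reference_xyz, x$white))
  cat(sprintf("  mean training dE00 after correction: %.4f\n", mean(de)))
  invisible(x)
}

#' @export
coef.save_calibration <- function(object, ...) {
  list(correction = object$correction, transform = object$transform)
}

#' @export
residuals.save_calibration <- function(object, ...) {
  object$corrected_xyz - object$reference_xyz
}

#' @export
fitted.save_calibration <- function(object, ...) object$corrected_xyz

#' Predict spectra, XYZ or PCA scores from RGB values
#'
#' Applies the fitted calibration chain (dark subtraction, linearisation,
#' polynomial correction, spectral transform) to new 8-bit RGB values.
#'
#' @param object a [save_calibrate()] fit.
#' @param newdata n x 3 matrix of 8-bit RGB values (or a length-3 vector).
#' @param type `"spectra"` (n x bands reflectance matrix, clipped to
#'   \[0, clip_max\]), `"xyz"` (corrected tristimulus rows) or `"scores"`.
#' @param ... unused.
#' @return matrix as described; spectra carry attribute `clip_count`.
#' @export
predict.save_calibration <- function(object, newdata,
                                     type = c("spectra", "xyz", "scores"), ...) {
  type <- match.arg(type)
  rgb <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  lin <- linearize_srgb(subtract_dark(rgb, object$dark_offset),
                        gamma_mode = object$gamma_mode, gamma = object$gamma)
  V <- expand_variables(lin, degree = object$degree)
  xyz <- apply_correction(object$correction, V)
  if (type == "xyz") return(xyz)
  scores <- scores_from_xyz(object, xyz)
  if (type == "scores") return(scores)
  spectra_from_scores(object, scores)
}

scores_from_xyz <- function(object, xyz) {
  v_colour <- expand_variables(xyz / 100, degree = object$degree,
                               vars = c("x", "y", "z"))
  check_term_labels(attr(object$transform, "term_labels"),
                    attr(v_colour, "term_labels"))
  v_colour %*% t(unclass(object$transform))
}

spectra_from_scores <- function(object, scores) {
  sp <- scores %*% t(object$basis$components)
  sp <- sweep(sp, 2, object$basis$mean_spectrum, "+")
  n_clip <- sum(sp < 0 | sp > object$clip_max)
  sp <- pmin(pmax(sp, 0), object$clip_max)
  attr(sp, "clip_count") <- n_clip
  sp
}

#' Reconstruct one reflectance spectrum from a tristimulus triple
#'
#' The Eq-7 pathway of the model: expand the corrected XYZ, map to PCA scores
#' through the spectral transform, then re-expand on the basis
#' (`mean + sum(score_i * component_i)`), clipping into \[0, clip_max\].
#'
#' @param xyz `c(X, Y, Z)` on the 0--100 scale (already colour-corrected).
#' @param bundle a [save_calibrate()] fit.
#' @return a [spectrum()] on the calibration grid, with attribute
#'   `clip_count`.
#' @export
xyz_to_spectrum <- function(xyz, bundle) {
  stopifnot(inherits(bundle, "save_calibration"))
  sp <- spectra_from_scores(bundle, scores_from_xyz(bundle, matrix(xyz, nrow = 1)))
  out <- spectrum(sp[1, ], bundle$grid)
  attr(out, "clip_count") <- attr(sp, "clip_count")
  out
}

#' Summarise a calibration fit
#'
#' @param object a [save_calibrate()] fit.
#' @param ... unused.
#' @return a `summary.save_calibration` list: the per-patch report plus mean
#'   colour differences before and after correction and the mean spectral
#'   RMSE.
#' @export
summary.save_calibration <- function(object, ...) {
  rep <- calibration_patch_table(object)
  out <- list(table = rep,
              mean_de00_pre = mean(rep$de00_pre),
              mean_de00_post = mean(rep$de00_post),
              mean_spectral_rmse = mean(rep$spectral_rmse),
              similarity = similarity_index(object$corrected_xyz,
                                            object$reference_xyz),
              n_components = object$n_components,
              cumulative_variance = sum(object$basis$explained_variance_fraction))
  class(out) <- "summary.save_calibration"
  out
}

#' @export
print.summary.save_calibration <- function(x, ...) {
  cat("Calibration summary\n")
  cat(sprintf("  mean dE00: %.4f before correction, %.4f after\n",
              x$mean_de00_pre, x$mean_de00_post))
  cat(sprintf("  mean spectral RMSE: %.5f   XYZ similarity index: %.4f\n",
              x$mean_spectral_rmse, x$similarity))
  cat(sprintf("  PCA: %d components, cumulative variance %.4f\n",
              x$n_components, x$cumulative_variance))
  invisible(x)
}

calibration_patch_table <- function(bundle) {
  white <- bundle$white
  lab_ref <- xyz_to_lab(bundle$reference_xyz, white)
  de_post <- ciede2000(xyz_to_lab(bundle$corrected_xyz, white), lab_ref)
  de_pre <- ciede2000(xyz_to_lab(bundle$naive_xyz, white), lab_ref)
  recon <- spectra_from_scores(bundle,
                               scores_from_xyz(bundle, bundle$corrected_xyz))
  rmse <- sqrt(rowMeans((recon - bundle$reference_spectra)^2))
  data.frame(patch_id = bundle$patch_ids,
             spectral_rmse = rmse,
             de00_pre = de_pre,
             de00_post = de_post,
             row.names = NULL)
}

#' Per-patch calibration error report
#'
#' Re-evaluates a fitted calibration against a chart/capture pair: spectral
#' RMSE between reconstructed and reference patch spectra, and CIEDE2000
#' between corrected (and uncorrected) camera colours and the reference
#' colours.
#'
#' @param bundle a [save_calibrate()] fit.
#' @param chart the [chart_reference()].
#' @param capture the [patch_capture()] to evaluate (may be a fresh capture
#'   of the same chart).
#' @return a list of class `calibration_report`: `patches` (one row per
#'   patch), `mean_de00_pre`, `mean_de00_post`, `mean_spectral_rmse`.
#' @export
calibration_report <- function(bundle, chart, capture) {
  stopifnot(inherits(bundle, "save_calibration"))
  if (nrow(capture$rgb) != nrow(chart$spectra)) {
    stop("capture and chart patch counts differ")
  }
  if (!grids_identical(bundle$grid, chart$grid)) {
    stop("bundle and chart grids differ")
  }
  lin <- linearize_srgb(subtract_dark(capture$rgb, capture$dark_offset),
                        gamma_mode = bundle$gamma_mode, gamma = bundle$gamma)
  xyz_corr <- predict(bundle, capture$rgb, type = "xyz")
  recon <- predict(bundle, capture$rgb, type = "spectra")
  white <- bundle$white
  lab_ref <- xyz_to_lab(chart$xyz, white)
  de_post <- ciede2000(xyz_to_lab(xyz_corr, white), lab_ref)
  de_pre <- ciede2000(xyz_to_lab(linear_srgb_to_xyz(lin), white), lab_ref)
  rmse <- sqrt(rowMeans((recon - chart$spectra)^2))
  structure(list(
    patches = data.frame(patch_id = chart$patch_ids, spectral_rmse = rmse,
                         de00_pre = de_pre, de00_post = de_post,
                         row.names = NULL),
    mean_de00_pre = mean(de_pre), mean_de00_post = mean(de_post),
    mean_spectral_rmse = mean(rmse)),
    class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("Calibration report (%d patches)\n", nrow(x$patches)))
  cat(sprintf("  mean dE00: %.4f pre, %.4f post   mean spectral RMSE: %.5f\n",
              x$mean_de00_pre, x$mean_de00_post, x$mean_spectral_rmse))
  invisible(x)
}

#' Plot reference vs reconstructed patch spectra
#'
#' @param x a [save_calibrate()] fit.
#' @param patches indices of patches to draw (default first 6).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.save_calibration <- function(x, patches = 1:6, ...) {
  wl <- x$grid$wavelengths
  recon <- spectra_from_scores(x, scores_from_xyz(x, x$corrected_xyz))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(patches)),
                       mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (i in patches) {
    graphics::matplot(wl, cbind(x$reference_spectra[i, ], recon[i, ]),
                      type = "l", lty = c(1, 2), col = c("black", "red"),
                      xlab = "wavelength (nm)", ylab = "reflectance",
                      main = x$patch_ids[i], ...)
  }
  invisible(x)
}
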