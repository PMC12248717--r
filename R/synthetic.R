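# The synthetic chart is an affine family over three smooth shapes: a flat
# base, a red transmission edge and a blue Gaussian bump. Three shapes keep
# every patch spectrum a function of its tristimulus coordinates (no
# metamers), which is what makes noiseless construct-and-recover
# calibration exact; the weights below were chosen once to mimic the colour
# families of a physical 24-patch checker.
chart_shapes <- function(grid) {
  wl <- grid$wavelengths
  cbind(flat = rep(1, grid$n),
        red_edge = stats::plogis((wl - 600) / 20),
        blue_bump = exp(-(wl - 465)^2 / (2 * 40^2)))
}

chart_weights <- function() {
  w <- rbind(
    dark_skin     = c(0.15,  0.18,  0.03),
    light_skin    = c(0.32,  0.30,  0.08),
    blue_sky      = c(0.16, -0.04,  0.32),
    foliage       = c(0.22, -0.08, -0.04),
    blue_flower   = c(0.25,  0.10,  0.38),
    bluish_green  = c(0.42, -0.25,  0.18),
    orange        = c(0.14,  0.68, -0.02),
    purplish_blue = c(0.10,  0.08,  0.48),
    moderate_red  = c(0.12,  0.58,  0.10),
    purple        = c(0.08,  0.22,  0.26),
    yellow_green  = c(0.38, -0.18, -0.14),
    orange_yellow = c(0.25,  0.60, -0.10),
    blue          = c(0.06,  0.03,  0.52),
    green         = c(0.40, -0.28, -0.06),
    red           = c(0.05,  0.75,  0.02),
    yellow        = c(0.33,  0.55, -0.16),
    magenta       = c(0.18,  0.52,  0.40),
    cyan          = c(0.38, -0.26,  0.34),
    white         = c(0.92,  0.00,  0.00),
    neutral_8     = c(0.59,  0.00,  0.00),
    neutral_65    = c(0.36,  0.00,  0.00),
    neutral_5     = c(0.19,  0.00,  0.00),
    neutral_35    = c(0.09,  0.00,  0.00),
    black         = c(0.031, 0.00,  0.00))
  colnames(w) <- c("flat", "red_edge", "blue_bump")
  w
}

#' Synthetic 24-patch reference chart
#'
#' A deterministic stand-in for a measured colour checker: 18 chromatic
#' patches built from smooth logistic/Gaussian shapes spanning the
#' red/green/blue/cyan/magenta/yellow families plus 6 spectrally flat
#' greyscale tones, all within \[0, 1\]. For real use, load measured patch
#' spectra with [read_chart_reference()] instead.
#'
#' @param grid target [spectral_grid()] (default [master_grid()]).
#' @inheritParams chart_reference
#' @return a [chart_reference()] with 24 patches.
#' @export
make_reference_chart <- function(grid = master_grid(),
                                 illuminant = illuminant_d65(grid),
                                 cmfs = cie_cmfs(grid)) {
  w <- chart_weights()
  spectra <- w %*% t(chart_shapes(grid))
  chart_reference(spectra, grid, patch_ids = rownames(w),
                  illuminant = illuminant, cmfs = cmfs)
}

#' Parametric virtual camera
#'
#' Forward model that calibration inverts: three spectral sensitivity
#' curves, a transfer curve, additive Gaussian noise on the linear signal,
#' a dark-current offset and optional 8-bit quantisation.
#'
#' Presets: `"ideal"` uses the CIE 1931 observer curves as sensitivities
#' with a linear transfer, no noise, no dark current and no quantisation
#' (patch captures are patch-region means, effectively continuous), so its
#' captures are exactly linear in tristimulus values. `"realistic"` uses
#' shifted Gaussian sensitivities (600/540/465 nm), the sRGB curve, noise
#' sd 0.01, dark offset 5 and 8-bit quantisation.
#'
#' @param preset `"ideal"` or `"realistic"`; ignored when `sensitivities`
#'   is supplied.
#' @param grid sensor [spectral_grid()] (default [master_grid()]).
#' @param sensitivities optional 3 x bands matrix of channel sensitivities.
#' @param gamma_mode,gamma transfer curve (see [linearize_srgb()]).
#' @param dark_offset per-channel 8-bit dark constant.
#' @param noise_sd Gaussian noise sd on the linear signal (>= 0).
#' @param bit_depth quantisation depth; `Inf` disables quantisation.
#' @param seed RNG seed used by [simulate_capture()] noise.
#' @return object of class `camera_model`.
#' @export
make_camera_model <- function(preset = c("ideal", "realistic"),
                              grid = master_grid(), sensitivities = NULL,
                              gamma_mode = NULL, gamma = 2.2,
                              dark_offset = NULL, noise_sd = NULL,
                              bit_depth = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(sensitivities)) {
    if (preset == "ideal") {
      cm <- cie_cmfs(grid)
      sensitivities <- rbind(R = cm$xbar, G = cm$ybar, B = cm$zbar)
      if (is.null(gamma_mode)) gamma_mode <- "linear"
      if (is.null(dark_offset)) dark_offset <- 0
      if (is.null(noise_sd)) noise_sd <- 0
      if (is.null(bit_depth)) bit_depth <- Inf
    } else {
      wl <- grid$wavelengths
      sensitivities <- rbind(
        R = exp(-(wl - 600)^2 / (2 * 50^2)),
        G = exp(-(wl - 540)^2 / (2 * 45^2)),
        B = exp(-(wl - 465)^2 / (2 * 35^2)))
      if (is.null(gamma_mode)) gamma_mode <- "srgb"
      if (is.null(dark_offset)) dark_offset <- 5
      if (is.null(noise_sd)) noise_sd <- 0.01
      if (is.null(bit_depth)) bit_depth <- 8
    }
  } else {
    sensitivities <- as.matrix(sensitivities)
    if (is.null(gamma_mode)) gamma_mode <- "linear"
    if (is.null(dark_offset)) dark_offset <- 0
    if (is.null(noise_sd)) noise_sd <- 0
    if (is.null(bit_depth)) bit_depth <- Inf
  }
  if (nrow(sensitivities) != 3 || ncol(sensitivities) != grid$n) {
    stop("sensitivities must be 3 x ", grid$n)
  }
  if (any(sensitivities < 0)) stop("sensitivities must be non-negative")
  if (any(rowSums(sensitivities) == 0)) {
    stop("each channel needs a non-zero sensitivity curve")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(dark_offset < 0)) stop("dark_offset must be >= 0")
  structure(list(sensitivities = sensitivities, grid = grid,
                 gamma_mode = gamma_mode, gamma = gamma,
                 dark_offset = rep(dark_offset, length.out = 3),
                 noise_sd = noise_sd, bit_depth = bit_depth, seed = seed,
                 preset = preset),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %s transfer, noise sd %g, dark %s, %s\n",
              x$gamma_mode, x$noise_sd,
              paste(x$dark_offset, collapse = "/"),
              if (is.finite(x$bit_depth)) paste0(x$bit_depth, "-bit") else "unquantised"))
  invisible(x)
}

camera_dn <- function(values, camera, illuminant) {
  S <- illuminant$values
  sens <- camera$sensitivities
  norm <- as.numeric(sens %*% S)            # response of a perfect reflector
  lin <- as.matrix(values) %*% t(sens * rep(S, each = 3)) %*% diag(1 / norm)
  if (camera$noise_sd > 0) {
    lin <- lin + matrix(stats::rnorm(length(lin), sd = camera$noise_sd),
                        nrow = nrow(lin))
  }
  lin <- pmin(pmax(lin, 0), 1)
  dn <- encode_srgb(lin, gamma_mode = camera$gamma_mode, gamma = camera$gamma,
                    quantize = FALSE)
  dn <- sweep(dn, 2, camera$dark_offset, "+")
  if (is.finite(camera$bit_depth)) dn <- round(dn)   # round-half-even
  pmin(pmax(dn, 0), 255)
}

#' Simulate a camera capture
#'
#' Forward imaging model: per channel, linear response
#' `integral(S R sens) / integral(S sens)` (so a perfect reflector reads
#' full scale), plus Gaussian noise on the linear signal, transfer-curve
#' encoding, dark-offset addition and (for finite bit depth) round-half-even
#' quantisation. Noise is drawn under the camera's seed, so repeated calls
#' are identical.
#'
#' @param x a [chart_reference()] (returns a [patch_capture()]) or a
#'   [hyperspectral_cube()] (returns an H x W x 3 8-bit array).
#' @param camera a [make_camera_model()].
#' @param illuminant capture illuminant on the camera grid (default D65).
#' @return a [patch_capture()] or an RGB array, per `x`.
#' @export
simulate_capture <- function(x, camera,
                             illuminant = illuminant_d65(camera$grid)) {
  stopifnot(inherits(camera, "camera_model"))
  if (!grids_identical(camera$grid, illuminant$grid)) {
    stop("camera and illuminant grids differ")
  }
  if (inherits(x, "chart_reference")) {
    if (!grids_identical(x$grid, camera$grid)) {
      stop("chart and camera grids differ")
    }
    dn <- with_seed(camera$seed, camera_dn(x$spectra, camera, illuminant))
    patch_capture(dn, dark_offset = camera$dark_offset,
                  patch_ids = x$patch_ids)
  } else if (inherits(x, "hyperspectral_cube")) {
    if (!grids_identical(x$grid, camera$grid)) {
      stop("cube and camera grids differ")
    }
    px <- matrix(x$values, nrow = x$height * x$width)
    dn <- with_seed(camera$seed, camera_dn(px, camera, illuminant))
    array(dn, dim = c(x$height, x$width, 3))
  } else {
    stop("x must be a chart_reference or hyperspectral_cube")
  }
}

#' Random smooth reflectance spectra
#'
#' Gaussian-process-style curves: white noise smoothed with a Gaussian
#' kernel of bandwidth `smoothness` (nm), standardised and squashed into
#' (0, 1) with a logistic link. Seed-deterministic.
#'
#' @param n number of spectra (>= 1).
#' @param smoothness kernel bandwidth in nm; larger = smoother.
#' @param seed RNG seed.
#' @param grid target [spectral_grid()].
#' @return n x bands matrix of reflectances in (0, 1).
#' @export
synth_spectra <- function(n, smoothness = 30, seed = 1, grid = master_grid()) {
  if (n < 1) stop("n must be >= 1")
  if (smoothness <= 0) stop("smoothness must be positive")
  wl <- grid$wavelengths
  K <- exp(-outer(wl, wl, "-")^2 / (2 * smoothness^2))
  K <- K / rowSums(K)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * grid$n), nrow = n) %*% t(K)
    z <- z / apply(z, 1, stats::sd)
    offs <- stats::rnorm(n, sd = 0.5)
    stats::plogis(1.5 * z + offs)
  })
}

#' Scene specification for synthetic endoscopy frames
#'
#' @param height,width scene size in pixels.
#' @param base_reflectance mucosa [spectrum()]; default a smooth pink tissue
#'   curve.
#' @param vessel_count number of vessels.
#' @param vessel_width vessel width in pixels.
#' @param absorption_dips data.frame `centre_nm, fwhm_nm, depth` of Gaussian
#'   absorption dips applied to vessel pixels; depths in \[0, 1\]. Default:
#'   the haemoglobin maxima at 415 and 540 nm.
#' @param dip_depth convenience scalar scaling the default dips.
#' @param seed RNG seed for vessel placement.
#' @param grid target [spectral_grid()].
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 48, width = 48, base_reflectance = NULL,
                       vessel_count = 3, vessel_width = 3,
                       absorption_dips = NULL, dip_depth = 0.5, seed = 1,
                       grid = master_grid()) {
  if (is.null(base_reflectance)) {
    wl <- grid$wavelengths
    base_reflectance <- spectrum(
      0.25 + 0.45 * stats::plogis((wl - 590) / 25) +
        0.06 * exp(-(wl - 465)^2 / (2 * 45^2)), grid)
  }
  if (is.null(absorption_dips)) {
    absorption_dips <- data.frame(centre_nm = c(415, 540),
                                  fwhm_nm = c(35, 45),
                                  depth = c(dip_depth, 0.8 * dip_depth))
  }
  if (any(absorption_dips$depth < 0 | absorption_dips$depth > 1)) {
    stop("dip depths must lie in [0, 1]")
  }
  if (any(absorption_dips$centre_nm < grid$start_nm |
            absorption_dips$centre_nm > grid$stop_nm)) {
    stop("dip centres must lie within the grid")
  }
  structure(list(height = height, width = width,
                 base_reflectance = base_reflectance,
                 vessel_count = vessel_count, vessel_width = vessel_width,
                 absorption_dips = absorption_dips, seed = seed, grid = grid),
            class = "scene_spec")
}

vessel_mask <- function(spec) {
  with_seed(spec$seed, {
    mask <- matrix(FALSE, spec$height, spec$width)
    cols <- matrix(rep(seq_len(spec$width), each = spec$height),
                   spec$height, spec$width)
    for (v in seq_len(spec$vessel_count)) {
      x0 <- stats::runif(1, 0.15, 0.85) * spec$width
      amp <- stats::runif(1, 0.02, 0.12) * spec$width
      period <- stats::runif(1, 0.5, 1.5) * spec$height
      phase <- stats::runif(1, 0, 2 * pi)
      centre <- x0 + amp * sin(2 * pi * seq_len(spec$height) / period + phase)
      mask <- mask | abs(cols - centre) < spec$vessel_width / 2
    }
    mask
  })
}

#' Synthetic endoscopy-like scene
#'
#' Builds a hyperspectral cube of smooth mucosa reflectance with sinuous
#' vessels whose pixels are attenuated by Gaussian absorption dips (the
#' haemoglobin maxima at 415 and 540 nm by default), plus the matching
#' white-light sRGB render and vessel mask. With the default narrow-band
#' specification the vessels show higher Michelson contrast in the
#' narrow-band render than in white light, which is the clinical point of
#' the technique.
#'
#' @param spec a [scene_spec()].
#' @return list of class `endoscopy_scene`: `cube`
#'   ([hyperspectral_cube()]), `wli` (H x W x 3 8-bit array), `mask`
#'   (logical vessel mask), `spec`.
#' @export
synth_endoscopy_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  grid <- spec$grid
  wl <- grid$wavelengths
  base <- spec$base_reflectance$values
  atten <- rep(1, grid$n)
  for (i in seq_len(nrow(spec$absorption_dips))) {
    d <- spec$absorption_dips[i, ]
    sigma <- d$fwhm_nm / (2 * sqrt(2 * log(2)))
    atten <- atten * (1 - d$depth * exp(-(wl - d$centre_nm)^2 / (2 * sigma^2)))
  }
  vessel <- base * atten
  mask <- vessel_mask(spec)
  cube_vals <- array(rep(base, each = spec$height * spec$width),
                     dim = c(spec$height, spec$width, grid$n))
  for (b in seq_len(grid$n)) {
    layer <- cube_vals[, , b]
    layer[mask] <- vessel[b]
    cube_vals[, , b] <- layer
  }
  cube <- hyperspectral_cube(cube_vals, grid)
  structure(list(cube = cube, wli = render_wli(cube), mask = mask,
                 spec = spec),
            class = "endoscopy_scene")
}

#' @export
print.endoscopy_scene <- function(x, ...) {
  cat(sprintf("<endoscopy_scene> %d x %d px, %d vessel pixels, dips at %s nm\n",
              x$spec$height, x$spec$width, sum(x$mask),
              paste(x$spec$absorption_dips$centre_nm, collapse = "/")))
  invisible(x)
}
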