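#' sRGB gamma linearisation
#'
#' Decodes 8-bit sRGB channel codes to linear intensities in \[0, 1\] using
#' the IEC 61966-2-1 piecewise electro-optical transfer function. A pure
#' power-law decode is available via `gamma_mode = "power"` for cameras that
#' apply a plain gamma curve.
#'
#' @param x numeric vector/array of 8-bit codes in \[0, 255\] (fractional
#'   values allowed, e.g. patch-region means).
#' @param gamma_mode `"srgb"` (default), `"power"`, or `"linear"` (identity
#'   scaling by 1/255).
#' @param gamma exponent used when `gamma_mode = "power"`.
#' @return linear intensities, same shape as `x`.
#' @examples
#' linearize_srgb(c(0, 128, 255))
#' @export
linearize_srgb <- function(x, gamma_mode = c("srgb", "power", "linear"),
                           gamma = 2.2) {
  gamma_mode <- match.arg(gamma_mode)
  if (any(x < 0 | x > 255, na.rm = TRUE)) {
    stop("channel codes must lie in [0, 255]; offending value ",
         x[which(x < 0 | x > 255)[1]])
  }
  u <- x / 255
  out <- switch(gamma_mode,
    srgb  = ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4),
    power = u^gamma,
    linear = u)
  if (is.array(x)) dim(out) <- dim(x)
  out
}

#' Encode linear intensity to 8-bit sRGB (inverse of [linearize_srgb()])
#'
#' @param v linear intensities; values are clamped to \[0, 1\] before
#'   encoding.
#' @inheritParams linearize_srgb
#' @param quantize round to integer codes (default `TRUE`).
#' @return 8-bit codes in \[0, 255\].
#' @export
encode_srgb <- function(v, gamma_mode = c("srgb", "power", "linear"),
                        gamma = 2.2, quantize = TRUE) {
  gamma_mode <- match.arg(gamma_mode)
  v <- pmin(pmax(v, 0), 1)
  u <- switch(gamma_mode,
    srgb  = ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055),
    power = v^(1 / gamma),
    linear = v)
  out <- u * 255
  if (quantize) out <- round(out)
  if (is.array(v)) dim(out) <- dim(v)
  out
}

#' Reflectance to CIE XYZ tristimulus values
#'
#' Discretises the colorimetric integrals
#' \deqn{X = k \int S(\lambda) R(\lambda) \bar x(\lambda)\, d\lambda}
#' (and likewise for Y, Z) as left-anchored Riemann sums with uniform weight
#' \eqn{\Delta\lambda}, with the normalisation
#' \eqn{k = 100 / \int S(\lambda)\bar y(\lambda) d\lambda} so that a perfect
#' reflector (\eqn{R \equiv 1}) gives Y = 100 under any positive illuminant.
#' Integration is restricted to `limits_nm` (default 400--700 nm) even when
#' the shared grid extends further.
#'
#' @param refl a [spectrum()] of reflectance values, or a numeric matrix with
#'   one reflectance spectrum per row (on the shared grid).
#' @param illum illuminant [spectrum()] on the same grid.
#' @param cmfs a [cie_cmfs()] set on the same grid.
#' @param limits_nm integration limits in nm, default `c(400, 700)`.
#' @return for a single spectrum, a named numeric vector `c(X, Y, Z)`; for a
#'   matrix input, an n x 3 matrix.
#' @export
reflectance_to_xyz <- function(refl, illum, cmfs, limits_nm = c(400, 700)) {
  stopifnot(inherits(illum, "spectrum"), inherits(cmfs, "cmf_set"))
  single <- inherits(refl, "spectrum")
  if (single) {
    if (!grids_identical(refl$grid, illum$grid)) {
      stop("reflectance and illuminant grids differ; resample first")
    }
    R <- matrix(refl$values, nrow = 1)
  } else {
    R <- as.matrix(refl)
    if (ncol(R) != illum$grid$n) {
      stop("reflectance matrix has ", ncol(R), " bands but the grid has ",
           illum$grid$n)
    }
  }
  if (!grids_identical(illum$grid, cmfs$grid)) {
    stop("illuminant and CMF grids differ; resample first")
  }
  wl <- illum$grid$wavelengths
  keep <- wl >= limits_nm[1] - 1e-9 & wl <= limits_nm[2] + 1e-9
  S <- illum$values[keep]
  if (all(S == 0)) stop("illuminant is zero over the integration range; k is undefined")
  if (any(S < 0)) stop("illuminant must be non-negative")
  dl <- illum$grid$step_nm
  k <- 100 / sum(S * cmfs$ybar[keep] * dl)
  Rk <- R[, keep, drop = FALSE]
  xyz <- cbind(
    X = k * dl * as.vector(Rk %*% (S * cmfs$xbar[keep])),
    Y = k * dl * as.vector(Rk %*% (S * cmfs$ybar[keep])),
    Z = k * dl * as.vector(Rk %*% (S * cmfs$zbar[keep])))
  if (single) xyz[1, ] else xyz
}

#' White point of an illuminant (XYZ of a perfect reflector)
#' @inheritParams reflectance_to_xyz
#' @return named numeric `c(X, Y, Z)` with Y = 100.
#' @export
illuminant_white <- function(illum, cmfs, limits_nm = c(400, 700)) {
  reflectance_to_xyz(spectrum(rep(1, illum$grid$n), illum$grid),
                     illum, cmfs, limits_nm)
}

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

lab_f_inv <- function(ft) {
  d <- 6 / 29
  ifelse(ft > d, ft^3, 3 * d^2 * (ft - 4 / 29))
}

#' CIE XYZ to CIELAB
#'
#' Standard forward transform with the cube-root / linear-segment switch.
#'
#' @param xyz numeric `c(X, Y, Z)` or an n x 3 matrix.
#' @param white reference white `c(X, Y, Z)`; strictly positive. Defaults to
#'   D65 as integrated by this package.
#' @return `c(L, a, b)` or an n x 3 matrix.
#' @export
xyz_to_lab <- function(xyz, white = d65_white()) {
  if (any(white <= 0)) stop("white point must have strictly positive X, Y, Z")
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  fx <- lab_f(m[, 1] / white[1])
  fy <- lab_f(m[, 2] / white[2])
  fz <- lab_f(m[, 3] / white[3])
  lab <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (is.matrix(xyz)) lab else lab[1, ]
}

#' CIELAB to CIE XYZ (inverse of [xyz_to_lab()])
#' @param lab `c(L, a, b)` or an n x 3 matrix.
#' @inheritParams xyz_to_lab
#' @export
lab_to_xyz <- function(lab, white = d65_white()) {
  if (any(white <= 0)) stop("white point must have strictly positive X, Y, Z")
  m <- if (is.matrix(lab)) lab else matrix(lab, nrow = 1)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(X = white[1] * lab_f_inv(fx),
               Y = white[2] * lab_f_inv(fy),
               Z = white[3] * lab_f_inv(fz))
  if (is.matrix(lab)) xyz else xyz[1, ]
}

d65_white_cache <- new.env(parent = emptyenv())

#' D65 white point on the package master grid
#' @return named numeric `c(X, Y, Z)` (Y = 100).
#' @export
d65_white <- function() {
  if (is.null(d65_white_cache$w)) {
    g <- master_grid()
    d65_white_cache$w <- illuminant_white(illuminant_d65(g), cie_cmfs(g))
  }
  d65_white_cache$w
}

# Linear-sRGB (D65) <-> XYZ on the 0-100 XYZ scale; IEC 61966-2-1 primaries.
srgb_to_xyz_matrix <- function() {
  matrix(c(0.4124564, 0.3575761, 0.1804375,
           0.2126729, 0.7151522, 0.0721750,
           0.0193339, 0.1191920, 0.9503041) * 100,
         nrow = 3, byrow = TRUE)
}

#' Linear sRGB to XYZ (0--100 scale) under the sRGB/D65 primaries
#' @param rgb linear intensities, `c(r, g, b)` or n x 3 matrix, nominal \[0,1\].
#' @return XYZ on the 0--100 scale, matching [reflectance_to_xyz()].
#' @export
linear_srgb_to_xyz <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, nrow = 1)
  xyz <- m %*% t(srgb_to_xyz_matrix())
  colnames(xyz) <- c("X", "Y", "Z")
  if (is.matrix(rgb)) xyz else xyz[1, ]
}

#' XYZ (0--100 scale) to linear sRGB under the sRGB/D65 primaries
#' @param xyz `c(X, Y, Z)` or n x 3 matrix on the 0--100 scale.
#' @return linear intensities (can fall outside \[0,1\] for out-of-gamut
#'   colours; not clamped).
#' @export
xyz_to_linear_srgb <- function(xyz) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, nrow = 1)
  rgb <- m %*% t(solve(srgb_to_xyz_matrix()))
  colnames(rgb) <- c("r", "g", "b")
  if (is.matrix(xyz)) rgb else rgb[1, ]
}

#' CIEDE2000 colour difference
#'
#' The published reference CIEDE2000 algorithm with parametric factors
#' kL = kC = kH = 1, including the hue-rotation term and all hue-angle branch
#' cases. Vectorised over rows.
#'
#' @param lab1,lab2 `c(L, a, b)` vectors or n x 3 matrices.
#' @return numeric vector of colour differences (dimensionless).
#' @examples
#' ciede2000(c(50, 2.6772, -79.7751), c(50, 0, -82.7485))  # 2.0425
#' @export
ciede2000 <- function(lab1, lab2) {
  m1 <- if (is.matrix(lab1)) lab1 else matrix(lab1, nrow = 1)
  m2 <- if (is.matrix(lab2)) lab2 else matrix(lab2, nrow = 1)
  stopifnot(ncol(m1) == 3, ncol(m2) == 3, nrow(m1) == nrow(m2))
  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]

  C1 <- sqrt(a1^2 + b1^2)
  C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2)
  C2p <- sqrt(a2p^2 + b2^2)

  hue <- function(ap, b) {
    h <- atan2(b, ap) * 180 / pi
    h <- ifelse(h < 0, h + 360, h)
    ifelse(ap == 0 & b == 0, 0, h)
  }
  h1p <- hue(a1p, b1)
  h2p <- hue(a2p, b2)

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  zero_chroma <- C1p * C2p == 0
  dhp <- ifelse(zero_chroma, 0,
           ifelse(abs(dh) <= 180, dh,
             ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp * pi / 360)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(zero_chroma, hsum,
           ifelse(abs(h1p - h2p) <= 180, hsum / 2,
             ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  rad <- pi / 180
  Tfac <- 1 - 0.17 * cos((hbp - 30) * rad) + 0.24 * cos(2 * hbp * rad) +
    0.32 * cos((3 * hbp + 6) * rad) - 0.20 * cos((4 * hbp - 63) * rad)
  dtheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tfac
  RT <- -sin(2 * dtheta * rad) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
         RT * (dCp / SC) * (dHp / SH))
}
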