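test_that("band responses are normalised and linear", {
  g <- master_grid()
  ones <- spectrum(rep(1, g$n), g)
  expect_equal(band_response(ones, 415, 30), 1)
  expect_equal(band_response(ones, 540, 20, weight = 0.7), 0.7)
  expect_equal(band_response(spectrum(rep(0, g$n), g), 415, 30), 0)
  expect_equal(band_response(spectrum(rep(0.5, g$n), g), 540, 20, weight = 2), 1)
  expect_error(band_response(ones, 350, 30), "outside")
})

test_that("the Cauchy-Lorentz density evaluates exactly and integrates to one", {
  # substituting x = x0 collapses the density to 1/(pi * gamma)
  for (gam in c(0.5, 2, 20)) {
    expect_equal(cauchy_weight(7, 7, gam), 1 / (pi * gam))
  }
  d <- seq(0.1, 50, length.out = 25)
  expect_equal(cauchy_weight(10 + d, 10, 3), cauchy_weight(10 - d, 10, 3))
  x <- seq(-1000 * 2, 1000 * 2, by = 0.05)
  expect_equal(sum(cauchy_weight(x, 0, 2)) * 0.05, 1, tolerance = 1e-3)
  expect_error(cauchy_weight(1, 0, 0), "gamma")
})

test_that("narrow-band rendering is uniform on uniform cubes and band-local", {
  g <- master_grid()
  base <- 0.3 + 0.4 * stats::plogis((g$wavelengths - 600) / 30)
  vals <- array(rep(base, each = 6), dim = c(2, 3, g$n))
  cube <- hyperspectral_cube(vals, g)
  spec <- default_nbi_spec()
  out <- render_nbi(cube, spec)
  expect_equal(max(apply(out, 3, function(m) diff(range(m)))), 0)

  # zeroing reflectance inside the 415 nm passband changes only channels fed
  # by the 415 column of the display map (G and B by default)
  vals415 <- vals
  in_band <- abs(g$wavelengths - 415) <= 30
  vals415[, , in_band] <- 0
  out415 <- render_nbi(hyperspectral_cube(vals415, g), spec)
  expect_identical(out415[, , 1], out[, , 1])       # red = 540 band only
  expect_true(all(out415[, , 2] < out[, , 2]))
  expect_true(all(out415[, , 3] < out[, , 3]))
})

test_that("narrow-band display colours are linear in reflectance before clamping", {
  g <- master_grid()
  set.seed(50)
  refl <- matrix(runif(5 * g$n, 0, 0.6), 5)
  spec <- default_nbi_spec(gamma_out = FALSE)
  resp <- function(m) {
    r <- savelight:::band_responses(m, g, spec) %*% t(spec$display_map)
    r  # all responses in [0,1): clamp is inactive
  }
  for (alpha in c(0.2, 0.7)) {
    expect_equal(resp(alpha * refl), alpha * resp(refl), tolerance = 1e-12)
  }
})

test_that("fast simulated annealing honours its contracts", {
  obj <- function(x) (x - 3)^2
  r0 <- fsa_minimize(obj, 0.5, fsa_config(max_iterations = 0, seed = 1))
  expect_equal(r0$par, 0.5)
  expect_equal(r0$value, obj(0.5))

  r <- fsa_minimize(obj, 0, fsa_config(max_iterations = 1e4, seed = 1))
  expect_lt(abs(r$par - 3), 1e-3)
  r2 <- fsa_minimize(obj, 0, fsa_config(max_iterations = 1e4, seed = 1))
  expect_identical(r$trace, r2$trace)
  expect_identical(r$par, r2$par)
  # best-so-far trace is monotone non-increasing
  expect_true(all(diff(r$trace) <= 0 + 1e-15))
  expect_error(fsa_minimize(function(x) NaN, 0, fsa_config()), "finite")
})

test_that("annealing leaves the global RNG stream untouched", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(fsa_minimize(function(x) sum(x^2), c(1, 1),
                         fsa_config(max_iterations = 50, seed = 7)))
  expect_identical(runif(1), a)
})

test_that("colour matching recovers a perturbed display map", {
  chart <- fixture_chart()
  spec0 <- default_nbi_spec()
  dm <- spec0$display_map
  set.seed(61)
  dm_true <- dm + matrix(rnorm(length(dm), sd = 0.15), 3)
  truth <- nbi_band_spec(spec0$bands, dm_true)
  resp <- savelight:::band_responses(chart$spectra, chart$grid, truth)
  rgb <- pmin(pmax(resp %*% t(dm_true), 0), 1)
  target_lab <- xyz_to_lab(linear_srgb_to_xyz(rgb))

  m <- match_nbi_colors(chart$spectra, target_lab, chart$grid, spec0)
  expect_lt(m$residual, m$initial_residual)
  expect_lt(m$residual, 0.5)
  expect_true(all(diff(m$trace) <= 1e-15))

  # degenerate case: targets already achieved
  m0 <- match_nbi_colors(chart$spectra, target_lab, chart$grid, m$spec)
  expect_lte(m0$residual, m$residual + 1e-9)
})

test_that("narrow-band specs survive a JSON round trip", {
  spec <- default_nbi_spec(include_650 = TRUE)
  spec$display_map[1, 3] <- 0.123456789012345
  path <- withr::local_tempfile(fileext = ".json")
  write_nbi_spec(spec, path)
  expect_identical(read_nbi_spec(path), spec)
})
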