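test_that("wavelength grids have the right sample counts and reject bad inputs", {
  expect_equal(spectral_grid(400, 700, 10)$n, 31L)
  expect_equal(spectral_grid(400, 780, 5)$n, 77L)
  expect_equal(master_grid()$wavelengths[1:3], c(400, 405, 410))
  expect_error(spectral_grid(700, 400, 10), "start must be < stop")
  expect_error(spectral_grid(400, 700, -5), "positive")
  expect_error(spectral_grid(400, 700, 7), "divide")
})

test_that("spectrum resampling interpolates linearly and extends at endpoints", {
  g2 <- spectral_grid(400, 500, 100)
  s <- spectrum(c(0, 1), g2)
  expect_identical(resample_spectrum(s, g2)$values, c(0, 1))
  mid <- resample_spectrum(s, spectral_grid(400, 500, 50))
  expect_equal(mid$values[2], 0.5)
  expect_false(mid$extended)

  src <- spectral_grid(420, 700, 5)
  sp <- spectrum(seq(0.3, 0.8, length.out = src$n), src)
  out <- resample_spectrum(sp, spectral_grid(400, 700, 5))
  expect_true(out$extended)
  expect_equal(out$values[1:4], rep(0.3, 4))  # 400-415 take the 420 value
  expect_error(spectrum(numeric(0), g2), "length")
})

test_that("sRGB transfer decodes published values and round-trips all 256 codes", {
  expect_equal(linearize_srgb(0), 0)
  expect_equal(linearize_srgb(255), 1)
  expect_equal(linearize_srgb(128), 0.21586, tolerance = 1e-4)
  codes <- 0:255
  expect_identical(encode_srgb(linearize_srgb(codes)), as.numeric(codes))
  expect_error(linearize_srgb(256), "\\[0, 255\\]")
  expect_error(linearize_srgb(-1), "\\[0, 255\\]")
  # power-law mode is its own inverse too
  expect_equal(encode_srgb(linearize_srgb(codes, "power"), "power"),
               as.numeric(codes))
})

test_that("tristimulus integration is normalised and linear in reflectance", {
  g <- master_grid()
  cmfs <- cie_cmfs(g)
  ones <- spectrum(rep(1, g$n), g)
  for (illum in list(illuminant_d65(g), illuminant_equal_energy(g))) {
    expect_equal(unname(reflectance_to_xyz(ones, illum, cmfs)["Y"]), 100,
                 tolerance = 1e-9)
  }
  d65 <- illuminant_d65(g)
  expect_equal(unname(reflectance_to_xyz(spectrum(rep(0, g$n), g), d65, cmfs)),
               c(0, 0, 0))
  half <- reflectance_to_xyz(spectrum(rep(0.5, g$n), g), d65, cmfs)
  full <- reflectance_to_xyz(ones, d65, cmfs)
  expect_equal(half, full / 2, tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:5) {
    r <- runif(g$n)
    alpha <- runif(1)
    x1 <- reflectance_to_xyz(spectrum(alpha * r, g), d65, cmfs)
    x2 <- alpha * reflectance_to_xyz(spectrum(r, g), d65, cmfs)
    expect_equal(x1, x2, tolerance = 1e-12)
  }

  g2 <- spectral_grid(400, 700, 10)
  expect_error(reflectance_to_xyz(ones, illuminant_d65(g2), cmfs), "grids differ")
  expect_error(
    reflectance_to_xyz(ones, spectrum(rep(0, g$n), g), cmfs),
    "undefined")
})

test_that("CIELAB transform hits its fixed points", {
  w <- d65_white()
  expect_equal(unname(xyz_to_lab(w, w)), c(100, 0, 0), tolerance = 1e-9)
  expect_equal(unname(xyz_to_lab(c(0, 0, 0), w)[1]), 0)
  grey <- w * 0.1842
  expect_equal(unname(xyz_to_lab(grey, w)[1]), 50, tolerance = 0.01)
  expect_error(xyz_to_lab(w, c(0, 100, 100)), "positive")
  # inverse transform round-trips random colours
  set.seed(3)
  lab <- cbind(runif(20, 0, 100), runif(20, -60, 60), runif(20, -60, 60))
  expect_equal(xyz_to_lab(lab_to_xyz(lab, w), w), lab,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("CIEDE2000 matches the published verification pairs to 1e-4", {
  tab <- read.csv(system.file("extdata", "ciede2000_pairs.csv",
                              package = "savelight"))
  expect_gte(nrow(tab), 30)
  got <- ciede2000(as.matrix(tab[, c("L1", "a1", "b1")]),
                   as.matrix(tab[, c("L2", "a2", "b2")]))
  expect_equal(got, tab$de00, tolerance = 1e-4, ignore_attr = TRUE)
  expect_lt(max(abs(got - tab$de00)), 1e-4)
})

test_that("CIEDE2000 is symmetric, non-negative, zero only at identity", {
  set.seed(7)
  lab1 <- cbind(runif(50, 0, 100), runif(50, -80, 80), runif(50, -80, 80))
  lab2 <- cbind(runif(50, 0, 100), runif(50, -80, 80), runif(50, -80, 80))
  d12 <- ciede2000(lab1, lab2)
  expect_true(all(d12 >= 0))
  expect_equal(d12, ciede2000(lab2, lab1), tolerance = 1e-12)
  expect_identical(ciede2000(lab1, lab1), rep(0, 50))
  expect_true(all(d12 > 0))
})
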