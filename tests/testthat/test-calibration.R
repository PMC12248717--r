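test_that("dark-current subtraction floors at zero", {
  expect_identical(subtract_dark(c(10, 100, 200), 0), c(10, 100, 200))
  expect_identical(subtract_dark(10, 25), 0)
  expect_identical(subtract_dark(100, 20), 80)
  m <- matrix(c(10, 100, 5, 30, 40, 50), 2, byrow = TRUE)
  expect_identical(subtract_dark(m, c(20, 20, 20)),
                   matrix(c(0, 80, 0, 10, 20, 30), 2, byrow = TRUE))
  expect_error(subtract_dark(10, -1), "non-negative")
})

test_that("variable expansion enumerates all monomials up to the degree", {
  v1 <- expand_variables(c(0.2, 0.5, 0.8), degree = 1)
  expect_identical(colnames(v1), c("1", "r", "g", "b"))
  expect_equal(as.numeric(v1), c(1, 0.2, 0.5, 0.8))

  # brute-force count of monomials i+j+k <= 3 over three variables
  combos <- expand.grid(i = 0:3, j = 0:3, k = 0:3)
  n_expected <- sum(rowSums(combos) <= 3)
  v3 <- expand_variables(matrix(runif(9), 3), degree = 3)
  expect_equal(ncol(v3), n_expected)
  expect_equal(ncol(v3), 20)

  z <- expand_variables(c(0, 0, 0), degree = 3)
  expect_equal(as.numeric(z), c(1, rep(0, 19)))
  expect_error(expand_variables(c(1, 2, 3), degree = 4), "degree")

  # every column really is the labelled monomial
  x <- c(0.3, 0.7, 0.9)
  v <- expand_variables(x, degree = 3)
  expect_equal(unname(v[1, "rgb"]), prod(x))
  expect_equal(unname(v[1, "r2g"]), x[1]^2 * x[2])
  expect_equal(unname(v[1, "b3"]), x[3]^3)
})

test_that("correction-matrix fit recovers a known generator", {
  set.seed(21)
  lin <- matrix(runif(72), 24, 3)
  V <- expand_variables(lin, degree = 3)
  C_star <- matrix(rnorm(60), 3, 20)
  xyz <- V %*% t(C_star)
  C_hat <- fit_correction_matrix(xyz, V)
  expect_lt(max(abs(unclass(C_hat) - C_star)), 1e-8)
  expect_equal(apply_correction(C_hat, V), xyz,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(fit_correction_matrix(xyz, V * 0), "zero")
  expect_error(fit_correction_matrix(xyz[1:10, ], V), "mismatch")
})

test_that("rank-deficient fits agree with a ridge normal-equations oracle", {
  set.seed(22)
  Vd <- matrix(rnorm(12 * 20), 12, 20)
  V <- Vd[c(1:12, 1:6), ]              # duplicated patches: rank 12 < 20 terms
  xyz <- V %*% matrix(rnorm(60), 20, 3)  # consistent underdetermined system
  C_hat <- fit_correction_matrix(xyz, V)
  # oracle: ridge-regularised dual normal equations on the distinct rows;
  # duplicate rows of a consistent system do not move the minimum-norm
  # solution, and the dual form keeps the ridge limit numerically exact
  eps <- 1e-10
  alpha <- solve(Vd %*% t(Vd) + eps * diag(nrow(Vd)), xyz[1:12, ])
  C_oracle <- t(t(Vd) %*% alpha)
  expect_lt(max(abs(unclass(C_hat) - C_oracle)), 1e-8)
})

test_that("apply_correction enforces matching term labels", {
  lin <- matrix(runif(9), 3)
  V3 <- expand_variables(lin, degree = 3)
  V1 <- expand_variables(lin, degree = 1)
  C <- fit_correction_matrix(matrix(runif(9), 3), V1)
  expect_error(apply_correction(C, V3), "term labels")
  # selector rows return the linear channels unchanged
  Csel <- unclass(C) * 0
  Csel[1, "r"] <- 1
  Csel[2, "g"] <- 1
  Csel[3, "b"] <- 1
  attr(Csel, "term_labels") <- attr(C, "term_labels")
  class(Csel) <- class(C)
  expect_equal(apply_correction(Csel, V1), lin, ignore_attr = TRUE)
})

test_that("PCA basis is orthonormal, ordered, and complete when all components kept", {
  chart <- fixture_chart()
  n <- nrow(chart$spectra)
  full <- pca_reflectance(chart$spectra, n_components = n - 1)
  G <- t(full$components) %*% full$components
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  evf <- full$explained_variance_fraction
  expect_true(all(diff(evf) <= 1e-12))
  expect_lte(sum(evf), 1 + 1e-9)
  recon <- full$scores %*% t(full$components)
  recon <- sweep(recon, 2, full$mean_spectrum, "+")
  expect_lt(max(abs(recon - chart$spectra)), 1e-10)
  expect_error(pca_reflectance(chart$spectra[1, , drop = FALSE]), "at least 2")
})

test_that("PCA finds the exact dimension of a constructed affine family", {
  g <- spectral_grid(400, 700, 10)
  wl <- g$wavelengths
  b1 <- sin(wl / 40)
  b2 <- exp(-(wl - 550)^2 / 5000)
  set.seed(5)
  coef <- matrix(rnorm(30), 15, 2)
  spectra <- 0.5 + coef %*% rbind(b1, b2) * 0.1
  p <- pca_reflectance(spectra, n_components = 4)
  expect_equal(sum(p$explained_variance_fraction[1:2]), 1, tolerance = 1e-9)
  # component sign convention: largest-magnitude coefficient positive
  for (j in 1:2) {
    expect_gt(p$components[which.max(abs(p$components[, j])), j], 0)
  }
})

test_that("spectral-transform fit respects row weighting and degenerate scores", {
  set.seed(31)
  xyz <- matrix(runif(30, 0, 100), 10, 3)
  vc <- expand_variables(xyz / 100, degree = 2, vars = c("x", "y", "z"))
  scores <- matrix(rnorm(40), 10, 4)
  M1 <- fit_spectral_transform(scores, vc)
  # duplicating every row leaves the least-squares solution unchanged
  M2 <- fit_spectral_transform(rbind(scores, scores), rbind(vc, vc))
  expect_equal(unclass(M1), unclass(M2), tolerance = 1e-8, ignore_attr = TRUE)
  M0 <- fit_spectral_transform(scores * 0, vc)
  expect_equal(max(abs(unclass(M0))), 0)
  expect_error(fit_spectral_transform(scores[1:3, ], vc), "mismatch")
})

test_that("similarity index matches hand arithmetic", {
  expect_equal(similarity_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(similarity_index(c(0, 0, 0), c(1, 2, 3)), 0)
  pred <- c(1, 2, 2)
  meas <- c(1, 2, 4)
  # by hand: rmse = sqrt(4/3); rms(meas) = sqrt(21/3)
  expect_equal(similarity_index(pred, meas), 1 - sqrt(4 / 3) / sqrt(21 / 3))
  expect_error(similarity_index(numeric(0), numeric(0)), "non-empty")
})

test_that("noiseless calibration reproduces the chart exactly", {
  chart <- fixture_chart()
  fit <- fixture_ideal_fit()
  cap <- fixture_ideal_capture()
  rep <- calibration_report(fit, chart, cap)
  expect_equal(nrow(rep$patches), 24)
  expect_lt(max(rep$patches$spectral_rmse), 1e-6)
  expect_lt(max(rep$patches$de00_post), 1e-6)
  expect_gt(rep$mean_de00_pre, rep$mean_de00_post)
})

test_that("calibration reduces colour error on a noisy realistic camera", {
  chart <- fixture_chart()
  cam <- make_camera_model("realistic", seed = 123)
  cap <- simulate_capture(chart, cam)
  fit <- save_calibrate(cap, chart)
  s <- summary(fit)
  expect_lt(s$mean_de00_post, s$mean_de00_pre)
  expect_lt(s$mean_spectral_rmse, 0.05)
})

test_that("calibration bundles survive a JSON round trip bit-exactly", {
  chart <- fixture_chart()
  cam <- make_camera_model("realistic", seed = 9)
  fit <- save_calibrate(simulate_capture(chart, cam), chart)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, path)
  fit2 <- read_calibration(path)
  keep <- setdiff(names(fit), "provenance")
  expect_identical(fit[keep], fit2[keep])
})
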