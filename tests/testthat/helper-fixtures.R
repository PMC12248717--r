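# Shared fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fixture_chart <- function() {
  if (is.null(.fix$chart)) .fix$chart <- make_reference_chart()
  .fix$chart
}

fixture_ideal_fit <- function() {
  if (is.null(.fix$ideal_fit)) {
    chart <- fixture_chart()
    cam <- make_camera_model("ideal")
    cap <- simulate_capture(chart, cam)
    .fix$ideal_capture <- cap
    .fix$ideal_fit <- save_calibrate(cap, chart, gamma_mode = "linear")
  }
  .fix$ideal_fit
}

fixture_ideal_capture <- function() {
  fixture_ideal_fit()
  .fix$ideal_capture
}

# deterministic 32 x 32 image pair used by the SSIM cross-check
fixture_image_pair <- function() {
  i <- matrix(0:31, 32, 32)
  j <- t(i)
  a <- (sin(i / 3) + cos(j / 5) + 2) / 4
  b <- pmin(pmax(a + 0.08 * sin((i + 1) * (j + 1) / 40), 0), 1)
  list(a = a, b = b)
}
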