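test_that("classification metrics match hand evaluation of the toy matrix", {
  cm <- confusion_matrix(matrix(c(8, 2, 1, 9), 2, byrow = TRUE),
                         labels = c("neg", "pos"))
  rep <- classification_metrics(cm)
  expect_equal(rep$per_class$precision[1], 88.89, tolerance = 0.01)
  expect_equal(rep$per_class$recall[1], 80.00, tolerance = 0.01)
  expect_equal(rep$per_class$f1[1], 84.21, tolerance = 0.01)
  expect_equal(rep$accuracy, 85)

  perfect <- classification_metrics(confusion_matrix(diag(c(5, 3, 7))))
  expect_true(all(perfect$per_class$precision == 100))
  expect_true(all(perfect$per_class$f1 == 100))
  expect_equal(perfect$accuracy, 100)
})

test_that("permuting class order permutes rows but keeps accuracy", {
  set.seed(70)
  m <- matrix(sample(0:20, 16, replace = TRUE), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  r1 <- classification_metrics(confusion_matrix(m))
  perm <- c(3, 1, 4, 2)
  r2 <- classification_metrics(confusion_matrix(m[perm, perm]))
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(r2$per_class[order(perm), -1], r1$per_class[, -1],
               ignore_attr = TRUE)
})

test_that("zero-denominator classes report 0 with an undefined flag", {
  cm <- confusion_matrix(matrix(c(5, 0, 3, 0), 2, byrow = TRUE))
  rep <- classification_metrics(cm)
  expect_equal(rep$per_class$precision[2], 0)
  expect_true(rep$per_class$precision_undefined[2])  # nothing predicted as class 2
  expect_false(rep$per_class$recall_undefined[2])
})

test_that("precision/recall/F1 identities hold against brute-force recomputation", {
  set.seed(71)
  for (rep_i in 1:100) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 4), k)
    got <- classification_metrics(confusion_matrix(m))$per_class
    for (i in seq_len(k)) {
      tp <- m[i, i]
      fp <- sum(m[-i, i])
      fn <- sum(m[i, -i])
      P <- if (tp + fp > 0) tp / (tp + fp) * 100 else 0
      R <- if (tp + fn > 0) tp / (tp + fn) * 100 else 0
      expect_equal(got$precision[i], P)
      expect_equal(got$recall[i], R)
      F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
      expect_equal(got$f1[i], F1)
      expect_true((got$f1[i] == 0) == (P == 0 || R == 0))
    }
  }
})

test_that("average precision matches the step-curve enumeration", {
  expect_equal(average_precision(c(9, 8, 7, 1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(4, 3, 2, 1), c(0, 1, 0, 0)), 0.5)
  # invariance under strictly monotone score transforms
  set.seed(72)
  s <- runif(10)
  l <- rbinom(10, 1, 0.4)
  if (!any(l)) l[1] <- 1
  expect_equal(average_precision(exp(5 * s), l), average_precision(s, l))

  # exhaustive check on all label arrangements of <= 6 items against an
  # independent step-curve integration
  step_curve_ap <- function(rel) {
    npos <- sum(rel)
    tp <- 0
    area <- 0
    recall_prev <- 0
    for (k in seq_along(rel)) {
      tp <- tp + rel[k]
      recall <- tp / npos
      area <- area + (recall - recall_prev) * (tp / k)
      recall_prev <- recall
    }
    area
  }
  for (n in 2:6) {
    for (mask in 1:(2^n - 1)) {
      rel <- as.integer(intToBits(mask))[1:n]
      expect_equal(average_precision(seq(n, 1), rel), step_curve_ap(rel))
    }
  }
  expect_error(average_precision(1:4, c(0, 0, 0, 0)), "positive")
})

test_that("mean average precision averages one-vs-rest APs", {
  scores <- cbind(a = c(0.9, 0.2, 0.7, 0.1), b = c(0.1, 0.8, 0.3, 0.9))
  labels <- cbind(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1))
  m <- mean_average_precision(scores, labels)
  expect_equal(unname(m$per_class), c(1, 1))
  expect_equal(m$mAP, 1)
})

test_that("image-quality report hits its analytic anchors", {
  a <- matrix(0.5, 2, 2)
  q0 <- image_quality_report(a, a)
  expect_equal(q0$rmse, 0)
  expect_identical(q0$psnr_db, Inf)
  expect_equal(q0$ssim, 1)
  expect_equal(q0$entropy_diff_percent, 0)

  b <- a
  b[1, 1] <- 1
  q <- image_quality_report(a, b)
  expect_equal(q$rmse, 0.25)
  expect_equal(q$psnr_db, 12.04, tolerance = 0.01)

  expect_error(image_quality_report(matrix(0, 2, 2), matrix(0, 3, 3)),
               "identical dimensions")
})

test_that("PSNR and RMSE satisfy their functional relation", {
  set.seed(73)
  for (i in 1:20) {
    x <- matrix(runif(64), 8)
    y <- matrix(runif(64), 8)
    q <- image_quality_report(x, y)
    expect_equal(q$psnr_db, 20 * log10(1 / q$rmse), tolerance = 1e-9)
  }
})

test_that("SSIM is symmetric and matches an independent implementation", {
  pair <- fixture_image_pair()
  expect_equal(ssim(pair$a, pair$b), ssim(pair$b, pair$a), tolerance = 1e-12)
  # frozen from scikit-image structural_similarity (gaussian_weights = TRUE,
  # sigma = 1.5, use_sample_covariance = FALSE, data_range = 1)
  expect_equal(ssim(pair$a, pair$b), 0.8898012900, tolerance = 1e-7)
  expect_equal(sqrt(mean((pair$a - pair$b)^2)), 0.0558621884, tolerance = 1e-9)
  set.seed(74)
  n <- matrix(runif(1024), 32)
  expect_lt(ssim(pair$a, n), ssim(pair$a, pair$a))
})
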