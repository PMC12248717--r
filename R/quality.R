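#' Confusion matrix
#'
#' Square contingency table of true class (rows) against predicted class
#' (columns). Either pass a count matrix directly, or truth/predicted label
#' vectors.
#'
#' @param x square numeric matrix of non-negative integer counts, or a vector
#'   of true labels.
#' @param predicted predicted labels (when `x` is a label vector).
#' @param labels optional ordered class labels.
#' @return matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(x, predicted = NULL, labels = NULL) {
  if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) stop("confusion matrix must be square")
    if (any(x < 0) || any(abs(x - round(x)) > 1e-9)) {
      stop("counts must be non-negative integers")
    }
    if (!is.null(labels)) rownames(x) <- colnames(x) <- labels
    if (is.null(rownames(x))) {
      rownames(x) <- colnames(x) <- paste0("class", seq_len(nrow(x)))
    }
    return(structure(x, class = c("confusion_matrix", "matrix")))
  }
  if (is.null(labels)) labels <- sort(unique(c(as.character(x),
                                               as.character(predicted))))
  tab <- table(factor(x, levels = labels), factor(predicted, levels = labels))
  m <- matrix(as.numeric(tab), nrow = length(labels),
              dimnames = list(labels, labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Read a confusion matrix from CSV (first column = true-class labels)
#' @param path CSV path.
#' @return a [confusion_matrix()].
#' @export
read_confusion_csv <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  confusion_matrix(as.matrix(tab), labels = rownames(tab))
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision, recall and F1 on the percent scale
#' (`P = TP/(TP+FP) x 100`, `R = TP/(TP+FN) x 100`,
#' `F1 = 2PR/(P+R)`), and overall accuracy (trace over total). Classes with
#' a zero denominator get the metric reported as 0 with an `undefined` flag
#' rather than an error, so batch evaluation survives empty classes.
#'
#' @param cm a [confusion_matrix()].
#' @return list of class `metrics_report`: `per_class` data.frame
#'   (precision/recall/f1 in percent plus undefined flags), `accuracy`
#'   (percent), `confusion`.
#' @export
classification_metrics <- function(cm) {
  cm <- confusion_matrix(unclass(as.matrix(cm)))
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_pct <- function(num, den) ifelse(den > 0, num / den * 100, 0)
  precision <- safe_pct(tp, tp + fp)
  recall <- safe_pct(tp, tp + fn)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(
    class = rownames(cm),
    precision = precision, recall = recall, f1 = f1,
    precision_undefined = tp + fp == 0,
    recall_undefined = tp + fn == 0,
    row.names = NULL)
  total <- sum(cm)
  structure(list(per_class = per_class,
                 accuracy = if (total > 0) sum(tp) / total * 100 else 0,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(sprintf("Accuracy: %.*f%%\n", digits, x$accuracy))
  tab <- x$per_class
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab[, c("class", "precision", "recall", "f1")], row.names = FALSE)
  if (!is.null(x$mAP)) cat(sprintf("mAP: %.4f\n", x$mAP))
  invisible(x)
}

#' Average precision of a ranking
#'
#' Area under the precision-recall step curve with right-continuous
#' interpolation: items are ranked by decreasing score (ties kept in input
#' order) and the area is the sum of precision-at-rank over the positive
#' items divided by the number of positives.
#'
#' @param scores numeric relevance scores, higher = ranked earlier.
#' @param labels binary relevance (logical or 0/1); at least one positive.
#' @return AP in \[0, 1\].
#' @examples
#' average_precision(c(4, 3, 2, 1), c(0, 1, 0, 0))  # 0.5
#' @export
average_precision <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (!any(labels)) stop("average precision needs at least one positive label")
  ord <- order(-scores, seq_along(scores))
  rel <- labels[ord]
  prec <- cumsum(rel) / seq_along(rel)
  sum(prec[rel]) / sum(rel)
}

#' Mean average precision over classes
#'
#' @param scores n x k matrix (or data.frame) of per-class scores.
#' @param labels n x k binary matrix of one-vs-rest relevance.
#' @return list with `per_class` APs and `mAP` (their mean).
#' @export
mean_average_precision <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.matrix(labels)
  stopifnot(all(dim(scores) == dim(labels)))
  ap <- vapply(seq_len(ncol(scores)), function(j) {
    average_precision(scores[, j], labels[, j])
  }, numeric(1))
  names(ap) <- colnames(scores)
  list(per_class = ap, mAP = mean(ap))
}

to_unit_intensity <- function(img) {
  a <- as.array(img) * 1.0
  if (max(a) > 1.5) a <- a / 255
  a
}

to_grey <- function(a) {
  if (length(dim(a)) == 3) {
    0.2989 * a[, , 1] + 0.5870 * a[, , 2] + 0.1140 * a[, , 3]
  } else a
}

gaussian_kernel_1d <- function(sigma = 1.5, radius = 5) {
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian filtering with replicate (nearest) edge padding
gaussian_filter2 <- function(m, kernel) {
  r <- (length(kernel) - 1) / 2
  n1 <- nrow(m)
  n2 <- ncol(m)
  pad_idx <- function(n) c(rep(1, r), seq_len(n), rep(n, r))
  p <- m[pad_idx(n1), , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * p[k:(k + n1 - 1), , drop = FALSE]
  }
  p <- out[, pad_idx(n2), drop = FALSE]
  out <- matrix(0, n1, n2)
  for (k in seq_along(kernel)) {
    out <- out + kernel[k] * p[, k:(k + n2 - 1), drop = FALSE]
  }
  out
}

#' Structural similarity index (SSIM)
#'
#' Mean SSIM over an 11 x 11 Gaussian window (sigma 1.5) with stabilising
#' constants K1 = 0.01, K2 = 0.03 on a unit data range; the half-window
#' border is cropped before averaging, per standard practice. Colour images
#' are converted to luma first.
#'
#' @param a,b images of equal size (matrices or H x W x 3 arrays; 8-bit
#'   codes or unit intensities).
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b) {
  ga <- to_grey(to_unit_intensity(a))
  gb <- to_grey(to_unit_intensity(b))
  if (!all(dim(ga) == dim(gb))) stop("images must have identical dimensions")
  kern <- gaussian_kernel_1d(1.5, 5)
  C1 <- 0.01^2
  C2 <- 0.03^2
  mu1 <- gaussian_filter2(ga, kern)
  mu2 <- gaussian_filter2(gb, kern)
  s11 <- gaussian_filter2(ga * ga, kern) - mu1^2
  s22 <- gaussian_filter2(gb * gb, kern) - mu2^2
  s12 <- gaussian_filter2(ga * gb, kern) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  r <- 5
  if (nrow(map) <= 2 * r || ncol(map) <= 2 * r) return(mean(map))
  mean(map[(r + 1):(nrow(map) - r), (r + 1):(ncol(map) - r)])
}

shannon_entropy_8bit <- function(g) {
  codes <- pmin(pmax(round(g * 255), 0), 255)
  p <- tabulate(codes + 1, nbins = 256)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Image-quality comparison report
#'
#' RMSE between unit intensities, PSNR (`20 log10(1/RMSE)` dB, `Inf` for
#' identical images), mean [ssim()], and relative greyscale Shannon-entropy
#' difference in percent (`|H(a) - H(b)| / H(b) x 100` with 256-bin
#' histograms; a package definition).
#'
#' @param a,b images of equal dimensions and channel count.
#' @return list of class `quality_report`: `rmse`, `psnr_db`, `ssim`,
#'   `entropy_diff_percent`.
#' @export
image_quality_report <- function(a, b) {
  ua <- to_unit_intensity(a)
  ub <- to_unit_intensity(b)
  if (!all(dim(ua) == dim(ub))) {
    stop("images must have identical dimensions and channel counts")
  }
  rmse <- sqrt(mean((ua - ub)^2))
  psnr <- if (rmse == 0) Inf else 20 * log10(1 / rmse)
  ha <- shannon_entropy_8bit(to_grey(ua))
  hb <- shannon_entropy_8bit(to_grey(ub))
  ent <- if (hb == 0) {
    if (ha == 0) 0 else Inf
  } else abs(ha - hb) / hb * 100
  structure(list(rmse = rmse, psnr_db = psnr, ssim = ssim(ua, ub),
                 entropy_diff_percent = ent),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("RMSE %.5f | PSNR %s dB | SSIM %.4f | entropy diff %.3f%%\n",
              x$rmse,
              if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.2f", x$psnr_db),
              x$ssim, x$entropy_diff_percent))
  invisible(x)
}

#' Michelson contrast between two pixel populations
#'
#' `(I_max - I_min) / (I_max + I_min)` computed on the mean luma of the two
#' populations; used to compare vessel visibility between white-light and
#' narrow-band renders.
#'
#' @param image matrix or H x W x 3 array.
#' @param mask logical matrix selecting the first population (e.g. vessels);
#'   its complement is the second.
#' @return contrast in \[0, 1\].
#' @export
michelson_contrast <- function(image, mask) {
  g <- to_grey(to_unit_intensity(image))
  if (!all(dim(g) == dim(mask))) stop("mask must match image dimensions")
  i1 <- mean(g[mask])
  i2 <- mean(g[!mask])
  hi <- max(i1, i2)
  lo <- min(i1, i2)
  if (hi + lo == 0) return(0)
  (hi - lo) / (hi + lo)
}
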