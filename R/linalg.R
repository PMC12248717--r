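#' Moore-Penrose pseudo-inverse with singular-value cutoff
#'
#' SVD-based pseudo-inverse; singular values below `rcond` times the largest
#' are treated as zero, so rank-deficient systems get the minimum-norm
#' least-squares solution reproducibly.
#'
#' @param A numeric matrix.
#' @param rcond relative singular-value cutoff (default 1e-10).
#' @return the pseudo-inverse of `A`.
#' @export
pinv <- function(A, rcond = 1e-10) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("matrix must be finite")
  s <- svd(A)
  keep <- s$d > rcond * max(s$d, 0)
  if (!any(keep)) stop("matrix is numerically zero; pseudo-inverse is degenerate")
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
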