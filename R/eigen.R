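#' Eigen-analysis of a site-score matrix
#'
#' Eigendecomposition of a symmetric matrix with eigenvalues sorted in
#' descending order (rank 0 = largest). The requested eigenvector is
#' returned with unit Euclidean norm and the sign convention that its
#' largest-magnitude component is positive (the overall sign of an
#' eigenvector is arbitrary; downstream metrics use absolute values).
#'
#' @param mat symmetric matrix.
#' @param which `"largest"`, `"smallest"`, or a 0-based integer rank.
#' @param tol symmetry tolerance relative to the largest absolute entry.
#' @return list with `value`, `vector` (unit norm), `rank` (0-based) and
#'   `sign_flipped` (whether the convention flipped the raw eigenvector).
#' @export
eigen_analysis <- function(mat, which = "largest", tol = 1e-8) {
  mat <- as.matrix(unclass_matrix(mat))
  scale <- max(abs(mat), 1e-300)
  if (max(abs(mat - t(mat))) > tol * scale)
    stop("matrix is not symmetric within tolerance")
  e <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  L <- length(e$values)
  rank <- if (identical(which, "largest")) 0L
          else if (identical(which, "smallest")) L - 1L
          else as.integer(which)
  if (rank < 0 || rank >= L) stop("requested eigen rank out of range")
  v <- e$vectors[, rank + 1L]
  v <- v / sqrt(sum(v^2))
  flipped <- v[which.max(abs(v))] < 0
  if (flipped) v <- -v
  list(value = e$values[rank + 1L], vector = v, rank = rank,
       sign_flipped = flipped)
}

#' Sorted eigenvalue spectrum
#'
#' @param mat symmetric matrix.
#' @return data.frame with columns `rank` (0 = largest) and `value`,
#'   eigenvalues in descending order.
#' @export
spectrum_table <- function(mat) {
  mat <- as.matrix(unclass_matrix(mat))
  vals <- eigen((mat + t(mat)) / 2, symmetric = TRUE, only.values = TRUE)$values
  data.frame(rank = seq_along(vals) - 1L, value = vals)
}

#' Count large-eigenvalue outliers of a spectrum
#'
#' Tukey-fence rule: an eigenvalue is a large-eigenvalue outlier if it
#' exceeds `Q3 + fence * IQR` of the full spectrum. The definition is a
#' pragmatic operationalization of "outlier" for automated checks and is
#' configurable.
#'
#' @param values numeric eigenvalues (any order).
#' @param fence multiplier on the interquartile range (default 3).
#' @return integer count.
#' @export
count_spectral_outliers <- function(values, fence = 3) {
  qs <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  sum(values > qs[2] + fence * (qs[2] - qs[1]))
}

#' Gap statistic for a rank-0 spectral outlier
#'
#' Tests whether the largest eigenvalue is an outlier: the gap between
#' rank 0 and rank 1 must exceed `factor` times the interquartile range of
#' the consecutive spacings among ranks 1..`n_ref`.
#'
#' @param values numeric eigenvalues (any order).
#' @param n_ref number of next-ranked eigenvalues whose spacings calibrate
#'   the bulk scale.
#' @param factor multiplier (default 3).
#' @return logical.
#' @export
has_rank0_outlier <- function(values, n_ref = 20, factor = 3) {
  v <- sort(values, decreasing = TRUE)
  gaps <- -diff(v[seq_len(min(n_ref + 1L, length(v)))])
  ref <- stats::IQR(gaps[-1L])
  gaps[1L] > factor * ref
}
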