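#' Recovery of the mutational-effect vector
#'
#' Normalized absolute-value scalar product between a site-score vector and
#' the ground-truth effect vector:
#' \deqn{\mathrm{Recovery} = \frac{\sum_i |v_i D_i|}{\sqrt{\sum_i v_i^2}
#'   \sqrt{\sum_i D_i^2}} \in [0, 1].}
#' Absolute values make the score invariant to per-component sign flips of
#' either vector (eigenvectors are defined up to sign) and to global
#' rescaling; 1 means perfect identification of effect magnitudes.
#'
#' @param v site vector (e.g. an eigenvector or conservation profile).
#' @param D effect vector (or numeric vector).
#' @return scalar in \[0, 1\].
#' @export
recovery <- function(v, D) {
  d <- effect_values(D)
  if (length(v) != length(d)) stop("vector lengths differ")
  nv <- sqrt(sum(v^2)); nd <- sqrt(sum(d^2))
  if (nv == 0 || nd == 0) stop("recovery undefined for a zero vector")
  sum(abs(v * d)) / (nv * nd)
}

#' Chance expectation of the recovery
#'
#' Closed-form mean recovery of the effect vector by an isotropic random
#' vector:
#' \deqn{\langle\mathrm{Recovery}\rangle \approx \sqrt{\frac{2}{\pi L}}\,
#'   \frac{\sum_i |D_i|}{\sqrt{\sum_i D_i^2}}.}
#'
#' @param D effect vector.
#' @return scalar null recovery.
#' @export
null_recovery <- function(D) {
  d <- effect_values(D)
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("null recovery undefined for a zero vector")
  sqrt(2 / (pi * length(d))) * sum(abs(d)) / nd
}

#' Symmetrized AUC for sector-site identification
#'
#' Ranks sites by `|scores|`, computes the ROC area under the curve for
#' discriminating sector from non-sector sites (midranks, i.e. trapezoidal
#' tie handling), and symmetrizes: \eqn{2|AUC - 0.5|}. The symmetrization
#' makes the score invariant to the arbitrary overall sign of eigenvectors
#' (a perfectly inverted ranking scores 1, like a perfect one).
#'
#' @param scores numeric site scores.
#' @param labels logical (or 0/1) sector membership, both classes present.
#' @return scalar in \[0, 1\].
#' @export
symmetrized_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("lengths differ")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(abs(scores))
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  2 * abs(auc - 0.5)
}

#' Block-diagonal approximation of a site-score matrix
#'
#' Reorders the sites so the sector comes first, then zeroes every entry
#' outside the sector x sector and non-sector x non-sector diagonal blocks.
#' The spectrum of the result is exactly the union of the two block spectra;
#' comparing it to the full spectrum shows how much of the spectral
#' structure is explained by the within-group couplings alone.
#'
#' @param mat L x L symmetric matrix.
#' @param sector_indices integer indices of sector sites (non-empty).
#' @return list: `matrix` (reordered, cross-blocks zeroed), `sector_block`,
#'   `other_block`, `order` (site permutation applied).
#' @export
block_diagonal_approximation <- function(mat, sector_indices) {
  mat <- as.matrix(unclass_matrix(mat))
  L <- nrow(mat)
  sector_indices <- as.integer(sector_indices)
  if (length(sector_indices) == 0) stop("sector must be non-empty")
  if (any(sector_indices < 1 | sector_indices > L)) stop("sector index out of range")
  other <- setdiff(seq_len(L), sector_indices)
  ord <- c(sector_indices, other)
  R <- mat[ord, ord]
  k <- length(sector_indices)
  if (k < L) {
    R[seq_len(k), (k + 1):L] <- 0
    R[(k + 1):L, seq_len(k)] <- 0
  }
  list(matrix = R,
       sector_block = R[seq_len(k), seq_len(k), drop = FALSE],
       other_block = if (k < L) R[(k + 1):L, (k + 1):L, drop = FALSE]
                     else matrix(0, 0, 0),
       order = ord)
}

#' Table of eigenvector components versus earliest mutation generation
#'
#' Long-format table linking each site's earliest-mutation generation `G`
#' (from a tracked phylogeny simulation) to the absolute value of its
#' component in one or more score vectors, for violin-plot style analyses of
#' how phylogeny loads onto inference methods.
#'
#' @param record `phylogeny_record` with `G` available.
#' @param score_vectors named list of numeric site vectors.
#' @param sector_indices optional sector site indices to annotate.
#' @return data.frame with columns `site`, `G`, `sector`, `method`,
#'   `component` (absolute value).
#' @export
g_component_table <- function(record, score_vectors, sector_indices = NULL) {
  if (is.null(record$G)) stop("record carries no G score")
  L <- length(record$G)
  stopifnot(is.list(score_vectors), length(names(score_vectors)) ==
              length(score_vectors))
  out <- lapply(names(score_vectors), function(nm) {
    v <- score_vectors[[nm]]
    if (length(v) != L) stop("score vector length must match the record")
    data.frame(site = seq_len(L), G = record$G,
               sector = seq_len(L) %in% sector_indices,
               method = nm, component = abs(v))
  })
  do.call(rbind, out)
}
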