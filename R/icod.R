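#' ICOD matrix for two-state data
#'
#' Inverse Covariance Off-Diagonal: the pseudocounted two-state covariance
#' matrix is inverted and its diagonal is set exactly to zero. Zeroing the
#' diagonal removes conservation signal, so the matrix focuses on
#' correlations. For equilibrium data under quadratic selection on an
#' additive trait, the off-diagonal entries approximate
#' \eqn{(1-\delta_{ij})\,\kappa D_i D_j}, so the top eigenvector recovers the
#' mutational-effect vector \eqn{D}.
#'
#' @param msa M x L spin matrix.
#' @param a pseudocount used for the covariance (default `1e-5`, the standard
#'   choice for synthetic two-state data; the inversion requires `a > 0` or a
#'   well-conditioned empirical covariance).
#' @param cond_threshold maximal acceptable reciprocal-condition-number
#'   deficit: an error is raised if `rcond(C) < 1/cond_threshold`.
#' @return L x L symmetric matrix, zero diagonal, attribute `method = "icod"`.
#' @export
icod_two_state <- function(msa, a = 1e-5, cond_threshold = 1e12) {
  C <- covariance_two_state(msa, a)
  inv <- invert_covariance(unclass_matrix(C), cond_threshold)
  diag(inv) <- 0
  structure(inv, method = "icod", a = a)
}

unclass_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

invert_covariance <- function(C, cond_threshold = 1e12) {
  C <- (C + t(C)) / 2
  rc <- rcond(C)
  if (!is.finite(rc) || rc < 1 / cond_threshold)
    stop(sprintf(paste("covariance matrix is ill-conditioned (rcond = %.2e);",
                       "increase the pseudocount"), rc))
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) solve(C) else chol2inv(ch)
}

#' ICOD matrix for 20-state (natural protein) data
#'
#' Reference-sequence-gauge ICOD: at each site the amino acid of the
#' reference sequence is dropped (19 retained states per site), the
#' pseudocounted (19L) x (19L) covariance is built and inverted, the
#' Frobenius norm of each 19 x 19 site-pair block is taken to compress it to
#' an L x L matrix, the diagonal is zeroed, and optionally the average
#' product correction is applied.
#'
#' @param msa M x L integer MSA with states `0..q-1` (use [encode_msa()] for
#'   character data); must be gap-free (impute first, see
#'   [impute_gaps_nearest()]).
#' @param ref_seq reference sequence: integer vector of length L in
#'   `0..q-1`, or a row index into `msa`.
#' @param a pseudocount (default 0.05, the standard choice for natural data).
#' @param q alphabet size (20 for proteins).
#' @param apply_apc apply [apc_correct()] to the final matrix.
#' @inheritParams icod_two_state
#' @return L x L symmetric matrix with zero diagonal.
#' @export
icod_natural <- function(msa, ref_seq, a = 0.05, q = 20, apply_apc = FALSE,
                         cond_threshold = 1e12) {
  msa <- as_state_matrix(msa, q)
  if (length(ref_seq) == 1L) ref_seq <- msa[ref_seq, ]
  if (length(ref_seq) != ncol(msa))
    stop("reference sequence length must match the MSA width")
  C <- covariance_full(msa, a = a, q = q, drop_states = as.integer(ref_seq))
  inv <- invert_covariance(unclass_matrix(C), cond_threshold)
  Fmat <- block_frobenius(inv, ncol(msa), q - 1L)
  diag(Fmat) <- 0
  if (apply_apc) Fmat <- apc_correct(Fmat)
  structure(Fmat, method = "icod_natural", a = a, apc = apply_apc)
}

#' Average product correction (APC)
#'
#' Subtracts from each off-diagonal entry the product of its row and column
#' off-diagonal means divided by the overall off-diagonal mean:
#' \eqn{M'_{ij} = M_{ij} - \bar M_i \bar M_j / \bar M}. This removes the
#' dominant rank-one background (e.g. phylogenetic or conservation-driven)
#' from a pairwise score matrix. The diagonal is ignored and returned as
#' zero.
#'
#' @param mat square symmetric matrix (diagonal ignored).
#' @return matrix of the same size, diagonal zero.
#' @export
apc_correct <- function(mat) {
  mat <- as.matrix(mat)
  L <- nrow(mat)
  if (L != ncol(mat)) stop("matrix must be square")
  off <- mat
  diag(off) <- NA
  row_mean <- rowMeans(off, na.rm = TRUE)
  all_mean <- mean(off, na.rm = TRUE)
  if (all_mean == 0) {
    warning("overall off-diagonal mean is zero; returning input unchanged")
    return(mat)
  }
  out <- mat - tcrossprod(row_mean) / all_mean
  diag(out) <- 0
  out
}
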