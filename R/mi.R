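#' Pairwise mutual information matrix
#'
#' \deqn{MI_{ij} = \sum_{\sigma,\sigma'} \tilde f_{ij}(\sigma,\sigma')
#'   \ln\frac{\tilde f_{ij}(\sigma,\sigma')}{\tilde f_i(\sigma)\tilde
#'   f_j(\sigma')}} computed from pseudocount-corrected frequencies (natural
#' logarithm; frequencies, not fitted probabilities, are used, so values
#' carry the finite-size bias common to all datasets of equal depth). The
#' diagonal (self-information, i.e. the per-site entropy) is set to zero by
#' default before any eigen-analysis, paralleling the ICOD convention.
#'
#' @param msa spin or integer-state MSA.
#' @param a pseudocount (default 0.001).
#' @param q number of states.
#' @param zero_diag set the diagonal to zero (default `TRUE`).
#' @return L x L symmetric non-negative (off-diagonal) matrix.
#' @export
mutual_information <- function(msa, a = 0.001, q = 2, zero_diag = TRUE) {
  ft <- pseudocount_frequencies(msa, a, q)
  L <- ft$L
  f1 <- as.vector(t(ft$f1))
  P <- ft$f2
  Q <- tcrossprod(f1)
  T <- matrix(0, nrow(P), ncol(P))
  pos <- P > 0
  T[pos] <- P[pos] * log(P[pos] / Q[pos])
  K <- matrix(0, L * q, L)
  K[cbind(seq_len(L * q), rep(seq_len(L), each = q))] <- 1
  MI <- crossprod(K, T) %*% K
  if (zero_diag) diag(MI) <- 0
  structure(MI, method = "mi", a = a)
}
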