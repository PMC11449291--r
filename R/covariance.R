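#' Two-state site covariance matrix
#'
#' For a spin MSA, the scalar covariance
#' \eqn{C_{ij} = \langle\sigma_i\sigma_j\rangle -
#' \langle\sigma_i\rangle\langle\sigma_j\rangle}. With a pseudocount
#' \eqn{a > 0} the pseudocount-corrected frequencies give
#' \deqn{C^{(a)}_{ij} = (1-a)\langle\sigma_i\sigma_j\rangle -
#'   (1-a)^2\langle\sigma_i\rangle\langle\sigma_j\rangle \quad (i \neq j),}
#' \deqn{C^{(a)}_{ii} = (1-a)^2(1-\langle\sigma_i\rangle^2) + a(2-a).}
#'
#' @param msa M x L spin matrix (-1/+1).
#' @param a pseudocount in \[0, 1\].
#' @return L x L symmetric matrix with attributes `method = "covariance"`
#'   and `a`.
#' @export
covariance_two_state <- function(msa, a = 0) {
  msa <- as.matrix(msa)
  check_spins(msa)
  if (a < 0 || a > 1) stop("pseudocount a must lie in [0, 1]")
  M <- nrow(msa)
  m <- colMeans(msa)
  S <- crossprod(msa) / M
  C <- (1 - a) * S - (1 - a)^2 * tcrossprod(m)
  diag(C) <- (1 - a)^2 * (1 - m^2) + a * (2 - a)
  structure(C, method = "covariance", a = a)
}

#' Full blocked covariance matrix of a q-state MSA
#'
#' The (q'L) x (q'L) covariance
#' \eqn{C_{ij}(\sigma,\sigma') = \tilde f_{ij}(\sigma,\sigma') -
#' \tilde f_i(\sigma)\tilde f_j(\sigma')} built from pseudocount-corrected
#' frequencies. Optionally one state per site is dropped (reference-sequence
#' gauge, q' = q - 1), as required before inversion: frequency normalization
#' makes one state per site redundant.
#'
#' @param msa integer-state (or spin) MSA.
#' @param a pseudocount.
#' @param q number of states.
#' @param drop_states optional integer vector (length L, values in `0..q-1`)
#'   of the state to drop at each site, e.g. the reference sequence.
#' @return square matrix with attribute `keep` (logical index into the full
#'   site-major (Lq) basis) and `q_prime`.
#' @export
covariance_full <- function(msa, a = 0, q = 2, drop_states = NULL) {
  ft <- pseudocount_frequencies(msa, a, q)
  f1 <- as.vector(t(ft$f1)) # site-major
  C <- ft$f2 - tcrossprod(f1)
  keep <- rep(TRUE, ft$L * q)
  if (!is.null(drop_states)) {
    if (length(drop_states) != ft$L)
      stop("drop_states must have one entry per site")
    if (any(drop_states < 0 | drop_states >= q))
      stop("drop_states must lie in 0..q-1")
    keep[(seq_len(ft$L) - 1L) * q + drop_states + 1L] <- FALSE
    C <- C[keep, keep]
  }
  structure(C, keep = keep, q_prime = if (is.null(drop_states)) q else q - 1L,
            L = ft$L, a = a)
}

# Frobenius norm of each q' x q' block of a (q'L) x (q'L) matrix -> L x L.
block_frobenius <- function(mat, L, q_prime) {
  K <- matrix(0, L * q_prime, L)
  K[cbind(seq_len(L * q_prime), rep(seq_len(L), each = q_prime))] <- 1
  sqrt(crossprod(K, (mat * mat)) %*% K)
}
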