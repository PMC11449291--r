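#' Statistical Coupling Analysis (SCA) matrix
#'
#' Combines covariance and conservation: each entry of the full blocked
#' covariance matrix is weighted by per-site, per-state conservation factors,
#' \deqn{\tilde C^{SCA}_{ij}(\sigma,\sigma') =
#'   \phi_i(\sigma)\,\phi_j(\sigma')\,C_{ij}(\sigma,\sigma'),}
#' and the Frobenius norm of each q x q site-pair block compresses the result
#' to an L x L matrix whose top eigenvectors carry the sector signal. The
#' weight is the relative-entropy gradient
#' \eqn{\phi_i(\sigma) = \left|\ln\frac{\tilde f_i(\sigma)(1-\bar
#' q_\sigma)}{(1-\tilde f_i(\sigma))\bar q_\sigma}\right|} with background
#' frequencies \eqn{\bar q} (0.5 per state for two-state data); frequencies
#' are clipped to `[eps, 1-eps]` to avoid infinities at fully conserved
#' sites. A site whose frequency equals the background gets zero weight and
#' drops out.
#'
#' @param msa spin (-1/+1) or integer-state MSA.
#' @param a pseudocount (default `1e-6`, numerical safety only).
#' @param q number of states.
#' @param background background state frequencies, length q, summing to 1
#'   (default uniform).
#' @param phi optional L x q matrix of weights overriding the default
#'   \eqn{\phi} (e.g. `phi = 1` weighting disabled gives the
#'   Frobenius-compressed plain covariance).
#' @param eps clipping bound for frequencies inside the logarithm.
#' @return L x L symmetric matrix, attribute `method = "sca"`.
#' @export
sca_matrix <- function(msa, a = 1e-6, q = 2, background = NULL, phi = NULL,
                       eps = 1e-6) {
  states <- as_state_matrix(msa, q)
  L <- ncol(states)
  if (is.null(background)) background <- rep(1 / q, q)
  if (length(background) != q || abs(sum(background) - 1) > 1e-8)
    stop("background frequencies must have length q and sum to 1")
  ft <- pseudocount_frequencies(states, a, q)
  if (is.null(phi)) {
    f <- pmin(pmax(ft$f1, eps), 1 - eps)
    bg <- matrix(background, L, q, byrow = TRUE)
    phi <- abs(log(f * (1 - bg) / ((1 - f) * bg)))
  } else if (length(phi) == 1L) {
    phi <- matrix(phi, L, q)
  }
  w <- as.vector(t(phi)) # site-major, matches covariance_full ordering
  f1 <- as.vector(t(ft$f1))
  C <- ft$f2 - tcrossprod(f1)
  Csca <- tcrossprod(w) * C
  out <- block_frobenius(Csca, L, q)
  structure(out, method = "sca", a = a)
}
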