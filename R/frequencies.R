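# Internal state-coding helpers ------------------------------------------

# Map an MSA to integer states 0..q-1. Spin matrices (-1/+1) map to 0/1.
as_state_matrix <- function(msa, q) {
  if (is.character(msa)) stop("character MSAs must be encoded first; see encode_msa()")
  msa <- as.matrix(msa)
  if (q == 2 && all(msa == 1L | msa == -1L)) {
    return(matrix(as.integer((msa + 1L) / 2L), nrow(msa), ncol(msa)))
  }
  if (any(msa < 0 | msa >= q | msa != round(msa)))
    stop("MSA entries must be integer states in 0..q-1 (or spins -1/+1 for q = 2)")
  matrix(as.integer(msa), nrow(msa), ncol(msa))
}

# M x (L*q) one-hot indicator, columns site-major: (site-1)*q + state + 1.
state_indicator <- function(states, q) {
  M <- nrow(states); L <- ncol(states)
  X <- matrix(0, M, L * q)
  idx <- cbind(rep(seq_len(M), L),
               rep((seq_len(L) - 1L) * q, each = M) + as.vector(states) + 1L)
  X[idx] <- 1
  X
}

#' Pseudocount-corrected single- and two-site frequencies
#'
#' Computes the empirical per-site state frequencies \eqn{f_i(\sigma)} and
#' pair frequencies \eqn{f_{ij}(\sigma, \sigma')} of an MSA and regularizes
#' them with a pseudocount `a`, mixing toward the uniform prior:
#' \deqn{\tilde f_i = a/q + (1-a) f_i, \qquad
#'       \tilde f_{ij} = a/q^2 + (1-a) f_{ij} \ (i \neq j),}
#' with the self-pair convention
#' \eqn{\tilde f_{ii}(\sigma,\sigma') = \delta_{\sigma\sigma'}\tilde
#' f_i(\sigma)}. With `a = 0` raw empirical frequencies are returned; with
#' `a = 1` all frequencies are uniform.
#'
#' @param msa M x L matrix: spins (-1/+1) for `q = 2`, or integer states
#'   `0..q-1`.
#' @param a pseudocount weight in \[0, 1\].
#' @param q number of states.
#' @return list of class `frequency_tables`: `f1` (L x q), `f2`
#'   ((Lq) x (Lq), site-major blocks), `a`, `q`, `L`, `M`.
#' @export
pseudocount_frequencies <- function(msa, a, q) {
  if (a < 0 || a > 1) stop("pseudocount a must lie in [0, 1]")
  states <- as_state_matrix(msa, q)
  M <- nrow(states); L <- ncol(states)
  X <- state_indicator(states, q)
  f1_raw <- matrix(colMeans(X), nrow = L, ncol = q, byrow = TRUE)
  f2_raw <- crossprod(X) / M

  f1 <- a / q + (1 - a) * f1_raw
  f2 <- a / q^2 + (1 - a) * f2_raw
  # self-pair blocks: diagonal delta * f1 tilde
  for (i in seq_len(L)) {
    ix <- (i - 1L) * q + seq_len(q)
    blk <- matrix(0, q, q)
    diag(blk) <- f1[i, ]
    f2[ix, ix] <- blk
  }
  structure(list(f1 = f1, f2 = f2, a = a, q = as.integer(q),
                 L = as.integer(L), M = as.integer(M)),
            class = "frequency_tables")
}

#' Entropy-based per-site conservation
#'
#' Kullback-Leibler divergence of the per-site state frequencies from the
#' uniform distribution, in base-`q` logarithms:
#' \deqn{\mathrm{Cons}_i = 1 + \sum_\sigma f_i(\sigma) \log_q f_i(\sigma),}
#' with the convention \eqn{0 \log 0 = 0}. Equals 1 for a fully conserved
#' site and 0 for a uniformly variable one. No pseudocount is applied by
#' default.
#'
#' @inheritParams pseudocount_frequencies
#' @param a optional pseudocount applied to the frequencies (default 0).
#' @return numeric vector of length L with values in \[0, 1\].
#' @export
conservation <- function(msa, q = 2, a = 0) {
  ft <- pseudocount_frequencies(msa, a, q)
  f <- ft$f1
  term <- ifelse(f > 0, f * log(f, base = q), 0)
  as.numeric(1 + rowSums(term))
}
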