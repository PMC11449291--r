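#' Quadratic trait Hamiltonian
#'
#' Energy of a binary sequence under nonlinear (quadratic) selection on the
#' additive trait \eqn{\tau(\sigma) = \sum_i D_i \sigma_i}:
#' \deqn{H(\sigma) = \frac{\kappa}{2}\left(\sum_i D_i \sigma_i -
#'   \tau^*\right)^2.}
#' Fitness is minus the energy; sequences whose trait equals the favored value
#' \eqn{\tau^*} have zero energy.
#'
#' @param seq integer/numeric vector of spins in \{-1, +1\}.
#' @param D effect vector ([make_effect_vector()] output or numeric vector).
#' @param params [selection_params()] object.
#' @return non-negative scalar energy.
#' @examples
#' hamiltonian(c(1, 1), c(1, 1), selection_params(2, 0)) # == 4
#' @export
hamiltonian <- function(seq, D, params) {
  d <- effect_values(D)
  if (length(seq) != length(d)) stop("sequence and D lengths differ")
  check_spins(seq)
  0.5 * params$kappa * (sum(d * seq) - params$tau_star)^2
}

check_spins <- function(x) {
  if (!all(x == 1L | x == -1L)) stop("sequence entries must be -1 or +1")
  invisible(TRUE)
}

# Derive independent sub-seeds from a root seed so that per-sequence and
# per-branch RNG streams do not perturb one another (adding sequences or
# reordering tree traversal leaves other draws unchanged).
derive_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
}

random_spin_sequence <- function(L) {
  sample(c(-1L, 1L), L, replace = TRUE)
}

warn_if_unreachable <- function(D, params) {
  d <- effect_values(D)
  if (abs(params$tau_star) > sum(abs(d)))
    warning("favored trait value tau* is unreachable: |tau*| > sum(|D|)")
  invisible(TRUE)
}

#' One Metropolis step on a binary sequence
#'
#' Proposes a spin flip at one uniformly chosen site and accepts it with
#' probability \eqn{\min(1, e^{-\Delta H})}, where \eqn{\Delta H} is the energy
#' change under [hamiltonian()]. Mostly useful for testing; simulations use
#' the compiled multi-step sampler.
#'
#' @inheritParams hamiltonian
#' @return list with `seq` (possibly flipped), `accepted` (logical) and `site`.
#' @export
metropolis_step <- function(seq, D, params) {
  d <- effect_values(D)
  check_spins(seq)
  if (length(seq) != length(d)) stop("sequence and D lengths differ")
  j <- sample.int(length(seq), 1L)
  tau <- sum(d * seq)
  tau_new <- tau - 2 * d[j] * seq[j]
  dH <- 0.5 * params$kappa *
    ((tau_new - params$tau_star)^2 - (tau - params$tau_star)^2)
  accepted <- dH <= 0 || stats::runif(1) < exp(-dH)
  out <- seq
  if (accepted) out[j] <- -out[j]
  list(seq = out, accepted = accepted, site = j)
}

#' Sample one equilibrium sequence by Metropolis Monte Carlo
#'
#' Starts from a uniform-random spin sequence and performs spin-flip proposals
#' until `n_accepted` mutations have been accepted (3000 by default, enough
#' for the energy to converge at benchmark parameters). The stationary
#' distribution is \eqn{P(\sigma) \propto e^{-H(\sigma)}}, so trait values of
#' sampled sequences concentrate around \eqn{\tau^*}.
#'
#' @param D effect vector.
#' @param params [selection_params()].
#' @param n_accepted number of accepted mutations before stopping.
#' @param seed optional integer seed.
#' @param stall_cap abort with an error after this many consecutive rejected
#'   proposals (guards against unattainable selection regimes).
#' @return integer vector of spins with attribute `trait` (final trait value).
#' @export
sample_equilibrium_sequence <- function(D, params, n_accepted = 3000L,
                                        seed = NULL, stall_cap = 1e6) {
  d <- effect_values(D)
  warn_if_unreachable(d, params)
  if (!is.null(seed)) set.seed(seed)
  s0 <- random_spin_sequence(length(d))
  if (n_accepted == 0) return(s0)
  res <- metropolis_run_cpp(s0, d, params$kappa, params$tau_star,
                            as.integer(n_accepted), stall_cap)
  structure(res$seq, trait = res$trait)
}

#' Sample an MSA of independent equilibrium sequences
#'
#' Runs [sample_equilibrium_sequence()] `M` times with independently derived
#' sub-seeds; rows of the result are exchangeable and mutually independent
#' ("no phylogeny" data).
#'
#' @param M number of sequences.
#' @param D effect vector.
#' @param params [selection_params()].
#' @param n_accepted accepted mutations per sequence.
#' @param seed optional root seed.
#' @inheritParams sample_equilibrium_sequence
#' @return M x L integer matrix of spins (-1/+1).
#' @export
sample_equilibrium_msa <- function(M, D, params, n_accepted = 3000L,
                                   seed = NULL, stall_cap = 1e6) {
  if (M < 1) stop("M must be >= 1")
  d <- effect_values(D)
  seeds <- derive_seeds(seed, M)
  msa <- matrix(0L, nrow = M, ncol = length(d))
  for (m in seq_len(M)) {
    msa[m, ] <- sample_equilibrium_sequence(d, params, n_accepted,
                                            seed = seeds[m],
                                            stall_cap = stall_cap)
  }
  msa
}
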