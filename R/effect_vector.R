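#' Construct a mutational-effect vector with a functional sector
#'
#' Builds the ground-truth vector \eqn{D} of per-site mutational effects on an
#' additive trait \eqn{\tau(\sigma) = \sum_i D_i \sigma_i}. The first `L_S`
#' sites form the functional sector and are drawn from
#' \eqn{N(\mu_S, \sigma_S^2)}; the remaining `L - L_S` background sites are
#' drawn from \eqn{N(\mu_B, \sigma_B^2)}. The defaults reproduce the standard
#' benchmark: 20 sector sites with mean effect 5 and variance 0.25 among 200
#' sites whose background mean effect is 0.5 (same variance).
#'
#' @param L sequence length (number of sites).
#' @param L_S sector size; the sector occupies sites `1:L_S`.
#' @param sector_mean,sector_sd mean and standard deviation of sector effects.
#' @param bg_mean,bg_sd mean and standard deviation of background effects.
#' @param flip_fraction fraction of sector components whose sign is negated
#'   (the first `round(flip_fraction * L_S)` sector sites), to emulate sectors
#'   mixing large positive and large negative effects.
#' @param seed optional integer seed; if supplied the draw is reproducible.
#' @return An object of class `effect_vector`: a list with elements `D`
#'   (numeric length `L`), `sector_indices`, `L` and `L_S`.
#' @examples
#' ev <- make_effect_vector(seed = 1)
#' mean(abs(ev$D[ev$sector_indices])) > mean(abs(ev$D[-ev$sector_indices]))
#' @export
make_effect_vector <- function(L = 200L, L_S = 20L,
                               sector_mean = 5, sector_sd = 0.5,
                               bg_mean = 0.5, bg_sd = 0.5,
                               flip_fraction = 0, seed = NULL) {
  if (L_S > L) stop("L_S must not exceed L")
  if (L_S < 0 || L < 1) stop("L and L_S must be non-negative, L >= 1")
  if (sector_sd < 0 || bg_sd < 0) stop("standard deviations must be >= 0")
  if (flip_fraction < 0 || flip_fraction > 1)
    stop("flip_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  D <- numeric(L)
  if (L_S > 0) D[seq_len(L_S)] <- stats::rnorm(L_S, sector_mean, sector_sd)
  if (L > L_S) D[(L_S + 1L):L] <- stats::rnorm(L - L_S, bg_mean, bg_sd)

  n_flip <- round(flip_fraction * L_S)
  if (n_flip > 0) D[seq_len(n_flip)] <- -D[seq_len(n_flip)]

  structure(list(D = D,
                 sector_indices = if (L_S > 0) seq_len(L_S) else integer(0),
                 L = as.integer(L), L_S = as.integer(L_S)),
            class = "effect_vector")
}

#' @export
print.effect_vector <- function(x, ...) {
  cat(sprintf("effect_vector: L = %d sites, sector L_S = %d (sites %s..%s)\n",
              x$L, x$L_S,
              if (x$L_S) min(x$sector_indices) else NA,
              if (x$L_S) max(x$sector_indices) else NA))
  cat(sprintf("  mean |D| sector: %.3f   background: %.3f\n",
              mean(abs(x$D[x$sector_indices])),
              if (x$L > x$L_S) mean(abs(x$D[-x$sector_indices])) else NA))
  invisible(x)
}

# Accept either an effect_vector or a bare numeric vector of effects.
effect_values <- function(D) {
  if (inherits(D, "effect_vector")) D$D else as.numeric(D)
}

#' Selection parameters for the quadratic trait Hamiltonian
#'
#' @param kappa selection strength (>= 0; 0 means neutral evolution).
#' @param tau_star favored trait value.
#' @return list with class `selection_params`.
#' @seealso [kappa_rule()] for the standard normalization of `kappa`.
#' @export
selection_params <- function(kappa, tau_star) {
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(kappa = kappa, tau_star = tau_star),
            class = "selection_params")
}

#' Normalize selection strength relative to the effect vector
#'
#' The benchmark parameterization sets \eqn{\kappa = t / \sum_i D_i^2} so that
#' \eqn{\kappa \sum_i D_i^2} equals a fixed target (10 by default), making the
#' selection strength comparable across realizations of `D`.
#'
#' @param D effect vector (or numeric vector of effects).
#' @param target desired value of `kappa * sum(D^2)`.
#' @return scalar kappa.
#' @export
kappa_rule <- function(D, target = 10) {
  d <- effect_values(D)
  target / sum(d^2)
}
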