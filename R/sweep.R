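#' Specify a site-scoring method for sweeps
#'
#' Bundles a scoring method with its pseudocount and the end of the spectrum
#' whose eigenvector carries the signal. Defaults follow the standard
#' choices: ICOD and SCA use the largest-eigenvalue eigenvector, covariance
#' the smallest, conservation is a per-site score with no eigen-analysis.
#'
#' @param method one of `"icod"`, `"covariance"`, `"sca"`, `"conservation"`,
#'   `"mi"`.
#' @param a pseudocount; `NULL` picks the method default (1e-5 for ICOD,
#'   0.001 for MI, 0 otherwise).
#' @param eigen_end `"largest"`, `"smallest"`, or `NULL` for the method
#'   default.
#' @param label optional label used in result tables.
#' @return list of class `method_spec`.
#' @export
method_spec <- function(method = c("icod", "covariance", "sca",
                                   "conservation", "mi"),
                        a = NULL, eigen_end = NULL, label = NULL) {
  method <- match.arg(method)
  defaults <- list(icod = list(a = 1e-5, end = "largest"),
                   covariance = list(a = 0, end = "smallest"),
                   sca = list(a = 0, end = "largest"),
                   conservation = list(a = 0, end = NA),
                   mi = list(a = 0.001, end = "largest"))
  dft <- defaults[[method]]
  structure(list(method = method,
                 a = if (is.null(a)) dft$a else a,
                 eigen_end = if (is.null(eigen_end)) dft$end else eigen_end,
                 label = if (is.null(label)) method else label),
            class = "method_spec")
}

#' Score the sites of a binary MSA with one method
#'
#' Computes the designated site-score vector for a spin MSA: the relevant
#' matrix (ICOD, covariance, SCA or MI) followed by the eigenvector at the
#' method's designated end of the spectrum, or the conservation profile.
#'
#' @param msa M x L spin matrix.
#' @param spec a [method_spec()] (or method name, converted with defaults).
#' @return numeric site vector of length L.
#' @export
score_msa <- function(msa, spec) {
  if (is.character(spec)) spec <- method_spec(spec)
  v <- switch(spec$method,
    icod = eigen_analysis(icod_two_state(msa, a = spec$a),
                          spec$eigen_end)$vector,
    covariance = eigen_analysis(covariance_two_state(msa, a = spec$a),
                                spec$eigen_end)$vector,
    sca = eigen_analysis(sca_matrix(msa, a = spec$a), spec$eigen_end)$vector,
    mi = eigen_analysis(mutual_information(msa, a = spec$a),
                        spec$eigen_end)$vector,
    conservation = conservation(msa, q = 2, a = spec$a))
  v
}

#' Recovery and symmetrized AUC across phylogeny strengths
#'
#' The central benchmark sweep: for every value of `mu` (accepted mutations
#' per branch of a perfect binary tree) and every realization, a dataset is
#' generated (ancestor equilibration plus evolution along the tree) and each
#' requested method scores its sites; recovery of the effect vector and the
#' symmetrized AUC against sector membership are recorded. All methods see
#' the same datasets, so pseudocount or method comparisons are paired.
#'
#' @param mu_values numeric vector of accepted mutations per branch.
#' @param methods list of [method_spec()]s (or character method names).
#' @param n_realizations independent data generations per `mu` (100 for
#'   full-scale runs; 10 is the fast default).
#' @param D effect vector; if `NULL` a fresh default benchmark vector is
#'   drawn from the root seed and kept fixed across the sweep.
#' @param params [selection_params()]; if `NULL`, kappa is set by
#'   [kappa_rule()] (target 10) and `tau_star = 90`.
#' @param n generations of the perfect binary tree (11 gives M = 2048).
#' @param n_equil ancestor equilibration acceptances.
#' @param seed root seed; realization streams are derived from it.
#' @return data.frame: `method`, `a`, `mu`, `realization`, `recovery`,
#'   `sym_auc`, plus attribute `null_recovery` (Eq.-13-style chance level for
#'   the `D` used).
#' @export
phylogeny_sweep <- function(mu_values, methods, n_realizations = 10,
                            D = NULL, params = NULL, n = 11L,
                            n_equil = 3000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(D)) D <- make_effect_vector()
  d <- effect_values(D)
  sector <- if (inherits(D, "effect_vector")) D$sector_indices
            else which(abs(d) > stats::median(abs(d)) * 3)
  if (is.null(params))
    params <- selection_params(kappa_rule(d), tau_star = 90)
  methods <- lapply(methods, function(m)
    if (is.character(m)) method_spec(m) else m)

  seeds <- matrix(derive_seeds(NULL, length(mu_values) * n_realizations),
                  nrow = length(mu_values))
  rows <- list()
  for (i in seq_along(mu_values)) {
    for (r in seq_len(n_realizations)) {
      rec <- evolve_on_binary_tree(d, params, mu = mu_values[i], n = n,
                                   n_equil = n_equil, seed = seeds[i, r])
      msa <- rec$leaf_msa
      for (sp in methods) {
        v <- score_msa(msa, sp)
        rows[[length(rows) + 1L]] <-
          data.frame(method = sp$label, a = sp$a, mu = mu_values[i],
                     realization = r,
                     recovery = recovery(v, d),
                     sym_auc = symmetrized_auc(v, seq_along(d) %in% sector))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "null_recovery") <- null_recovery(d)
  attr(out, "D") <- d
  out
}

#' Summarize a sweep table
#'
#' Mean and standard deviation of recovery and symmetrized AUC per method
#' and phylogeny level.
#'
#' @param sweep data.frame from [phylogeny_sweep()].
#' @return data.frame with one row per (method, a, mu).
#' @export
summarize_sweep <- function(sweep) {
  agg <- stats::aggregate(cbind(recovery, sym_auc) ~ method + a + mu,
                          data = sweep, FUN = mean)
  sds <- stats::aggregate(cbind(recovery, sym_auc) ~ method + a + mu,
                          data = sweep, FUN = stats::sd)
  names(agg)[4:5] <- c("recovery_mean", "sym_auc_mean")
  agg$recovery_sd <- sds$recovery
  agg$sym_auc_sd <- sds$sym_auc
  agg[order(agg$method, agg$a, agg$mu), ]
}
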