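# Shared fixtures for the benchmark world: L = 200 sites, 20-site sector with
# effects ~ N(5, 0.25), background ~ N(0.5, 0.25), kappa * sum(D^2) = 10,
# tau* = 90, perfect binary tree with 11 generations (M = 2048 leaves).
# Generated datasets are cached so multiple test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

bench_D <- function() {
  if (is.null(.fixture_cache$D))
    .fixture_cache$D <- make_effect_vector(seed = 42)
  .fixture_cache$D
}

bench_params <- function() selection_params(kappa_rule(bench_D()), 90)

# Equilibrium ("no phylogeny") MSA at benchmark parameters.
bench_equilibrium <- function(M = 2048, seed = 2100) {
  key <- sprintf("eq_%d_%d", M, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- sample_equilibrium_msa(M, bench_D(),
                                                    bench_params(), seed = seed)
  .fixture_cache[[key]]
}

# Phylogeny dataset at a given mu (full benchmark tree, n = 11).
bench_tree <- function(mu, seed = 3000 + mu) {
  key <- sprintf("tree_%g_%d", mu, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- evolve_on_binary_tree(bench_D(), bench_params(),
                                                   mu = mu, n = 11, seed = seed)
  .fixture_cache[[key]]
}

# Small, fast world for unit tests that do not need benchmark scale.
small_D <- function() make_effect_vector(L = 30, L_S = 6, seed = 5)
small_params <- function(D = small_D())
  selection_params(kappa_rule(D), tau_star = 0.3 * sum(abs(effect_values(D))))

# Brute-force mean pairwise Hamming (independent oracle).
brute_hamming <- function(msa) {
  M <- nrow(msa)
  tot <- 0
  for (i in seq_len(M - 1))
    for (j in (i + 1):M)
      tot <- tot + mean(msa[i, ] != msa[j, ])
  tot / (M * (M - 1) / 2)
}
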