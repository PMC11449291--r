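# Sequence simulator: effect vectors, Hamiltonian, Metropolis sampling and
# evolution along trees.

test_that("effect vector construction follows the sector layout", {
  ev <- make_effect_vector(seed = 1)
  expect_length(ev$D, 200)
  expect_identical(ev$sector_indices, 1:20)
  expect_gt(mean(abs(ev$D[ev$sector_indices])),
            mean(abs(ev$D[-ev$sector_indices])))

  # sign-flip variant: first half of the sector negated, magnitudes unchanged
  ev_flip <- make_effect_vector(flip_fraction = 0.5, seed = 1)
  expect_equal(ev_flip$D[1:10], -ev$D[1:10])
  expect_equal(ev_flip$D[11:200], ev$D[11:200])

  # degenerate no-sector case
  ev0 <- make_effect_vector(L = 10, L_S = 0, bg_mean = 0, bg_sd = 0)
  expect_equal(ev0$D, rep(0, 10))

  expect_error(make_effect_vector(L = 5, L_S = 6), "L_S")
  expect_error(make_effect_vector(sector_sd = -1), "deviation")

  expect_identical(make_effect_vector(seed = 9)$D,
                   make_effect_vector(seed = 9)$D)
})

test_that("Hamiltonian is the quadratic trait energy", {
  expect_equal(hamiltonian(c(1, 1), c(1, 1), selection_params(2, 0)), 4)
  # trait at the favored value -> zero energy
  expect_equal(hamiltonian(c(1, -1), c(1, 1), selection_params(5, 0)), 0)
  # neutral limit
  expect_equal(hamiltonian(c(1, 1, -1), c(2, 1, 3), selection_params(0, 7)), 0)
  expect_gte(hamiltonian(c(-1, 1), c(3, 2), selection_params(1, 4)), 0)
  expect_error(hamiltonian(c(1, 1, 1), c(1, 1), selection_params(1, 0)),
               "length")
})

test_that("Metropolis acceptance follows the criterion", {
  set.seed(1)
  # neutral: every proposal accepted
  for (i in 1:20) {
    st <- metropolis_step(c(1, -1, 1, -1), c(1, 2, 3, 4), selection_params(0, 0))
    expect_true(st$accepted)
  }
  # downhill (toward tau*) always accepted: all-(+1) sequence, tau* = 0,
  # any flip reduces |tau|
  for (i in 1:20) {
    st <- metropolis_step(rep(1L, 6), rep(1, 6), selection_params(2, 0))
    expect_true(st$accepted)
    expect_equal(sum(st$seq), 4)
  }
})

test_that("equilibrium sampler matches exact enumeration at small L", {
  # Exact oracle at L = 8: enumerate all 256 sequences, build the Metropolis
  # kernel, and compute the mean trait of the just-after-acceptance ensemble
  # (the sampler stops at the N-th accepted mutation). Boltzmann stationarity
  # of the kernel is asserted on the way.
  L <- 8
  set.seed(5)
  D <- stats::rnorm(L, 1, 0.3)
  kap <- 10 / sum(D^2)
  ts <- 3
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), L)))
  tau <- as.vector(S %*% D)
  H <- 0.5 * kap * (tau - ts)^2
  boltz <- exp(-H) / sum(exp(-H))
  key <- apply(S, 1, paste, collapse = ",")
  idx <- stats::setNames(seq_len(nrow(S)), key)
  P <- matrix(0, nrow(S), nrow(S))
  for (x in seq_len(nrow(S))) {
    stay <- 0
    for (j in seq_len(L)) {
      y <- S[x, ]; y[j] <- -y[j]
      yi <- idx[[paste(y, collapse = ",")]]
      acc <- min(1, exp(-(H[yi] - H[x])))
      P[x, yi] <- acc / L
      stay <- stay + (1 - acc) / L
    }
    P[x, x] <- stay
  }
  expect_equal(as.vector(boltz %*% P), boltz, tolerance = 1e-12)
  A <- P; diag(A) <- 0
  nu <- as.vector(boltz %*% A); nu <- nu / sum(nu)
  oracle_mean <- sum(nu * tau)
  oracle_sd <- sqrt(sum(nu * tau^2) - oracle_mean^2)

  M <- 4000
  msa <- sample_equilibrium_msa(M, D, selection_params(kap, ts),
                                n_accepted = 400, seed = 1)
  se <- oracle_sd / sqrt(M)
  expect_lt(abs(mean(msa %*% D) - oracle_mean), 4 * se)
})

test_that("neutral equilibrium is uniform and n_accepted = 0 is the identity", {
  D <- rep(1, 40)
  neutral <- selection_params(0, 0)
  msa <- sample_equilibrium_msa(600, D, neutral, n_accepted = 200, seed = 3)
  # binomial bound on per-site magnetization
  expect_true(all(abs(colMeans(msa)) < 3 / sqrt(600)))

  set.seed(17)
  s0 <- sample_equilibrium_sequence(D, neutral, n_accepted = 0, seed = 17)
  set.seed(17)
  expect_identical(as.integer(s0), sample(c(-1L, 1L), 40, replace = TRUE))
})

test_that("trait concentrates near tau* and sharpens with kappa", {
  ev <- bench_D()
  msa <- sample_equilibrium_msa(500, ev, bench_params(), seed = 7)
  traits <- as.vector(msa %*% ev$D)
  # entropy pulls the mean somewhat below tau* = 90 (see vignette); the
  # distribution still concentrates near it compared to the random-sequence
  # scale sd(tau_0) = sqrt(sum(D^2)) ~ 23 around 0
  expect_lt(abs(mean(traits) - 90), 15)
  strong <- selection_params(4 * bench_params()$kappa, 90)
  traits2 <- as.vector(sample_equilibrium_msa(500, ev, strong,
                                              seed = 8) %*% ev$D)
  expect_lt(stats::sd(traits2), stats::sd(traits))
  expect_lt(abs(mean(traits2) - 90), abs(mean(traits) - 90))
})

test_that("unreachable favored trait warns and zero-effect D is handled", {
  expect_warning(sample_equilibrium_sequence(rep(0.1, 10),
                                             selection_params(1, 100),
                                             n_accepted = 5, seed = 1),
                 "unreachable")
})

test_that("binary-tree evolution keeps the stated bookkeeping", {
  D <- small_D(); pars <- small_params()
  mu <- 4; n <- 5
  rec <- evolve_on_binary_tree(D, pars, mu = mu, n = n, seed = 11)
  M <- nrow(rec$leaf_msa)
  expect_equal(M, 2^n)
  expect_equal(ape::Ntip(rec$tree), 2^n)

  # sibling leaves differ by at most 2*mu sites, any pair by at most 2*mu*n
  leaves <- (2^n):(2^(n + 1) - 1)
  for (k in seq(leaves[1], leaves[1] + 30, by = 2)) {
    i <- which(leaves == k); j <- which(leaves == k + 1)
    expect_lte(sum(rec$leaf_msa[i, ] != rec$leaf_msa[j, ]), 2 * mu)
  }
  expect_lte(max(vapply(2:M, function(j)
    sum(rec$leaf_msa[1, ] != rec$leaf_msa[j, ]), numeric(1))), 2 * mu * n)

  # replay: every node sequence equals the ancestor plus its branch flips
  root <- rec$node_sequences[1, ]
  for (k in c(leaves[1], leaves[M %/% 2], leaves[M])) {
    path <- k
    while (path[1] > 1) path <- c(path[1] %/% 2, path)
    s <- root
    for (node in path[-1]) {
      flips <- rec$mutation_log$site[rec$mutation_log$node == node]
      for (f in flips) s[f] <- -s[f]
    }
    expect_identical(s, rec$node_sequences[k, ])
  }

  # G consistency: a site with G = g matches the root at all levels < g
  lev <- floor(log2(seq_len(nrow(rec$node_sequences))))
  for (i in seq_along(rec$G)) {
    g <- rec$G[i]
    if (g > 1) {
      early <- which(lev > 0 & lev < g)
      expect_true(all(rec$node_sequences[early, i] == root[i]))
    }
    if (g <= n) {
      expect_true(any(rec$node_sequences[lev == g, i] != root[i]))
    }
  }

  # mu = 0: leaves identical to ancestor, G all sentinel
  rec0 <- evolve_on_binary_tree(D, pars, mu = 0, n = 3, seed = 12)
  expect_true(all(rec0$leaf_msa == matrix(rec0$node_sequences[1, ], 8, 30,
                                          byrow = TRUE)))
  expect_true(all(rec0$G == 4))

  # determinism
  rec2 <- evolve_on_binary_tree(D, pars, mu = mu, n = n, seed = 11)
  expect_identical(rec$leaf_msa, rec2$leaf_msa)
  expect_identical(rec$G, rec2$G)
})

test_that("sampler stalls with a diagnostic when acceptances are unattainable", {
  # ancestor at tau = tau* with huge kappa: every flip is astronomically
  # unlikely to be accepted
  D <- rep(1, 4)
  pars <- selection_params(50, 0)
  anc <- c(1L, 1L, -1L, -1L)
  expect_error(evolve_on_binary_tree(D, pars, mu = 2, n = 1, ancestor = anc,
                                     seed = 1, stall_cap = 500),
               "stalled")
})

test_that("newick evolution matches the binary-tree implementation", {
  D <- small_D(); pars <- small_params()

  # star tree with zero branch lengths: leaves identical to ancestor
  star <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  rec <- evolve_on_newick_tree(D, pars, star, rate_constant = 5, seed = 3)
  expect_true(all(rec$leaf_msa == matrix(rec$node_sequences[5, ], 4, 30,
                                         byrow = TRUE)))

  # two leaves on very long branches: pair as distant as two independent
  # equilibrium sequences
  two <- ape::read.tree(text = "(a:1,b:1);")
  rec2 <- evolve_on_newick_tree(D, pars, two, rate_constant = 3000, seed = 4)
  d_tree <- mean(rec2$leaf_msa[1, ] != rec2$leaf_msa[2, ])
  eq <- sample_equilibrium_msa(400, D, pars, n_accepted = 1000, seed = 5)
  d_eq <- mean_pairwise_hamming(eq)
  expect_lt(abs(d_tree - d_eq), 0.15)

  # perfect binary topology as newick, rate * length = mu: summary statistics
  # match the native implementation up to Poisson jitter
  mu <- 6; n <- 5
  bt <- evolve_on_binary_tree(D, pars, mu = mu, n = n, seed = 6)
  nwk <- ape::write.tree(bt$tree)
  recn <- evolve_on_newick_tree(D, pars, ape::read.tree(text = nwk),
                                rate_constant = 1, seed = 6)
  expect_equal(nrow(recn$leaf_msa), 2^n)
  expect_equal(recn$mean_m, mu * n, tolerance = 0.25)
  expect_lt(abs(mean_pairwise_hamming(recn$leaf_msa) -
                  mean_pairwise_hamming(bt$leaf_msa)), 0.1)

  expect_error(evolve_on_newick_tree(D, pars,
                                     ape::read.tree(text = "(a,b);"),
                                     rate_constant = 1, seed = 1),
               "branch lengths")
})

test_that("mean pairwise Hamming distance matches brute force", {
  msa <- matrix(rep(c(1L, -1L), each = 12), nrow = 2, byrow = TRUE)
  expect_equal(mean_pairwise_hamming(rbind(msa[1, ], msa[1, ])), 0)
  set.seed(8)
  r <- matrix(sample(c(-1L, 1L), 7 * 11, replace = TRUE), 7, 11)
  expect_equal(mean_pairwise_hamming(r), brute_hamming(r))
  expect_error(mean_pairwise_hamming(r[1, , drop = FALSE]), "2 sequences")
})

test_that("spin MSAs round-trip through FASTA and records serialize", {
  set.seed(4)
  msa <- matrix(sample(c(-1L, 1L), 5 * 8, replace = TRUE), 5, 8)
  path <- tempfile(fileext = ".fasta")
  write_binary_fasta(msa, path)
  back <- read_binary_fasta(path)
  expect_equal(unname(back), unname(msa), ignore_attr = TRUE)

  rec <- evolve_on_binary_tree(small_D(), small_params(), mu = 2, n = 3,
                               seed = 2)
  dir <- tempfile()
  write_phylogeny_record(rec, dir)
  expect_true(all(file.exists(file.path(dir,
    c("tree.nwk", "leaves.fasta", "internal_nodes.fasta", "G.csv",
      "mutation_log.csv")))))
  G <- utils::read.csv(file.path(dir, "G.csv"))
  expect_equal(G$G, rec$G)
  expect_equal(ape::Ntip(ape::read.tree(file.path(dir, "tree.nwk"))), 8)
})
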