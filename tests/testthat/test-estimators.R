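# Frequency estimation, conservation, covariance, ICOD, SCA, MI, APC, and
# eigen-analysis.

test_that("pseudocount frequencies reproduce hand counts and limits", {
  # two sequences over two sites: site 1 = (A, A), site 2 = (A, B)
  msa <- rbind(c(0L, 0L), c(0L, 1L))
  ft <- pseudocount_frequencies(msa, a = 0, q = 2)
  expect_equal(ft$f1[1, ], c(1, 0))
  expect_equal(ft$f1[2, ], c(0.5, 0.5))
  blk <- ft$f2[1:2, 3:4] # f_12(sigma_1, sigma_2)
  expect_equal(blk, matrix(c(0.5, 0, 0.5, 0), 2, 2), ignore_attr = TRUE)

  # a = 1: pure uniform prior
  ft1 <- pseudocount_frequencies(msa, a = 1, q = 2)
  expect_true(all(abs(ft1$f1 - 0.5) < 1e-12))
  expect_true(all(abs(ft1$f2[1:2, 3:4] - 0.25) < 1e-12))

  expect_error(pseudocount_frequencies(rbind(c(0L, 3L)), a = 0, q = 2),
               "states")
})

test_that("frequency normalization and the self-pair identity are exact", {
  set.seed(1)
  for (q in c(2, 4)) {
    msa <- matrix(sample(0:(q - 1), 30 * 6, replace = TRUE), 30, 6)
    for (a in c(0, 0.05, 0.5)) {
      ft <- pseudocount_frequencies(msa, a, q)
      expect_equal(rowSums(ft$f1), rep(1, 6))
      for (i in 1:6) {
        ix <- (i - 1) * q + seq_len(q)
        for (j in 1:6) {
          jx <- (j - 1) * q + seq_len(q)
          expect_equal(sum(ft$f2[ix, jx]), 1, tolerance = 1e-12)
        }
        blk <- ft$f2[ix, ix]
        expect_equal(blk, diag(ft$f1[i, ], q), ignore_attr = TRUE)
      }
    }
  }
})

test_that("conservation is the base-q KL divergence from uniform", {
  # fully conserved site -> 1; uniform site -> 0
  msa <- cbind(rep(-1L, 10), rep(c(-1L, 1L), 5))
  cons <- conservation(msa, q = 2)
  expect_equal(cons, c(1, 0))

  # f = (0.9, 0.1): 1 - binary entropy in bits
  col <- matrix(c(rep(-1L, 9), 1L), ncol = 1)
  expected <- 1 + 0.9 * log2(0.9) + 0.1 * log2(0.1)
  expect_equal(conservation(col, q = 2)[1], expected)
  expect_equal(expected, 0.531, tolerance = 1e-3)

  # mixing with a balanced column can only decrease conservation
  set.seed(2)
  for (r in 1:20) {
    n1 <- sample(0:16, 1)
    col <- matrix(c(rep(-1L, n1), rep(1L, 16 - n1)), ncol = 1)
    mixed <- rbind(col, matrix(rep(c(-1L, 1L), 8), ncol = 1))
    expect_lte(conservation(mixed, q = 2)[1], conservation(col, q = 2)[1] + 1e-12)
  }
})

test_that("two-state covariance matches its closed forms", {
  # balanced site: C_ii = 1; two always-equal balanced sites: C_ij = 1
  msa <- cbind(rep(c(-1L, 1L), 8), rep(c(-1L, 1L), 8))
  C <- covariance_two_state(msa)
  expect_equal(C[1, 1], 1)
  expect_equal(C[1, 2], 1)

  # a = 1: identity matrix
  C1 <- covariance_two_state(msa, a = 1)
  expect_equal(unclass(C1), diag(2), ignore_attr = TRUE)

  expect_error(covariance_two_state(cbind(c(0, 1))), "-1 or \\+1")

  # pseudocount formulas against direct computation
  set.seed(3)
  m <- matrix(sample(c(-1L, 1L), 50 * 4, replace = TRUE), 50, 4)
  a <- 0.2
  Ca <- covariance_two_state(m, a)
  mu <- colMeans(m); S <- crossprod(m) / 50
  for (i in 1:4) for (j in 1:4) {
    expected <- if (i == j) (1 - a)^2 * (1 - mu[i]^2) + a * (2 - a)
                else (1 - a) * S[i, j] - (1 - a)^2 * mu[i] * mu[j]
    expect_equal(Ca[i, j], expected)
  }
})

test_that("full blocked covariance reduces to the scalar two-state form", {
  set.seed(4)
  msa <- matrix(sample(c(-1L, 1L), 60 * 5, replace = TRUE), 60, 5)
  Cfull <- covariance_full(msa, a = 0, q = 2)
  Cspin <- covariance_two_state(msa, a = 0)
  # spins are sigma = 2x - 1, so cov(sigma_i, sigma_j) = 4 cov(x_i, x_j)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    expect_equal(4 * Cfull[(i - 1) * 2 + 2, (j - 1) * 2 + 2], Cspin[i, j])
  }

  # independent uniform columns: off-diagonal blocks vanish at CLT rate
  set.seed(5)
  big <- matrix(sample(0:3, 2000 * 5, replace = TRUE), 2000, 5)
  Cb <- covariance_full(big, a = 0, q = 4)
  off <- Cb
  for (i in 1:5) off[(i - 1) * 4 + 1:4, (i - 1) * 4 + 1:4] <- 0
  expect_lt(max(abs(off)), 5 / sqrt(2000))

  # a single repeated sequence has no variance at all
  rep1 <- matrix(rep(c(0L, 2L, 1L), each = 10), 10, 3)
  expect_lt(max(abs(covariance_full(rep1, a = 0, q = 3))), 1e-12)

  # reference gauge drops one state per site
  Cg <- covariance_full(msa, a = 0.01, q = 2, drop_states = rep(0L, 5))
  expect_equal(dim(Cg), c(5L, 5L))
})

test_that("two-state ICOD has zero diagonal and approximates kappa D D^t", {
  ev <- small_D(); pars <- small_params()
  msa <- sample_equilibrium_msa(2000, ev, pars, n_accepted = 1000, seed = 6)
  ic <- icod_two_state(msa)
  expect_true(all(diag(ic) == 0))
  expect_lt(max(abs(ic - t(ic))), 1e-10)

  analytic <- pars$kappa * tcrossprod(ev$D)
  off <- upper.tri(ic)
  r2000 <- stats::cor(ic[off], analytic[off])
  expect_gt(r2000, 0.8)

  # correlation grows with sample size
  ic500 <- icod_two_state(sample_equilibrium_msa(300, ev, pars,
                                                 n_accepted = 1000, seed = 7))
  expect_gt(r2000, stats::cor(ic500[off], analytic[off]))

  # singular covariance (M < L, no pseudocount) is rejected with a diagnostic
  tiny <- sample_equilibrium_msa(10, ev, pars, n_accepted = 100, seed = 8)
  expect_error(icod_two_state(tiny, a = 0), "ill-conditioned")
})

test_that("matrix methods are invariant to row permutation and spin flip", {
  set.seed(9)
  msa <- matrix(sample(c(-1L, 1L), 80 * 6, replace = TRUE), 80, 6)
  perm <- msa[sample(80), ]
  expect_equal(covariance_two_state(perm), covariance_two_state(msa))
  expect_equal(sca_matrix(perm), sca_matrix(msa))
  expect_equal(mutual_information(perm), mutual_information(msa))
  expect_equal(icod_two_state(perm), icod_two_state(msa), tolerance = 1e-10)
  # global spin flip leaves covariance and ICOD unchanged
  expect_equal(covariance_two_state(-msa), covariance_two_state(msa))
  expect_equal(icod_two_state(-msa), icod_two_state(msa), tolerance = 1e-10)
})

test_that("20-state gauged ICOD agrees with the two-state version", {
  ev <- small_D(); pars <- small_params()
  msa <- sample_equilibrium_msa(800, ev, pars, n_accepted = 1000, seed = 8)
  chars <- matrix(ifelse(msa == -1, "A", "C"), nrow(msa), ncol(msa))
  enc <- encode_msa(chars)
  ic20 <- icod_natural(enc, ref_seq = enc[1, ], a = 0.05)
  expect_true(all(diag(ic20) == 0))
  v20 <- eigen_analysis(ic20, "largest")$vector
  v2 <- eigen_analysis(icod_two_state(msa), "largest")$vector
  # same sector call; full orderings correlate (background sites are noisy)
  expect_setequal(top_sites(v20, 6), top_sites(v2, 6))
  expect_gt(stats::cor(abs(v20), abs(v2), method = "spearman"), 0.5)

  expect_error(icod_natural(enc, ref_seq = enc[1, 1:5], a = 0.05), "length")
})

test_that("APC removes constant and rank-one-constant background", {
  cm <- matrix(0.7, 8, 8); diag(cm) <- 0
  expect_lt(max(abs(apc_correct(cm))), 1e-12)

  # rank-one with positive weights: near-zero residual (exact for constant s)
  s <- seq(0.5, 1.5, length.out = 10)
  m <- tcrossprod(s); diag(m) <- 0
  # brute-force oracle for the correction formula
  L <- 10
  expected <- m
  rm_ <- sapply(1:L, function(i) mean(m[i, -i]))
  am <- mean(m[row(m) != col(m)])
  for (i in 1:L) for (j in 1:L)
    expected[i, j] <- m[i, j] - rm_[i] * rm_[j] / am
  diag(expected) <- 0
  expect_equal(apc_correct(m), expected, tolerance = 1e-12)
  expect_lt(max(abs(apc_correct(m))) / max(abs(m)), 0.1)

  # constant direction: the first application annihilates exactly, the second
  # returns its input unchanged (with a warning about a zero mean)
  const <- tcrossprod(rep(2, 6)); diag(const) <- 0
  once <- apc_correct(const)
  expect_lt(max(abs(once)), 1e-12)
  twice <- suppressWarnings(apc_correct(once))
  expect_lt(max(abs(twice - once)), 1e-10)
})

test_that("SCA weighting behaves as specified", {
  set.seed(10)
  msa <- matrix(sample(c(-1L, 1L), 100 * 5, replace = TRUE), 100, 5)
  # weighting disabled: Frobenius-compressed plain covariance
  plain <- sca_matrix(msa, a = 0, phi = 1)
  Cf <- covariance_full(msa, a = 0, q = 2)
  K <- matrix(0, 10, 5); K[cbind(1:10, rep(1:5, each = 2))] <- 1
  expect_equal(unclass(plain), sqrt(t(K) %*% (Cf * Cf) %*% K),
               ignore_attr = TRUE)

  # a site exactly at the background frequency gets zero weight
  balanced <- cbind(rep(c(-1L, 1L), 50), msa[, 2:5])
  S <- sca_matrix(balanced, a = 0)
  expect_lt(max(abs(S[1, ])), 1e-10)

  expect_error(sca_matrix(msa, background = c(0.9, 0.2)), "sum to 1")
})

test_that("mutual information has its exact limits and positivity", {
  # perfectly dependent balanced sites: MI = ln 2
  dep <- cbind(rep(c(-1L, 1L), 10), rep(c(-1L, 1L), 10))
  expect_equal(mutual_information(dep, a = 0)[1, 2], log(2))

  # exactly independent product frequencies: MI = 0
  ind <- cbind(c(-1L, -1L, 1L, 1L), c(-1L, 1L, -1L, 1L))
  expect_lt(abs(mutual_information(ind, a = 0)[1, 2]), 1e-12)

  # nonnegative off-diagonal at any pseudocount
  set.seed(11)
  r <- matrix(sample(c(-1L, 1L), 40 * 6, replace = TRUE), 40, 6)
  for (a in c(0, 0.001, 0.3)) {
    MI <- mutual_information(r, a = a)
    expect_gte(min(MI[upper.tri(MI)]), -1e-12)
  }
  # diagonal convention
  expect_true(all(diag(mutual_information(r)) == 0))
  kept <- mutual_information(r, zero_diag = FALSE)
  expect_gt(min(diag(kept)), 0)
})

test_that("eigen-analysis conventions and the outer-product spectrum", {
  ev <- bench_D()
  kap <- kappa_rule(ev) # kappa * sum(D^2) = 10 by construction
  outer_mat <- kap * tcrossprod(ev$D) # diagonal kept
  ea <- eigen_analysis(outer_mat, "largest")
  expect_equal(ea$value, 10, tolerance = 1e-10)
  expect_equal(abs(ea$vector), abs(ev$D) / sqrt(sum(ev$D^2)), tolerance = 1e-8)
  expect_equal(recovery(ea$vector, ev), 1, tolerance = 1e-10)
  # remaining eigenvalues vanish
  expect_lt(abs(spectrum_table(outer_mat)$value[2]), 1e-10)

  id <- eigen_analysis(diag(5), 2)
  expect_equal(id$value, 1)
  expect_equal(sum(id$vector^2), 1)
  expect_gt(id$vector[which.max(abs(id$vector))], 0)

  expect_error(eigen_analysis(matrix(c(1, 2, 3, 4), 2, 2)), "symmetric")
  expect_error(eigen_analysis(diag(3), 5), "rank")
})
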