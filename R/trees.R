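#' Evolve an ancestral sequence along a perfect binary tree
#'
#' Starting from an ancestor (an equilibrium sequence by default, or a random
#' sequence when `neutral = TRUE`), evolves the sequence along a perfect
#' binary tree with `n` generations (tree levels). On every branch exactly
#' `mu` Metropolis-accepted mutations are performed under the same selection
#' as at equilibrium (every proposal is accepted when `neutral = TRUE`,
#' i.e. kappa is set to 0). The leaf sequences form an MSA carrying both
#' phylogenetic and selection-induced correlations; smaller `mu` means
#' stronger phylogeny.
#'
#' Internal nodes are indexed in heap order (node 1 = root, node k has
#' children 2k and 2k+1; leaves are nodes `2^n .. 2^(n+1)-1`). The per-site
#' score `G` records the earliest generation (level, 1-based from the root's
#' children) at which any node's state at that site differs from the root
#' state; sites that never deviate get the sentinel `n + 1`.
#'
#' @param D effect vector.
#' @param params [selection_params()].
#' @param mu accepted mutations per branch (>= 0).
#' @param n number of generations (levels); the MSA has `2^n` rows.
#' @param ancestor optional spin sequence to use as the root; if `NULL`, an
#'   equilibrium sequence is sampled (`n_equil` acceptances), or a random
#'   sequence if `neutral = TRUE`.
#' @param neutral if `TRUE`, all proposals are accepted (no selection) both
#'   for the ancestor and along branches.
#' @param n_equil accepted mutations used to equilibrate the ancestor.
#' @param seed optional root seed; branch streams are derived from it.
#' @param stall_cap consecutive-rejection cap passed to the sampler.
#' @return An object of class `phylogeny_record`: list with `tree` (ape
#'   `phylo`), `node_sequences` (heap-ordered node x L matrix),
#'   `leaf_msa` (`2^n` x L spin matrix), `G` (integer per-site score,
#'   sentinel `n + 1`), `mutation_log` (data.frame: node, level, order, site),
#'   plus the simulation parameters.
#' @export
evolve_on_binary_tree <- function(D, params, mu, n, ancestor = NULL,
                                  neutral = FALSE, n_equil = 3000L,
                                  seed = NULL, stall_cap = 1e6) {
  if (mu < 0) stop("mu must be >= 0")
  if (n < 1) stop("n must be >= 1")
  d <- effect_values(D)
  L <- length(d)
  kappa <- if (neutral) 0 else params$kappa
  n_nodes <- 2L^(n + 1L) - 1L
  seeds <- derive_seeds(seed, n_nodes) # seeds[1] = ancestor, seeds[k] = branch into node k

  if (is.null(ancestor)) {
    if (neutral) {
      set.seed(seeds[1L])
      ancestor <- random_spin_sequence(L)
    } else {
      ancestor <- sample_equilibrium_sequence(d, params, n_equil,
                                              seed = seeds[1L],
                                              stall_cap = stall_cap)
    }
  }
  check_spins(ancestor)
  if (length(ancestor) != L) stop("ancestor length must match D")

  node_seqs <- matrix(0L, nrow = n_nodes, ncol = L)
  node_seqs[1L, ] <- as.integer(ancestor)
  logs <- vector("list", n_nodes)
  for (k in 2:n_nodes) {
    parent <- k %/% 2L
    set.seed(seeds[k])
    res <- metropolis_run_cpp(node_seqs[parent, ], d, kappa, params$tau_star,
                              as.integer(mu), stall_cap)
    node_seqs[k, ] <- res$seq
    if (length(res$flips))
      logs[[k]] <- data.frame(node = k, level = floor(log2(k)),
                              order = seq_along(res$flips), site = res$flips)
  }
  mutation_log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  if (is.null(mutation_log))
    mutation_log <- data.frame(node = integer(0), level = integer(0),
                               order = integer(0), site = integer(0))

  leaves <- (2L^n):(2L^(n + 1L) - 1L)
  levels <- floor(log2(seq_len(n_nodes)))
  G <- earliest_mutation_generation(node_seqs, levels, sentinel = n + 1L)

  structure(list(tree = binary_tree_phylo(n, branch_length = mu),
                 node_sequences = node_seqs,
                 leaf_msa = node_seqs[leaves, , drop = FALSE],
                 G = G,
                 mutation_log = mutation_log,
                 mu = mu, n = as.integer(n), neutral = neutral,
                 D = d, params = params, kind = "perfect_binary"),
            class = "phylogeny_record")
}

# Earliest level at which any node's state differs from the root state, per
# site; `sentinel` for sites identical to the root everywhere.
earliest_mutation_generation <- function(node_seqs, levels, sentinel) {
  root <- node_seqs[1L, ]
  L <- ncol(node_seqs)
  G <- rep.int(as.integer(sentinel), L)
  for (g in sort(unique(levels[levels > 0]))) {
    rows <- which(levels == g)
    differs <- colSums(node_seqs[rows, , drop = FALSE] !=
                         matrix(root, length(rows), L, byrow = TRUE)) > 0
    G[differs & G == sentinel] <- g
  }
  G
}

# ape phylo for a perfect binary tree with heap-ordered construction; tips are
# labeled leaf<heap index> in heap order.
binary_tree_phylo <- function(n, branch_length = 1) {
  n_tip <- 2L^n
  n_nodes <- 2L * n_tip - 1L
  heap <- seq_len(n_nodes)
  is_leaf <- heap >= n_tip
  # ape numbering: tips 1..n_tip (heap leaves in order), internals n_tip+1..
  ape_id <- integer(n_nodes)
  ape_id[is_leaf] <- seq_len(n_tip)
  ape_id[!is_leaf] <- n_tip + seq_len(n_tip - 1L)
  children <- 2:n_nodes
  edge <- cbind(ape_id[children %/% 2L], ape_id[children])
  tr <- list(edge = edge,
             tip.label = paste0("leaf", heap[is_leaf]),
             edge.length = rep(branch_length, nrow(edge)),
             Nnode = n_tip - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Evolve an ancestral sequence along an arbitrary newick tree
#'
#' As [evolve_on_binary_tree()], but the topology and branch lengths come from
#' a newick tree (path or `ape::phylo` object) and the number of accepted
#' mutations on each branch is drawn from a Poisson law with mean
#' `rate_constant * branch_length`.
#'
#' @param D effect vector.
#' @param params [selection_params()].
#' @param tree an `ape::phylo` object or a path to a newick file; branch
#'   lengths are required.
#' @param rate_constant accepted mutations per unit branch length (> 0).
#' @inheritParams evolve_on_binary_tree
#' @return A `phylogeny_record`. `node_sequences` rows follow ape node
#'   numbering (tips first); `leaf_msa` rows are in `tree$tip.label` order.
#'   `G` is computed with generation = number of edges from the root, and the
#'   element `mean_m` reports the average root-to-leaf number of accepted
#'   mutations.
#' @export
evolve_on_newick_tree <- function(D, params, tree, rate_constant,
                                  ancestor = NULL, neutral = FALSE,
                                  n_equil = 3000L, seed = NULL,
                                  stall_cap = 1e6) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or newick path")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (rate_constant < 0) stop("rate_constant must be >= 0")
  d <- effect_values(D)
  L <- length(d)
  kappa <- if (neutral) 0 else params$kappa

  tree <- ape::reorder.phylo(tree, "cladewise")
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  seeds <- derive_seeds(seed, n_nodes + 1L)

  if (is.null(ancestor)) {
    if (neutral) {
      set.seed(seeds[1L])
      ancestor <- random_spin_sequence(L)
    } else {
      ancestor <- sample_equilibrium_sequence(d, params, n_equil,
                                              seed = seeds[1L],
                                              stall_cap = stall_cap)
    }
  }
  check_spins(ancestor)
  if (length(ancestor) != L) stop("ancestor length must match D")

  node_seqs <- matrix(0L, nrow = n_nodes, ncol = L)
  node_seqs[root, ] <- as.integer(ancestor)
  depth <- integer(n_nodes); depth[root] <- 0L
  m_count <- numeric(n_nodes) # accepted mutations from root to each node
  logs <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    set.seed(seeds[child + 1L])
    m <- stats::rpois(1L, rate_constant * tree$edge.length[e])
    res <- metropolis_run_cpp(node_seqs[parent, ], d, kappa, params$tau_star,
                              m, stall_cap)
    node_seqs[child, ] <- res$seq
    depth[child] <- depth[parent] + 1L
    m_count[child] <- m_count[parent] + m
    if (length(res$flips))
      logs[[e]] <- data.frame(node = child, level = depth[child],
                              order = seq_along(res$flips), site = res$flips)
  }
  mutation_log <- do.call(rbind, logs[!vapply(logs, is.null, logical(1))])
  if (is.null(mutation_log))
    mutation_log <- data.frame(node = integer(0), level = integer(0),
                               order = integer(0), site = integer(0))

  max_depth <- max(depth)
  levels <- depth
  G <- {
    root_state <- node_seqs[root, ]
    Gv <- rep.int(max_depth + 1L, L)
    for (g in seq_len(max_depth)) {
      rows <- which(levels == g)
      if (!length(rows)) next
      differs <- colSums(node_seqs[rows, , drop = FALSE] !=
                           matrix(root_state, length(rows), L, byrow = TRUE)) > 0
      Gv[differs & Gv == max_depth + 1L] <- g
    }
    Gv
  }

  structure(list(tree = tree,
                 node_sequences = node_seqs,
                 leaf_msa = node_seqs[seq_len(n_tip), , drop = FALSE],
                 G = G,
                 mutation_log = mutation_log,
                 rate_constant = rate_constant,
                 mean_m = mean(m_count[seq_len(n_tip)]),
                 n = max_depth, neutral = neutral,
                 D = d, params = params, kind = "newick"),
            class = "phylogeny_record")
}

#' @export
print.phylogeny_record <- function(x, ...) {
  cat(sprintf("phylogeny_record (%s): %d leaves x %d sites\n",
              x$kind, nrow(x$leaf_msa), ncol(x$leaf_msa)))
  if (x$kind == "perfect_binary")
    cat(sprintf("  n = %d generations, mu = %s accepted mutations/branch%s\n",
                x$n, format(x$mu), if (x$neutral) " (neutral)" else ""))
  else
    cat(sprintf("  max depth %d, rate %s, mean root-to-leaf mutations %.1f\n",
                x$n, format(x$rate_constant), x$mean_m))
  invisible(x)
}

#' Mean pairwise Hamming distance of a binary MSA
#'
#' Average over all unordered sequence pairs of the fraction of sites at which
#' the two sequences differ. Computed in O(ML) via column sums.
#'
#' @param msa M x L spin matrix (-1/+1), or a `phylogeny_record` (its leaf
#'   MSA is used).
#' @return scalar in \[0, 1\].
#' @export
mean_pairwise_hamming <- function(msa) {
  if (inherits(msa, "phylogeny_record")) msa <- msa$leaf_msa
  M <- nrow(msa); L <- ncol(msa)
  if (is.null(M) || M < 2) stop("need at least 2 sequences")
  check_spins(msa)
  s <- colSums(msa)
  mean_dot <- (sum(s^2) - M * L) / (M * (M - 1))
  (L - mean_dot) / (2 * L)
}
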