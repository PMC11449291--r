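# Natural-MSA machinery: gap filtering, Jukes-Cantor phylogenetic cutoffs,
# nearest-neighbor gap imputation, multi-cutoff eigenvector aggregation and
# diversity metrics. Works on character matrices (rows = sequences, rownames
# = identifiers, entries = single letters, "-" = gap).

GAP <- "-"

#' Standard amino-acid alphabet
#' @return character vector of the 20 amino acids (alphabetical one-letter).
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Encode a character MSA as integer states
#'
#' @param msa character matrix.
#' @param alphabet ordered state alphabet; symbols map to `0..q-1`.
#' @return integer matrix; unknown symbols (including gaps if not in the
#'   alphabet) raise an error.
#' @export
encode_msa <- function(msa, alphabet = aa_alphabet()) {
  idx <- match(msa, alphabet) - 1L
  if (anyNA(idx)) stop("MSA contains symbols outside the alphabet")
  matrix(idx, nrow(msa), ncol(msa), dimnames = dimnames(msa))
}

check_char_msa <- function(msa, reference_id = NULL) {
  if (!is.character(msa) || !is.matrix(msa)) stop("expected a character matrix MSA")
  if (!is.null(reference_id) && !(reference_id %in% rownames(msa)))
    stop(sprintf("reference sequence '%s' not found in the MSA", reference_id))
  invisible(TRUE)
}

#' Filter a raw MSA by reference match states and gap content
#'
#' Applies the standard three filters in order: keep only the columns where
#' the reference sequence is non-gap; drop columns with more than
#' `max_col_gap` gaps; drop sequences with more than `max_seq_gap` gaps
#' (computed on the retained columns). The reference is always retained. The
#' operation is idempotent.
#'
#' @param msa character matrix with rownames.
#' @param reference_id rowname of the reference (e.g. DMS wild-type).
#' @param max_col_gap maximal column gap fraction (default 0.3).
#' @param max_seq_gap maximal sequence gap fraction (default 0.2).
#' @return filtered character matrix.
#' @export
filter_msa <- function(msa, reference_id, max_col_gap = 0.3,
                       max_seq_gap = 0.2) {
  check_char_msa(msa, reference_id)
  ref <- msa[reference_id, ]
  msa <- msa[, ref != GAP, drop = FALSE]
  col_gap <- colMeans(msa == GAP)
  msa <- msa[, col_gap <= max_col_gap, drop = FALSE]
  if (ncol(msa) == 0) stop("no columns left after filtering")
  seq_gap <- rowMeans(msa == GAP)
  keep <- seq_gap <= max_seq_gap | rownames(msa) == reference_id
  msa <- msa[keep, , drop = FALSE]
  if (nrow(msa) == 0) stop("no sequences left after filtering")
  msa
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' \eqn{d = -\frac{q-1}{q}\ln\left(1 - \frac{q}{q-1} p\right)} where `p` is
#' the fraction of differing sites among the sites where neither sequence
#' has a gap. Saturated distances (argument of the log <= 0) are capped at
#' `d_max`.
#'
#' @param a,b character vectors of equal length.
#' @param q alphabet size (20 for proteins).
#' @param d_max cap for saturated distances.
#' @return non-negative distance.
#' @export
jukes_cantor_distance <- function(a, b, q = 20, d_max = 10) {
  if (length(a) != length(b)) stop("sequence lengths differ")
  ok <- a != GAP & b != GAP
  if (!any(ok)) stop("no comparable (gap-free in both) sites")
  p <- mean(a[ok] != b[ok])
  arg <- 1 - q * p / (q - 1)
  if (arg <= 0) return(d_max)
  min(-(q - 1) / q * log(arg), d_max)
}

# All pairwise JC distances (used by imputation); small-M helper.
jc_distance_matrix <- function(msa, q = 20, d_max = 10) {
  M <- nrow(msa)
  Dm <- matrix(0, M, M, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      Dm[i, j] <- Dm[j, i] <- jukes_cantor_distance(msa[i, ], msa[j, ],
                                                    q = q, d_max = d_max)
    }
  }
  Dm
}

#' Subsample an MSA at a phylogenetic cutoff
#'
#' Retains the sequences whose Jukes-Cantor distance to the reference is at
#' most `cutoff`. Nested by construction: smaller cutoffs give subsets of
#' larger ones. The standard cutoff grid for multi-depth analyses is
#' `c(0.4, 0.6, 0.8, seq(0.9, 2.0, by = 0.1))` (15 MSAs).
#'
#' @param msa character matrix with rownames.
#' @param cutoff maximal Jukes-Cantor distance to the reference.
#' @param reference_id rowname of the reference sequence.
#' @inheritParams jukes_cantor_distance
#' @return character matrix (the reference is always included).
#' @export
cutoff_subsample <- function(msa, cutoff, reference_id, q = 20, d_max = 10) {
  check_char_msa(msa, reference_id)
  ref <- msa[reference_id, ]
  d <- apply(msa, 1, jukes_cantor_distance, b = ref, q = q, d_max = d_max)
  out <- msa[d <= cutoff, , drop = FALSE]
  if (nrow(out) == 0) stop("no sequences within the cutoff")
  out
}

#' Default phylogenetic cutoff grid
#' @return numeric vector of 15 Jukes-Cantor cutoffs.
#' @export
default_cutoff_grid <- function() c(0.4, 0.6, 0.8, seq(0.9, 2.0, by = 0.1))

#' Impute gaps from the nearest sequence
#'
#' Replaces every gap by the state carried at the same site by the nearest
#' sequence (Jukes-Cantor distance) that is non-gap there. Ties are broken
#' by smallest row index, making the result deterministic. Non-gap symbols
#' are never altered.
#'
#' @param msa character matrix.
#' @inheritParams jukes_cantor_distance
#' @return gap-free character matrix.
#' @export
impute_gaps_nearest <- function(msa, q = 20, d_max = 10) {
  check_char_msa(msa)
  gaps <- which(msa == GAP, arr.ind = TRUE)
  if (nrow(gaps) == 0) return(msa)
  Dm <- jc_distance_matrix(msa, q = q, d_max = d_max)
  diag(Dm) <- Inf
  out <- msa
  for (k in seq_len(nrow(gaps))) {
    m <- gaps[k, 1]; j <- gaps[k, 2]
    donors <- which(msa[, j] != GAP)
    if (!length(donors))
      stop(sprintf("site %d is gapped in every sequence; cannot impute", j))
    best <- donors[order(Dm[m, donors], donors)][1]
    out[m, j] <- msa[best, j]
  }
  out
}

#' Aggregate per-cutoff eigenvectors into one score vector
#'
#' Eigenvectors computed on MSAs at different phylogenetic cutoffs are
#' sign-aligned (flipped when their Pearson correlation with the first
#' vector is negative) and summed component by component. The overall sign
#' of the sum remains arbitrary; downstream scoring uses absolute values.
#'
#' @param vectors list of numeric vectors of equal length.
#' @return numeric vector (componentwise sum after sign alignment).
#' @export
aggregate_eigenvectors <- function(vectors) {
  if (!length(vectors)) stop("need at least one vector")
  L <- length(vectors[[1]])
  if (any(vapply(vectors, length, integer(1)) != L))
    stop("vectors must have equal lengths")
  ref <- vectors[[1]]
  out <- ref
  for (v in vectors[-1]) {
    cc <- suppressWarnings(stats::cor(ref, v))
    if (!is.na(cc) && cc < 0) v <- -v
    out <- out + v
  }
  out
}

#' Mean pairwise Hamming distance of a categorical MSA
#'
#' @param msa character (or integer) matrix, M >= 2 rows.
#' @return mean over unordered pairs of the fraction of differing sites.
#' @export
mean_pairwise_hamming_protein <- function(msa) {
  M <- nrow(msa)
  if (is.null(M) || M < 2) stop("need at least 2 sequences")
  tot <- 0
  for (i in seq_len(M - 1)) {
    block <- msa[(i + 1):M, , drop = FALSE] !=
      matrix(msa[i, ], M - i, ncol(msa), byrow = TRUE)
    tot <- tot + sum(rowMeans(block))
  }
  tot / (M * (M - 1) / 2)
}

#' Effective depth of an MSA
#'
#' Diversity-corrected number of sequences,
#' \eqn{M_{eff} = \sum_m 1/n_m}, where \eqn{n_m} counts the sequences
#' (including `m` itself) whose normalized Hamming distance to sequence `m`
#' is below `theta`.
#'
#' @param msa character or integer matrix.
#' @param theta Hamming-distance lumping threshold (default 0.2).
#' @return scalar in \[1, M\].
#' @export
effective_depth <- function(msa, theta = 0.2) {
  M <- nrow(msa)
  if (is.null(M) || M < 2) stop("need at least 2 sequences")
  n_m <- integer(M)
  for (i in seq_len(M)) {
    d <- rowMeans(msa != matrix(msa[i, ], M, ncol(msa), byrow = TRUE))
    n_m[i] <- sum(d < theta)
  }
  sum(1 / n_m)
}

#' Overlap of two methods' top-site predictions against ground truth
#'
#' Given the top-`L_S` site sets predicted by two methods and the
#' ground-truth important sites, counts the true positives found by both
#' methods, by the first only, and by the second only.
#'
#' @param sites_a,sites_b integer site sets (top-`L_S` by each method).
#' @param truth integer set of ground-truth important sites.
#' @return named integer vector `c(both, only_a, only_b)`.
#' @export
overlap_counts <- function(sites_a, sites_b, truth) {
  both <- length(intersect(intersect(sites_a, sites_b), truth))
  only_a <- length(intersect(setdiff(sites_a, sites_b), truth))
  only_b <- length(intersect(setdiff(sites_b, sites_a), truth))
  c(both = both, only_a = only_a, only_b = only_b)
}

#' Top sites of a score vector
#'
#' Ranks sites by absolute score, ties broken by site index.
#'
#' @param v numeric site scores.
#' @param k number of sites to return.
#' @return integer vector of site indices.
#' @export
top_sites <- function(v, k) {
  if (k > length(v)) stop("k exceeds the number of sites")
  order(-abs(v), seq_along(v))[seq_len(k)]
}
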