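# Serialization: spin MSAs as FASTA ('A' = -1, 'B' = +1) or CSV of +/-1;
# phylogeny records as a plain-text directory bundle.

SPIN_CHARS <- c(`-1` = "A", `1` = "B")

#' Write a binary (spin) MSA to FASTA
#'
#' Spins are encoded as characters: -1 as 'A', +1 as 'B' (mapping recorded in
#' the first header comment).
#'
#' @param msa M x L spin matrix.
#' @param path output file.
#' @param ids optional sequence identifiers (default `seq1..seqM`).
#' @export
write_binary_fasta <- function(msa, path, ids = NULL) {
  check_spins(msa)
  M <- nrow(msa)
  if (is.null(ids)) ids <- paste0("seq", seq_len(M))
  chars <- matrix(SPIN_CHARS[as.character(msa)], M, ncol(msa))
  seqs <- apply(chars, 1, paste0, collapse = "")
  names(seqs) <- ids
  names(seqs)[1] <- paste0(ids[1], " spin_coding=A:-1,B:+1")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a binary (spin) MSA from FASTA
#'
#' @param path FASTA file written by [write_binary_fasta()] ('A' = -1,
#'   'B' = +1).
#' @return M x L spin matrix with sequence ids as rownames.
#' @export
read_binary_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  chars <- do.call(rbind, strsplit(as.character(ss), ""))
  if (!all(chars %in% c("A", "B"))) stop("expected only A/B characters")
  msa <- matrix(ifelse(chars == "A", -1L, 1L), nrow(chars), ncol(chars))
  rownames(msa) <- sub(" .*", "", names(ss))
  msa
}

#' Read a character (protein) MSA from FASTA
#'
#' @param path FASTA file.
#' @return character matrix (rows = sequences, rownames = ids).
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  chars <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(chars) <- sub(" .*", "", names(ss))
  chars
}

#' Write a character (protein) MSA to FASTA
#'
#' @param msa character matrix with rownames.
#' @param path output file.
#' @export
write_protein_fasta <- function(msa, path) {
  seqs <- apply(msa, 1, paste0, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Serialize a phylogeny record to a directory
#'
#' Writes `tree.nwk`, `leaves.fasta`, `internal_nodes.fasta`, `G.csv` and
#' `mutation_log.csv` (all plain text) into `dir`.
#'
#' @param record `phylogeny_record`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phylogeny_record <- function(record, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(record$tree, file.path(dir, "tree.nwk"))
  n_leaf <- nrow(record$leaf_msa)
  n_nodes <- nrow(record$node_sequences)
  leaf_rows <- if (record$kind == "perfect_binary")
    (n_nodes - n_leaf + 1L):n_nodes else seq_len(n_leaf)
  internal_rows <- setdiff(seq_len(n_nodes), leaf_rows)
  write_binary_fasta(record$leaf_msa, file.path(dir, "leaves.fasta"),
                     ids = paste0("leaf", leaf_rows))
  write_binary_fasta(record$node_sequences[internal_rows, , drop = FALSE],
                     file.path(dir, "internal_nodes.fasta"),
                     ids = paste0("node", internal_rows))
  utils::write.csv(data.frame(site = seq_along(record$G), G = record$G),
                   file.path(dir, "G.csv"), row.names = FALSE)
  utils::write.csv(record$mutation_log, file.path(dir, "mutation_log.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a site-score matrix to CSV
#'
#' @param mat L x L matrix.
#' @param path output file; header row/column are site indices.
#' @export
write_score_matrix <- function(mat, path) {
  df <- as.data.frame(as.matrix(unclass_matrix(mat)))
  names(df) <- seq_len(ncol(df))
  utils::write.csv(cbind(site = seq_len(nrow(df)), df), path,
                   row.names = FALSE)
  invisible(path)
}
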