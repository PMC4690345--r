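# Independent oracles and fixture builders shared by the test files.
# Everything here goes through utils::adist (generalised unit-cost
# Levenshtein distance) or plain enumeration, never through the package's
# own microvariant machinery.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

lv <- function(a, b) utils::adist(a, b)

# all DNA strings of a given length (L = 0 gives the empty string)
all_kmers <- function(L) {
  if (L <= 0) return("")
  do.call(paste0, rev(expand.grid(rep(list(BASES), L),
                                  stringsAsFactors = FALSE)))
}

# brute-force set of strings at Levenshtein distance exactly 1:
# enumerate every candidate of length L-1, L, L+1 and measure
brute_d1_set <- function(s) {
  L <- nchar(s)
  cands <- unique(unlist(lapply((L - 1):(L + 1), all_kmers)))
  cands[drop(utils::adist(s, cands)) == 1]
}

# one random edit, independent of the package's generator
rand_edit <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  op <- sample(if (L > 1) 1:3 else c(1, 2), 1)
  if (op == 1) { # substitution
    i <- sample.int(L, 1)
    ch[i] <- sample(BASES[BASES != ch[i]], 1)
  } else if (op == 2) { # insertion
    i <- sample.int(L + 1, 1)
    ch <- append(ch, sample(BASES, 1), after = i - 1)
  } else { # deletion
    ch <- ch[-sample.int(L, 1)]
  }
  paste(ch, collapse = "")
}

# records for a pool that actually contains 1- and 2-edit relatives:
# a few random roots, then sequences derived from random existing members
# by 1-2 edits, deduplicated, with random abundances
perturbed_records <- function(n, len_range = c(20, 60), n_roots = NULL) {
  if (is.null(n_roots)) n_roots <- max(2L, n %/% 10L)
  seqs <- replicate(min(n_roots, n),
                    rand_dna(sample(len_range[1]:len_range[2], 1)))
  seqs <- unique(seqs)
  guard <- 0
  while (length(seqs) < n && guard < 50 * n) {
    guard <- guard + 1
    cand <- rand_edit(sample(seqs, 1))
    if (sample(c(TRUE, FALSE), 1)) cand <- rand_edit(cand)
    if (nzchar(cand) && !cand %in% seqs) seqs <- c(seqs, cand)
  }
  data.frame(id = sprintf("amp%04d", seq_along(seqs)),
             sequence = seqs,
             abundance = sample(1:100, length(seqs), replace = TRUE),
             stringsAsFactors = FALSE)
}

# partition of pool sequences into connected components of the
# "Levenshtein distance <= d" graph, computed by brute force
brute_components <- function(seqs, d) {
  dm <- utils::adist(seqs, seqs)
  g <- igraph::graph_from_adjacency_matrix(dm <= d, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  canonical_partition(split(seqs, comp))
}

# canonical form of a partition: each block a sorted character vector,
# blocks ordered by their first element
canonical_partition <- function(blocks) {
  blocks <- lapply(blocks, function(b) unname(sort(as.character(b))))
  unname(blocks[order(vapply(blocks, `[`, character(1), 1))])
}

# clustering result as a canonical partition of sequences
result_partition <- function(result, pool) {
  canonical_partition(lapply(result$otus, function(o) {
    pool$amplicons$sequence[o$members$pos]
  }))
}

# ground-truth community partition as sequences
truth_partition <- function(community) {
  canonical_partition(split(community$records$sequence,
                            community$truth$otu))
}
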