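.check_dna <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("`sequence` must be a single DNA string", call. = FALSE)
  }
  if (!nzchar(sequence)) {
    stop("`sequence` must be non-empty", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("`sequence` must contain only A/C/G/T", call. = FALSE)
  }
  sequence
}

#' Enumerate all microvariants of a sequence
#'
#' A microvariant is a sequence at unit-cost edit distance exactly 1 from the
#' original: one substitution (3 per position), one deletion (1 per position)
#' or one insertion (4 per gap, L + 1 gaps). Different edits can produce the
#' same string (e.g. inserting G before or after a G), so the result is
#' deduplicated; for a sequence of length L it holds 6L + 5 to 7L + 4 distinct
#' strings, the minimum being reached by homopolymers. Deleting the single
#' base of a length-1 sequence yields the empty string, which is kept: it is
#' a legitimate 1-edit neighbour and can never collide with a pool sequence
#' (pool sequences are non-empty).
#'
#' Neighbour search at d = 1 rests on this enumeration: instead of aligning an
#' amplicon against every other amplicon, the engine generates its
#' microvariants and looks each one up in the pool's exact-string index.
#'
#' @param sequence A non-empty string over A/C/G/T.
#' @return Character vector of distinct microvariants (order unspecified;
#'   treat as a set). The origin itself is never included.
#' @examples
#' sort(enumerate_microvariants("G"))
#' length(enumerate_microvariants("AG"))  # 18 = 7*2 + 4
#' @export
enumerate_microvariants <- function(sequence) {
  .check_dna(sequence)
  bases <- c("A", "C", "G", "T")
  L <- nchar(sequence)
  pos <- seq_len(L)
  pre <- substring(sequence, 1L, pos - 1L)
  post <- substring(sequence, pos + 1L, L)
  ch <- substring(sequence, pos, pos)

  sub_base <- unlist(lapply(ch, function(x) bases[bases != x]),
                     use.names = FALSE)
  subs <- paste0(rep.int(pre, rep.int(3L, L)), sub_base,
                 rep.int(post, rep.int(3L, L)))
  dels <- unique(paste0(pre, post))

  gap <- 0:L
  gpre <- substring(sequence, 1L, gap)
  gpost <- substring(sequence, gap + 1L, L)
  ins <- unique(paste0(rep.int(gpre, rep.int(4L, L + 1L)), bases,
                       rep.int(gpost, rep.int(4L, L + 1L))))

  # substitutions are pairwise distinct and the three length classes cannot
  # collide, so only deletions and insertions needed in-class deduplication
  c(subs, dels, ins)
}

#' Count distinct microvariants in closed form
#'
#' The number of distinct microvariants of a sequence of length L depends
#' only on its number of homopolymer runs r: all 3L substitutions are
#' distinct, the deletions collapse to one per run, and one-base insertions
#' always yield 3L + 4 distinct strings, giving 6L + 4 + r in total. This
#' ranges from 6L + 5 (a pure homopolymer, r = 1) to 7L + 4 (no two adjacent
#' bases equal, r = L).
#'
#' @param sequence A non-empty string over A/C/G/T.
#' @return Integer count, equal to `length(enumerate_microvariants(sequence))`.
#' @examples
#' microvariant_count(strrep("G", 130))  # 785, the minimum for L = 130
#' microvariant_count(strrep("AC", 65))  # 914, the maximum for L = 130
#' @export
microvariant_count <- function(sequence) {
  .check_dna(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  runs <- 1L + sum(ch[-1L] != ch[-L])
  as.integer(6L * L + 4L + runs)
}

#' Bounds on the number of microvariants
#'
#' @param length Sequence length L (positive integer).
#' @return Named integer vector `c(min = 6L + 5, max = 7L + 4)`.
#' @examples
#' count_bounds(130)  # c(min = 785, max = 914)
#' @export
count_bounds <- function(length) {
  if (!is.numeric(length) || base::length(length) != 1L || is.na(length) ||
      length != as.integer(length) || length < 1) {
    stop("`length` must be a single integer >= 1", call. = FALSE)
  }
  L <- as.integer(length)
  c(min = 6L * L + 5L, max = 7L * L + 4L)
}
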