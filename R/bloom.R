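#' Bloom filter for sequence membership
#'
#' A space-efficient probabilistic set used to screen microvariant
#' candidates during fastidious grafting. Membership tests can yield false
#' positives (at roughly `fp_rate`) but never false negatives: every inserted
#' string always tests positive. A positive answer is therefore only a
#' candidate and every grafting decision is confirmed by an exact lookup.
#'
#' The number of bits is `-capacity * log(fp_rate) / log(2)^2` unless
#' `bits_per_entry` is given, in which case `capacity * bits_per_entry` bits
#' are allocated — shrinking `bits_per_entry` trades accuracy (more false
#' positives to screen out, hence more time) for memory. The number of hash
#' functions is the usual optimum `m/n * log(2)`; indices are derived by
#' double hashing from two independent polynomial string hashes.
#'
#' @param capacity Expected number of distinct strings to insert.
#' @param fp_rate Target false-positive probability (default 0.01).
#' @param bits_per_entry Optional override of the bits allocated per
#'   expected entry.
#' @return An object of class `bloom_filter` (environment; mutated in place
#'   by [bloom_add()]).
#' @examples
#' bf <- bloom_filter(1000)
#' bloom_add(bf, c("ACGT", "TTTT"))
#' bloom_contains(bf, c("ACGT", "GGGG"))
#' @export
bloom_filter <- function(capacity, fp_rate = 0.01, bits_per_entry = NULL) {
  stopifnot(is.numeric(capacity), length(capacity) == 1L, capacity >= 1,
            is.numeric(fp_rate), fp_rate > 0, fp_rate < 1)
  if (is.null(bits_per_entry)) {
    m <- ceiling(-capacity * log(fp_rate) / log(2)^2)
  } else {
    stopifnot(is.numeric(bits_per_entry), bits_per_entry >= 1)
    m <- ceiling(capacity * bits_per_entry)
  }
  m <- max(64, m)
  k <- max(1L, as.integer(round(m / capacity * log(2))))
  bf <- new.env(parent = emptyenv())
  bf$bits <- logical(m)
  bf$m <- m
  bf$k <- k
  bf$n_added <- 0
  class(bf) <- "bloom_filter"
  bf
}

#' @export
print.bloom_filter <- function(x, ...) {
  cat("<bloom_filter> ", x$m, " bits, ", x$k, " hash functions, ",
      x$n_added, " insertions\n", sep = "")
  invisible(x)
}

# Polynomial rolling hash, vectorised over strings. Characters are folded in
# one position at a time so the cost is O(max length) vector operations. The
# modulus keeps intermediate products below 2^53, so arithmetic stays exact
# in doubles. The string length is folded in last to separate prefixes.
.string_hash <- function(x, mult, mod) {
  n <- length(x)
  h <- numeric(n)
  if (!n) return(h)
  len <- nchar(x)
  maxlen <- max(len)
  for (j in seq_len(maxlen)) {
    live <- len >= j
    code <- match(substring(x[live], j, j), LETTERS, nomatch = 27L)
    h[live] <- (h[live] * mult + code) %% mod
  }
  (h * mult + len + 1) %% mod
}

.bloom_positions <- function(bf, x) {
  h1 <- .string_hash(x, 31, 2147483647)
  h2 <- .string_hash(x, 131, 2147483629)
  # double hashing: k slots per string, matrix k x length(x)
  i <- seq_len(bf$k) - 1L
  pos <- outer(i, h2) + rep(h1, each = bf$k)
  (pos %% bf$m) + 1
}

#' @rdname bloom_filter
#' @param bf A `bloom_filter`.
#' @param x Character vector of strings to insert or test.
#' @export
bloom_add <- function(bf, x) {
  if (!length(x)) return(invisible(bf))
  bf$bits[.bloom_positions(bf, x)] <- TRUE
  bf$n_added <- bf$n_added + length(x)
  invisible(bf)
}

#' @rdname bloom_filter
#' @return `bloom_contains` returns a logical vector: `FALSE` is definitive,
#'   `TRUE` is a candidate that needs exact confirmation.
#' @export
bloom_contains <- function(bf, x) {
  if (!length(x)) return(logical(0))
  pos <- .bloom_positions(bf, x)
  colSums(matrix(bf$bits[pos], nrow = bf$k)) == bf$k
}
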