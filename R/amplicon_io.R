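#' Abundance annotation dialect
#'
#' Amplicon FASTA headers carry the read count of each dereplicated sequence
#' either as a trailing underscore suffix (`>id_123`) or as a usearch-style
#' size annotation (`>id;size=123` or `>id;size=123;`). A dialect object
#' records which convention to expect and, optionally, a default abundance to
#' assume when a header carries no annotation at all.
#'
#' @param style `"underscore"` (default) or `"size_annotation"`.
#' @param default_abundance Positive integer used for records lacking an
#'   annotation, or `NULL` (the default) to treat a missing annotation as an
#'   error.
#' @return An object of class `abundance_dialect`.
#' @examples
#' abundance_dialect()
#' abundance_dialect("size_annotation", default_abundance = 1)
#' @export
abundance_dialect <- function(style = c("underscore", "size_annotation"),
                              default_abundance = NULL) {
  style <- match.arg(style)
  if (!is.null(default_abundance)) {
    if (length(default_abundance) != 1L || is.na(default_abundance) ||
        default_abundance != as.integer(default_abundance) ||
        default_abundance < 1) {
      stop("`default_abundance` must be a single positive integer or NULL",
           call. = FALSE)
    }
    default_abundance <- as.numeric(default_abundance)
  }
  structure(list(style = style, default_abundance = default_abundance),
            class = "abundance_dialect")
}

#' @export
print.abundance_dialect <- function(x, ...) {
  cat("<abundance_dialect> style:", x$style, "default:",
      if (is.null(x$default_abundance)) "none (annotation required)"
      else format(x$default_abundance), "\n")
  invisible(x)
}

.as_dialect <- function(dialect) {
  if (inherits(dialect, "abundance_dialect")) return(dialect)
  if (is.character(dialect)) return(abundance_dialect(dialect))
  stop("`dialect` must be an abundance_dialect object", call. = FALSE)
}

# Split annotated headers into (id, abundance). Returns abundance NA where no
# annotation is present; the caller decides whether that is an error.
.strip_annotation <- function(ids, style) {
  if (style == "underscore") {
    m <- regexpr("_([0-9]+)$", ids)
    ab <- rep(NA_real_, length(ids))
    hit <- m > 0L
    ab[hit] <- as.numeric(sub("^_", "", regmatches(ids, m)))
    ids[hit] <- substr(ids[hit], 1L, m[hit] - 1L)
  } else {
    m <- regexpr(";size=[0-9]+;?", ids)
    ab <- rep(NA_real_, length(ids))
    hit <- m > 0L
    ab[hit] <- as.numeric(gsub("[^0-9]", "", regmatches(ids, m)))
    ids[hit] <- sub(";size=[0-9]+;?", "", ids[hit])
    ids <- sub(";$", "", ids)
  }
  list(id = ids, abundance = ab)
}

#' Read an amplicon FASTA file
#'
#' Parses a (possibly line-wrapped, mixed-case) FASTA file of amplicons and
#' extracts the per-record abundance from the header according to `dialect`.
#' The identifier is the first whitespace-delimited token of the header with
#' the abundance annotation removed.
#'
#' Sequences are uppercased and must consist solely of A, C, G and T; any
#' other character (including IUPAC ambiguity codes such as N, and U from RNA)
#' is a hard error naming the offending record, because silently dropping or
#' rewriting reads would distort downstream abundances.
#'
#' @param path Path to a FASTA file.
#' @param dialect An [abundance_dialect()] (or a style string).
#' @return A data frame of amplicon records with columns `id`, `sequence` and
#'   `abundance`, in file order, one row per input record (not dereplicated).
#' @seealso [build_pool()] to dereplicate, sort and index the records.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a_5", "ACGT", ">b_2", "acgt"), fa)
#' parse_fasta(fa)
#' @export
parse_fasta <- function(path, dialect = abundance_dialect()) {
  dialect <- .as_dialect(dialect)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  if (is.null(headers)) headers <- character(0)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL

  ann <- .strip_annotation(ids, dialect$style)
  missing <- is.na(ann$abundance)
  if (any(missing)) {
    if (is.null(dialect$default_abundance)) {
      stop("record '", ids[which(missing)[1L]],
           "' has no abundance annotation and no default abundance is set",
           call. = FALSE)
    }
    ann$abundance[missing] <- dialect$default_abundance
  }
  bad_ab <- ann$abundance < 1
  if (any(bad_ab)) {
    stop("record '", ann$id[which(bad_ab)[1L]],
         "' has abundance ", ann$abundance[which(bad_ab)[1L]],
         "; abundances must be positive integers", call. = FALSE)
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("record '", ann$id[which(empty)[1L]], "' has an empty sequence",
         call. = FALSE)
  }
  bad_chr <- grepl("[^ACGT]", seqs)
  if (any(bad_chr)) {
    i <- which(bad_chr)[1L]
    chr <- regmatches(seqs[i], regexpr("[^ACGT]", seqs[i]))
    stop("record '", ann$id[i], "' contains non-ACGT character '", chr,
         "'; ambiguous bases and RNA alphabets are not accepted",
         call. = FALSE)
  }
  data.frame(id = ann$id, sequence = seqs, abundance = ann$abundance,
             stringsAsFactors = FALSE)
}

#' Format an annotated identifier
#'
#' @param id Identifier(s) without annotation.
#' @param abundance Abundance value(s).
#' @param dialect An [abundance_dialect()] or style string.
#' @return Character vector of annotated identifiers.
#' @examples
#' annotate_id("seed", 50)
#' annotate_id("seed", 50, "size_annotation")
#' @export
annotate_id <- function(id, abundance, dialect = abundance_dialect()) {
  dialect <- .as_dialect(dialect)
  if (dialect$style == "underscore") {
    paste0(id, "_", format(abundance, scientific = FALSE, trim = TRUE))
  } else {
    paste0(id, ";size=", format(abundance, scientific = FALSE, trim = TRUE))
  }
}

.new_pool <- function(df) {
  stopifnot(is.data.frame(df))
  if (nrow(df)) {
    # strictly non-increasing abundance; ties broken by ascending sequence so
    # the pool order never depends on input order
    o <- order(-df$abundance, df$sequence, method = "radix")
    df <- df[o, , drop = FALSE]
  }
  rownames(df) <- NULL
  index <- new.env(hash = TRUE, parent = emptyenv(),
                   size = max(29L, nrow(df)))
  if (nrow(df)) {
    list2env(stats::setNames(as.list(seq_len(nrow(df))), df$sequence),
             envir = index)
  }
  structure(list(amplicons = df, index = index), class = "amplicon_pool")
}

#' Dereplicate amplicon records into a pool
#'
#' Merges strictly identical sequences: the merged abundance is the sum of the
#' member abundances and the merged identifier is that of the most abundant
#' member (ties broken by first occurrence). This is exactly the d = 0
#' clustering mode. The resulting pool is sorted by decreasing abundance with
#' ties broken by ascending lexicographic sequence order, and indexed for
#' exact-string lookup.
#'
#' @param records Data frame with columns `id`, `sequence`, `abundance`
#'   (as returned by [parse_fasta()]).
#' @return An `amplicon_pool` object.
#' @examples
#' recs <- data.frame(id = c("a", "b", "c"),
#'                    sequence = c("ACGT", "ACGT", "AAAA"),
#'                    abundance = c(3, 2, 1))
#' dereplicate(recs)
#' @export
dereplicate <- function(records) {
  records <- .check_records(records)
  if (!nrow(records)) {
    return(.new_pool(records))
  }
  totals <- rowsum(records$abundance, group = records$sequence)
  # representative id: highest abundance first, then first occurrence
  o <- order(-records$abundance, seq_len(nrow(records)), method = "radix")
  lead <- records[o, , drop = FALSE]
  lead <- lead[!duplicated(lead$sequence), , drop = FALSE]
  df <- data.frame(id = lead$id,
                   sequence = lead$sequence,
                   abundance = totals[lead$sequence, 1L],
                   stringsAsFactors = FALSE)
  .new_pool(df)
}

.check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence", "abundance") %in% names(records))) {
    stop("`records` must be a data frame with columns id, sequence, abundance",
         call. = FALSE)
  }
  records
}

#' Build the clustering pool
#'
#' @param records Parsed amplicon records (see [parse_fasta()]).
#' @param assume_dereplicated If `TRUE`, duplicate sequences in the input are
#'   a hard error (the caller asserts that dereplication already happened);
#'   otherwise [dereplicate()] is applied first. Sorting and indexing are
#'   always enforced.
#' @return An `amplicon_pool` object.
#' @export
build_pool <- function(records, assume_dereplicated = FALSE) {
  records <- .check_records(records)
  if (assume_dereplicated) {
    dup <- which(duplicated(records$sequence))
    if (length(dup)) {
      j <- dup[1L]
      i <- match(records$sequence[j], records$sequence)
      stop("input declared dereplicated but records '", records$id[i],
           "' and '", records$id[j], "' share the same sequence",
           call. = FALSE)
    }
    .new_pool(records)
  } else {
    dereplicate(records)
  }
}

#' @export
print.amplicon_pool <- function(x, ...) {
  n <- nrow(x$amplicons)
  cat("<amplicon_pool> ", n, " unique amplicons, ",
      format(sum(x$amplicons$abundance), scientific = FALSE),
      " reads\n", sep = "")
  if (n) {
    utils::head(x$amplicons, 5L) |> print()
    if (n > 5L) cat("... and", n - 5L, "more\n")
  }
  invisible(x)
}

#' @export
length.amplicon_pool <- function(x) nrow(x$amplicons)

#' Look up pool positions by exact sequence
#'
#' @param pool An `amplicon_pool`.
#' @param sequences Character vector of sequences.
#' @return Integer vector of pool positions, `NA` where absent.
#' @keywords internal
#' @export
pool_lookup <- function(pool, sequences) {
  if (!length(sequences)) return(integer(0))
  hits <- mget(sequences, envir = pool$index,
               ifnotfound = list(NA_integer_))
  as.integer(unlist(hits, use.names = FALSE))
}

#' Write amplicon records or a pool as annotated FASTA
#'
#' Sequences are written on a single line each, headers annotated with the
#' abundance in the chosen dialect.
#'
#' @param x An `amplicon_pool` or a record data frame.
#' @param path Output file path (or connection).
#' @param dialect An [abundance_dialect()] or style string.
#' @return Invisibly, the path.
#' @export
write_amplicon_fasta <- function(x, path, dialect = abundance_dialect()) {
  dialect <- .as_dialect(dialect)
  df <- if (inherits(x, "amplicon_pool")) x$amplicons else .check_records(x)
  lines <- character(0)
  if (nrow(df)) {
    lines <- as.vector(rbind(
      paste0(">", annotate_id(df$id, df$abundance, dialect)),
      df$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}
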