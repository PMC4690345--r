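#' Specification of a synthetic amplicon community
#'
#' Describes a community of `n_true_otus` abundant seed sequences, each
#' surrounded by rarer satellite sequences derived from it by a fixed number
#' of edits — the "abundant amplicon with a halo of rare microvariants"
#' structure typical of dereplicated marker-gene data. Seeds are placed
#' pairwise more than `2 * (max_edits + 1)` edits apart so that no path of
#' satellites (and, for `max_edits = 2`, no virtual linking amplicon) can
#' connect two ground-truth OTUs.
#'
#' Satellite abundances follow a geometric decay from the seed abundance
#' (`floor(seed_abundance * abundance_ratio^k)` for the k-th satellite, never
#' below 1) when `max_edits = 1`; the decay keeps abundances monotone along
#' every attachment path, so the chain-breaking gate stays inactive inside
#' true OTUs and clustering recovery isolates the linkage machinery alone.
#' When `max_edits = 2` every satellite is instead a singleton (abundance 1):
#' such satellites are invisible to d = 1 linkage, form light OTUs on their
#' own, and are recovered exactly by the fastidious graft.
#'
#' @param n_true_otus Number of ground-truth OTUs (default 4).
#' @param seed_length Length of the seed sequences (default 130 nt, a
#'   typical short hypervariable-region amplicon).
#' @param satellites_per_otu Satellites derived from each seed (default 5).
#' @param max_edits Edits separating each satellite from its seed: 1
#'   (recoverable by plain d = 1 clustering) or 2 (recoverable only with
#'   the fastidious option).
#' @param seed_abundance Abundance of each seed (default 100; must be > 1).
#' @param abundance_ratio Geometric decay ratio in (0, 1) for satellite
#'   abundances (default 0.5).
#' @param rng_seed Integer seed making the community fully reproducible.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_true_otus = 4, seed_length = 130,
                           satellites_per_otu = 5, max_edits = 1,
                           seed_abundance = 100, abundance_ratio = 0.5,
                           rng_seed = 1) {
  stopifnot(n_true_otus >= 1, seed_length >= 1, satellites_per_otu >= 0,
            max_edits %in% c(1, 2), seed_abundance > 1,
            abundance_ratio > 0, abundance_ratio < 1)
  structure(list(n_true_otus = as.integer(n_true_otus),
                 seed_length = as.integer(seed_length),
                 satellites_per_otu = as.integer(satellites_per_otu),
                 max_edits = as.integer(max_edits),
                 seed_abundance = as.numeric(seed_abundance),
                 abundance_ratio = abundance_ratio,
                 rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

.random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# one random edit; op chosen among substitution / insertion / deletion
.random_edit <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  bases <- c("A", "C", "G", "T")
  op <- sample(if (L > 1L) c("sub", "ins", "del") else c("sub", "ins"), 1L)
  if (op == "sub") {
    i <- sample.int(L, 1L)
    ch[i] <- sample(bases[bases != ch[i]], 1L)
  } else if (op == "del") {
    ch <- ch[-sample.int(L, 1L)]
  } else {
    i <- sample.int(L + 1L, 1L)
    ch <- append(ch, sample(bases, 1L), after = i - 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic amplicon community with known ground truth
#'
#' Draws seed sequences and satellites according to `spec`, checking every
#' construction constraint explicitly: seeds pairwise more than
#' `2 * (max_edits + 1)` edits apart, each satellite at exactly `max_edits`
#' edits from its seed, all sequences distinct, and (for `max_edits = 2`)
#' each satellite at distance at least 2 from every other sequence so that
#' plain d = 1 clustering must leave it behind. Generation is fully
#' deterministic given `spec$rng_seed` and does not disturb the caller's
#' random number stream.
#'
#' @param spec A [community_spec()].
#' @return List of class `amplicon_community` with elements
#'   * `records`: data frame `id`, `sequence`, `abundance` ready for
#'     [build_pool()] or [write_amplicon_fasta()];
#'   * `truth`: data frame `id`, `otu` giving the ground-truth partition;
#'   * `spec`: the input specification.
#' @examples
#' com <- generate_community(community_spec(n_true_otus = 2, rng_seed = 42))
#' head(com$records)
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$rng_seed)

  min_sep <- 2L * (spec$max_edits + 1L)
  seeds <- character(0)
  tries <- 0L
  while (length(seeds) < spec$n_true_otus) {
    tries <- tries + 1L
    if (tries > 100L * spec$n_true_otus) {
      stop("could not place ", spec$n_true_otus, " seeds of length ",
           spec$seed_length, " pairwise more than ", min_sep,
           " edits apart; the specification is infeasible", call. = FALSE)
    }
    cand <- .random_dna(spec$seed_length)
    if (!length(seeds) || min(utils::adist(cand, seeds)) > min_sep) {
      seeds <- c(seeds, cand)
    }
  }

  ids <- sprintf("otu%02d", seq_len(spec$n_true_otus))
  records <- data.frame(id = ids, sequence = seeds,
                        abundance = rep(spec$seed_abundance,
                                        spec$n_true_otus),
                        stringsAsFactors = FALSE)
  truth_otu <- seq_len(spec$n_true_otus)

  for (i in seq_len(spec$n_true_otus)) {
    for (k in seq_len(spec$satellites_per_otu)) {
      sat <- NULL
      for (try in seq_len(200L)) {
        cand <- seeds[i]
        for (e in seq_len(spec$max_edits)) cand <- .random_edit(cand)
        if (utils::adist(cand, seeds[i]) != spec$max_edits) next
        if (cand %in% records$sequence) next
        if (spec$max_edits == 2L) {
          # must be out of d = 1 reach of everything already in the pool
          others <- records$sequence[records$sequence != seeds[i]]
          if (length(others) && min(utils::adist(cand, others)) < 2) next
        }
        sat <- cand
        break
      }
      if (is.null(sat)) {
        stop("could not place satellite ", k, " of OTU ", i,
             " after bounded retries; the specification is infeasible",
             call. = FALSE)
      }
      ab <- if (spec$max_edits == 1L) {
        max(1, floor(spec$seed_abundance * spec$abundance_ratio^k))
      } else {
        1
      }
      records <- rbind(records,
                       data.frame(id = sprintf("otu%02d.v%02d", i, k),
                                  sequence = sat, abundance = ab,
                                  stringsAsFactors = FALSE))
      truth_otu <- c(truth_otu, i)
    }
  }

  structure(list(records = records,
                 truth = data.frame(id = records$id, otu = truth_otu,
                                    stringsAsFactors = FALSE),
                 spec = spec),
            class = "amplicon_community")
}

#' @export
print.amplicon_community <- function(x, ...) {
  cat("<amplicon_community> ", nrow(x$records), " amplicons in ",
      x$spec$n_true_otus, " ground-truth OTUs (max_edits = ",
      x$spec$max_edits, ", rng_seed = ", x$spec$rng_seed, ")\n", sep = "")
  invisible(x)
}
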