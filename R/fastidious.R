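#' Split OTUs into light and heavy sets
#'
#' A light OTU has total abundance strictly below `boundary`; every other OTU
#' is heavy. With the default boundary of 3 the light set is exactly the
#' singletons and doubletons.
#'
#' @param result A `cluster_result`.
#' @param boundary Integer >= 2. A boundary below 2 selects nothing (every
#'   amplicon has abundance >= 1) and is rejected as a user mistake.
#' @return List with integer elements `light` and `heavy` (OTU indices).
#' @export
partition_otus <- function(result, boundary = 3) {
  if (!is.numeric(boundary) || length(boundary) != 1L || is.na(boundary) ||
      boundary != as.integer(boundary) || boundary < 2) {
    stop("`boundary` must be a single integer >= 2", call. = FALSE)
  }
  totals <- otu_abundances(result)
  list(light = which(totals < boundary), heavy = which(totals >= boundary))
}

# Original (non-grafted) members of an OTU. Grafting decisions are always
# made against original membership so that re-running the graft step cannot
# chain new light OTUs through previously grafted members.
.own_members <- function(otu) {
  otu$members[!otu$members$grafted, , drop = FALSE]
}

# Environment keys must be non-empty, but the empty string is a legitimate
# microvariant of length-1 sequences; prefix every key to allow it.
.vkey <- function(x) paste0("k", x)

#' Graft light OTUs onto heavy OTUs
#'
#' Fastidious refinement of a d = 1 clustering: a light OTU (total abundance
#' below `params$boundary`) is grafted onto a heavy OTU whenever some amplicon
#' of the light OTU lies within 2 edits of some amplicon of the heavy OTU —
#' that is, whenever a virtual linking amplicon one edit from each side could
#' exist. The search follows the microvariant machinery: all microvariants of
#' all light-OTU amplicons are inserted into a Bloom filter (and an exact
#' index), microvariants of heavy-OTU amplicons are then probed against the
#' filter, and every filter hit is confirmed exactly before it can count.
#'
#' Each light OTU is grafted onto at most one heavy OTU: if several qualify,
#' the one with the largest pre-graft total abundance wins, ties going to
#' the lower OTU index. Light-to-light grafts and graft chains are never
#' formed, and all decisions use pre-graft abundances and pre-graft
#' membership, so the outcome is independent of processing order and the
#' operation is idempotent. Grafted members keep their original generation
#' and parent links; one graft edge (heavy anchor to light anchor, flagged
#' `is_graft`) is added per grafted OTU, and surviving OTUs are renumbered
#' consecutively in seed order.
#'
#' @param result A `cluster_result` from [cluster_amplicons()] with d = 1.
#' @param pool The pool that was clustered.
#' @param params A [cluster_params()] with `fastidious = TRUE` (and hence
#'   `d = 1`). Defaults to the result's own parameters with fastidious
#'   switched on.
#' @param fp_rate,bits_per_entry Bloom filter sizing, passed to
#'   [bloom_filter()].
#' @return A new `cluster_result`; `grafts` holds one row per grafted OTU
#'   with the pre-graft OTU indices and the anchor pool positions.
#' @examples
#' recs <- data.frame(id = c("X", "Y"),
#'                    sequence = c("AAAAAAAA", "AATTAAAA"),
#'                    abundance = c(50, 1))
#' pool <- build_pool(recs)
#' res <- cluster_amplicons(pool, cluster_params(d = 1))
#' fastidious_graft(res, pool)
#' @export
fastidious_graft <- function(result, pool, params = NULL,
                             fp_rate = 0.01, bits_per_entry = NULL) {
  stopifnot(inherits(result, "cluster_result"),
            inherits(pool, "amplicon_pool"))
  if (is.null(params)) {
    params <- result$params
    params$fastidious <- TRUE
  }
  if (!isTRUE(params$fastidious) || params$d != 1L) {
    stop("the fastidious option can only be used with d = 1", call. = FALSE)
  }

  parts <- partition_otus(result, params$boundary)
  if (!length(parts$light) || !length(parts$heavy)) return(result)

  seqs <- pool$amplicons$sequence
  totals <- otu_abundances(result)

  # phase 1: microvariants of every light amplicon go into the Bloom filter
  # and into an exact index mapping variant -> light pool positions
  light_pos <- unlist(lapply(result$otus[parts$light],
                             function(o) .own_members(o)$pos),
                      use.names = FALSE)
  light_otu_of <- integer(length(seqs))
  for (i in parts$light) {
    light_otu_of[.own_members(result$otus[[i]])$pos] <- i
  }
  capacity <- sum(7 * nchar(seqs[light_pos]) + 4)
  bf <- bloom_filter(capacity, fp_rate = fp_rate,
                     bits_per_entry = bits_per_entry)
  exact <- new.env(hash = TRUE, parent = emptyenv())
  for (p in light_pos) {
    v <- enumerate_microvariants(seqs[p])
    bloom_add(bf, v)
    keys <- .vkey(v)
    for (key in keys) exact[[key]] <- c(exact[[key]], p)
  }

  # phase 2: probe microvariants of heavy amplicons; a Bloom hit is only a
  # candidate and must resolve in the exact index to count
  cand <- list()
  for (hi in parts$heavy) {
    for (h in .own_members(result$otus[[hi]])$pos) {
      v <- enumerate_microvariants(seqs[h])
      hit <- v[bloom_contains(bf, v)]
      if (!length(hit)) next
      lp <- unique(unlist(mget(.vkey(hit), envir = exact,
                               ifnotfound = list(NULL)),
                          use.names = FALSE))
      if (length(lp)) {
        cand[[length(cand) + 1L]] <-
          data.frame(light_otu = light_otu_of[lp], heavy_otu = hi,
                     light_anchor = lp, heavy_anchor = h)
      }
    }
  }
  if (!length(cand)) return(result)
  cand <- unique(do.call(rbind, cand))

  # winner per light OTU: largest pre-graft heavy abundance, then lowest
  # heavy index; anchors tie-broken by pool position for determinism
  grafts <- .empty_grafts()
  for (lo in sort(unique(cand$light_otu))) {
    rows <- cand[cand$light_otu == lo, , drop = FALSE]
    rows <- rows[order(-totals[rows$heavy_otu], rows$heavy_otu,
                       rows$heavy_anchor, rows$light_anchor), , drop = FALSE]
    win <- rows[1L, ]
    diff <- as.integer(utils::adist(seqs[win$light_anchor],
                                    seqs[win$heavy_anchor]))
    stopifnot(diff <= 2L) # shared microvariant guarantees this
    grafts <- rbind(grafts,
                    data.frame(light_otu = win$light_otu,
                               heavy_otu = win$heavy_otu,
                               light_anchor = win$light_anchor,
                               heavy_anchor = win$heavy_anchor,
                               differences = diff))
  }

  .apply_grafts(result, grafts)
}

# Merge grafted light OTUs into their heavy hosts, renumber surviving OTUs
# in seed order and remap edge OTU indices to the final numbering.
.apply_grafts <- function(result, grafts) {
  if (!nrow(grafts)) return(result)
  otus <- result$otus
  for (r in seq_len(nrow(grafts))) {
    lo <- grafts$light_otu[r]
    hi <- grafts$heavy_otu[r]
    light_members <- otus[[lo]]$members
    light_members$grafted <- TRUE
    otus[[hi]]$members <- rbind(otus[[hi]]$members, light_members)
    otus[[hi]]$total_abundance <-
      otus[[hi]]$total_abundance + otus[[lo]]$total_abundance
  }

  survivors <- setdiff(seq_along(otus), grafts$light_otu)
  remap <- integer(length(otus))
  remap[survivors] <- seq_along(survivors)
  remap[grafts$light_otu] <- remap[grafts$heavy_otu]

  otus <- otus[survivors]
  for (i in seq_along(otus)) otus[[i]]$otu_index <- i

  edges <- result$internal_edges
  edges$otu <- remap[edges$otu]
  graft_edges <- data.frame(parent = grafts$heavy_anchor,
                            child = grafts$light_anchor,
                            differences = grafts$differences,
                            otu = remap[grafts$heavy_otu],
                            # the step at which the virtual link extends the
                            # heavy OTU past its natural d = 1 limit
                            generation = vapply(
                              grafts$heavy_otu,
                              function(h) result$otus[[h]]$max_generation + 1L,
                              integer(1)),
                            is_graft = TRUE)
  edges <- rbind(edges, graft_edges)
  edges <- edges[order(edges$otu, edges$is_graft, edges$generation,
                       edges$child), , drop = FALSE]
  rownames(edges) <- NULL

  result$otus <- otus
  result$internal_edges <- edges
  result$grafts <- rbind(result$grafts, grafts)
  rownames(result$grafts) <- NULL
  result
}

#' Brute-force grafting oracle
#'
#' Recomputes grafting decisions from the definition, without microvariants
#' or Bloom filters: a light OTU can graft onto a heavy OTU iff some pair of
#' their (original) amplicons is within unit-cost Levenshtein distance 2,
#' and the winning heavy OTU is the qualifying one with the largest
#' pre-graft total abundance (ties to the lower index). Intended for
#' validation on small pools; cost is quadratic in pool size.
#'
#' @param result A `cluster_result` (before grafting).
#' @param pool The clustered pool.
#' @param boundary Light/heavy abundance boundary.
#' @return Data frame with columns `light_otu`, `heavy_otu`, one row per
#'   graftable light OTU, sorted by `light_otu`.
#' @export
graft_oracle <- function(result, pool, boundary = 3) {
  parts <- partition_otus(result, boundary)
  totals <- otu_abundances(result)
  seqs <- pool$amplicons$sequence
  out <- data.frame(light_otu = integer(0), heavy_otu = integer(0))
  for (lo in parts$light) {
    lseq <- seqs[.own_members(result$otus[[lo]])$pos]
    best <- NA_integer_
    for (hi in parts$heavy) {
      hseq <- seqs[.own_members(result$otus[[hi]])$pos]
      if (min(utils::adist(lseq, hseq)) <= 2) {
        if (is.na(best) || totals[hi] > totals[best] ||
            (totals[hi] == totals[best] && hi < best)) {
          best <- hi
        }
      }
    }
    if (!is.na(best)) {
      out <- rbind(out, data.frame(light_otu = lo, heavy_otu = best))
    }
  }
  rownames(out) <- NULL
  out
}
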