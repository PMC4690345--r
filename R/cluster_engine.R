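#' Clustering parameters
#'
#' @param d Local clustering threshold: the maximum number of differences
#'   (unit-cost Levenshtein distance) between an amplicon and the existing
#'   cluster member it attaches to — not between the amplicon and the seed.
#'   `d = 0` performs dereplication only (one OTU per unique sequence);
#'   `d = 1` (the default and recommended value) uses the linear-time
#'   microvariant engine; `d >= 2` falls back to pairwise scanning.
#' @param break_chains If `TRUE` (default), refuse any attachment that would
#'   let abundance increase along a seed-to-member path, so chained clusters
#'   are split at abundance valleys. Equal abundance is allowed: only a
#'   strict increase is forbidden.
#' @param fastidious If `TRUE`, low-abundance OTUs are later grafted onto
#'   larger ones through virtual linking amplicons (see
#'   [fastidious_graft()]). Only available with `d = 1`.
#' @param boundary OTUs with total abundance strictly below this value are
#'   considered low-abundance ("light") during grafting. The default 3 makes
#'   exactly the singletons and doubletons light. Must be at least 2.
#' @return An object of class `cluster_params`.
#' @examples
#' cluster_params()
#' cluster_params(d = 1, fastidious = TRUE, boundary = 3)
#' @export
cluster_params <- function(d = 1, break_chains = TRUE, fastidious = FALSE,
                           boundary = 3) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) ||
      d != as.integer(d) || d < 0) {
    stop("`d` must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(boundary) || length(boundary) != 1L || is.na(boundary) ||
      boundary != as.integer(boundary) || boundary < 2) {
    stop("`boundary` must be a single integer >= 2 ",
         "(boundary 2 selects only singletons; lower values select nothing)",
         call. = FALSE)
  }
  if (isTRUE(fastidious) && d != 1) {
    stop("the fastidious option can only be used with d = 1", call. = FALSE)
  }
  structure(list(d = as.integer(d), break_chains = isTRUE(break_chains),
                 fastidious = isTRUE(fastidious),
                 boundary = as.integer(boundary)),
            class = "cluster_params")
}

#' @export
print.cluster_params <- function(x, ...) {
  cat("<cluster_params> d =", x$d,
      "| break_chains =", x$break_chains,
      "| fastidious =", x$fastidious,
      "| boundary =", x$boundary, "\n")
  invisible(x)
}

#' Chain-breaking gate
#'
#' Decides whether a candidate child may attach under a parent. With chain
#' breaking on, the attachment is allowed only when the child's abundance
#' does not exceed the parent's, which prevents any increase in abundance
#' along a continuous amplicon path; equal abundances pass. With breaking
#' off the gate always allows the attachment. A refused child simply stays
#' unassigned and may later found its own OTU; the refused edges are the
#' ones an OTU graph draws in red (see [build_network()]).
#'
#' @param parent,child Pool positions.
#' @param pool An `amplicon_pool`.
#' @param params A [cluster_params()] object.
#' @return `TRUE` to attach, `FALSE` to refuse.
#' @export
breaking_gate <- function(parent, child, pool, params) {
  !params$break_chains ||
    pool$amplicons$abundance[child] <= pool$amplicons$abundance[parent]
}

#' d = 1 neighbours by exact-string lookup
#'
#' Finds all unassigned pool amplicons at edit distance exactly 1 from the
#' given amplicon by enumerating its microvariants and looking each one up
#' in the pool's hash index — no pairwise alignment is ever performed, so
#' the cost is independent of the pool size.
#'
#' @param amplicon Pool position of the query amplicon.
#' @param pool An `amplicon_pool`.
#' @param assigned Logical mask over pool positions; `TRUE` entries are
#'   already claimed by an OTU and are excluded.
#' @return Integer vector of pool positions, sorted in pool order.
#' @export
neighbors_d1 <- function(amplicon, pool, assigned) {
  variants <- enumerate_microvariants(pool$amplicons$sequence[amplicon])
  variants <- variants[nzchar(variants)]
  hits <- pool_lookup(pool, variants)
  hits <- hits[!is.na(hits)]
  sort(hits[!assigned[hits]])
}

#' Generic neighbours by pool scan
#'
#' Fallback neighbour search for any d >= 1: scans the unassigned pool,
#' discards candidates whose length differs from the query by more than d
#' (a Levenshtein lower bound), and keeps those within unit-cost edit
#' distance d. For d = 1 this returns exactly the same set as
#' [neighbors_d1()], only slower.
#'
#' @inheritParams neighbors_d1
#' @param d Maximum number of differences (>= 1).
#' @return Integer vector of pool positions, sorted in pool order.
#' @export
neighbors_generic <- function(amplicon, pool, assigned, d) {
  stopifnot(d >= 1)
  .neighbors_generic_dist(amplicon, pool, assigned, d)$pos
}

.neighbors_generic_dist <- function(amplicon, pool, assigned, d) {
  seqs <- pool$amplicons$sequence
  cand <- which(!assigned)
  cand <- cand[cand != amplicon]
  if (length(cand)) {
    cand <- cand[abs(nchar(seqs[cand]) - nchar(seqs[amplicon])) <= d]
  }
  if (!length(cand)) {
    return(list(pos = integer(0), differences = integer(0)))
  }
  dist <- drop(utils::adist(seqs[amplicon], seqs[cand]))
  keep <- dist <= d
  o <- order(cand[keep])
  list(pos = cand[keep][o], differences = as.integer(dist[keep][o]))
}

#' Cluster an amplicon pool into OTUs
#'
#' Iterative single-linkage clustering with a local threshold. The
#' highest-ranked unassigned amplicon founds a new OTU (generation 0) and the
#' OTU grows breadth-first: each amplicon of the current generation, taken in
#' pool order, recruits every still-unassigned amplicon within `d`
#' differences, subject to the chain-breaking gate; recruits form the next
#' generation, and growth stops when a generation adds nothing. OTUs are
#' numbered in seed order. Because the pool order is a deterministic function
#' of the sequences and abundances alone, the partition never depends on
#' input order.
#'
#' With `d = 0` the pool (already dereplicated) is returned as one OTU per
#' amplicon. Grafting is not applied here even when `params$fastidious` is
#' set; run [fastidious_graft()] on the result.
#'
#' @param pool An `amplicon_pool` from [build_pool()].
#' @param params A [cluster_params()] object.
#' @return An object of class `cluster_result`: a list with elements
#'   * `otus`: list of OTUs, each with `otu_index`, `seed` (pool position),
#'     `members` (data frame `pos`, `generation`, `parent`, `differences`,
#'     `grafted`, in attachment order, seed first), `total_abundance` and
#'     `max_generation`;
#'   * `internal_edges`: data frame of attachment edges (`parent`, `child`,
#'     `differences`, `otu`, `generation`, `is_graft`);
#'   * `cut_edges`: data frame of edges refused by the breaking gate
#'     (`parent`, `child`);
#'   * `grafts`: graft records (empty until [fastidious_graft()]);
#'   * `params` and `n_amplicons`.
#' @examples
#' recs <- data.frame(id = c("A", "B", "C"),
#'                    sequence = c("AAAA", "AAAT", "AATT"),
#'                    abundance = c(10, 5, 2))
#' cluster_amplicons(build_pool(recs), cluster_params(d = 1))
#' @export
cluster_amplicons <- function(pool, params = cluster_params()) {
  stopifnot(inherits(pool, "amplicon_pool"),
            inherits(params, "cluster_params"))
  n <- nrow(pool$amplicons)
  abundance <- pool$amplicons$abundance

  assigned <- logical(n)
  otu_of <- integer(n)
  generation <- integer(n)
  parent <- rep(NA_integer_, n)
  differences <- rep(NA_integer_, n)
  otu_members <- list()
  cut_parent <- integer(0)
  cut_child <- integer(0)

  find_neighbors <- if (params$d == 1) {
    function(p) {
      pos <- neighbors_d1(p, pool, assigned)
      list(pos = pos, differences = rep.int(1L, length(pos)))
    }
  } else {
    function(p) .neighbors_generic_dist(p, pool, assigned, params$d)
  }

  k <- 0L
  for (s in seq_len(n)) {
    if (assigned[s]) next
    k <- k + 1L
    assigned[s] <- TRUE
    otu_of[s] <- k
    members <- s
    frontier <- s
    g <- 0L
    while (length(frontier) && params$d > 0L) {
      g <- g + 1L
      nxt <- integer(0)
      for (p in frontier) {
        nb <- find_neighbors(p)
        for (j in seq_along(nb$pos)) {
          h <- nb$pos[j]
          if (assigned[h]) next # claimed earlier within this generation
          if (breaking_gate(p, h, pool, params)) {
            assigned[h] <- TRUE
            otu_of[h] <- k
            generation[h] <- g
            parent[h] <- p
            differences[h] <- nb$differences[j]
            members <- c(members, h)
            nxt <- c(nxt, h)
          } else {
            cut_parent <- c(cut_parent, p)
            cut_child <- c(cut_child, h)
          }
        }
      }
      frontier <- sort(nxt)
    }
    otu_members[[k]] <- members
  }

  otus <- vector("list", k)
  for (i in seq_len(k)) {
    m <- otu_members[[i]]
    otus[[i]] <- list(
      otu_index = i,
      seed = m[1L],
      members = data.frame(pos = m,
                           generation = generation[m],
                           parent = parent[m],
                           differences = differences[m],
                           grafted = FALSE),
      total_abundance = sum(abundance[m]),
      max_generation = max(generation[m]))
  }

  child <- which(!is.na(parent))
  internal_edges <- data.frame(parent = parent[child], child = child,
                               differences = differences[child],
                               otu = otu_of[child],
                               generation = generation[child],
                               is_graft = logical(length(child)))
  internal_edges <- internal_edges[order(internal_edges$otu,
                                         internal_edges$generation,
                                         internal_edges$child), , drop = FALSE]
  rownames(internal_edges) <- NULL

  cuts <- data.frame(parent = cut_parent, child = cut_child)
  cuts <- unique(cuts)
  rownames(cuts) <- NULL

  structure(list(otus = otus,
                 internal_edges = internal_edges,
                 cut_edges = cuts,
                 grafts = .empty_grafts(),
                 params = params,
                 n_amplicons = n),
            class = "cluster_result")
}

.empty_grafts <- function() {
  data.frame(light_otu = integer(0), heavy_otu = integer(0),
             light_anchor = integer(0), heavy_anchor = integer(0),
             differences = integer(0))
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", length(x$otus), " OTUs over ", x$n_amplicons,
      " amplicons (d = ", x$params$d,
      if (x$params$break_chains) ", chain breaking on" else
        ", chain breaking off",
      if (nrow(x$grafts)) paste0(", ", nrow(x$grafts), " grafts") else "",
      ")\n", sep = "")
  invisible(x)
}

#' Total abundance of each OTU
#'
#' @param result A `cluster_result`.
#' @return Numeric vector of OTU total abundances, in OTU order.
#' @export
otu_abundances <- function(result) {
  vapply(result$otus, function(o) o$total_abundance, numeric(1))
}

#' Map pool positions to OTU indices
#'
#' @param result A `cluster_result`.
#' @return Integer vector: entry i is the index of the OTU holding pool
#'   position i (grafted members belong to their final, post-graft OTU).
#' @export
otu_assignments <- function(result) {
  out <- integer(result$n_amplicons)
  for (o in result$otus) out[o$members$pos] <- o$otu_index
  out
}
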