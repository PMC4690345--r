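#' Write OTU membership lists
#'
#' One line per final OTU: the annotated identifiers of its members separated
#' by single spaces, seed first, then members in attachment order; members
#' grafted onto the OTU come after its own members.
#'
#' @param result A `cluster_result`.
#' @param pool The clustered pool.
#' @param path Output path or connection.
#' @param dialect An [abundance_dialect()] or style string.
#' @return Invisibly, `path`.
#' @export
write_otus <- function(result, pool, path, dialect = abundance_dialect()) {
  dialect <- .as_dialect(dialect)
  amp <- pool$amplicons
  lines <- vapply(result$otus, function(o) {
    pos <- o$members$pos
    paste(annotate_id(amp$id[pos], amp$abundance[pos], dialect),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write OTU representatives as FASTA
#'
#' The representative of an OTU is its most abundant amplicon (the seed);
#' its abundance annotation is updated to the total (post-graft) abundance of
#' the OTU, so downstream abundance-aware tools see the whole cluster.
#'
#' @inheritParams write_otus
#' @return Invisibly, `path`.
#' @export
write_representatives <- function(result, pool, path,
                                  dialect = abundance_dialect()) {
  dialect <- .as_dialect(dialect)
  amp <- pool$amplicons
  seeds <- vapply(result$otus, function(o) o$seed, integer(1))
  totals <- otu_abundances(result)
  df <- data.frame(id = amp$id[seeds], sequence = amp$sequence[seeds],
                   abundance = totals, stringsAsFactors = FALSE)
  write_amplicon_fasta(df, path, dialect)
}

#' Write per-OTU statistics
#'
#' Tab-separated, one row per final OTU, with a leading `#`-comment header
#' line naming the columns: number of unique amplicons, total abundance,
#' seed identifier, seed abundance, number of members with abundance 1,
#' maximum generation reached during growth (grafted members excluded), and
#' number of grafted members.
#'
#' @inheritParams write_otus
#' @return Invisibly, `path`.
#' @export
write_statistics <- function(result, pool, path) {
  amp <- pool$amplicons
  rows <- vapply(result$otus, function(o) {
    m <- o$members
    own <- m[!m$grafted, , drop = FALSE]
    paste(nrow(m),
          format(o$total_abundance, scientific = FALSE),
          amp$id[o$seed],
          format(amp$abundance[o$seed], scientific = FALSE),
          sum(amp$abundance[m$pos] == 1),
          max(own$generation),
          sum(m$grafted),
          sep = "\t")
  }, character(1))
  writeLines(c(paste0("# amplicons\ttotal_abundance\tseed\tseed_abundance",
                      "\tsingletons\tmax_generation\tgrafted"),
               rows), path)
  invisible(path)
}

#' Write the internal structure of all OTUs
#'
#' Tab-separated, one row per attachment edge: parent identifier, child
#' identifier, number of differences, final OTU index, and the generation at
#' which the child joined. Graft edges appear with their actual number of
#' differences (at most 2). Dereplication-only runs (d = 0) produce an empty
#' file.
#'
#' @inheritParams write_otus
#' @return Invisibly, `path`.
#' @export
write_internal_structure <- function(result, pool, path) {
  amp <- pool$amplicons
  e <- result$internal_edges
  lines <- if (nrow(e)) {
    paste(amp$id[e$parent], amp$id[e$child], e$differences, e$otu,
          e$generation, sep = "\t")
  } else {
    character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build the graph of one OTU
#'
#' Nodes are the OTU's members (carrying their abundance); edges are the
#' attachment tree recorded during growth, including any graft edge. With
#' `include_cut_edges = TRUE` the graph additionally holds every 1-edit pair
#' among the members and every 1-edit pair reaching into other OTUs; edges
#' that the breaking gate refused, and all edges crossing into another OTU,
#' are flagged `is_cut` (these are the edges a drawing colours red — the
#' places where chain breaking separates abundant OTUs joined only through a
#' low-abundance amplicon). Nodes from adjacent OTUs reached by a cut edge
#' are included so the situation is visible.
#'
#' @param result A `cluster_result`.
#' @param pool The clustered pool.
#' @param otu_index Index of the OTU to extract.
#' @param include_cut_edges Also compute non-tree 1-edit pairs and refused
#'   edges (default `FALSE`).
#' @return An object of class `otu_network`: list with data frames `nodes`
#'   (`id`, `abundance`) and `edges` (`from`, `to`, `differences`, `is_cut`,
#'   `is_graft`).
#' @export
build_network <- function(result, pool, otu_index,
                          include_cut_edges = FALSE) {
  if (!is.numeric(otu_index) || length(otu_index) != 1L ||
      is.na(otu_index) || otu_index < 1 || otu_index > length(result$otus)) {
    stop("`otu_index` must be an OTU index between 1 and ",
         length(result$otus), call. = FALSE)
  }
  amp <- pool$amplicons
  otu <- result$otus[[otu_index]]
  members <- otu$members$pos
  in_otu <- logical(nrow(amp))
  in_otu[members] <- TRUE

  e <- result$internal_edges
  e <- e[e$otu == otu_index, , drop = FALSE]
  edges <- data.frame(a = e$parent, b = e$child,
                      differences = e$differences,
                      is_cut = logical(nrow(e)), is_graft = e$is_graft)
  nodes_pos <- members

  if (include_cut_edges) {
    refused <- paste(pmin(result$cut_edges$parent, result$cut_edges$child),
                     pmax(result$cut_edges$parent, result$cut_edges$child))
    extra <- list()
    for (a in members) {
      hits <- pool_lookup(pool, {
        v <- enumerate_microvariants(amp$sequence[a])
        v[nzchar(v)]
      })
      hits <- hits[!is.na(hits)]
      for (b in hits) {
        if (in_otu[b] && b < a) next # keep intra pairs once
        key <- paste(min(a, b), max(a, b))
        cross <- !in_otu[b]
        extra[[length(extra) + 1L]] <-
          data.frame(a = a, b = b, differences = 1L,
                     is_cut = cross || key %in% refused,
                     is_graft = FALSE)
      }
    }
    if (length(extra)) {
      extra <- do.call(rbind, extra)
      seen <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
      key <- paste(pmin(extra$a, extra$b), pmax(extra$a, extra$b))
      extra <- extra[!key %in% seen & !duplicated(key), , drop = FALSE]
      edges <- rbind(edges, extra)
      nodes_pos <- sort(unique(c(nodes_pos, extra$a, extra$b)))
    }
  }

  structure(list(
    nodes = data.frame(id = amp$id[nodes_pos],
                       abundance = amp$abundance[nodes_pos],
                       stringsAsFactors = FALSE),
    edges = data.frame(from = amp$id[edges$a], to = amp$id[edges$b],
                       differences = edges$differences,
                       is_cut = edges$is_cut, is_graft = edges$is_graft,
                       stringsAsFactors = FALSE)),
    class = "otu_network")
}

#' @export
print.otu_network <- function(x, ...) {
  cat("<otu_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", sum(x$edges$is_cut), " cut, ", sum(x$edges$is_graft),
      " graft)\n", sep = "")
  invisible(x)
}

# nodes are annotated with their abundance only when it is 10 or more;
# rarer nodes stay unlabelled so dense haloes of satellites remain readable
.node_labels <- function(abundance) {
  ifelse(abundance >= 10,
         format(abundance, scientific = FALSE, trim = TRUE), NA)
}

.network_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Export an OTU graph to a standard format
#'
#' Writes the graph with `abundance` as a node attribute and `differences`,
#' `is_cut` and `is_graft` as edge attributes. `edge_tsv` is a plain
#' tab-separated edge list with a header; `graphml` and `dot` are written
#' through igraph.
#'
#' @param network An `otu_network` from [build_network()].
#' @param path Output path.
#' @param format One of `"edge_tsv"`, `"graphml"`, `"dot"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(network, path,
                           format = c("edge_tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    net <- network
    if (format == "dot") { # DOT has no boolean attribute type
      net$edges$is_cut <- as.integer(net$edges$is_cut)
      net$edges$is_graft <- as.integer(net$edges$is_graft)
    }
    igraph::write_graph(.network_igraph(net), path, format = format)
  }
  invisible(path)
}

#' Draw an OTU graph
#'
#' Renders a two-dimensional layout in which node area and colour scale with
#' abundance, nodes are labelled with their abundance when it is 10 or more,
#' cut edges are drawn in red and graft edges dashed. Edge lengths carry no
#' information: the layout only spreads the graph for legibility.
#'
#' @param network An `otu_network`.
#' @param path Output image path; `.png` and `.svg` are recognised.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return Invisibly, `path`.
#' @export
render_network <- function(network, path, width = 800, height = 800) {
  g <- .network_igraph(network)
  ab <- network$nodes$abundance
  size <- 6 + 14 * sqrt(ab / max(ab))
  pal <- grDevices::colorRampPalette(c("#FFF7BC", "#FB6A4A", "#99000D"))(64)
  col <- pal[pmax(1L, ceiling(64 * ab / max(ab)))]
  labels <- .node_labels(ab)
  ecol <- ifelse(network$edges$is_cut, "red", "grey40")
  elty <- ifelse(network$edges$is_graft, 2L, 1L)

  ext <- tolower(sub("^.*\\.", "", path))
  if (ext == "svg") {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else {
    grDevices::png(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  igraph::plot.igraph(g, layout = igraph::layout_with_fr(g),
                      vertex.size = size, vertex.color = col,
                      vertex.label = labels, vertex.label.color = "black",
                      edge.color = if (nrow(network$edges)) ecol else NULL,
                      edge.lty = if (nrow(network$edges)) elty else NULL)
  invisible(path)
}
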