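chain_pool <- function(abundances) {
  build_pool(data.frame(id = c("A", "B", "C"),
                        sequence = c("AAAA", "AAAT", "AATT"),
                        abundance = abundances))
}

test_that("a monotone 3-amplicon chain forms one OTU across generations", {
  pool <- chain_pool(c(10, 5, 2))
  res <- cluster_amplicons(pool, cluster_params(d = 1))
  expect_length(res$otus, 1)
  m <- res$otus[[1]]$members
  seqs <- pool$amplicons$sequence[m$pos]
  expect_equal(seqs, c("AAAA", "AAAT", "AATT"))
  expect_equal(m$generation, c(0L, 1L, 2L))
  expect_equal(pool$amplicons$sequence[m$parent[-1]], c("AAAA", "AAAT"))
  expect_equal(res$otus[[1]]$total_abundance, 17)
  expect_equal(res$otus[[1]]$max_generation, 2L)
})

test_that("amplicons further than d apart never link", {
  pool <- build_pool(data.frame(id = c("A", "C"),
                                sequence = c("AAAA", "CCCC"),
                                abundance = c(10, 2)))
  res <- cluster_amplicons(pool, cluster_params(d = 1))
  expect_length(res$otus, 2)
})

test_that("the abundance valley in a chain is cut only when breaking is on", {
  pool <- chain_pool(c(10, 1, 8))
  on <- cluster_amplicons(pool, cluster_params(break_chains = TRUE))
  off <- cluster_amplicons(pool, cluster_params(break_chains = FALSE))
  expect_length(on$otus, 2)
  expect_length(off$otus, 1)
  expect_setequal(pool$amplicons$sequence[on$otus[[1]]$members$pos],
                  c("AAAA", "AAAT"))
  expect_equal(pool$amplicons$sequence[on$otus[[2]]$members$pos], "AATT")
  # the refused edge is recorded for graph output
  expect_equal(nrow(on$cut_edges), 1)
  expect_setequal(pool$amplicons$sequence[unlist(on$cut_edges)],
                  c("AAAT", "AATT"))
  expect_equal(nrow(off$cut_edges), 0)
})

test_that("breaking gate allows equality and can be disabled", {
  equal_pool <- build_pool(data.frame(id = c("p", "c"),
                                      sequence = c("AAAA", "AAAT"),
                                      abundance = c(10, 10)))
  params_on <- cluster_params(break_chains = TRUE)
  # equal abundances: no increase, both directions pass
  expect_true(breaking_gate(1, 2, equal_pool, params_on))
  expect_true(breaking_gate(2, 1, equal_pool, params_on))

  pool <- build_pool(data.frame(id = c("p", "c"),
                                sequence = c("AAAA", "AAAT"),
                                abundance = c(10, 5)))
  expect_true(breaking_gate(1, 2, pool, params_on))
  expect_false(breaking_gate(2, 1, pool, params_on))  # strict increase
  expect_true(breaking_gate(2, 1, pool, cluster_params(break_chains = FALSE)))
})

test_that("d = 0 yields one OTU per dereplicated amplicon", {
  recs <- data.frame(id = c("a", "b", "c"),
                     sequence = c("ACGT", "ACGT", "AAAA"),
                     abundance = c(3, 2, 1))
  res <- cluster_amplicons(build_pool(recs), cluster_params(d = 0))
  expect_length(res$otus, 2)
  expect_equal(nrow(res$internal_edges), 0)
  expect_equal(vapply(res$otus, function(o) o$max_generation, integer(1)),
               c(0L, 0L))
})

test_that("empty and singleton pools are handled", {
  empty <- build_pool(data.frame(id = character(0), sequence = character(0),
                                 abundance = numeric(0)))
  res <- cluster_amplicons(empty, cluster_params())
  expect_length(res$otus, 0)
  expect_equal(nrow(res$internal_edges), 0)

  one <- build_pool(data.frame(id = "x", sequence = "ACGT", abundance = 3))
  res1 <- cluster_amplicons(one, cluster_params())
  expect_length(res1$otus, 1)
  expect_equal(res1$otus[[1]]$max_generation, 0L)
})

test_that("parameter validation rejects invalid combinations", {
  expect_error(cluster_params(d = -1), "non-negative")
  expect_error(cluster_params(d = 2, fastidious = TRUE), "d = 1")
  expect_error(cluster_params(boundary = 1), ">= 2")
})

test_that("d=1 neighbours from the hash index equal the brute-force set", {
  set.seed(33)
  recs <- perturbed_records(150, c(20, 25))
  pool <- build_pool(recs)
  seqs <- pool$amplicons$sequence
  assigned <- logical(length(seqs))
  for (a in sample(seq_along(seqs), 40)) {
    expected <- which(drop(utils::adist(seqs[a], seqs)) == 1)
    expect_identical(neighbors_d1(a, pool, assigned), expected)
    expect_identical(neighbors_generic(a, pool, assigned, 1), expected)
  }
  # masked amplicons are excluded
  assigned[] <- TRUE
  expect_identical(neighbors_d1(1, pool, assigned), integer(0))
})

test_that("generic neighbours honour d = 2 and the length prefilter", {
  pool <- build_pool(data.frame(id = c("A", "B", "C"),
                                sequence = c("AAAA", "AATT", "AAAATTT"),
                                abundance = c(5, 3, 1)))
  a <- match("AAAA", pool$amplicons$sequence)
  got <- neighbors_generic(a, pool, logical(3), 2)
  expect_identical(pool$amplicons$sequence[got], "AATT") # distance 2
  # |length difference| = 3 > d: never a neighbour
  expect_false(match("AAAATTT", pool$amplicons$sequence) %in% got)
})

test_that("partitions match brute-force single linkage with breaking off", {
  set.seed(44)
  for (rep in 1:6) {
    recs <- perturbed_records(sample(40:90, 1), c(12, 20))
    pool <- build_pool(recs)
    for (d in 1:2) {
      params <- cluster_params(d = d, break_chains = FALSE)
      res <- cluster_amplicons(pool, params)
      expect_equal(result_partition(res, pool),
                   brute_components(pool$amplicons$sequence, d))
    }
  }
})

test_that("the d=1 fast path and the generic scan build identical results", {
  set.seed(55)
  for (rep in 1:4) {
    pool <- build_pool(perturbed_records(60, c(10, 16)))
    for (breaking in c(TRUE, FALSE)) {
      fast <- cluster_amplicons(pool, cluster_params(1, breaking))
      slow_params <- cluster_params(1, breaking)
      # force the generic scan by pretending d came in above 1
      slow <- with_mocked_bindings(
        cluster_amplicons(pool, slow_params),
        neighbors_d1 = function(amplicon, pool, assigned) {
          neighbors_generic(amplicon, pool, assigned, 1)
        })
      expect_equal(fast, slow)
    }
  }
})

test_that("structural invariants hold on random pools", {
  set.seed(66)
  for (rep in 1:5) {
    recs <- perturbed_records(sample(50:120, 1), c(15, 22))
    pool <- build_pool(recs)
    res <- cluster_amplicons(pool, cluster_params(d = 1))
    ab <- pool$amplicons$abundance

    # partition: every amplicon in exactly one OTU, abundance conserved
    all_pos <- unlist(lapply(res$otus, function(o) o$members$pos))
    expect_setequal(all_pos, seq_len(length(pool)))
    expect_length(all_pos, length(pool))
    expect_equal(sum(otu_abundances(res)), sum(ab))

    for (o in res$otus) {
      m <- o$members
      # seed dominates its OTU
      expect_equal(m$pos[1], o$seed)
      expect_equal(m$generation[1], 0L)
      expect_true(all(ab[o$seed] >= ab[m$pos]))
      expect_equal(o$total_abundance, sum(ab[m$pos]))
      # parents one generation up, already members, never more abundant
      kids <- m[-1, , drop = FALSE]
      if (nrow(kids)) {
        expect_true(all(kids$parent %in% m$pos))
        expect_equal(kids$generation,
                     m$generation[match(kids$parent, m$pos)] + 1L)
        expect_true(all(ab[kids$pos] <= ab[kids$parent]))
      }
      # edges restricted to the OTU form a tree on its members
      e <- res$internal_edges[res$internal_edges$otu == o$otu_index, ]
      expect_equal(nrow(e), nrow(m) - 1)
      expect_setequal(e$child, kids$pos)
    }
  }
})

test_that("permuting the input records never changes the clustering", {
  set.seed(77)
  recs <- perturbed_records(80, c(12, 18))
  pool <- build_pool(recs)
  base <- cluster_amplicons(pool, cluster_params())
  for (rep in 1:3) {
    perm <- build_pool(recs[sample(nrow(recs)), ])
    expect_equal(cluster_amplicons(perm, cluster_params()), base)
  }
})
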