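---
title: "Fine-scale OTU clustering with a local threshold: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale OTU clustering with a local threshold: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclust)
```

## The clustering model

`ampliclust` partitions a pool of dereplicated amplicons into OTUs by
iterative single linkage under a *local* threshold *d*. The highest-ranked
unassigned amplicon founds an OTU (generation 0); every amplicon of the
current generation, in pool order, recruits all still-unassigned amplicons
within *d* unit-cost edit operations (substitution, insertion, deletion each
cost 1); recruits form the next generation; growth stops when a generation
adds nothing. The threshold is local — it constrains each attachment, not the
distance to the seed — so an OTU can extend far beyond *d* when the data
support it, and never merges with sequences that are close to nothing in it.

This model assumes the input is dereplicated marker-gene data in which true
biological units appear as an abundant sequence surrounded by rare 1-edit
derivatives. Pool order (decreasing abundance, ties by ascending sequence) is
a pure function of the sequence/abundance multiset, which makes every
downstream result independent of input order.

### The d = 1 engine

For the default *d* = 1 the engine never aligns sequences. A sequence of
length *L* has 3*L* substitution variants, one deletion variant per
homopolymer run (*r* runs), and always 3*L* + 4 distinct insertion variants
(4(*L* + 1) insertions, of which *L* duplicate an existing base adjacent to
the gap), for 6*L* + 4 + *r* distinct microvariants in total — between
6*L* + 5 (homopolymer) and 7*L* + 4 (no two adjacent bases equal). The
engine enumerates this set and queries a hash index of the pool, so the work
per amplicon is O(*L*), independent of pool size. `microvariant_count()`
implements the closed form and the test suite proves it equal to exhaustive
enumeration for every sequence up to length 6, and equal to
`length(enumerate_microvariants())` on random sequences.

The deletion variant of a length-1 sequence is the empty string. It is kept
in the enumerated set (the closed form counts it) but can never match a pool
entry, because pool sequences are non-empty.

### Chain breaking

With breaking on (default) an attachment is refused when the child is
strictly more abundant than the parent, so abundance is non-increasing along
every seed-to-member path. Equality passes: only an *increase* signals that
the path has crossed into another unit's halo. The gate is per-edge: an
amplicon refused under one parent may attach later under a less abundant
parent of the same OTU. This interpretation (rather than banning the
amplicon from the OTU outright) keeps the rule purely local; the refused
edges are recorded and exposed as the red "cut" edges of OTU graphs.

### Fastidious grafting

Low-abundance OTUs (total abundance < `boundary`, default 3) are often
stranded error variants two edits from a large OTU. The fastidious pass
grafts a light OTU onto a heavy one exactly when some light amplicon lies
within 2 edits of some heavy amplicon — the condition under which a virtual
linking amplicon one edit from each side can exist. Implementation:
microvariants of every light amplicon are inserted into a Bloom filter and
an exact hash map; microvariants of heavy amplicons are probed against the
filter; a filter hit only counts after exact confirmation in the map. Two
strings at distance 1 or 2 always share a strict microvariant (take an edit
midpoint, or a third edit applied to both), and a shared microvariant
implies distance at most 2, so the probe is exact — the Bloom filter is
purely an engineering device and its false positives are screened out, while
false negatives are impossible by the filter contract (a property test
asserts this).

Open choices here were resolved as follows and are asserted by tests:

* several qualifying heavy OTUs: the largest pre-graft total abundance wins,
  ties to the lower OTU index;
* all decisions (light/heavy split, winner, candidate scan) use *pre-graft*
  abundances and *original* membership, so grafting is independent of
  processing order and idempotent — a light OTU can never chain through a
  previously grafted member, and light-to-light grafts cannot occur;
* grafted members keep their original generations and internal edges; the
  graft edge is recorded from the heavy anchor to the light anchor with its
  true distance (1 is possible when chain breaking cut that edge earlier; 2
  is typical) and a generation of the heavy OTU's maximum plus one.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `d` | 1 | local attachment threshold, in edit operations; 0 = dereplicate only; >= 2 uses the quadratic scan |
| `break_chains` | `TRUE` | refuse abundance increases along paths |
| `fastidious` | `FALSE` | graft light OTUs after clustering (d = 1 only; at higher d the 2d-edit neighbourhood explodes combinatorially) |
| `boundary` | 3 | light OTU = total abundance < boundary, i.e. singletons and doubletons; must be >= 2 (below 2 selects nothing) |
| `fp_rate`, `bits_per_entry` | 0.01, derived | Bloom filter sizing; smaller filters cost confirmation time, never correctness |

## Numerical and degenerate-input choices

* Distance is unit-cost Levenshtein throughout (`utils::adist` for the
  generic path and all oracles). Tools deriving differences from scored
  alignments can disagree on rare ties; for d = 1 the microvariant
  definition is unambiguous.
* Ambiguous bases (N) and RNA (U) are hard errors at parsing, never
  converted or skipped — silent data loss would distort abundances.
* Abundance ties in pool order break by ascending sequence; a child
  reachable from two same-generation parents attaches to the earlier one in
  pool order; both rules exist only to make results deterministic.
* Duplicate sequences with `assume_dereplicated = TRUE` are an error naming
  both records; otherwise they are merged, summing abundances, with the
  identifier of the most abundant member (ties: first seen).
* An empty record set clusters to an empty result; a singleton pool is one
  OTU of generation 0.

## The synthetic community generator

`generate_community()` emulates the structure the clustering model assumes:
`n_true_otus` abundant seeds, each with `satellites_per_otu` rarer
satellites at exactly `max_edits` edits. Satellite abundances decay
geometrically from the seed (ratio 0.5 by default), keeping abundance
monotone along attachment paths so the breaking gate stays inactive inside
true OTUs and recovery tests isolate the linkage machinery; with
`max_edits = 2` satellites are singletons instead, so they are invisible to
d = 1 linkage and light under the default boundary — recoverable only by the
fastidious pass. Seeds are drawn at random and kept pairwise more than
`2 * (max_edits + 1)` edits apart. That is deliberately stricter than the
minimum needed to keep ground-truth OTUs from merging: at separation
`2 * max_edits + 1` two OTUs could still be bridged by a satellite pair one
edit apart (max_edits = 1) or by a virtual linking amplicon (max_edits = 2).
Infeasible requests (seeds that cannot be placed) fail after bounded
retries.

The generator emulates clean halo structure only. It does not simulate
chimeras, realistic per-position error profiles, length variation within an
OTU, or abundance noise, so passing recovery tests demonstrates correctness
of the clustering machinery on data matching its assumptions — not
biological accuracy on real communities, where OTU boundaries are genuinely
ambiguous.

## Problem sizes used in the test suite

The suite verifies the enumeration formula exhaustively over all 5,456
sequences up to length 6 (against brute-force distance computation over all
candidate strings), checks clustering and grafting against quadratic
brute-force oracles on 50 random pools of up to 200 amplicons of 20–60 nt,
and runs parameter-recovery over 20 random community specifications. These
sizes give the oracles full coverage of every code path (multi-generation
growth, cut edges, competing graft hosts) while keeping the oracle side —
which is quadratic by design — proportionate; the engine itself handles much
larger pools, linearly in pool size for d = 1.

## Known limitations

* d >= 2 clustering is a quadratic pool scan — correct but not for
  large pools; the fastidious pass is restricted to d = 1.
* Chain breaking interacts with growth order at abundance plateaus: equal
  abundances pass the gate in both directions, so a plateau never splits.
* The graph renderer's layout is force-directed and unseeded; only the
  exported structure (nodes, edges, attributes) is stable, and edge lengths
  carry no information.
* Memory capping of the Bloom filter beyond `bits_per_entry` is not
  implemented; the `-c` flag is accepted for interface compatibility and
  logged as a no-op.
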