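Package: ampliclust
Title: Fine-Scale Amplicon Clustering into OTUs with a Local Threshold
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo clustering of marker-gene amplicons into operational
    taxonomic units (OTUs) by iterative single linkage with a small local
    threshold d. For d = 1 the engine enumerates all microvariants (single
    substitutions, insertions and deletions) of each amplicon and finds
    neighbours by exact-string hash lookup, so clustering time grows
    linearly with the number of amplicons instead of quadratically.
    Includes abundance-aware chain breaking, a fastidious refinement that
    grafts low-abundance OTUs onto larger ones through virtual linking
    amplicons screened by a Bloom filter, strict (d = 0) dereplication
    of reads, OTU representative and statistics output, a synthetic
    community generator with known ground truth, and export and rendering
    of OTU graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    optparse,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
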