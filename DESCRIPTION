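Package: ssrclone
Title: Duplicate Detection in Clonal Germplasm Collections from Dominant SSR Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies duplicate (clonal) accessions in genebank collections
    genotyped with dominant, presence/absence-scored SSR (microsatellite)
    fragments, as is standard practice for tetraploid crops such as potato.
    Reads and validates binary band matrices, computes pairwise mismatch
    counts under pairwise deletion of missing data, calls duplicate clusters
    by single-linkage at a mismatch threshold and reports a cluster census,
    builds UPGMA and neighbor-joining dendrograms with column-bootstrap
    branch support and support-based polytomy collapse, and ships a
    synthetic-fingerprint simulator with planted clonal structure so the
    whole pipeline can be exercised against a known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
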