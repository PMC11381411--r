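# Shared fixtures: all built in code, no files needed.

# Small hand-readable matrix: 3 accessions x 4 fragments, one missing cell.
tiny_matrix <- function() {
  band_matrix(matrix(c(1L, 1L, 0L, 1L,
                       1L, NA, 0L, 0L,
                       0L, 1L, 1L, 0L),
                     nrow = 3, byrow = TRUE,
                     dimnames = list(c("A", "B", "C"),
                                     c("f1", "f2", "f3", "f4"))))
}

# Random band matrix with controlled missingness.
rand_band_matrix <- function(n, p, missing_rate = 0.1) {
  x <- matrix(sample(0:1, n * p, replace = TRUE), nrow = n)
  x[runif(n * p) < missing_rate] <- NA_integer_
  # guarantee every pair overlaps: make first two columns fully scored
  x[, 1:2] <- sample(0:1, 2 * n, replace = TRUE)
  dimnames(x) <- list(sprintf("a%02d", seq_len(n)), sprintf("f%02d", seq_len(p)))
  band_matrix(x)
}

# Brute-force oracle: recount every pair cell by cell with an explicit loop.
naive_differences <- function(m) {
  n <- nrow(m)
  d <- cmp <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    both <- !is.na(m[i, ]) & !is.na(m[j, ])
    cmp[i, j] <- sum(both)
    d[i, j] <- sum(m[i, both] != m[j, both])
  }
  list(diff = d, compared = cmp)
}

# Distance object straight from a symmetric integer matrix (for cluster and
# tree tests that start from known distances).
dist_fixture <- function(mat, total_bands = max(mat)) {
  ids <- rownames(mat)
  structure(list(diff = mat, compared = matrix(total_bands, nrow(mat), ncol(mat),
                                               dimnames = dimnames(mat)),
                 total_bands = total_bands, accession_ids = ids),
            class = "band_distance")
}

sym_mat <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  m[upper.tri(m)] <- as.integer(v)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

# Quick small simulation config used across tests.
small_sim <- function(seed, n_singletons = 10L,
                      group_sizes = c(2L, 2L, 3L), ...) {
  sim_config(n_loci = 20L, n_singletons = n_singletons,
             group_sizes = group_sizes, seed = seed, ...)
}

# TRUE when the realized distances keep the planted gap at threshold t:
# every between-genotype pair differs by more than t. (Within-group pairs may
# exceed t: two clones each t flips from the founder can be 2t apart, and
# single linkage chains them through the founder, which is always a member.)
gap_holds <- function(sim, d, t = 5L) {
  geno <- sim$truth$genotype[match(rownames(d$diff), sim$truth$accession_id)]
  same <- outer(geno, geno, "==")
  all(d$diff[upper.tri(d$diff) & !same] > t)
}
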