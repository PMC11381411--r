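test_that("UPGMA places merges at half the average difference", {
  d <- dist_fixture(sym_mat(c(2L, 8L, 8L), c("A", "B", "C")))
  tr <- upgma_tree(d)
  depth <- ape::node.depth.edgelength(tr)
  # all leaves at the root-to-leaf depth of 4 (root height = 8/2)
  expect_equal(unname(depth[1:3]), rep(4, 3))
  # A and B coalesce at height 1 (difference 2 / 2)
  mrca <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(unname(depth[mrca]), 3)  # depth from root: 4 - 1
  expect_error(upgma_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA trees are ultrametric for arbitrary inputs", {
  set.seed(31)
  for (rep in 1:10) {
    m <- rand_band_matrix(sample(4:12, 1), 25, missing_rate = 0.1)
    tr <- upgma_tree(pairwise_differences(m))
    depth <- ape::node.depth.edgelength(tr)
    leaf_depths <- depth[seq_along(tr$tip.label)]
    expect_lt(max(leaf_depths) - min(leaf_depths), 1e-9)
  }
})

test_that("UPGMA recovers the generating heights from ultrametric distances", {
  set.seed(17)
  for (rep in 1:5) {
    gen <- ape::rcoal(6)
    D <- ape::cophenetic.phylo(gen)
    tr <- upgma_tree(D[sort(rownames(D)), sort(rownames(D))])
    D2 <- ape::cophenetic.phylo(tr)
    expect_equal(D2[rownames(D), colnames(D)], D, tolerance = 1e-9)
  }
})

test_that("NJ is exact on additive distances up to 12 leaves", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    gen <- ape::unroot(ape::rtree(n))
    gen$edge.length <- gen$edge.length + 0.1  # keep branches clearly positive
    D <- ape::cophenetic.phylo(gen)
    tr <- nj_tree(D)
    expect_equal(ape::dist.topo(gen, tr), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    D2 <- ape::cophenetic.phylo(tr)
    expect_equal(D2[rownames(D), colnames(D)], D, tolerance = 1e-8)
    expect_equal(attr(tr, "n_clamped"), 0L)
  }
})

test_that("3-leaf NJ solves the three-point formulas", {
  ids <- c("A", "B", "C")
  D <- sym_mat(c(6L, 8L, 10L), ids)  # AB=6, AC=8, BC=10
  tr <- nj_tree(dist_fixture(D))
  # leaf edge lengths: a=(AB+AC-BC)/2=2, b=(AB+BC-AC)/2=4, c=(AC+BC-AB)/2=6
  el <- tr$edge.length[match(seq_along(ids), tr$edge[, 2])]
  expect_equal(unname(el[match(ids, tr$tip.label)]), c(2, 4, 6))
  expect_error(nj_tree(dist_fixture(sym_mat(1L, c("A", "B")))), "at least 3")
})

test_that("negative NJ branch estimates are clamped and logged", {
  # strongly non-additive distances known to produce negative NJ estimates
  D <- sym_mat(c(4L, 7L, 1L, 2L, 11L, 14L, 18L, 19L, 1L, 10L), letters[1:5])
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_equal(attr(tr, "n_clamped"), 2L)
  expect_equal(attr(tr, "clamp_deficit"), 0.625 + 11 / 3, tolerance = 1e-9)
})

test_that("bootstrap supports are seeded, reproducible, and {0,100} at one replicate", {
  sim <- generate_collection(small_sim(seed = 13))
  m <- sim$matrix
  b1 <- bootstrap_support(m, "upgma", n_replicates = 20, seed = 99)
  b2 <- bootstrap_support(m, "upgma", n_replicates = 20, seed = 99)
  expect_identical(b1$node.label, b2$node.label)
  expect_identical(to_newick(b1), to_newick(b2))

  one <- bootstrap_support(m, "nj", n_replicates = 1, seed = 4)
  expect_true(all(as.integer(one$node.label) %in% c(0L, 100L)))
  expect_error(bootstrap_support(m, "upgma", n_replicates = 0), ">= 1")
})

test_that("a unanimous clean split gets 100% support", {
  # two clusters separated by many identical informative columns, no conflict
  block <- c(rep(0L, 4), rep(1L, 4))
  x <- matrix(rep(block, 30), nrow = 8)
  dimnames(x) <- list(sprintf("t%d", 1:8), sprintf("f%d", 1:30))
  bt <- bootstrap_support(band_matrix(x), "upgma", n_replicates = 25, seed = 1)
  split_node <- ape::getMRCA(bt, c("t1", "t2", "t3", "t4"))
  supp <- as.integer(bt$node.label[split_node - length(bt$tip.label)])
  expect_equal(supp, 100L)
})

test_that("collapse keeps strong edges, removes weak ones, preserves depths", {
  sim <- generate_collection(small_sim(seed = 23))
  bt <- bootstrap_support(sim$matrix, "upgma", n_replicates = 30, seed = 8)
  depth_before <- ape::node.depth.edgelength(bt)

  # all supports >= 0: collapsing at 0 is the identity
  same <- collapse_branches(bt, min_support = 0)
  expect_equal(to_newick(same), to_newick(bt))

  # collapsing above the max support leaves a star
  star <- collapse_branches(bt, min_support = 101)
  expect_equal(star$Nnode, 1L)
  expect_setequal(star$tip.label, bt$tip.label)

  # mixed threshold: surviving splits are exactly the strong subset
  col <- collapse_branches(bt, min_support = 75)
  supp <- suppressWarnings(as.numeric(bt$node.label))
  # recompute which original splits had support >= 75
  parts <- ape::prop.part(bt)
  labs <- attr(parts, "labels")
  keep <- vapply(seq_along(parts), function(i) {
    s <- supp[i]
    is.na(s) || s >= 75
  }, logical(1))
  enc <- vapply(parts, function(p) paste(sort(labs[p]), collapse = ","), character(1))
  expected <- sort(unique(enc[keep & lengths(parts) < length(labs)]))
  got <- sort(vapply(ape::prop.part(col)[-1], function(p)
    paste(sort(attr(ape::prop.part(col), "labels")[p]), collapse = ","), character(1)))
  expect_setequal(got, setdiff(expected, paste(sort(labs), collapse = ",")))

  # leaf depths unchanged by contraction
  depth_after <- ape::node.depth.edgelength(col)
  expect_equal(sort(depth_after[seq_along(col$tip.label)]),
               sort(depth_before[seq_along(bt$tip.label)]), tolerance = 1e-12)
})

test_that("newick serialisation round-trips, including polytomies", {
  d <- dist_fixture(sym_mat(c(2L, 8L, 8L), c("A", "B", "C")))
  tr <- upgma_tree(d)
  s <- to_newick(tr)
  back <- ape::read.tree(text = s)
  expect_equal(sort(back$tip.label), c("A", "B", "C"))
  # A,B sit together under the root at their original heights
  expect_setequal(ape::extract.clade(back, ape::getMRCA(back, c("A", "B")))$tip.label,
                  c("A", "B"))
  expect_equal(ape::node.depth.edgelength(back)[1:3],
               ape::node.depth.edgelength(tr)[1:3])

  sim <- generate_collection(small_sim(seed = 3))
  bt <- bootstrap_support(sim$matrix, "upgma", n_replicates = 10, seed = 2)
  col <- collapse_branches(bt, 75)
  f <- withr::local_tempfile(fileext = ".nwk")
  to_newick(col, f)
  back2 <- ape::read.tree(f)
  expect_setequal(back2$tip.label, col$tip.label)
  expect_equal(back2$Nnode, col$Nnode)
  # supports survive as internal node labels
  expect_true(any(grepl("^[0-9]+$", back2$node.label)))
})

test_that("every planted group forms a supported clade on clean-gap data", {
  sim <- generate_collection(small_sim(seed = 41, group_sizes = c(2L, 3L, 4L),
                                       within_clone_flips = c(0L, 2L)))
  d <- pairwise_differences(sim$matrix)
  stopifnot(gap_holds(sim, d))
  bt <- bootstrap_support(sim$matrix, "upgma", n_replicates = 50, seed = 6)
  col <- collapse_branches(bt, 75)
  for (mem in truth_clusters(sim$truth)) {
    mrca <- ape::getMRCA(col, mem)
    clade_tips <- ape::extract.clade(col, mrca)$tip.label
    expect_setequal(clade_tips, mem)
  }
})
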