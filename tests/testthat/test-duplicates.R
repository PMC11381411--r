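test_that("single linkage chains through the threshold and reports the full range", {
  # A-B=1, B-C=5, A-C=6 at threshold 5: one component, max_diff exceeds t
  d <- dist_fixture(sym_mat(c(1L, 6L, 5L), c("A", "B", "C")))
  census <- call_duplicates(d, threshold = 5)
  expect_length(census$clusters, 1L)
  cl <- census$clusters[[1]]
  expect_equal(cl$members, c("A", "B", "C"))
  expect_equal(cl$min_diff, 1L)
  expect_equal(cl$max_diff, 6L)
  expect_equal(census$n_unique_genotypes, 1L)

  # complete linkage refuses the chain
  cc <- call_duplicates(d, threshold = 5, linkage = "complete")
  expect_equal(vapply(cc$clusters, function(x) length(x$members), integer(1)), 2L)
})

test_that("no links means no clusters and every accession is its own genotype", {
  d <- dist_fixture(sym_mat(c(10L, 12L, 11L), c("A", "B", "C")))
  census <- call_duplicates(d, threshold = 5)
  expect_length(census$clusters, 0L)
  expect_equal(census$n_singletons, 3L)
  expect_equal(census$n_unique_genotypes, 3L)
  expect_error(call_duplicates(d, threshold = -1), "non-negative")
})

test_that("labels are deterministic: size-descending, ties by smallest member", {
  ids <- c("w", "x", "a", "b", "c")
  m <- matrix(50L, 5, 5, dimnames = list(ids, ids))
  diag(m) <- 0L
  m["w", "x"] <- m["x", "w"] <- 1L          # pair {w,x}
  m["a", "b"] <- m["b", "a"] <- 2L          # pair {a,b}; c stays single
  census <- call_duplicates(dist_fixture(m), threshold = 5)
  expect_equal(census$clusters[[1]]$cluster_id, "C-1")
  expect_equal(census$clusters[[1]]$members, c("a", "b"))  # tie broken by id
  expect_equal(census$clusters[[2]]$members, c("w", "x"))
})

test_that("raising the threshold only merges, never splits, and covers more", {
  set.seed(21)
  for (rep in 1:10) {
    m <- rand_band_matrix(10, 20, missing_rate = 0.1)
    d <- pairwise_differences(m)
    prev_cov <- -1L
    prev <- NULL
    for (t in c(0L, 2L, 5L, 10L)) {
      census <- call_duplicates(d, threshold = t)
      expect_gte(census$n_accessions_in_clusters, prev_cov)
      prev_cov <- census$n_accessions_in_clusters
      # bookkeeping identity on every run
      expect_equal(census$n_unique_genotypes,
                   census$n_singletons + length(census$clusters))
      expect_equal(census$n_accessions_in_clusters + census$n_singletons,
                   census$n_accessions)
      # clusters at lower t are refinements of clusters at higher t
      if (!is.null(prev)) {
        for (cl in prev) {
          host <- vapply(census$clusters, function(c2)
            all(cl$members %in% c2$members), logical(1))
          expect_equal(sum(host), 1L)
        }
      }
      prev <- census$clusters
    }
  }
})

test_that("within-cluster pair mass at <= t equals the histogram mass at <= t", {
  sim <- generate_collection(small_sim(seed = 77, n_singletons = 15))
  d <- pairwise_differences(sim$matrix)
  census <- call_duplicates(d, threshold = 5)
  within_pairs <- sum(vapply(census$clusters, function(cl) {
    sub <- d$diff[cl$members, cl$members]
    sum(sub[upper.tri(sub)] <= 5L)
  }, integer(1)))
  h <- difference_histogram(d)
  vals <- as.integer(names(h$counts))
  expect_equal(within_pairs, sum(h$counts[vals <= 5L]))
})

test_that("census table renders member names and difference ranges", {
  d <- dist_fixture(sym_mat(c(0L, 50L, 50L), c("A1", "A2", "B1")))
  census <- call_duplicates(d, threshold = 5)
  tab <- census_table(census)
  expect_equal(tab$cluster_id, "C-1")
  expect_equal(tab$members, "A1, A2")
  expect_equal(tab$size, 2L)
  expect_equal(tab$differences, "0")

  meta <- data.frame(accession_id = c("A1", "A2", "B1"),
                     name = c("Kerrs Pink", "Arran Victory", "Mandel"),
                     collection = "NordGen", country = "Sweden",
                     clonal_type = "landrace")
  tab2 <- census_table(census, meta)
  expect_equal(tab2$members, "Arran Victory, Kerrs Pink")

  # min != max renders as a range
  d2 <- dist_fixture(sym_mat(c(0L, 3L, 2L), c("A", "B", "C")))
  tab3 <- census_table(call_duplicates(d2, threshold = 5))
  expect_equal(tab3$differences, "0 - 3")
})

test_that("census files are written in long CSV plus rendered text", {
  d <- dist_fixture(sym_mat(c(1L, 60L, 60L), c("A", "B", "C")))
  census <- call_duplicates(d, threshold = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".txt")
  write_census(census, f, text_path = ft)
  long <- utils::read.csv(f)
  expect_equal(long$member, c("A", "B"))
  expect_equal(unique(long$cluster_id), "C-1")
  expect_match(readLines(ft), "C-1", all = FALSE)
})

test_that("threshold suggestion reads the first empty histogram bin", {
  # differences 0,1,2 present, 3 empty, then bulk at 50
  v <- c(0L, 1L, 2L, 50L, 50L, 50L, 50L, 50L, 51L, 52L)
  d <- dist_fixture(sym_mat(v, c("a", "b", "c", "d", "e")))
  expect_equal(suggest_threshold(d), 2L)
  # no zero-difference spike -> nothing to suggest
  d2 <- dist_fixture(sym_mat(c(50L, 51L, 52L), c("a", "b", "c")))
  expect_true(is.na(suggest_threshold(d2)))
})

test_that("planted clonal groups are recovered exactly from simulated data", {
  sim <- generate_collection(small_sim(seed = 5, group_sizes = c(2L, 3L, 4L)))
  d <- pairwise_differences(sim$matrix)
  census <- call_duplicates(d, threshold = 5)
  expect_true(same_clusters(census, truth_clusters(sim$truth)))
  tab <- census_table(census)
  expect_equal(nrow(tab), 3L)  # one row per planted group
})
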