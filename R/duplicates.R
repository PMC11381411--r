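#' Call duplicate (clonal) clusters at a mismatch threshold
#'
#' Accessions whose fingerprints differ by at most `threshold` bands are
#' linked, and the connected components of the resulting graph with two or
#' more members are reported as duplicate clusters (single-linkage transitive
#' closure). Under chaining the largest within-cluster difference can exceed
#' the threshold; both extremes are reported per cluster so such cases are
#' visible. A complete-linkage alternative, in which every within-cluster
#' pair must satisfy the threshold, is available via `linkage = "complete"`
#' for sensitivity analysis.
#'
#' @param d a [pairwise_differences()] result.
#' @param threshold maximum difference count linking two accessions
#'   (default 5, the conventional cut for clonal potato material scored on
#'   ~500 bands, i.e. about 1% divergence).
#' @param linkage `"single"` (connected components, default) or `"complete"`
#'   (complete-linkage clusters cut at the threshold).
#' @return a list of class `duplicate_census`: `clusters` (each with
#'   `cluster_id`, `members`, `min_diff`, `max_diff`), `threshold`,
#'   `linkage`, `n_accessions`, `n_accessions_in_clusters`, `n_singletons`,
#'   `n_unique_genotypes`, and `size_distribution` (cluster size -> count).
#'   Clusters are labelled `C-1`, `C-2`, ... in order of decreasing size,
#'   ties broken by smallest member id, so reruns are reproducible.
#' @export
call_duplicates <- function(d, threshold = 5L, linkage = c("single", "complete")) {
  stopifnot(inherits(d, "band_distance"))
  linkage <- match.arg(linkage)
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  ids <- d$accession_ids
  n <- length(ids)
  if (linkage == "single") {
    adj <- d$diff <= threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    hc <- stats::hclust(stats::as.dist(d$diff), method = "complete")
    memb <- stats::cutree(hc, h = threshold)
  }
  groups <- split(ids, memb)
  groups <- groups[lengths(groups) >= 2L]
  clusters <- lapply(groups, function(mem) {
    sub <- d$diff[mem, mem, drop = FALSE]
    dv <- sub[upper.tri(sub)]
    list(members = sort(mem), min_diff = min(dv), max_diff = max(dv))
  })
  ord <- order(-vapply(clusters, function(cl) length(cl$members), integer(1)),
               vapply(clusters, function(cl) cl$members[1L], character(1)))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- sprintf("C-%d", i)
  n_in <- sum(vapply(clusters, function(cl) length(cl$members), integer(1)))
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  size_distribution <- if (length(sizes)) table(sizes) else table(integer(0))
  structure(list(
    clusters = unname(clusters),
    threshold = as.integer(threshold),
    linkage = linkage,
    n_accessions = n,
    n_accessions_in_clusters = n_in,
    n_singletons = n - n_in,
    n_unique_genotypes = (n - n_in) + length(clusters),
    size_distribution = size_distribution
  ), class = "duplicate_census")
}

#' @export
print.duplicate_census <- function(x, ...) {
  cat(sprintf("duplicate census at threshold %d (%s linkage)\n", x$threshold, x$linkage))
  cat(sprintf("  %d accessions: %d in %d clusters, %d singletons -> %d unique genotypes\n",
              x$n_accessions, x$n_accessions_in_clusters, length(x$clusters),
              x$n_singletons, x$n_unique_genotypes))
  if (length(x$clusters)) {
    cat("  cluster sizes: ")
    print(x$size_distribution)
  }
  invisible(x)
}

#' Tabulate a duplicate census
#'
#' One row per cluster: label, members (name-sorted, metadata names when
#' available), size and the observed within-cluster difference range,
#' rendered as `"min - max"` or a single value when the two coincide —
#' the layout genebank curators use when reviewing candidate duplicates.
#'
#' @param census a [call_duplicates()] result.
#' @param meta optional metadata data.frame from [read_accession_metadata()];
#'   member names are taken from its `name` column where present, falling
#'   back to the accession id.
#' @return a data.frame with columns `cluster_id`, `members`, `size`,
#'   `differences`, `min_diff`, `max_diff`.
#' @export
census_table <- function(census, meta = NULL) {
  stopifnot(inherits(census, "duplicate_census"))
  label <- function(ids) {
    if (!is.null(meta)) {
      i <- match(ids, meta$accession_id)
      nm <- ifelse(is.na(i), ids, meta$name[i])
    } else nm <- ids
    paste(sort(nm), collapse = ", ")
  }
  rows <- lapply(census$clusters, function(cl) {
    data.frame(
      cluster_id = cl$cluster_id,
      members = label(cl$members),
      size = length(cl$members),
      differences = if (cl$min_diff == cl$max_diff) as.character(cl$min_diff)
                    else sprintf("%d - %d", cl$min_diff, cl$max_diff),
      min_diff = cl$min_diff,
      max_diff = cl$max_diff,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(cluster_id = character(0), members = character(0),
                      size = integer(0), differences = character(0),
                      min_diff = integer(0), max_diff = integer(0)))
  }
  do.call(rbind, rows)
}

#' Write a duplicate census
#'
#' Emits a machine-readable long CSV (one row per cluster member) and, when
#' `text_path` is given, a human-readable table mirroring how such cluster
#' censuses are published.
#'
#' @param census a [call_duplicates()] result.
#' @param path destination for the CSV.
#' @param meta optional metadata (see [census_table()]).
#' @param text_path optional destination for the rendered text table.
#' @export
write_census <- function(census, path, meta = NULL, text_path = NULL) {
  stopifnot(inherits(census, "duplicate_census"))
  long <- do.call(rbind, lapply(census$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, member = cl$members,
               size = length(cl$members), min_diff = cl$min_diff,
               max_diff = cl$max_diff, stringsAsFactors = FALSE)
  }))
  if (is.null(long))
    long <- data.frame(cluster_id = character(0), member = character(0),
                       size = integer(0), min_diff = integer(0), max_diff = integer(0))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  if (!is.null(text_path)) {
    tab <- census_table(census, meta)
    lines <- c(sprintf("Duplicate clusters at <= %d differences (%s linkage)",
                       census$threshold, census$linkage),
               sprintf("%d accessions in %d clusters; %d singletons; %d unique genotypes",
                       census$n_accessions_in_clusters, length(census$clusters),
                       census$n_singletons, census$n_unique_genotypes),
               "",
               sprintf("%-6s | %-4s | %-9s | %s", "id", "n", "diffs", "members"),
               vapply(seq_len(nrow(tab)), function(i)
                 sprintf("%-6s | %-4d | %-9s | %s", tab$cluster_id[i], tab$size[i],
                         tab$differences[i], tab$members[i]), character(1)))
    writeLines(lines, text_path)
  }
  invisible(path)
}

#' Suggest a duplicate threshold from the difference histogram
#'
#' Scans difference values upward from zero and returns the value just below
#' the first empty histogram bin — the natural reading of the gap between the
#' duplicate spike and the distinct-genotype bulk. The suggestion is only
#' ever reported; callers must opt in to using it.
#'
#' @param d a [pairwise_differences()] result.
#' @return integer threshold suggestion, or `NA` when the histogram has no
#'   empty bin below its maximum (no visible gap) or no zero-difference pairs.
#' @export
suggest_threshold <- function(d) {
  h <- difference_histogram(d)
  vals <- as.integer(names(h$counts))
  if (!(0L %in% vals)) return(NA_integer_)
  full <- rep(0L, max(vals) + 1L)
  full[vals + 1L] <- h$counts
  gap <- which(full == 0L)
  if (!length(gap)) return(NA_integer_)
  as.integer(gap[1L] - 2L)
}
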