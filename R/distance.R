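#' Pairwise band differences under pairwise deletion
#'
#' For every unordered pair of accessions, counts the fragments scored
#' (non-missing) in both members and, among those, the fragments where the
#' two fingerprints disagree. Missing cells are dropped per pair (pairwise
#' deletion), never per column, so a band missing in one accession still
#' contributes to comparisons among the others. Monomorphic bands stay in
#' the computation; they simply contribute zero mismatches, which keeps the
#' fixed total-band denominator of [proportion_matrix()] literal.
#'
#' @param m a [band_matrix()].
#' @return an object of class `band_distance`: a list with integer matrices
#'   `diff` (mismatch counts) and `compared` (mutually scored bands), the
#'   scalar `total_bands`, and the accession ids.
#' @details A pair with no mutually scored band has no defined distance and
#'   raises an error naming the pair; with tens of markers such a pair
#'   signals a corrupt matrix, not a value to propagate.
#' @export
pairwise_differences <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  x <- unclass(m)
  P <- (x == 1L & !is.na(x)) * 1
  A <- (x == 0L & !is.na(x)) * 1
  Obs <- (!is.na(x)) * 1
  d <- tcrossprod(P, A)
  d <- d + t(d)
  cmp <- tcrossprod(Obs)
  diag(d) <- 0
  storage.mode(d) <- "integer"
  storage.mode(cmp) <- "integer"
  zero <- which(cmp == 0L & upper.tri(cmp), arr.ind = TRUE)
  if (nrow(zero)) {
    stop(sprintf("no mutually scored band for pair %s / %s: distance undefined",
                 rownames(x)[zero[1L, 1L]], rownames(x)[zero[1L, 2L]]),
         call. = FALSE)
  }
  dimnames(d) <- dimnames(cmp) <- list(rownames(x), rownames(x))
  structure(list(diff = d, compared = cmp, total_bands = ncol(x),
                 accession_ids = rownames(x)),
            class = "band_distance")
}

#' @export
print.band_distance <- function(x, ...) {
  dv <- x$diff[upper.tri(x$diff)]
  cat(sprintf("band_distance: %d accessions, %d total bands\n",
              length(x$accession_ids), x$total_bands))
  cat(sprintf("  differences: min %d, mean %.1f, max %d over %d pairs\n",
              min(dv), mean(dv), max(dv), length(dv)))
  invisible(x)
}

#' Proportion-divergence matrix
#'
#' Divides each pairwise difference count by the total number of bands in the
#' matrix (e.g. 1/493 = 0.2% for a single mismatch in a 493-band study). The
#' denominator is deliberately the fixed band total, not the per-pair
#' compared count, so values are comparable across pairs with different
#' missingness; set `denominator = "compared"` for the per-pair alternative.
#'
#' @param d a [pairwise_differences()] result.
#' @param denominator `"total"` (default) or `"compared"`.
#' @return a symmetric numeric matrix of fractions.
#' @export
proportion_matrix <- function(d, denominator = c("total", "compared")) {
  stopifnot(inherits(d, "band_distance"))
  denominator <- match.arg(denominator)
  if (denominator == "total") {
    if (d$total_bands <= 0) stop("total_bands must be positive", call. = FALSE)
    p <- d$diff / d$total_bands
  } else {
    p <- d$diff / d$compared
    diag(p) <- 0
  }
  p
}

#' Histogram of pairwise difference counts
#'
#' Tabulates the number of accession pairs at each difference value over all
#' unordered pairs. In a clonally propagated collection the histogram is
#' characteristically bimodal: a spike near zero (duplicates) separated by a
#' sparse band from the bulk of genuinely distinct genotypes.
#'
#' @param d a [pairwise_differences()] result.
#' @return a list of class `diff_histogram` with `counts` (named integer
#'   vector, names are difference values) and `n_pairs`.
#' @export
difference_histogram <- function(d) {
  stopifnot(inherits(d, "band_distance"))
  dv <- d$diff[upper.tri(d$diff)]
  tab <- table(dv)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(counts = counts, n_pairs = length(dv)), class = "diff_histogram")
}

#' @export
print.diff_histogram <- function(x, ...) {
  cat(sprintf("difference histogram over %d pairs\n", x$n_pairs))
  print(x$counts)
  invisible(x)
}

#' Mean pairwise difference
#'
#' @param d a [pairwise_differences()] result.
#' @return arithmetic mean of the difference counts over all unordered pairs.
#' @export
mean_difference <- function(d) {
  stopifnot(inherits(d, "band_distance"))
  if (length(d$accession_ids) < 2L) stop("need at least 2 accessions", call. = FALSE)
  mean(d$diff[upper.tri(d$diff)])
}

#' Count pairs in a divergence band
#'
#' Number of unordered pairs with difference count in `(low, high]` — strictly
#' more than `low`, at most `high`. Useful for checking how sparse the gap
#' between the duplicate spike and the distinct-genotype bulk is.
#'
#' @param d a [pairwise_differences()] result.
#' @param low,high integers with `0 <= low <= high`.
#' @return integer count of pairs.
#' @export
divergence_band <- function(d, low, high) {
  stopifnot(inherits(d, "band_distance"))
  if (low < 0 || high < low) stop("need 0 <= low <= high", call. = FALSE)
  dv <- d$diff[upper.tri(d$diff)]
  sum(dv > low & dv <= high)
}

#' Export a distance matrix
#'
#' `write_distance_csv()` writes the square mismatch-count matrix as CSV with
#' accession ids in the first column. `write_distance_phylip()` writes the
#' square PHYLIP distance format (count of taxa on the first line, then one
#' row per taxon: id followed by its distances) accepted by external tree
#' programs, for cross-checking dendrograms against other implementations.
#'
#' @param d a [pairwise_differences()] result.
#' @param path destination path.
#' @export
write_distance_csv <- function(d, path) {
  stopifnot(inherits(d, "band_distance"))
  df <- data.frame(accession_id = rownames(d$diff), d$diff, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
write_distance_phylip <- function(d, path) {
  stopifnot(inherits(d, "band_distance"))
  n <- nrow(d$diff)
  ids <- gsub("[ \t]", "_", rownames(d$diff))
  lines <- c(sprintf("%5d", n),
             vapply(seq_len(n), function(i)
               paste(c(ids[i], format(d$diff[i, ])), collapse = "  "),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
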