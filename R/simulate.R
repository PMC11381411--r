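#' Configuration for the synthetic fingerprint simulator
#'
#' Defaults emulate a Nordic-scale clonal potato collection genotyped with
#' ~60 SSR markers and dominant band scoring: 62 loci with 3–12 alleles
#' each (giving ~460–470 band columns), 1–4 present bands per locus per
#' tetraploid genotype, 109 singleton genotypes plus 31 clonal groups
#' (21 pairs, 4 triples, 3 quadruples, 1 quintuple, one group of 8 and one
#' of 10 — 198 accessions, 140 genotypes in all), members of a group within
#' 0–5 band flips of their founder, and ~1% missing cells. Allele
#' frequencies within a locus are geometrically skewed (`allele_skew`), so
#' unrelated genotypes share common alleles and typically differ by 70–140
#' bands rather than the much larger counts uniform allele choice would
#' give.
#'
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus integer range (length 2) of allele-pool sizes.
#' @param bands_per_genotype integer range of distinct present bands a
#'   genotype carries per locus (tetraploid: at most 4).
#' @param allele_skew geometric decay parameter in (0, 1) for within-locus
#'   allele frequencies; larger values concentrate mass on few alleles.
#' @param group_sizes integer vector: one entry per planted clonal group,
#'   giving its size (each >= 2).
#' @param n_singletons number of genotypes represented by a single accession.
#' @param within_clone_flips integer range of band flips separating a group
#'   member from its founder.
#' @param missing_rate per-cell probability of a missing score.
#' @param seed optional integer seed used by [generate_collection()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 62L,
                       alleles_per_locus = c(3L, 12L),
                       bands_per_genotype = c(1L, 4L),
                       allele_skew = 0.65,
                       group_sizes = rep(c(2L, 3L, 4L, 5L, 8L, 10L),
                                         c(21L, 4L, 3L, 1L, 1L, 1L)),
                       n_singletons = 109L,
                       within_clone_flips = c(0L, 5L),
                       missing_rate = 0.01,
                       seed = NULL) {
  cfg <- list(n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              bands_per_genotype = as.integer(bands_per_genotype),
              allele_skew = allele_skew,
              group_sizes = as.integer(group_sizes),
              n_singletons = as.integer(n_singletons),
              within_clone_flips = as.integer(within_clone_flips),
              missing_rate = missing_rate,
              seed = seed)
  if (cfg$n_loci < 1L) stop("n_loci must be positive", call. = FALSE)
  if (length(cfg$alleles_per_locus) != 2L || cfg$alleles_per_locus[1L] < 2L ||
      diff(cfg$alleles_per_locus) < 0L)
    stop("alleles_per_locus must be an increasing range with lower bound >= 2",
         call. = FALSE)
  if (length(cfg$bands_per_genotype) != 2L || cfg$bands_per_genotype[1L] < 1L ||
      cfg$bands_per_genotype[2L] > 4L || diff(cfg$bands_per_genotype) < 0L)
    stop("bands_per_genotype must be a range within 1..4 (tetraploid)", call. = FALSE)
  if (!(allele_skew > 0 && allele_skew < 1))
    stop("allele_skew must be in (0, 1)", call. = FALSE)
  if (any(cfg$group_sizes < 2L)) stop("every clonal group needs >= 2 members", call. = FALSE)
  if (cfg$n_singletons < 0L) stop("n_singletons must be non-negative", call. = FALSE)
  if (length(cfg$within_clone_flips) != 2L || cfg$within_clone_flips[1L] < 0L ||
      diff(cfg$within_clone_flips) < 0L)
    stop("within_clone_flips must be a non-negative increasing range", call. = FALSE)
  if (cfg$within_clone_flips[2L] > 20L)
    stop("within_clone_flips upper bound too large to keep the planted gap ",
         "below the between-genotype difference regime", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (cfg$n_singletons + length(cfg$group_sizes) < 2L)
    stop("need at least 2 genotypes", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Flip bands of a clone's fingerprint
#'
#' Toggles exactly `n_flips` distinct band positions of a fingerprint,
#' modelling the somatic mutation and scoring error that separates members
#' of a clonal group by a handful of band differences.
#'
#' @param genotype_bands integer vector of 0/1 band states.
#' @param n_flips number of positions to toggle, chosen uniformly without
#'   replacement.
#' @return the perturbed band vector; its Hamming distance to the input is
#'   exactly `n_flips`.
#' @export
perturb_clone <- function(genotype_bands, n_flips) {
  if (n_flips < 0) stop("n_flips must be non-negative", call. = FALSE)
  if (n_flips > length(genotype_bands))
    stop("n_flips exceeds fingerprint length", call. = FALSE)
  if (n_flips == 0) return(genotype_bands)
  pos <- sample.int(length(genotype_bands), n_flips)
  genotype_bands[pos] <- 1L - genotype_bands[pos]
  genotype_bands
}

#' Generate a synthetic clonal collection with ground truth
#'
#' Draws an allele pool per locus, one fingerprint per unique genotype
#' (bands chosen per locus with geometrically skewed allele frequencies),
#' expands each planted clonal group from its founder by [perturb_clone()]
#' (the founder is itself the first member, so every member lies within the
#' flip range of it), sprinkles missing cells, shuffles accession order and
#' records which genotype each accession came from.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `ssr_simulation` with elements `matrix` (a
#'   [band_matrix()] with locus labels), `truth` (data.frame `accession_id`,
#'   `genotype`, `group_id`; `group_id` is `NA` for singletons) and `meta`
#'   (a plausible metadata sidecar in the [read_accession_metadata()]
#'   layout).
#' @export
generate_collection <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_groups <- length(cfg$group_sizes)
  n_geno <- cfg$n_singletons + n_groups
  pool_sizes <- sample(seq(cfg$alleles_per_locus[1L], cfg$alleles_per_locus[2L]),
                       cfg$n_loci, replace = TRUE)
  marker <- sprintf("SSR%02d", seq_len(cfg$n_loci))
  base_bp <- sample(80:280, cfg$n_loci, replace = TRUE)
  frag_locus <- rep(marker, pool_sizes)
  frag_ids <- unlist(lapply(seq_len(cfg$n_loci), function(l)
    sprintf("%s_%d", marker[l], base_bp[l] + 2L * seq_len(pool_sizes[l]))))
  n_frag <- length(frag_ids)
  col_of_locus <- split(seq_len(n_frag), factor(frag_locus, levels = marker))

  draw_genotype <- function() {
    v <- integer(n_frag)
    for (l in seq_len(cfg$n_loci)) {
      a <- pool_sizes[l]
      w <- cfg$allele_skew * (1 - cfg$allele_skew)^(seq_len(a) - 1L)
      kmax <- min(cfg$bands_per_genotype[2L], a)
      kmin <- min(cfg$bands_per_genotype[1L], kmax)
      k <- if (kmin == kmax) kmin else sample(seq(kmin, kmax), 1L)
      v[col_of_locus[[l]][sample.int(a, k, prob = w)]] <- 1L
    }
    v
  }
  genotypes <- t(vapply(seq_len(n_geno), function(i) draw_genotype(), integer(n_frag)))
  geno_labels <- sprintf("G%03d", seq_len(n_geno))

  n_acc <- cfg$n_singletons + sum(cfg$group_sizes)
  cells <- matrix(NA_integer_, nrow = n_acc, ncol = n_frag)
  truth_geno <- character(n_acc)
  truth_group <- rep(NA_character_, n_acc)
  i <- 0L
  for (g in seq_len(n_groups)) {
    founder <- genotypes[g, ]
    for (k in seq_len(cfg$group_sizes[g])) {
      i <- i + 1L
      flips <- if (k == 1L) 0L else
        sample(seq(cfg$within_clone_flips[1L], cfg$within_clone_flips[2L]), 1L)
      cells[i, ] <- perturb_clone(founder, flips)
      truth_geno[i] <- geno_labels[g]
      truth_group[i] <- sprintf("G-%d", g)
    }
  }
  for (s in seq_len(cfg$n_singletons)) {
    i <- i + 1L
    cells[i, ] <- genotypes[n_groups + s, ]
    truth_geno[i] <- geno_labels[n_groups + s]
  }
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(cells)) < cfg$missing_rate
    cells[drop] <- NA_integer_
  }
  ord <- sample.int(n_acc)
  cells <- cells[ord, , drop = FALSE]
  truth_geno <- truth_geno[ord]
  truth_group <- truth_group[ord]
  acc_ids <- sprintf("ACC-%03d", seq_len(n_acc))
  dimnames(cells) <- list(acc_ids, frag_ids)

  clone_index <- stats::ave(seq_len(n_acc), truth_geno, FUN = seq_along)
  meta <- data.frame(
    accession_id = acc_ids,
    name = sprintf("%s clone %d", truth_geno, clone_index),
    collection = sample(c("LKF-Vandel", "NordGen", "NGS"), n_acc, replace = TRUE),
    country = sample(c("Denmark", "Finland", "Iceland", "Norway", "Sweden"),
                     n_acc, replace = TRUE),
    clonal_type = sample(c("landrace", "improved variety", "breeding line", "unknown"),
                         n_acc, replace = TRUE, prob = c(0.4, 0.4, 0.1, 0.1)),
    stringsAsFactors = FALSE
  )
  structure(list(
    matrix = band_matrix(cells, loci = frag_locus),
    truth = data.frame(accession_id = acc_ids, genotype = truth_geno,
                       group_id = truth_group, stringsAsFactors = FALSE),
    meta = meta,
    config = cfg
  ), class = "ssr_simulation")
}

#' @export
print.ssr_simulation <- function(x, ...) {
  cat(sprintf("ssr_simulation: %d accessions x %d fragments, %d planted groups\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(stats::na.omit(x$truth$group_id)))))
  invisible(x)
}

#' Planted clusters from simulator ground truth
#'
#' Reshapes the truth table into the same cluster structure
#' [call_duplicates()] emits (member sets ordered by decreasing size, ties
#' by smallest member id), so recovered and planted partitions can be
#' compared directly with [same_clusters()].
#'
#' @param truth the `truth` data.frame of an [generate_collection()] result.
#' @return a list of character vectors of member accession ids.
#' @export
truth_clusters <- function(truth) {
  grouped <- truth[!is.na(truth$group_id), ]
  groups <- split(grouped$accession_id, grouped$group_id)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1L))
  unname(groups[ord])
}

#' Compare two cluster partitions
#'
#' @param a,b lists of member-id vectors, or a [call_duplicates()] census.
#' @return `TRUE` iff both contain exactly the same member sets.
#' @export
same_clusters <- function(a, b) {
  norm <- function(x) {
    if (inherits(x, "duplicate_census"))
      x <- lapply(x$clusters, function(cl) cl$members)
    unname(sort(vapply(x, function(mem) paste(sort(mem), collapse = "|"),
                       character(1))))
  }
  identical(norm(a), norm(b))
}

#' Write a simulated collection to disk
#'
#' Emits the same matrix and metadata CSVs [read_band_matrix()] and
#' [read_accession_metadata()] read, plus a `truth.csv`
#' (`accession_id,genotype,group_id`).
#'
#' @param sim an [generate_collection()] result.
#' @param dir destination directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ssr_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_band_matrix(sim$matrix, file.path(dir, "matrix.csv"))
  utils::write.csv(sim$meta, file.path(dir, "metadata.csv"), row.names = FALSE,
                   quote = TRUE)
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}
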