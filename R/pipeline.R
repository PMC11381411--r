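#' Run the full duplicate-identification pipeline
#'
#' One reproducible run: read (or simulate) a band matrix, validate it,
#' compute pairwise-deletion differences, the difference histogram and mean,
#' call the duplicate census at the threshold, build the requested trees
#' with bootstrap support, collapse weakly supported branches, and write all
#' artifacts to `out_dir`. Identical configuration and seed produce
#' byte-identical outputs.
#'
#' Artifacts written: `validation.txt`, `histogram.csv`, `distances.csv`,
#' `distances.phy`, `census.csv`, `census.txt`,
#' `tree_<method>.nwk`, `tree_<method>_collapsed.nwk`, `report.json`, and in
#' simulate mode `matrix.csv`, `metadata.csv`, `truth.csv`. On failure the
#' stage name is prefixed to the error and files created by the failed run
#' are removed.
#'
#' @param matrix_path path to a band-matrix CSV (see [read_band_matrix()]);
#'   ignored when `sim` is given.
#' @param metadata_path optional accession metadata CSV.
#' @param sim optional [sim_config()]; when given, the collection is
#'   simulated instead of read.
#' @param out_dir output directory, created if needed.
#' @param threshold duplicate threshold in band differences (default 5).
#' @param methods tree methods to run, subset of `c("upgma", "nj")`.
#' @param n_replicates bootstrap replicates (default 500).
#' @param min_support collapse threshold in percent (default 75).
#' @param linkage clustering rule for [call_duplicates()].
#' @param seed integer seed governing simulation and bootstrap.
#' @param dialect named list of token options passed to [read_band_matrix()]
#'   (`sep`, `present`, `absent`, `missing`).
#' @return the run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(matrix_path = NULL, metadata_path = NULL, sim = NULL,
                         out_dir, threshold = 5L, methods = c("upgma", "nj"),
                         n_replicates = 500L, min_support = 75,
                         linkage = c("single", "complete"),
                         seed = NULL, dialect = list()) {
  linkage <- match.arg(linkage)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(matrix_path) && is.null(sim))
    stop("either matrix_path or sim must be given", call. = FALSE)
  created_dir <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- "setup"
  report <- tryCatch({
    if (!is.null(seed)) set.seed(seed)

    stage <- "input"
    if (!is.null(sim)) {
      sim_run <- generate_collection(sim)
      m <- sim_run$matrix
      meta <- sim_run$meta
      write_band_matrix(m, out("matrix.csv"))
      utils::write.csv(meta, out("metadata.csv"), row.names = FALSE, quote = TRUE)
      utils::write.csv(sim_run$truth, out("truth.csv"), row.names = FALSE, quote = FALSE)
    } else {
      m <- do.call(read_band_matrix, c(list(path = matrix_path), dialect))
      meta <- if (!is.null(metadata_path)) read_accession_metadata(metadata_path)
              else NULL
      sim_run <- NULL
    }

    stage <- "validate"
    val <- validate_matrix(m)
    writeLines(utils::capture.output(print(val)), out("validation.txt"))

    stage <- "distances"
    d <- pairwise_differences(m)
    write_distance_csv(d, out("distances.csv"))
    write_distance_phylip(d, out("distances.phy"))
    h <- difference_histogram(d)
    utils::write.csv(data.frame(differences = as.integer(names(h$counts)),
                                n_pairs = h$counts, row.names = NULL),
                     out("histogram.csv"), row.names = FALSE)

    stage <- "duplicates"
    census <- call_duplicates(d, threshold = threshold, linkage = linkage)
    write_census(census, out("census.csv"), meta = meta, text_path = out("census.txt"))

    stage <- "trees"
    tree_log <- list()
    tree_files <- list()
    for (method in methods) {
      bt <- bootstrap_support(m, method = method, n_replicates = n_replicates)
      to_newick(bt, out(sprintf("tree_%s.nwk", method)))
      collapsed <- collapse_branches(bt, min_support = min_support)
      to_newick(collapsed, out(sprintf("tree_%s_collapsed.nwk", method)))
      tree_files[[method]] <- sprintf("tree_%s.nwk", method)
      tree_log[[method]] <- list(
        n_replicates = attr(bt, "n_replicates"),
        n_redrawn_replicates = attr(bt, "n_redrawn"),
        n_clamped_branches = if (method == "nj") attr(bt, "n_clamped") else 0L,
        n_internal_edges_kept = sum(
          suppressWarnings(as.numeric(collapsed$node.label)) >= min_support,
          na.rm = TRUE)
      )
    }

    stage <- "report"
    report <- list(
      config = list(threshold = as.integer(threshold), linkage = linkage,
                    methods = methods, n_replicates = as.integer(n_replicates),
                    min_support = min_support, seed = seed,
                    simulated = !is.null(sim)),
      validation = unclass(val),
      mean_difference = mean_difference(d),
      histogram = list(differences = as.integer(names(h$counts)),
                       n_pairs = unname(h$counts)),
      census = list(
        n_clusters = length(census$clusters),
        n_accessions = census$n_accessions,
        n_accessions_in_clusters = census$n_accessions_in_clusters,
        n_singletons = census$n_singletons,
        n_unique_genotypes = census$n_unique_genotypes,
        size_distribution = as.list(stats::setNames(
          as.integer(census$size_distribution),
          names(census$size_distribution)))
      ),
      trees = tree_log,
      files = c(list(census = "census.csv", distances = "distances.csv"),
                tree_files)
    )
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    report
  }, error = function(e) {
    unlink(written)
    if (created_dir) unlink(out_dir, recursive = TRUE)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
  invisible(report)
}
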