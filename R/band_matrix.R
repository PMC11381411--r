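#' Construct a band matrix
#'
#' A band matrix is the standard container for dominant SSR fingerprints:
#' rows are accessions, columns are amplified fragments (bands), and each
#' cell records whether the fragment was observed in that accession.
#' Dominant scoring (present/absent, no allele dosage) is the usual choice
#' for autotetraploid crops such as potato, where dosage cannot be called
#' reliably from fragment intensities.
#'
#' @param cells integer or logical matrix with one row per accession and one
#'   column per fragment; values must be `1` (present), `0` (absent) or `NA`
#'   (missing/uninterpretable). Row names are accession ids, column names are
#'   fragment ids; both are required and must be unique.
#' @param loci optional character vector, one entry per fragment, giving the
#'   SSR marker (locus) each band belongs to. Only the simulator and
#'   documentation use the grouping; distances are always per band.
#' @return an object of class `band_matrix`: the integer matrix with the
#'   `loci` attribute attached.
#' @examples
#' m <- band_matrix(matrix(c(1, 1, 0, 1, 0, NA), nrow = 2,
#'                         dimnames = list(c("A", "B"), c("f1", "f2", "f3"))))
#' n_accessions(m)
#' @export
band_matrix <- function(cells, loci = NULL) {
  if (!is.matrix(cells)) stop("`cells` must be a matrix", call. = FALSE)
  storage.mode(cells) <- "integer"
  bad <- !(cells %in% c(0L, 1L, NA_integer_))
  if (any(bad)) {
    stop("band matrix cells must be 0, 1 or NA; found ",
         paste(unique(cells[bad]), collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) < 2L) stop("a band matrix needs at least 2 accessions", call. = FALSE)
  if (ncol(cells) < 1L) stop("a band matrix needs at least 1 fragment", call. = FALSE)
  if (is.null(rownames(cells)) || is.null(colnames(cells)))
    stop("accession ids (row names) and fragment ids (column names) are required",
         call. = FALSE)
  if (anyDuplicated(rownames(cells)))
    stop("duplicated accession ids: ",
         paste(unique(rownames(cells)[duplicated(rownames(cells))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(cells)))
    stop("duplicated fragment ids: ",
         paste(unique(colnames(cells)[duplicated(colnames(cells))]), collapse = ", "),
         call. = FALSE)
  if (!is.null(loci)) {
    if (length(loci) != ncol(cells))
      stop("`loci` must have one entry per fragment", call. = FALSE)
    loci <- as.character(loci)
  }
  structure(cells, loci = loci, class = c("band_matrix", "matrix", "array"))
}

#' @rdname band_matrix
#' @param m a `band_matrix`
#' @export
n_accessions <- function(m) nrow(m)

#' @rdname band_matrix
#' @export
n_fragments <- function(m) ncol(m)

#' @rdname band_matrix
#' @export
accession_ids <- function(m) rownames(m)

#' @rdname band_matrix
#' @export
fragment_ids <- function(m) colnames(m)

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band_matrix: %d accessions x %d fragments (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  loci <- attr(x, "loci")
  if (!is.null(loci)) cat(sprintf("  %d loci\n", length(unique(loci))))
  invisible(x)
}

#' Read a band matrix from a delimited text file
#'
#' Expects a header row of fragment ids, then one row per accession whose
#' first field is the accession id. The tokens used for the three cell states
#' are configurable so that matrices exported from different scoring tools
#' can be read without editing the file.
#'
#' @param path path to the file.
#' @param sep field separator (default `","`).
#' @param present,absent tokens coding band presence/absence (defaults `"1"`,
#'   `"0"`).
#' @param missing character vector of tokens read as missing (default
#'   `c("?", "NA", "")`).
#' @param loci optional locus label per fragment column, passed through to
#'   [band_matrix()].
#' @return a [band_matrix()].
#' @export
read_band_matrix <- function(path, sep = ",", present = "1", absent = "0",
                             missing = c("?", "NA", ""), loci = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("band matrix file needs a header and at least one row",
                               call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1L]])
  frag_ids <- header[-1L]
  nfrag <- length(frag_ids)
  rows <- fields[-1L]
  acc_ids <- character(length(rows))
  cells <- matrix(NA_integer_, nrow = length(rows), ncol = nfrag)
  for (i in seq_along(rows)) {
    row <- trimws(rows[[i]])
    if (length(row) != nfrag + 1L) {
      stop(sprintf("row %d ('%s') has %d fields, expected %d",
                   i, row[1L], length(row), nfrag + 1L), call. = FALSE)
    }
    acc_ids[i] <- row[1L]
    tok <- row[-1L]
    v <- rep(NA_integer_, nfrag)
    v[tok == present] <- 1L
    v[tok == absent] <- 0L
    known <- tok == present | tok == absent | tok %in% missing
    if (!all(known)) {
      j <- which(!known)[1L]
      stop(sprintf("unknown token '%s' at row %d ('%s'), column %d ('%s')",
                   tok[j], i, acc_ids[i], j, frag_ids[j]), call. = FALSE)
    }
    cells[i, ] <- v
  }
  dimnames(cells) <- list(acc_ids, frag_ids)
  band_matrix(cells, loci = loci)
}

#' Write a band matrix to a delimited text file
#'
#' Writes the matrix in the same layout [read_band_matrix()] expects, so that
#' a write/read round trip reproduces the matrix cell for cell.
#'
#' @param m a [band_matrix()].
#' @param path destination path.
#' @param sep field separator.
#' @param present,absent,missing tokens to emit for the three cell states
#'   (defaults `"1"`, `"0"`, `"?"`).
#' @export
write_band_matrix <- function(m, path, sep = ",", present = "1", absent = "0",
                              missing = "?") {
  stopifnot(inherits(m, "band_matrix"))
  chr <- matrix(missing, nrow = nrow(m), ncol = ncol(m))
  chr[which(m == 1L)] <- present
  chr[which(m == 0L)] <- absent
  lines <- c(paste(c("accession_id", colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], chr[i, ]), collapse = sep), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Validate a band matrix and summarise its content
#'
#' Counts polymorphic fragments (those whose non-missing cells include both
#' present and absent) and monomorphic ones (all non-missing cells identical,
#' or all missing). Structural issues are collected in `problems` rather than
#' raised, so a partially defective matrix can still be inspected.
#'
#' @param m a [band_matrix()].
#' @return a list of class `band_validation` with fields `n_accessions`,
#'   `n_fragments`, `n_missing_cells`, `n_polymorphic`, `n_monomorphic`,
#'   `problems`.
#' @export
validate_matrix <- function(m) {
  stopifnot(inherits(m, "band_matrix"))
  has1 <- colSums(m == 1L, na.rm = TRUE) > 0L
  has0 <- colSums(m == 0L, na.rm = TRUE) > 0L
  poly <- has1 & has0
  problems <- character(0)
  all_missing_rows <- rownames(m)[rowSums(!is.na(m)) == 0L]
  if (length(all_missing_rows))
    problems <- c(problems, paste0("accession with all cells missing: ",
                                   paste(all_missing_rows, collapse = ", ")))
  all_missing_cols <- sum(colSums(!is.na(m)) == 0L)
  if (all_missing_cols > 0L)
    problems <- c(problems, sprintf("%d fragment(s) with all cells missing",
                                    all_missing_cols))
  structure(list(
    n_accessions = nrow(m),
    n_fragments = ncol(m),
    n_missing_cells = sum(is.na(m)),
    n_polymorphic = sum(poly),
    n_monomorphic = sum(!poly),
    problems = problems
  ), class = "band_validation")
}

#' @export
print.band_validation <- function(x, ...) {
  cat(sprintf("band matrix: %d accessions, %d fragments (%d polymorphic, %d monomorphic), %d missing cells\n",
              x$n_accessions, x$n_fragments, x$n_polymorphic, x$n_monomorphic,
              x$n_missing_cells))
  if (length(x$problems)) {
    cat("problems:\n")
    for (p in x$problems) cat("  - ", p, "\n", sep = "")
  }
  invisible(x)
}

.clonal_types <- c("landrace", "improved variety", "breeding line", "unknown")

#' Read an accession metadata sidecar table
#'
#' Metadata (name, source collection, country of origin, clonal type) lives
#' in a separate CSV keyed by accession id, keeping the band matrix itself
#' purely binary.
#'
#' @param path CSV with columns `accession_id`, `name`, `collection`,
#'   `country`, `clonal_type`.
#' @param collections optional character vector of permitted collection
#'   labels; unknown labels are reported as an error when supplied.
#' @return a data.frame with one row per accession.
#' @export
read_accession_metadata <- function(path, collections = NULL) {
  meta <- utils::read.csv(path, colClasses = "character")
  need <- c("accession_id", "name", "collection", "country", "clonal_type")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(!nzchar(meta$accession_id))) stop("empty accession_id in metadata", call. = FALSE)
  if (anyDuplicated(meta$accession_id))
    stop("duplicated accession_id in metadata", call. = FALSE)
  bad <- !(meta$clonal_type %in% .clonal_types)
  if (any(bad))
    stop("unknown clonal_type: ", paste(unique(meta$clonal_type[bad]), collapse = ", "),
         "; expected one of ", paste(.clonal_types, collapse = ", "), call. = FALSE)
  if (!is.null(collections)) {
    bad <- !(meta$collection %in% collections)
    if (any(bad))
      stop("unknown collection: ", paste(unique(meta$collection[bad]), collapse = ", "),
           call. = FALSE)
  }
  meta[, need]
}
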