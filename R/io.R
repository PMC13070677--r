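#' Read a spatial transcriptomics dataset from disk
#'
#' Two plain-text directory layouts are supported:
#' \describe{
#'   \item{`mtx_dir`}{`matrix.mtx` (MatrixMarket, spots x genes) +
#'     `genes.tsv` (one gene id per line) + `coords.tsv` (tab-separated; two
#'     columns `x`, `y` in matrix row order, or three columns with the spot id
#'     first; a header row is detected automatically) + optional `spots.tsv`
#'     with one spot id per line.}
#'   \item{`csv`}{`expression.csv` — dense spot-by-gene table, first column
#'     the spot id, header the gene ids — plus `coords.csv` keyed by spot id
#'     with columns `x` and `y`.}
#' }
#'
#' @param path Directory containing the files above.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param layer Layer tag to attach (default `"counts"`).
#' @return An [st_dataset()].
#' @seealso [write_st()] for the inverse; the pair round-trips exactly for
#'   `mtx_dir` and to float precision for `csv`.
#' @export
read_st <- function(path, format = c("mtx_dir", "csv"), layer = "counts") {
  format <- check_format(format)
  if (!dir.exists(path)) stop("no such directory: ", path)
  switch(format,
    mtx_dir = {
      need <- file.path(path, c("matrix.mtx", "genes.tsv", "coords.tsv"))
      missing <- need[!file.exists(need)]
      if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))
      x <- as.matrix(Matrix::readMM(need[1]))
      genes <- readLines(need[2])
      if (length(genes) != ncol(x))
        stop("genes.tsv has ", length(genes), " ids for ", ncol(x), " columns")
      colnames(x) <- genes
      spots_file <- file.path(path, "spots.tsv")
      rownames(x) <- if (file.exists(spots_file)) readLines(spots_file)
                     else paste0("spot_", seq_len(nrow(x)))
      coords <- read_coords_tsv(need[3], rownames(x))
      st_dataset(x, coords, layer = layer)
    },
    csv = {
      ef <- file.path(path, "expression.csv")
      cf <- file.path(path, "coords.csv")
      if (!file.exists(ef) || !file.exists(cf))
        stop("expected expression.csv and coords.csv under ", path)
      tab <- utils::read.csv(ef, row.names = 1, check.names = FALSE)
      x <- as.matrix(tab)
      co <- utils::read.csv(cf, row.names = 1, check.names = FALSE)
      if (!setequal(rownames(co), rownames(x)))
        stop("spot ids of coords.csv do not match expression.csv")
      coords <- as.matrix(co[rownames(x), c("x", "y")])
      st_dataset(x, coords, layer = layer)
    })
}

read_coords_tsv <- function(file, spot_ids) {
  first <- strsplit(readLines(file, n = 1), "\t", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first[length(first)]))))
  co <- utils::read.delim(file, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(co) == 3L) {
    ids <- as.character(co[[1]])
    if (!setequal(ids, spot_ids))
      stop("spot ids in coords.tsv do not match the matrix spot ids")
    rownames(co) <- ids
    co <- co[spot_ids, 2:3]
  } else if (ncol(co) != 2L) {
    stop("coords.tsv must have 2 columns (x, y) or 3 (id, x, y)")
  }
  if (nrow(co) != length(spot_ids))
    stop("coords.tsv has ", nrow(co), " rows for ", length(spot_ids), " spots")
  out <- as.matrix(co)
  storage.mode(out) <- "double"
  rownames(out) <- spot_ids
  out
}

#' Write a spatial transcriptomics dataset to disk
#'
#' Inverse of [read_st()]; creates the directory if needed. `mtx_dir` writes
#' `matrix.mtx`, `genes.tsv`, `spots.tsv` and `coords.tsv` (id, x, y with a
#' header); `csv` writes `expression.csv` and `coords.csv`.
#'
#' @param st An [st_dataset()].
#' @param path Output directory.
#' @param format `"mtx_dir"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_st <- function(st, path, format = c("mtx_dir", "csv")) {
  stopifnot(inherits(st, "st_dataset"))
  format <- check_format(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  switch(format,
    mtx_dir = {
      Matrix::writeMM(methods::as(Matrix::Matrix(st$x, sparse = TRUE),
                                  "generalMatrix"),
                      file.path(path, "matrix.mtx"))
      writeLines(colnames(st$x), file.path(path, "genes.tsv"))
      writeLines(rownames(st$x), file.path(path, "spots.tsv"))
      utils::write.table(
        data.frame(spot = rownames(st$x), x = st$coords[, 1], y = st$coords[, 2]),
        file.path(path, "coords.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
    },
    csv = {
      utils::write.csv(as.data.frame(st$x), file.path(path, "expression.csv"))
      utils::write.csv(data.frame(x = st$coords[, 1], y = st$coords[, 2],
                                  row.names = rownames(st$x)),
                       file.path(path, "coords.csv"))
    })
  invisible(path)
}

check_format <- function(format) {
  if (identical(format, "h5ad"))
    stop("h5ad is not supported by this package; use 'mtx_dir' or 'csv'")
  match.arg(format, c("mtx_dir", "csv"))
}

#' Read a labeled single-cell reference from disk
#'
#' Same layouts as [read_st()] but with per-cell labels instead of
#' coordinates: `mtx_dir` expects `matrix.mtx` (cells x genes), `genes.tsv`,
#' optional `cells.tsv`, and `labels.tsv` (one cell-type name per line);
#' `csv` expects `expression.csv` and `labels.csv` (columns: cell id,
#' `cell_type`).
#'
#' @inheritParams read_st
#' @return A [labeled_reference()].
#' @export
read_reference <- function(path, format = c("mtx_dir", "csv")) {
  format <- check_format(format)
  if (!dir.exists(path)) stop("no such directory: ", path)
  switch(format,
    mtx_dir = {
      x <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
      colnames(x) <- readLines(file.path(path, "genes.tsv"))
      cells_file <- file.path(path, "cells.tsv")
      rownames(x) <- if (file.exists(cells_file)) readLines(cells_file)
                     else paste0("cell_", seq_len(nrow(x)))
      labels <- readLines(file.path(path, "labels.tsv"))
      labeled_reference(x, labels)
    },
    csv = {
      x <- as.matrix(utils::read.csv(file.path(path, "expression.csv"),
                                     row.names = 1, check.names = FALSE))
      lab <- utils::read.csv(file.path(path, "labels.csv"), row.names = 1)
      if (!setequal(rownames(lab), rownames(x)))
        stop("cell ids of labels.csv do not match expression.csv")
      labeled_reference(x, as.character(lab[rownames(x), "cell_type"]))
    })
}

#' Write a labeled reference to disk
#'
#' @param ref A [labeled_reference()].
#' @inheritParams write_st
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, format = c("mtx_dir", "csv")) {
  stopifnot(inherits(ref, "labeled_reference"))
  format <- check_format(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  switch(format,
    mtx_dir = {
      Matrix::writeMM(methods::as(Matrix::Matrix(ref$counts, sparse = TRUE),
                                  "generalMatrix"),
                      file.path(path, "matrix.mtx"))
      writeLines(colnames(ref$counts), file.path(path, "genes.tsv"))
      writeLines(rownames(ref$counts), file.path(path, "cells.tsv"))
      writeLines(ref$labels, file.path(path, "labels.tsv"))
    },
    csv = {
      utils::write.csv(as.data.frame(ref$counts),
                       file.path(path, "expression.csv"))
      utils::write.csv(data.frame(cell_type = ref$labels,
                                  row.names = rownames(ref$counts)),
                       file.path(path, "labels.csv"))
    })
  invisible(path)
}

#' Write a simulated dataset (counts, coordinates, ground truth)
#'
#' Writes the pseudo-spot [st_dataset()] via [write_st()], the ground-truth
#' proportion matrix as `proportions.csv` (spot id x type names), and the
#' generator provenance (seed, parameters) as `provenance.json`.
#'
#' @param sim A [sim_st()].
#' @inheritParams write_st
#' @return `path`, invisibly.
#' @export
write_sim_st <- function(sim, path, format = c("mtx_dir", "csv")) {
  stopifnot(inherits(sim, "sim_st"))
  write_st(sim$st, path, format = format)
  utils::write.csv(as.data.frame(sim$proportions),
                   file.path(path, "proportions.csv"))
  jsonlite::write_json(sim$provenance, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a proportions CSV (spot id x cell type)
#'
#' @param path CSV file with spot ids in the first column and one column per
#'   cell type.
#' @return Numeric matrix with spot ids as row names.
#' @export
read_proportions <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
}
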