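#' Spatial transcriptomics dataset
#'
#' Bundle a spot-by-gene expression matrix with 2D spot coordinates. This is
#' the container both real and simulated data flow through: rows are spots,
#' columns are genes, and `coords` holds one (x, y) pair per spot.
#'
#' @param x Numeric matrix (base or `Matrix` sparse), spots in rows, genes in
#'   columns. Row names are spot ids, column names gene ids; defaults are
#'   generated when absent.
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   columns (x, y). Row names, if present, must match the spot ids of `x`.
#' @param layer Which processing stage the values represent: raw `"counts"`,
#'   library-size-normalized log values (`"normalized"`), or per-gene
#'   standardized values (`"scaled"`).
#' @return An object of class `"st_dataset"`: a list with elements `x`,
#'   `coords` and `layer`.
#' @examples
#' st <- st_dataset(matrix(rpois(20, 5), 4, 5), cbind(x = 1:4, y = rep(1, 4)))
#' st
#' @export
st_dataset <- function(x, coords, layer = c("counts", "normalized", "scaled")) {
  layer <- match.arg(layer)
  x <- as_expr_matrix(x)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop("'coords' must be a numeric matrix with two columns (x, y)")
  if (nrow(coords) != nrow(x))
    stop("coordinate rows (", nrow(coords), ") do not match expression rows (",
         nrow(x), ")")
  if (!all(is.finite(coords)))
    stop("'coords' contains non-finite values")
  if (!is.null(rownames(coords)) && !identical(rownames(coords), rownames(x)))
    stop("spot ids of 'coords' do not match spot ids of 'x'")
  rownames(coords) <- rownames(x)
  colnames(coords) <- c("x", "y")
  if (layer == "counts" && any(x < 0))
    stop("counts layer must be nonnegative")
  structure(list(x = x, coords = coords, layer = layer), class = "st_dataset")
}

#' Labeled single-cell reference
#'
#' A cell-by-gene count matrix with a cell-type label per cell. Used only to
#' simulate training pseudo-spots with known proportions (see
#' [simulate_spots()]); the deconvolution itself never sees individual cells.
#'
#' @param counts Nonnegative cell-by-gene count matrix (cells in rows).
#' @param labels Character or factor vector of per-cell cell-type names,
#'   length `nrow(counts)`.
#' @param type_names Optional ordered character vector of the k distinct types;
#'   defaults to the sorted unique labels. Every label must appear in it and
#'   every listed type must have at least one cell.
#' @return An object of class `"labeled_reference"` with elements `counts`,
#'   `labels` (character) and `type_names`.
#' @export
labeled_reference <- function(counts, labels, type_names = NULL) {
  counts <- as_expr_matrix(counts)
  if (any(counts < 0)) stop("reference counts must be nonnegative")
  labels <- as.character(labels)
  if (length(labels) != nrow(counts))
    stop("'labels' length (", length(labels), ") does not match cell count (",
         nrow(counts), ")")
  if (is.null(type_names)) type_names <- sort(unique(labels))
  if (!all(labels %in% type_names))
    stop("labels not listed in 'type_names': ",
         paste(setdiff(labels, type_names), collapse = ", "))
  missing_types <- setdiff(type_names, labels)
  if (length(missing_types))
    stop("cell types with zero cells: ", paste(missing_types, collapse = ", "))
  structure(list(counts = counts, labels = labels, type_names = type_names),
            class = "labeled_reference")
}

#' Simulated spatial transcriptomics dataset with ground truth
#'
#' An [st_dataset()] of aggregated pseudo-spot counts together with the
#' ground-truth spot-by-type proportion matrix realized during simulation.
#' Normally produced by [simulate_spots()] rather than called directly.
#'
#' @param st An `st_dataset` of pseudo-spot counts.
#' @param proportions Spot-by-type matrix; every row must be on the simplex.
#' @param type_names Cell-type names, one per proportion column.
#' @param provenance List recording the generator call (seed, parameters).
#' @return An object of class `"sim_st"`.
#' @export
sim_st <- function(st, proportions, type_names, provenance = list()) {
  stopifnot(inherits(st, "st_dataset"))
  proportions <- as.matrix(proportions)
  if (nrow(proportions) != nrow(st$x))
    stop("proportion rows do not match spot count")
  if (ncol(proportions) != length(type_names))
    stop("proportion columns do not match number of type names")
  if (any(proportions < 0) || any(abs(rowSums(proportions) - 1) > 1e-9))
    stop("every proportion row must be nonnegative and sum to 1")
  colnames(proportions) <- type_names
  rownames(proportions) <- rownames(st$x)
  structure(list(st = st, proportions = proportions, type_names = type_names,
                 provenance = provenance),
            class = "sim_st")
}

# Coerce to a dense base matrix with unique ids on both axes.
as_expr_matrix <- function(x) {
  if (inherits(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L) stop("expression matrix is empty")
  if (is.null(rownames(x))) rownames(x) <- paste0("obs_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("gene_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("observation ids are not unique")
  if (anyDuplicated(colnames(x))) stop("gene ids are not unique")
  x
}

#' @export
print.st_dataset <- function(x, ...) {
  cat("Spatial transcriptomics dataset (", x$layer, " layer)\n", sep = "")
  cat("  ", nrow(x$x), " spots x ", ncol(x$x), " genes\n", sep = "")
  rng <- apply(x$coords, 2, range)
  cat(sprintf("  coords: x in [%g, %g], y in [%g, %g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
  invisible(x)
}

#' @export
print.labeled_reference <- function(x, ...) {
  cat("Labeled single-cell reference\n")
  cat("  ", nrow(x$counts), " cells x ", ncol(x$counts), " genes, ",
      length(x$type_names), " cell types\n", sep = "")
  print(table(factor(x$labels, levels = x$type_names)))
  invisible(x)
}

#' @export
print.sim_st <- function(x, ...) {
  cat("Simulated ST dataset with ground-truth proportions\n")
  cat("  ", nrow(x$st$x), " spots x ", ncol(x$st$x), " genes, ",
      length(x$type_names), " cell types\n", sep = "")
  if (!is.null(x$provenance$seed))
    cat("  generator seed: ", x$provenance$seed, "\n", sep = "")
  invisible(x)
}
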