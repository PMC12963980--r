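#' Construct a spatial expression dataset
#'
#' Bundles a genes-by-spots expression matrix with per-spot 2-D coordinates.
#' This is the common input container for all detectors and ensembles: rows
#' are genes, columns are spots, and the i-th row of `coords` describes the
#' spot in the i-th column of `expr`.
#'
#' @param expr Numeric matrix, P genes x N spots. Row and column names, when
#'   present, must agree with `gene_ids` / `spot_ids`.
#' @param coords Data frame or matrix with one row per spot and columns
#'   `spot_id`, `x`, `y` (a bare two-column matrix is accepted when
#'   `spot_ids` is given or `expr` has column names).
#' @param gene_ids,spot_ids Character vectors of unique identifiers; default
#'   to the dimnames of `expr`.
#' @param normalized Logical flag recording whether `expr` holds normalized
#'   values rather than raw counts.
#'
#' @return An object of class `spatial_dataset`: a list with elements
#'   `expr` (named matrix), `coords` (tibble with `spot_id`, `x`, `y`) and
#'   `normalized`.
#' @examples
#' expr <- matrix(rpois(12, 3), 3, 4,
#'                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' coords <- data.frame(spot_id = paste0("s", 1:4), x = c(0, 1, 0, 1),
#'                      y = c(0, 0, 1, 1))
#' ds <- spatial_dataset(expr, coords)
#' n_genes(ds)
#' @export
spatial_dataset <- function(expr, coords, gene_ids = rownames(expr),
                            spot_ids = colnames(expr), normalized = FALSE) {
  expr <- as.matrix(expr)
  if (!is.numeric(expr)) abort("`expr` must be a numeric matrix.")
  if (nrow(expr) < 1L || ncol(expr) < 2L) {
    abort("`expr` needs at least 1 gene and 2 spots.")
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(expr)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(ncol(expr)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != nrow(expr)) abort("`gene_ids` length != nrow(expr).")
  if (length(spot_ids) != ncol(expr)) abort("`spot_ids` length != ncol(expr).")
  if (anyDuplicated(gene_ids)) {
    abort(paste0("Duplicate gene ids: ",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(spot_ids)) abort("Duplicate spot ids.")
  if (!all(is.finite(expr))) abort("`expr` contains non-finite values.")
  if (!normalized && any(expr < 0)) abort("Raw counts must be non-negative.")

  if (is.matrix(coords)) {
    coords <- as.data.frame(coords)
    if (ncol(coords) == 2L) coords <- cbind(spot_id = spot_ids, coords)
    names(coords) <- c("spot_id", "x", "y")
  }
  coords <- as_tibble(coords)
  if (!all(c("spot_id", "x", "y") %in% names(coords))) {
    abort("`coords` must have columns spot_id, x, y.")
  }
  coords <- coords[, c("spot_id", "x", "y")]
  coords$spot_id <- as.character(coords$spot_id)
  if (!is.numeric(coords$x) || !is.numeric(coords$y) ||
      !all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    abort("Coordinates must be finite numerics.")
  }
  if (nrow(coords) != ncol(expr)) abort("`coords` must have one row per spot.")
  if (!setequal(coords$spot_id, spot_ids)) {
    missing <- setdiff(spot_ids, coords$spot_id)
    extra <- setdiff(coords$spot_id, spot_ids)
    abort(paste0("Spot ids in `coords` and `expr` disagree. Missing from coords: ",
                 paste(missing, collapse = ", "), "; extra in coords: ",
                 paste(extra, collapse = ", ")))
  }
  # order spots to match the coordinate table
  expr <- expr[, match(coords$spot_id, spot_ids), drop = FALSE]
  dimnames(expr) <- list(gene_ids, coords$spot_id)
  structure(list(expr = expr, coords = coords, normalized = isTRUE(normalized)),
            class = "spatial_dataset")
}

#' @rdname spatial_dataset
#' @param ds A `spatial_dataset`.
#' @export
n_genes <- function(ds) nrow(ds$expr)

#' @rdname spatial_dataset
#' @export
n_spots <- function(ds) ncol(ds$expr)

#' @rdname spatial_dataset
#' @export
gene_ids <- function(ds) rownames(ds$expr)

#' @rdname spatial_dataset
#' @export
spot_ids <- function(ds) colnames(ds$expr)

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d genes x %d spots (%s)\n",
              n_genes(x), n_spots(x),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Load an expression matrix and spot coordinates from disk
#'
#' Reads either a Matrix Market (`.mtx`) file with `features.tsv` /
#' `barcodes.tsv` sidecars in the same directory, or a dense delimited file
#' with gene ids in the first column and spot ids in the header (or the
#' transpose, see `orientation`). Coordinates come from a delimited file
#' with columns `spot_id`, `x`, `y`; the returned dataset orders spots to
#' match the coordinate table.
#'
#' @param expr_path Path to the expression file (`.mtx`, `.csv` or `.tsv`).
#' @param coords_path Path to the coordinate table.
#' @param orientation `"genes_by_spots"` (default) or `"spots_by_genes"`,
#'   describing the on-disk layout of a dense matrix.
#' @return A [spatial_dataset] with `normalized = FALSE`.
#' @export
load_dataset <- function(expr_path, coords_path,
                         orientation = c("genes_by_spots", "spots_by_genes")) {
  orientation <- match.arg(orientation)
  coords <- read_delim_auto(coords_path)
  if (ncol(coords) < 3L) abort("Coordinate file needs columns spot_id, x, y.")
  names(coords)[1:3] <- c("spot_id", "x", "y")
  coords <- coords[, c("spot_id", "x", "y")]
  if (!is.numeric(coords$x) || !is.numeric(coords$y)) {
    abort("Non-numeric coordinate column in coordinate file.")
  }

  if (grepl("\\.mtx(\\.gz)?$", expr_path)) {
    m <- as.matrix(Matrix::readMM(expr_path))
    dir <- dirname(expr_path)
    feats <- read_id_column(file.path(dir, "features.tsv"))
    bars <- read_id_column(file.path(dir, "barcodes.tsv"))
    if (orientation == "spots_by_genes") m <- t(m)
    if (length(feats) != nrow(m) || length(bars) != ncol(m)) {
      abort("features.tsv / barcodes.tsv sizes do not match the MTX matrix.")
    }
    dimnames(m) <- list(feats, bars)
  } else {
    tab <- read_delim_auto(expr_path)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(m)) abort("Expression file contains non-numeric entries.")
    rownames(m) <- ids
    if (orientation == "spots_by_genes") m <- t(m)
  }

  missing <- setdiff(colnames(m), coords$spot_id)
  extra <- setdiff(coords$spot_id, colnames(m))
  if (length(missing) || length(extra)) {
    abort(paste0("Spot sets in expression and coordinate files differ. ",
                 if (length(missing)) paste0("Missing from coords: ",
                                             paste(missing, collapse = ", "), ". "),
                 if (length(extra)) paste0("Missing from expression: ",
                                           paste(extra, collapse = ", "), ".")))
  }
  spatial_dataset(m, coords, normalized = FALSE)
}

#' Write a dataset to dense delimited files
#'
#' Inverse of [load_dataset()] for the dense text layout: a TSV with genes as
#' rows and spot ids as header, plus a `spot_id,x,y` coordinate TSV.
#'
#' @inheritParams n_genes
#' @param expr_path,coords_path Output paths (tab-separated).
#' @export
write_dataset <- function(ds, expr_path, coords_path) {
  tab <- as_tibble(ds$expr, rownames = "gene_id")
  readr::write_tsv(tab, expr_path)
  readr::write_tsv(ds$coords, coords_path)
  invisible(c(expr_path, coords_path))
}

#' Library-size normalize an expression dataset
#'
#' Scales every spot (column) so its total equals `target_sum`, then
#' optionally applies `log(1 + v)`. This is the standard preprocessing for
#' the built-in detectors; it preserves the zero pattern of the matrix.
#'
#' @inheritParams n_genes
#' @param target_sum Positive scale for per-spot totals; defaults to the
#'   median spot total of `ds`.
#' @param log1p Apply the log(1+v) transform after scaling (default `TRUE`).
#' @return A `spatial_dataset` with `normalized = TRUE`.
#' @export
normalize_dataset <- function(ds, target_sum = NULL, log1p = TRUE) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (any(ds$expr < 0)) abort("normalize_dataset() expects non-negative counts.")
  totals <- colSums(ds$expr)
  if (any(totals == 0)) {
    abort(paste0("Spot(s) with zero total count: ",
                 paste(spot_ids(ds)[totals == 0], collapse = ", ")))
  }
  if (is.null(target_sum)) target_sum <- stats::median(totals)
  if (!is.numeric(target_sum) || target_sum <= 0) {
    abort("`target_sum` must be a positive number.")
  }
  m <- sweep(ds$expr, 2L, totals / target_sum, "/")
  if (isTRUE(log1p)) m <- log1p(m)
  out <- ds
  out$expr <- m
  out$normalized <- TRUE
  out
}

# --- internal IO helpers -----------------------------------------------------

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

read_id_column <- function(path) {
  if (!file.exists(path)) abort(paste0("Missing sidecar file: ", path))
  as.character(readr::read_tsv(path, col_names = FALSE,
                               show_col_types = FALSE, progress = FALSE)[[1L]])
}
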