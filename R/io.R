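#' Construct a raw count matrix
#'
#' Container for a genes x spots matrix of nonnegative expression counts
#' (or pre-normalized values) with gene and spot identifiers.
#'
#' @param values numeric matrix, genes in rows, spots in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   `colnames(values)`.
#' @return A `raw_counts` object (a numeric matrix with dimnames and class).
#' @export
raw_counts <- function(values, gene_ids = rownames(values),
                       spot_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(spot_ids)) spot_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length does not match number of rows")
  if (length(spot_ids) != ncol(values))
    stop("spot_ids length does not match number of columns")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(spot_ids)) stop("duplicate spot_ids")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("matrix must have at least one gene and one spot")
  if (!all(is.finite(values))) stop("non-finite values in count matrix")
  if (any(values < 0)) stop("negative entries in count matrix")
  dimnames(values) <- list(gene_ids, spot_ids)
  class(values) <- c("raw_counts", class(values))
  values
}

#' Construct an expression matrix
#'
#' Like [raw_counts()] but carries a `normalized` flag and permits negative
#' values (log-scale residual expression is signed).
#'
#' @inheritParams raw_counts
#' @param normalized logical flag; `TRUE` when values are on the normalized
#'   scale the spatial test expects.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              spot_ids = colnames(values),
                              normalized = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(spot_ids)) spot_ids <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(spot_ids)) stop("duplicate spot_ids")
  if (!all(is.finite(values))) stop("non-finite expression values")
  dimnames(values) <- list(as.character(gene_ids), as.character(spot_ids))
  attr(values, "normalized") <- isTRUE(normalized)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' Construct a spot coordinate table
#'
#' @param coords numeric matrix, spots x d (d = 2 for standard slides).
#' @param spot_ids character identifiers aligned with rows of `coords`.
#' @return A `spatial_coords` object (numeric matrix with rownames).
#' @export
spatial_coords <- function(coords, spot_ids = rownames(coords)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (is.null(spot_ids)) spot_ids <- paste0("s", seq_len(nrow(coords)))
  if (length(spot_ids) != nrow(coords))
    stop("spot_ids length does not match number of coordinate rows")
  if (anyDuplicated(spot_ids)) stop("duplicate spot_ids")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  rownames(coords) <- as.character(spot_ids)
  class(coords) <- c("spatial_coords", "matrix", "array")
  coords
}

#' Read an expression matrix from disk
#'
#' Supports 10x-style MatrixMarket triplets (`matrix.mtx` plus co-located
#' `features.tsv` / `barcodes.tsv`) and delimited text with genes in rows,
#' a header of spot identifiers, and gene identifiers in the first column.
#'
#' @param path path to the `.mtx` file or the delimited file.
#' @param format `"mtx"`, `"delimited"`, or `"auto"` (by file extension).
#' @param features,barcodes optional explicit paths to the feature/barcode
#'   files accompanying an MTX matrix.
#' @param spots_as_rows for delimited input, set `TRUE` when the file is
#'   transposed (spots in rows); the matrix is coerced to genes x spots.
#' @return A [raw_counts()] object, genes x spots.
#' @export
load_expression <- function(path, format = c("auto", "mtx", "delimited"),
                            features = NULL, barcodes = NULL,
                            spots_as_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delimited"
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(features))
      features <- file.path(dirname(path), "features.tsv")
    if (is.null(barcodes))
      barcodes <- file.path(dirname(path), "barcodes.tsv")
    if (!file.exists(features)) stop("features file not found: ", features)
    if (!file.exists(barcodes)) stop("barcodes file not found: ", barcodes)
    gid <- data.table::fread(features, header = FALSE)[[1L]]
    sid <- data.table::fread(barcodes, header = FALSE)[[1L]]
    if (length(gid) != nrow(m))
      stop("features file has ", length(gid), " entries, matrix has ",
           nrow(m), " rows")
    if (length(sid) != ncol(m))
      stop("barcodes file has ", length(sid), " entries, matrix has ",
           ncol(m), " columns")
    return(raw_counts(m, gid, sid))
  }
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (isTRUE(spots_as_rows)) m <- t(m)
  raw_counts(m)
}

#' Read spot coordinates from delimited text
#'
#' Expects columns `spot_id`, `x`, `y` (extra coordinate columns are kept).
#'
#' @param path path to a TSV/CSV file.
#' @return A [spatial_coords()] object.
#' @export
load_coords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  spatial_coords(as.matrix(dt[, -1L, drop = FALSE]),
                 spot_ids = as.character(dt[[1L]]))
}

#' Align expression columns with a coordinate table
#'
#' Matches by spot identifier when both objects carry ids; otherwise falls
#' back to positional alignment with a warning.
#'
#' @param expr `raw_counts` or `expression_matrix`.
#' @param coords `spatial_coords`.
#' @return A list with the reordered `expr` and `coords`.
#' @export
align_spots <- function(expr, coords) {
  eid <- colnames(expr)
  cid <- rownames(coords)
  if (ncol(expr) != nrow(coords) && !setequal(eid, cid))
    stop("expression has ", ncol(expr), " spots but coordinates have ",
         nrow(coords))
  if (!is.null(eid) && !is.null(cid) && setequal(eid, cid)) {
    coords <- coords[match(eid, cid), , drop = FALSE]
    class(coords) <- c("spatial_coords", "matrix", "array")
  } else {
    warning("spot ids unavailable or mismatched; aligning by position")
    rownames(coords) <- eid
  }
  list(expr = expr, coords = coords)
}

#' Filter out sparse genes
#'
#' Keeps genes whose fraction of spots with nonzero expression is at least
#' `min_frac`; gene order is preserved.
#'
#' @param counts a [raw_counts()] object.
#' @param min_frac minimum nonzero fraction in `[0, 1]`; default 0.01.
#' @return A filtered `raw_counts` object.
#' @export
filter_genes <- function(counts, min_frac = 0.01) {
  stopifnot(min_frac >= 0, min_frac <= 1)
  frac <- rowMeans(unclass(counts) != 0)
  keep <- frac >= min_frac
  if (!any(keep)) stop("all genes removed by the sparsity filter")
  out <- unclass(counts)[keep, , drop = FALSE]
  raw_counts(out)
}

#' Normalize counts for the Gaussian-process test
#'
#' `lognorm` scales each spot to the median library size and applies
#' `log1p`; `none` passes values through with the `normalized` flag set,
#' for data normalized upstream.
#'
#' @param counts a [raw_counts()] object.
#' @param method `"lognorm"` or `"none"`.
#' @return An [expression_matrix()].
#' @export
normalize_counts <- function(counts, method = c("lognorm", "none")) {
  method <- match.arg(method)
  v <- unclass(counts)
  if (method == "none")
    return(expression_matrix(v, normalized = TRUE))
  lib <- colSums(v)
  if (any(lib == 0)) stop("spot(s) with zero library size: ",
                          paste(colnames(v)[lib == 0], collapse = ", "))
  sf <- stats::median(lib) / lib
  expression_matrix(log1p(sweep(v, 2L, sf, "*")), normalized = TRUE)
}

#' Write an expression matrix in a supported format
#'
#' @param x `raw_counts` or `expression_matrix`.
#' @param path output path; `.mtx` writes the MatrixMarket triplet with
#'   `features.tsv` and `barcodes.tsv` next to it, anything else writes
#'   delimited text (tab-separated, genes in rows).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  v <- unclass(x)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), path)
    data.table::fwrite(data.table::data.table(rownames(v)),
                       file.path(dirname(path), "features.tsv"),
                       col.names = FALSE, sep = "\t")
    data.table::fwrite(data.table::data.table(colnames(v)),
                       file.path(dirname(path), "barcodes.tsv"),
                       col.names = FALSE, sep = "\t")
  } else {
    dt <- data.table::data.table(gene_id = rownames(v))
    dt <- cbind(dt, data.table::as.data.table(v))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Write spot coordinates as delimited text
#'
#' @param coords a [spatial_coords()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_coords <- function(coords, path) {
  v <- unclass(coords)
  cn <- colnames(v)
  if (is.null(cn)) cn <- c("x", "y", "z")[seq_len(ncol(v))]
  dt <- data.table::data.table(spot_id = rownames(v))
  for (j in seq_len(ncol(v))) dt[[cn[j]]] <- v[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
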