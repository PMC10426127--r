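#' Construct a single-cell count matrix container
#'
#' Bundles a sparse feature x cell count matrix with per-cell metadata and a
#' low-dimensional embedding (the representation pools are built in, e.g., a
#' batch-corrected PCA or UMAP computed upstream).
#'
#' @param counts Sparse or dense nonnegative matrix, features x cells.
#' @param feature_ids,cell_ids Row/column identifiers (defaults to dimnames).
#' @param cell_meta Data frame with one row per cell; must contain
#'   `cell_type`, optionally `batch` and a `cell_id` key column.
#' @param embedding Numeric matrix, cells x E coordinates.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, feature_ids = rownames(counts),
                         cell_ids = colnames(counts), cell_meta, embedding) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(feature_ids)) feature_ids <- paste0("feature_", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(counts)))
  if (length(feature_ids) != nrow(counts)) stop("feature_ids length does not match matrix rows")
  if (length(cell_ids) != ncol(counts)) stop("cell_ids length does not match matrix columns")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"cell_type" %in% names(cell_meta)) stop("cell_meta must contain a cell_type column")
  if (nrow(cell_meta) != ncol(counts)) stop("cell_meta rows do not match number of cells")
  if ("cell_id" %in% names(cell_meta) && !identical(cell_meta$cell_id, cell_ids)) {
    stop("cell_meta$cell_id does not match cell_ids")
  }
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != ncol(counts)) stop("embedding rows do not match number of cells")
  dimnames(counts) <- list(feature_ids, cell_ids)
  rownames(embedding) <- cell_ids
  structure(
    list(counts = counts, feature_ids = feature_ids, cell_ids = cell_ids,
         cell_meta = cell_meta, embedding = embedding),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " features x ", ncol(x$counts), " cells; ",
      ncol(x$embedding), "-D embedding\n", sep = "")
  invisible(x)
}

#' Read a raw count matrix with metadata and embedding
#'
#' Reads the sparse MTX + label TSV layout used by most single-cell
#' pipelines: a MatrixMarket counts file, one-column feature and cell label
#' files, a per-cell metadata TSV (columns `cell_id`, `cell_type`,
#' optionally `batch`), and a per-cell embedding TSV (`cell_id` plus
#' coordinate columns).
#'
#' @param mtx Path to the MatrixMarket counts file (features x cells).
#' @param features,cells Paths to feature/cell label files (no header).
#' @param meta Path to the per-cell metadata TSV.
#' @param embedding Path to the per-cell embedding TSV.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(mtx, features, cells, meta, embedding) {
  m <- Matrix::readMM(mtx)
  feature_ids <- readLines(features)
  cell_ids <- readLines(cells)
  if (length(feature_ids) != nrow(m)) {
    stop("feature label count in '", features, "' does not match matrix rows")
  }
  if (length(cell_ids) != ncol(m)) {
    stop("cell label count in '", cells, "' does not match matrix columns")
  }
  meta_tbl <- readr::read_tsv(meta, show_col_types = FALSE)
  if (!all(cell_ids %in% meta_tbl$cell_id)) {
    stop("metadata file '", meta, "' is missing cells present in the matrix")
  }
  meta_tbl <- meta_tbl[match(cell_ids, meta_tbl$cell_id), ]
  emb_tbl <- readr::read_tsv(embedding, show_col_types = FALSE)
  if (!all(cell_ids %in% emb_tbl$cell_id)) {
    stop("embedding file '", embedding, "' is missing cells present in the matrix")
  }
  emb_tbl <- emb_tbl[match(cell_ids, emb_tbl$cell_id), ]
  emb <- as.matrix(emb_tbl[setdiff(names(emb_tbl), "cell_id")])
  count_matrix(m, feature_ids, cell_ids, meta_tbl, emb)
}

#' Write a numeric matrix as a TSV with row and column labels
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path. The first column (`id`) holds row names.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- tibble::as_tibble(as.data.frame(mat), rownames = "id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#'
#' @param path TSV path with an `id` first column.
#' @return Numeric matrix with rownames from `id`.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  mat <- as.matrix(df[setdiff(names(df), "id")])
  rownames(mat) <- df$id
  mat
}
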