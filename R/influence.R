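#' Leave-one-out influence scores for one model
#'
#' The influence of motif (filter) i in pool j is the mean, over the N
#' inner-validation sequences, of the difference between the intact
#' prediction b_ijk and the perturbed prediction c_ijk obtained by setting
#' every parameter of filter i (its convolutional weights and its readout
#' row) to zero. Because a zeroed filter produces ELU(0) = 0 activations
#' and the readout is linear, the difference reduces to
#' `fc_weights[i, j] * mean_k activations[k, i]`, which is what the
#' vectorized computation evaluates; a brute-force per-filter re-evaluation
#' gives identical scores.
#'
#' @param checkpoint A `scover_checkpoint`.
#' @param seqs The [sequence_set()] the model was trained on.
#' @param which_seqs Validation sequence indices; defaults to the
#'   checkpoint's inner-validation split.
#' @return An `influence_matrix`: d x p numeric matrix (rows named
#'   `<run>_<filter>`) with attributes `level = "motif_pool"` and
#'   `z_transformed = FALSE`.
#' @export
loo_influence <- function(checkpoint, seqs, which_seqs = NULL) {
  stopifnot(inherits(checkpoint, "scover_checkpoint"))
  which_seqs <- which_seqs %||% checkpoint$idx_val
  if (is.null(which_seqs) || length(which_seqs) == 0L) {
    stop("empty validation set: supply which_seqs")
  }
  params <- checkpoint$params
  fwd <- scover_forward(params, seqs, which_seqs = which_seqs)
  mean_act <- colMeans(fwd$activations)            # mean_k a_ik
  n <- params$fc_weights * mean_act                # recycles by row: d x p
  run <- checkpoint$fold %||% 1L
  dimnames(n) <- list(paste0(run, "_", seq_len(params$config$d)), NULL)
  influence_matrix(n, level = "motif_pool")
}

influence_matrix <- function(mat, level, z_transformed = FALSE) {
  structure(mat, level = level, z_transformed = z_transformed,
            class = c("influence_matrix", "matrix", "array"))
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat("<influence_matrix> ", nrow(x), " x ", ncol(x), " (level: ",
      attr(x, "level"), if (attr(x, "z_transformed")) ", z-transformed", ")\n",
      sep = "")
  invisible(x)
}

#' Leave-one-out influence for a whole ensemble
#'
#' Concatenates the per-model influence matrices rowwise, giving the
#' r*d x p motif-by-pool matrix; (run, filter) identity is kept in the
#' rownames so cluster aggregation can span models.
#'
#' @param ensemble A `scover_ensemble`.
#' @param seqs Training [sequence_set()].
#' @return An `influence_matrix` with `r * d` rows.
#' @export
ensemble_influence <- function(ensemble, seqs) {
  stopifnot(inherits(ensemble, "scover_ensemble"))
  seqs <- align_ensemble_seqs(ensemble, seqs)
  mats <- lapply(ensemble$checkpoints, loo_influence, seqs = seqs)
  out <- do.call(rbind, mats)
  colnames(out) <- ensemble$pool_names
  influence_matrix(out, level = "motif_pool")
}

#' Aggregate influence scores to clusters and cell types
#'
#' Averages pool columns within each cell type and/or sums motif rows
#' within each retained motif cluster. Motifs labeled "non-aligned" or
#' masked as non-reproducible are excluded from cluster aggregation.
#'
#' @param infl An `influence_matrix` at motif x pool level.
#' @param pool_celltype Optional character vector (one per column): the
#'   modal cell type of each pool; when given, columns are averaged per
#'   cell type.
#' @param clusters Optional assignment of motifs to clusters: a
#'   `motif_set` with `cluster`/`retained` columns (from
#'   [assign_clusters()]) or a tibble with columns `motif`, `cluster` and
#'   optionally `retained`.
#' @return An `influence_matrix` at the requested aggregation level.
#' @export
aggregate_influence <- function(infl, pool_celltype = NULL, clusters = NULL) {
  stopifnot(inherits(infl, "influence_matrix"))
  mat <- unclass(infl)
  level_rows <- "motif"; level_cols <- "pool"
  if (!is.null(clusters)) {
    tbl <- tibble::as_tibble(clusters)[, intersect(c("motif", "cluster", "retained"),
                                                   names(clusters))]
    if (!all(c("motif", "cluster") %in% names(tbl))) {
      stop("clusters needs columns motif and cluster")
    }
    if (!"retained" %in% names(tbl)) tbl$retained <- TRUE
    tbl <- dplyr::filter(tbl, .data$cluster != "non-aligned", .data$retained,
                         .data$motif %in% rownames(mat))
    if (nrow(tbl) == 0) stop("no retained, aligned motifs to aggregate")
    groups <- split(tbl$motif, tbl$cluster)
    mat <- do.call(rbind, lapply(groups, function(ms) {
      colSums(mat[ms, , drop = FALSE])
    }))
    level_rows <- "cluster"
  }
  if (!is.null(pool_celltype)) {
    if (length(pool_celltype) != ncol(mat)) {
      stop("pool_celltype length does not match the number of pools")
    }
    types <- sort(unique(pool_celltype))
    bad <- pool_celltype[is.na(pool_celltype)]
    if (length(bad) > 0) stop("unknown (NA) cell type label")
    mat <- do.call(cbind, lapply(types, function(ct) {
      rowMeans(mat[, pool_celltype == ct, drop = FALSE])
    }))
    colnames(mat) <- types
    level_cols <- "celltype"
  }
  influence_matrix(mat, level = paste(level_rows, level_cols, sep = "_"))
}

#' Row-wise z-transformation
#'
#' Centers and scales each row to mean 0, SD 1 (population SD, dividing by
#' n), used to highlight cell-type-specific patterns against a shared
#' baseline. Constant rows become all zeros with a warning.
#'
#' @param mat Numeric matrix (or `influence_matrix`).
#' @return Matrix of the same shape; for influence matrices the
#'   `z_transformed` attribute is set.
#' @export
z_transform <- function(mat) {
  was_infl <- inherits(mat, "influence_matrix")
  lvl <- attr(mat, "level")
  m <- unclass(mat)
  mu <- rowMeans(m)
  sdev <- sqrt(rowMeans((m - mu)^2))
  const <- sdev == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) z-transformed to zero")
    sdev[const] <- 1
  }
  out <- (m - mu) / sdev
  out[const, ] <- 0
  if (was_infl) influence_matrix(out, level = lvl, z_transformed = TRUE) else out
}
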