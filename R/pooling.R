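#' Select seed cells by covering-grid geometric sketching
#'
#' Chooses `n_seeds` cells that span the embedding evenly rather than
#' proportionally to density, preserving rare cell states. The embedding is
#' covered with an axis-aligned grid whose cube side is found by binary
#' search so that the number of occupied cubes is at least `n_seeds`; one
#' random cell is drawn per occupied cube and the selection is truncated at
#' random to exactly `n_seeds`.
#'
#' @param embedding Numeric matrix, cells x E coordinates (rownames used as
#'   cell ids when present).
#' @param n_seeds Number of seed cells (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer vector of seed cell indices (named with cell ids when
#'   the embedding has rownames).
#' @export
geometric_sketch <- function(embedding, n_seeds = 1000, seed = NULL) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n_seeds > n) stop("n_seeds exceeds the number of cells")
  if (!is.null(seed)) set.seed(seed)
  ids <- rownames(embedding)
  finish <- function(idx) if (is.null(ids)) idx else setNames(idx, ids[idx])
  if (n_seeds == n) return(finish(seq_len(n)))

  mins <- apply(embedding, 2L, min)
  ranges <- apply(embedding, 2L, function(x) diff(range(x)))
  ranges[ranges == 0] <- 1
  centered <- sweep(embedding, 2L, mins)

  occupied_cubes <- function(side) {
    keys <- floor(sweep(centered, 2L, rep(side, ncol(centered)), "/"))
    match_key <- do.call(paste, c(as.data.frame(keys), sep = "_"))
    split(seq_len(n), match_key)
  }

  # binary search the largest side whose occupied-cube count is >= n_seeds
  lo <- 0; hi <- max(ranges) * 1.01
  best <- NULL
  for (iter in 1:50) {
    mid <- (lo + hi) / 2
    cubes <- occupied_cubes(mid)
    if (length(cubes) >= n_seeds) {
      best <- cubes
      lo <- mid
    } else {
      hi <- mid
    }
  }
  if (is.null(best)) best <- occupied_cubes(lo) # duplicates may cap cube count
  picked <- vapply(best, function(cells) {
    if (length(cells) == 1L) cells else sample(cells, 1L)
  }, 1L)
  if (length(picked) >= n_seeds) {
    picked <- sample(picked, n_seeds)
  } else {
    extra <- sample(setdiff(seq_len(n), picked), n_seeds - length(picked))
    picked <- c(picked, extra)
  }
  finish(sort(unname(picked)))
}

#' Pool cells over kNN neighborhoods of seed cells
#'
#' For each seed cell, forms a pool of the seed plus its `pool_size - 1`
#' nearest cells by Euclidean distance in the embedding, sums their raw
#' counts, and applies a natural-log `log(1 + x)` transform. Each pool is
#' annotated with its modal (most abundant) cell type and the fraction of
#' members of that type.
#'
#' @param counts A [count_matrix()].
#' @param seeds Seed cell indices (e.g., from [geometric_sketch()]).
#' @param pool_size Cells per pool q (default 100). With
#'   `include_seed = TRUE` (default) a pool is the seed plus its q-1 nearest
#'   neighbors, so pools hold exactly q cells; `include_seed = FALSE`
#'   reproduces the seed-plus-q-neighbors convention (q+1 cells).
#' @param include_seed See `pool_size`.
#' @return An object of class `pooled_dataset` with `values` (features x
#'   pools log1p matrix), `pool_members`, `pool_celltype`, `pool_purity`,
#'   `seeds` and `pool_size`.
#' @export
pool_cells <- function(counts, seeds, pool_size = 100, include_seed = TRUE) {
  stopifnot(inherits(counts, "count_matrix"))
  seeds <- unname(seeds)
  if (anyDuplicated(seeds)) stop("duplicate seed cells")
  n <- ncol(counts$counts)
  if (any(seeds < 1 | seeds > n)) stop("seed indices out of range")
  q <- as.integer(pool_size)
  if (q < 1 || q > n) stop("pool_size must be between 1 and the number of cells")

  emb <- counts$embedding
  # squared Euclidean distances seed x cells via the expansion trick
  cn <- rowSums(emb^2)
  members <- vector("list", length(seeds))
  n_neighbors <- if (include_seed) q - 1L else q
  for (s in seq_along(seeds)) {
    i <- seeds[s]
    d2 <- cn - 2 * drop(emb %*% emb[i, ])
    d2[i] <- -Inf                     # the seed always belongs to its pool
    ord <- order(d2)
    members[[s]] <- ord[seq_len(n_neighbors + 1L)]
  }

  indicator <- Matrix::sparseMatrix(
    i = unlist(members),
    j = rep(seq_along(seeds), lengths(members)),
    x = 1,
    dims = c(n, length(seeds))
  )
  pooled_counts <- as.matrix(counts$counts %*% indicator)
  values <- log1p(pooled_counts)
  dimnames(values) <- list(counts$feature_ids, paste0("pool_", seq_along(seeds)))

  cell_types <- counts$cell_meta$cell_type
  ann <- lapply(members, function(mm) {
    tab <- sort(table(cell_types[mm]), decreasing = TRUE)
    top <- tab[tab == max(tab)]
    # lexicographic tie-break keeps annotation deterministic
    modal <- sort(names(top))[1]
    list(type = modal, purity = unname(tab[[modal]]) / length(mm))
  })
  structure(
    list(values = values,
         pool_members = lapply(members, function(mm) counts$cell_ids[mm]),
         pool_celltype = vapply(ann, `[[`, "", "type"),
         pool_purity = vapply(ann, `[[`, 1, "purity"),
         seeds = seeds, pool_size = q, include_seed = include_seed),
    class = "pooled_dataset"
  )
}

#' @export
print.pooled_dataset <- function(x, ...) {
  cat("<pooled_dataset> ", nrow(x$values), " features x ", ncol(x$values),
      " pools (q = ", x$pool_size, ")\n", sep = "")
  invisible(x)
}

#' Filter lowly detected features from a pooled dataset
#'
#' Drops features detected (value > 0) in fewer than `min_detect_frac` of
#' pools; features detected in fewer than `rescue_frac` of pools are only
#' retained when the mean of their non-zero values exceeds
#' `rescue_mean_threshold`. Thresholds are compared against the natural-log
#' pooled values; the preset rescue constants (log10(3), log10(4)) are
#' applied literally as numeric cutoffs.
#'
#' @param pooled A `pooled_dataset`.
#' @param min_detect_frac,rescue_frac,rescue_mean_threshold Filter
#'   parameters; see [filter_preset()] for the dataset presets.
#' @return The filtered `pooled_dataset` (row order preserved).
#' @export
filter_features <- function(pooled, min_detect_frac = 0.05, rescue_frac = 0.16,
                            rescue_mean_threshold = log10(3)) {
  stopifnot(inherits(pooled, "pooled_dataset"))
  if (!(min_detect_frac >= 0 && min_detect_frac <= rescue_frac && rescue_frac <= 1)) {
    stop("need 0 <= min_detect_frac <= rescue_frac <= 1")
  }
  v <- pooled$values
  detect <- rowMeans(v > 0)
  nz_mean <- apply(v, 1L, function(r) if (any(r > 0)) mean(r[r > 0]) else 0)
  keep <- detect >= min_detect_frac &
    (detect >= rescue_frac | nz_mean > rescue_mean_threshold)
  if (!any(keep)) {
    stop("no features pass the detection filter; relax min_detect_frac or the rescue threshold")
  }
  pooled$values <- v[keep, , drop = FALSE]
  pooled
}

#' Dataset-specific feature-filter presets
#'
#' Returns the detection-filter parameters used for the three reference
#' dataset types: `"kidney"` (scRNA-seq promoters, 5%/16%/log10(3)),
#' `"tabula-muris"` (scRNA-seq promoters, 3%/8%/log10(4)) and `"brain"`
#' (scATAC-seq peaks, 6%/15%/log10(4)).
#'
#' @param preset One of "kidney", "tabula-muris", "brain".
#' @return Named list of filter arguments for [filter_features()].
#' @export
filter_preset <- function(preset = c("kidney", "tabula-muris", "brain")) {
  switch(match.arg(preset),
    "kidney" = list(min_detect_frac = 0.05, rescue_frac = 0.16,
                    rescue_mean_threshold = log10(3)),
    "tabula-muris" = list(min_detect_frac = 0.03, rescue_frac = 0.08,
                          rescue_mean_threshold = log10(4)),
    "brain" = list(min_detect_frac = 0.06, rescue_frac = 0.15,
                   rescue_mean_threshold = log10(4))
  )
}

#' Summarize a pooled dataset
#'
#' @param pooled A `pooled_dataset`.
#' @param counts Optional originating [count_matrix()]; when given, the raw
#'   sparsity is reported alongside the pooled sparsity.
#' @return A list of class `pooling_report`: `pools` (per-pool tibble with
#'   purity and number of cell types), `cell_usage` (per-cell inclusion
#'   counts), `sparsity_pooled`, and `sparsity_raw` (NA without `counts`).
#' @export
pooling_report <- function(pooled, counts = NULL) {
  stopifnot(inherits(pooled, "pooled_dataset"))
  n_types <- rep(NA_integer_, length(pooled$pool_members))
  if (!is.null(counts)) {
    type_of <- setNames(counts$cell_meta$cell_type, counts$cell_ids)
    n_types <- vapply(pooled$pool_members,
                      function(mm) length(unique(type_of[mm])), 1L)
  }
  pools <- tibble::tibble(
    pool = colnames(pooled$values),
    cell_type = pooled$pool_celltype,
    purity = pooled$pool_purity,
    n_cell_types = n_types
  )
  usage <- table(unlist(pooled$pool_members))
  cell_usage <- tibble::tibble(cell_id = names(usage),
                               n_pools = as.integer(usage))
  structure(
    list(pools = pools,
         cell_usage = cell_usage,
         sparsity_pooled = mean(pooled$values == 0),
         sparsity_raw = if (is.null(counts)) NA_real_ else
           1 - Matrix::nnzero(counts$counts) / length(counts$counts)),
    class = "pooling_report"
  )
}

#' @export
print.pooling_report <- function(x, ...) {
  cat("<pooling_report> ", nrow(x$pools), " pools; median purity ",
      round(median(x$pools$purity), 3), "; pooled sparsity ",
      round(x$sparsity_pooled, 3), "\n", sep = "")
  invisible(x)
}
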