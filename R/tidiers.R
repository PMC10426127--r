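#' Tidy a trained ensemble
#'
#' @param x A `scover_ensemble`.
#' @param ... Unused.
#' @return Per-fold metrics as a tibble: fold, metric, r_squared, plus the
#'   fold's best validation MSE and chosen hyperparameters.
#' @method tidy scover_ensemble
#' @export
tidy.scover_ensemble <- function(x, ...) {
  hp <- dplyr::bind_rows(lapply(x$checkpoints, function(ck) {
    tibble::tibble(fold = ck$fold, best_val_mse = ck$best_val_mse,
                   epochs_run = ck$epochs_run,
                   lr = ck$hp$lr, batch_size = ck$hp$batch_size)
  }))
  dplyr::left_join(x$metrics, hp, by = "fold")
}

#' Summarize a trained ensemble in one row
#'
#' @param x A `scover_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: number of models, d, m, mean outer-test R^2
#'   (intact), and the control R^2 values when present.
#' @method glance scover_ensemble
#' @export
glance.scover_ensemble <- function(x, ...) {
  by_metric <- x$metrics |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(r2 = mean(.data$r_squared)) |>
    tidyr::pivot_wider(names_from = "metric", values_from = "r2",
                       names_prefix = "r2_")
  dplyr::bind_cols(
    tibble::tibble(n_models = length(x$checkpoints),
                   d = x$config$d, m = x$config$m,
                   n_sequences = length(x$ids), n_pools = x$config$p),
    by_metric
  )
}

#' Tidy an influence matrix into long form
#'
#' @param x An `influence_matrix`.
#' @param ... Unused.
#' @return Tibble with columns row, column, influence (row/column names
#'   reflect the aggregation level).
#' @method tidy influence_matrix
#' @export
tidy.influence_matrix <- function(x, ...) {
  lvl <- strsplit(attr(x, "level"), "_")[[1]]
  m <- unclass(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("row_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col_", seq_len(ncol(m)))
  tibble::as_tibble(as.data.frame(m), rownames = lvl[1]) |>
    tidyr::pivot_longer(-dplyr::all_of(lvl[1]), names_to = lvl[2],
                        values_to = "influence")
}

#' Heatmap of an influence matrix
#'
#' @param object An `influence_matrix` (typically cluster x celltype,
#'   often z-transformed).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot influence_matrix
#' @export
autoplot.influence_matrix <- function(object, ...) {
  lvl <- strsplit(attr(object, "level"), "_")[[1]]
  df <- tidy.influence_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[lvl[2]]], y = .data[[lvl[1]]],
                                   fill = .data$influence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B") +
    ggplot2::labs(x = lvl[2], y = lvl[1],
                  fill = if (attr(object, "z_transformed")) "z(influence)" else "influence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pool purity overview
#'
#' @param object A `pooling_report`.
#' @param ... Unused.
#' @return A ggplot histogram of per-pool modal cell-type fractions.
#' @method autoplot pooling_report
#' @export
autoplot.pooling_report <- function(object, ...) {
  ggplot2::ggplot(object$pools, ggplot2::aes(x = .data$purity)) +
    ggplot2::geom_histogram(bins = 20, boundary = 1, fill = "grey35") +
    ggplot2::labs(x = "largest cell-type fraction per pool", y = "pools") +
    ggplot2::theme_minimal()
}

#' Position-wise motif matrix for logo plotting
#'
#' Returns a motif's PPM in long form (position, nucleotide, probability,
#' information content), the data a logo is drawn from.
#'
#' @param motifs A `motif_set`.
#' @param motif Motif name (`<run>_<filter>`).
#' @return Tibble: position, nucleotide, probability, ic.
#' @export
motif_logo_data <- function(motifs, motif) {
  stopifnot(inherits(motifs, "motif_set"))
  row <- which(motifs$motif == motif)
  if (length(row) != 1L) stop("motif '", motif, "' not found")
  ppm <- motifs$ppm[[row]]
  if (is.null(ppm)) stop("motif '", motif, "' has no contributing sequences")
  ic_col <- 2 + colSums(ifelse(ppm > 0, ppm * log2(ppm), 0))
  tibble::tibble(
    position = rep(seq_len(ncol(ppm)), each = 4L),
    nucleotide = rep(NUCLEOTIDES, ncol(ppm)),
    probability = as.vector(ppm),
    ic = as.vector(sweep(ppm, 2L, ic_col, "*"))
  )
}

#' Bar chart of a motif's information content profile
#'
#' @param motifs A `motif_set`.
#' @param motif Motif name.
#' @return A ggplot object (stacked per-nucleotide information content).
#' @export
plot_motif <- function(motifs, motif) {
  df <- motif_logo_data(motifs, motif)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ic,
                                   fill = .data$nucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "position", y = "information (bits)", title = motif) +
    ggplot2::theme_minimal()
}
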