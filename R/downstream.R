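# Spearman correlation with a two-sided p-value from the large-sample t
# approximation; returns NA correlation for constant vectors.
spearman_test <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlate motif-cluster influence with TF expression
#'
#' For each motif cluster and each candidate transcription factor assigned
#' to it, computes the Spearman correlation between the cluster's summed
#' influence scores and the TF's pooled expression across pools, with
#' two-sided p-values and Benjamini-Hochberg correction across all
#' (cluster, TF) pairs. High |rho| marks the TF most likely to underlie
#' the motif's activity; strong negative correlations suggest repressors.
#'
#' @param cluster_influence An `influence_matrix` at cluster x pool level
#'   (rows named by cluster).
#' @param expression Numeric matrix of pooled expression (features x
#'   pools), columns aligned with the influence pools; TF rows are looked
#'   up by name.
#' @param cluster_tf_table Tibble with columns `tf` and `cluster` listing
#'   candidate TFs per cluster.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return A tibble: cluster, tf, rho, p_value, q_value, significant,
#'   mean_expression. TFs absent from the expression matrix are dropped
#'   with a warning; constant vectors yield NA rho with a warning.
#' @export
tf_correlation <- function(cluster_influence, expression, cluster_tf_table,
                           alpha = 0.05) {
  stopifnot(ncol(cluster_influence) == ncol(expression))
  tbl <- tibble::as_tibble(cluster_tf_table)
  stopifnot(all(c("tf", "cluster") %in% names(tbl)))
  tbl <- dplyr::filter(tbl, .data$cluster %in% rownames(cluster_influence))
  missing_tf <- setdiff(tbl$tf, rownames(expression))
  if (length(missing_tf) > 0) {
    warning("TF(s) absent from expression matrix, dropped: ",
            paste(missing_tf, collapse = ", "))
    tbl <- dplyr::filter(tbl, .data$tf %in% rownames(expression))
  }
  if (nrow(tbl) == 0) stop("no (cluster, TF) pairs to test")
  res <- purrr::pmap_dfr(tbl[c("cluster", "tf")], function(cluster, tf) {
    st <- spearman_test(as.numeric(cluster_influence[cluster, ]),
                        as.numeric(expression[tf, ]))
    tibble::tibble(cluster = cluster, tf = tf, rho = st$rho, p_value = st$p,
                   mean_expression = mean(expression[tf, ]))
  })
  if (any(is.na(res$rho))) warning("constant vector(s): rho reported as NA")
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$q_value) & res$q_value < alpha
  dplyr::select(res, "cluster", "tf", "rho", "p_value", "q_value",
                "significant", "mean_expression")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]), vapply(lines, `[[`, "", 1L))
}

#' Correlate gene-set expression with motif-cluster influence
#'
#' Keeps gene sets with fewer than `max_set_size` genes, computes each
#' set's mean pooled expression per pool, correlates it (Spearman) with
#' every cluster's influence scores, keeps the `top_n` sets by maximum
#' absolute correlation, and clusters those sets into `k_groups` groups by
#' average-linkage hierarchical clustering on Euclidean distance of their
#' correlation profiles.
#'
#' @param expression Pooled expression matrix (features x pools).
#' @param gene_sets Named list of gene-id vectors (see [read_gmt()]).
#' @param cluster_influence Cluster x pool `influence_matrix`.
#' @param max_set_size Sets with at least this many genes are discarded
#'   (default 50, i.e., only sets with < 50 genes are used).
#' @param top_n Number of top sets kept (default 500).
#' @param k_groups Number of groups to cut the tree into (default 3).
#' @return List: `correlations` (tibble set x cluster long form), `groups`
#'   (tibble set, group), `matrix` (sets x clusters rho matrix).
#' @export
gene_set_correlation <- function(expression, gene_sets, cluster_influence,
                                 max_set_size = 50, top_n = 500, k_groups = 3) {
  gene_sets <- gene_sets[vapply(gene_sets, length, 1L) < max_set_size]
  if (length(gene_sets) == 0) stop("no gene sets below the size threshold")
  scores <- list()
  skipped <- character(0)
  for (nm in names(gene_sets)) {
    genes <- intersect(gene_sets[[nm]], rownames(expression))
    if (length(genes) == 0) { skipped <- c(skipped, nm); next }
    scores[[nm]] <- colMeans(expression[genes, , drop = FALSE])
  }
  if (length(skipped) > 0) {
    warning(length(skipped), " gene set(s) with no matching genes skipped")
  }
  if (length(scores) == 0) stop("no gene sets with matching genes")
  clusters <- rownames(cluster_influence)
  rho <- do.call(rbind, lapply(scores, function(sc) {
    vapply(clusters, function(cl) {
      spearman_test(sc, as.numeric(cluster_influence[cl, ]))$rho
    }, 1)
  }))
  colnames(rho) <- clusters
  keep_n <- min(top_n, nrow(rho))
  ord <- order(apply(abs(rho), 1L, max, na.rm = TRUE), decreasing = TRUE)
  rho_top <- rho[ord[seq_len(keep_n)], , drop = FALSE]
  groups <- if (nrow(rho_top) > k_groups) {
    hc <- hclust(dist(rho_top), method = "average")
    cutree(hc, k = k_groups)
  } else {
    setNames(seq_len(nrow(rho_top)), rownames(rho_top))
  }
  list(
    correlations = tibble::as_tibble(as.data.frame(rho_top), rownames = "set") |>
      tidyr::pivot_longer(-"set", names_to = "cluster", values_to = "rho"),
    groups = tibble::tibble(set = rownames(rho_top),
                            group = unname(groups[rownames(rho_top)])),
    matrix = rho_top
  )
}

#' Per-sequence motif-space matrix
#'
#' Concatenates the post-ELU max-pooled activation matrices of all
#' ensemble models columnwise, giving a sequences x (r*d) matrix (column
#' order run-major, filter-minor; columns named `<run>_<filter>`). This is
#' the representation used to embed promoters by their motif content.
#'
#' @param ensemble A `scover_ensemble`.
#' @param seqs A [sequence_set()] (any sequences of the training length).
#' @param clusters Optional motif cluster assignment (as in
#'   [aggregate_influence()]); when given, per-cluster summed activations
#'   are also returned.
#' @return List: `matrix` (n x r*d), and with `clusters` also
#'   `cluster_scores` (n x n_clusters summed member-filter activations).
#' @export
motif_space <- function(ensemble, seqs, clusters = NULL) {
  stopifnot(inherits(ensemble, "scover_ensemble"))
  mats <- lapply(ensemble$checkpoints, function(ck) {
    fwd <- scover_forward(ck$params, seqs)
    colnames(fwd$activations) <- paste0(ck$fold %||% 1L, "_",
                                        seq_len(ck$params$config$d))
    fwd$activations
  })
  mat <- do.call(cbind, mats)
  rownames(mat) <- seqs$ids
  out <- list(matrix = mat)
  if (!is.null(clusters)) {
    tbl <- tibble::as_tibble(clusters)
    if (!"retained" %in% names(tbl)) tbl$retained <- TRUE
    tbl <- dplyr::filter(tbl, .data$cluster != "non-aligned", .data$retained,
                         .data$motif %in% colnames(mat))
    groups <- split(tbl$motif, tbl$cluster)
    out$cluster_scores <- do.call(cbind, lapply(groups, function(ms) {
      rowSums(mat[, ms, drop = FALSE])
    }))
  }
  out
}

#' Genes carrying each motif family, and their co-occurrence
#'
#' For each motif family, selects the genes whose family activation score
#' exceeds 75% (by default) of the family's maximum gene score, then
#' tabulates all pairwise intersection sizes between the family gene sets.
#'
#' @param family_scores Genes x families matrix (e.g.,
#'   `motif_space()$cluster_scores`).
#' @param frac Fraction of the per-family maximum used as threshold
#'   (default 0.75; genes strictly above it are kept).
#' @return List: `sets` (named list of gene-id vectors; empty with a
#'   warning for families whose maximum score is <= 0), `intersections`
#'   (tibble family_a, family_b, n with per-family sizes on the diagonal).
#' @export
co_occurrence_sets <- function(family_scores, frac = 0.75) {
  stopifnot(is.matrix(family_scores), !is.null(colnames(family_scores)))
  genes <- rownames(family_scores) %||% as.character(seq_len(nrow(family_scores)))
  sets <- lapply(colnames(family_scores), function(fam) {
    sc <- family_scores[, fam]
    mx <- max(sc)
    if (mx <= 0) {
      warning("family '", fam, "' has no positive scores; empty set")
      return(character(0))
    }
    genes[sc > frac * mx]
  })
  names(sets) <- colnames(family_scores)
  fams <- names(sets)
  inter <- tidyr::expand_grid(family_a = fams, family_b = fams) |>
    dplyr::mutate(n = purrr::map2_int(.data$family_a, .data$family_b,
                                      ~ length(intersect(sets[[.x]], sets[[.y]]))))
  list(sets = sets, intersections = inter)
}

#' Signature score per pool
#'
#' Scores each pool as the mean pooled expression of a marker gene list
#' (e.g., proliferation markers MKI67, PLK1, E2F1, FOXM1, ...), and can
#' correlate the score against influence rows or any numeric pool-level
#' covariate such as an externally computed pseudotime normalized to
#' [0, 1].
#'
#' @param expression Pooled expression matrix (features x pools).
#' @param genes Marker gene ids; those absent are ignored (error if none
#'   are present).
#' @param against Optional numeric vector or influence row (length =
#'   number of pools) to correlate with.
#' @return With `against = NULL`, a named numeric vector of per-pool
#'   scores. Otherwise a list with `score`, `rho`, `p_value` (Spearman).
#' @export
signature_score <- function(expression, genes, against = NULL) {
  present <- intersect(genes, rownames(expression))
  if (length(present) == 0) stop("none of the signature genes are present")
  score <- colMeans(expression[present, , drop = FALSE])
  if (is.null(against)) return(score)
  stopifnot(length(against) == length(score))
  st <- spearman_test(score, as.numeric(against))
  list(score = score, rho = st$rho, p_value = st$p)
}
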