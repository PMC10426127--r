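#' Simulation configuration
#'
#' Defines the synthetic study conditions: background sequences with
#' planted PWM instances, simulated cell types with type-specific motif
#' effect sizes, and sparse per-cell counts that pool back to the intended
#' targets. Defaults describe the package's reference fixture: 2000
#' sequences of 200 nt, five sharp 12-nt motifs planted independently with
#' probability 0.5, five cell types with one dominant (mostly activating,
#' one repressive) motif each, 1000 cells pooled into 50 pools of 20.
#'
#' @param n_sequences,L Number and length of sequences.
#' @param motif_ppms Named list of 4 x m PPMs; `NULL` samples
#'   `n_motifs` consensus-based PPMs (`motif_sharpness` probability mass on
#'   the consensus base).
#' @param n_motifs,motif_width,motif_sharpness Used when sampling PPMs.
#' @param plant_prob Per (sequence, motif) planting probability.
#' @param gc Background GC fraction (default 0.5).
#' @param n_cells,n_celltypes,n_pools,pool_size Cell-level design.
#' @param effect Motif x celltype effect matrix W on the log-expression
#'   scale; `NULL` uses a diagonal design with effects
#'   (2.0, 1.6, 1.2, -0.8, 0.9).
#' @param baseline Baseline log1p expression (default 1.5).
#' @param noise_sd Gaussian noise SD added to the analytic pooled targets
#'   (default 0.1).
#' @param embedding_sd Within-cell-type SD of the Gaussian-blob embedding
#'   (default 0.5, blob centers 10 apart).
#' @param seed Default RNG seed carried in the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sequences = 2000, L = 200,
                       motif_ppms = NULL, n_motifs = 5, motif_width = 12,
                       motif_sharpness = 0.85, plant_prob = 0.5, gc = 0.5,
                       n_cells = 1000, n_celltypes = 5, n_pools = 50,
                       pool_size = 20, effect = NULL, baseline = 1.5,
                       noise_sd = 0.1, embedding_sd = 0.5, seed = 1) {
  if (!is.null(motif_ppms)) {
    n_motifs <- length(motif_ppms)
    motif_width <- ncol(motif_ppms[[1]])
  }
  if (is.null(effect)) {
    # graded cell-type specificity: each motif has a dominant cell type and
    # effects that halve with circular cell-type distance; motif 4 is a
    # repressor. Influence is shared across related cell types rather than
    # exactly zero elsewhere, as in real regulatory programs.
    strength <- rep_len(c(2.0, 1.6, 1.2, -0.8, 0.9), n_motifs)
    effect <- outer(seq_len(n_motifs), seq_len(n_celltypes), function(m, t) {
      dd <- pmin(abs(m - t) %% n_celltypes, n_celltypes - abs(m - t) %% n_celltypes)
      2^(-dd)
    }) * strength
  }
  stopifnot(nrow(effect) == n_motifs, motif_width <= L,
            plant_prob >= 0, plant_prob <= 1, gc >= 0, gc <= 1)
  structure(
    list(n_sequences = n_sequences, L = L, motif_ppms = motif_ppms,
         n_motifs = n_motifs, motif_width = motif_width,
         motif_sharpness = motif_sharpness, plant_prob = plant_prob, gc = gc,
         n_cells = n_cells, n_celltypes = ncol(effect), n_pools = n_pools,
         pool_size = pool_size, effect = effect, baseline = baseline,
         noise_sd = noise_sd, embedding_sd = embedding_sd, seed = seed),
    class = "sim_config"
  )
}

sample_consensus_ppm <- function(m, sharpness) {
  cons <- sample.int(4L, m, replace = TRUE)
  ppm <- matrix((1 - sharpness) / 3, 4L, m, dimnames = list(NUCLEOTIDES, NULL))
  ppm[cbind(cons, seq_len(m))] <- sharpness
  ppm
}

sample_ppm_instance <- function(ppm) {
  paste(NUCLEOTIDES[vapply(seq_len(ncol(ppm)), function(j) {
    sample.int(4L, 1L, prob = ppm[, j])
  }, 1L)], collapse = "")
}

#' Simulate background sequences with planted motifs
#'
#' Draws i.i.d. background sequences at the configured GC fraction and
#' plants each motif independently with its probability at a uniform
#' random non-overlapping position, the instance sampled column-wise from
#' the motif's PPM. Planting that cannot find a non-overlapping position
#' within 100 tries is skipped with a warning.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (default from the config).
#' @return List: `seqs` (a [sequence_set()]), `truth` with `instances`
#'   (tibble: id, motif, position (1-based), instance), `counts`
#'   (sequences x motifs instance counts), `motif_ppms`, and the config.
#' @export
simulate_sequences <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  ppms <- config$motif_ppms %||% setNames(
    lapply(seq_len(config$n_motifs),
           function(i) sample_consensus_ppm(config$motif_width, config$motif_sharpness)),
    paste0("planted_", seq_len(config$n_motifs))
  )
  m <- ncol(ppms[[1]])
  L <- config$L
  n <- config$n_sequences
  base_prob <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
                 G = config$gc / 2, T = (1 - config$gc) / 2)
  ids <- sprintf("gene_%04d", seq_len(n))
  seqs <- character(n)
  counts <- matrix(0L, n, length(ppms), dimnames = list(ids, names(ppms)))
  inst_rows <- list()
  n_skipped <- 0L
  for (i in seq_len(n)) {
    s <- sample(NUCLEOTIDES, L, replace = TRUE, prob = base_prob)
    occupied <- rep(FALSE, L)
    for (mo in seq_along(ppms)) {
      if (runif(1) >= config$plant_prob) next
      placed <- FALSE
      for (try in 1:100) {
        pos <- sample.int(L - m + 1L, 1L)
        span <- pos:(pos + m - 1L)
        if (!any(occupied[span])) {
          inst <- sample_ppm_instance(ppms[[mo]])
          s[span] <- strsplit(inst, "")[[1]]
          occupied[span] <- TRUE
          counts[i, mo] <- counts[i, mo] + 1L
          inst_rows[[length(inst_rows) + 1L]] <-
            tibble::tibble(id = ids[i], motif = names(ppms)[mo],
                           position = pos, instance = inst)
          placed <- TRUE
          break
        }
      }
      if (!placed) n_skipped <- n_skipped + 1L
    }
    seqs[i] <- paste(s, collapse = "")
  }
  if (n_skipped > 0) {
    warning(n_skipped, " planting(s) skipped: no non-overlapping position after 100 tries")
  }
  instances <- if (length(inst_rows) > 0) {
    dplyr::bind_rows(inst_rows)
  } else {
    tibble::tibble(id = character(), motif = character(),
                   position = integer(), instance = character())
  }
  list(seqs = sequence_set(seqs, ids = ids, drop_n = FALSE),
       truth = list(instances = instances, counts = counts,
                    motif_ppms = ppms, config = config))
}

#' Simulate cells, embedding, and pooled targets from planted-motif truth
#'
#' Assigns cells evenly to cell types, embeds them as cell-type-centered
#' Gaussian blobs, and derives per-gene, per-cell-type expected pooled
#' log-expression `E = baseline + instance_counts %*% W[, type]` (floored
#' at 0). Two consistent views are produced: an analytic pooled target
#' matrix (`E` plus Gaussian noise, floored at 0; exact when
#' `noise_sd = 0`) with pools assigned to cell types round-robin, and raw
#' per-cell Poisson counts with per-cell rate `(exp(E) - 1) / pool_size`,
#' so that summing a pure pool of `pool_size` cells and applying log1p
#' recovers `E` in expectation. Per-cell-type TF expression proxies (one
#' per motif, tracking the magnitude of the motif's effect) are included
#' for TF-association analyses.
#'
#' @param truth The `truth` element of [simulate_sequences()].
#' @param config A [sim_config()].
#' @param seed RNG seed (default config seed + 1).
#' @return List: `targets` (analytic `pooled_dataset`), `cells` (a
#'   [count_matrix()]), `expected` (genes x celltypes matrix E),
#'   `tf_expression` (TFs x pools of the analytic targets), `tf_table`,
#'   `cluster_table`, `pool_celltype`.
#' @export
simulate_pooled_targets <- function(truth, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  W <- config$effect
  n_types <- ncol(W)
  types <- paste0("type_", seq_len(n_types))
  genes <- rownames(truth$counts)
  E <- config$baseline + truth$counts %*% W          # genes x celltypes
  E[E < 0] <- 0
  colnames(E) <- types

  # analytic pooled targets: round-robin cell-type assignment over pools
  pool_type <- rep_len(types, config$n_pools)
  values <- E[, pool_type, drop = FALSE] +
    matrix(rnorm(length(genes) * config$n_pools, 0, config$noise_sd),
           length(genes), config$n_pools)
  values[values < 0] <- 0
  colnames(values) <- paste0("pool_", seq_len(config$n_pools))
  targets <- structure(
    list(values = values, pool_members = as.list(paste0("virtual_", seq_len(config$n_pools))),
         pool_celltype = pool_type, pool_purity = rep(1, config$n_pools),
         seeds = seq_len(config$n_pools), pool_size = config$pool_size,
         include_seed = TRUE),
    class = "pooled_dataset"
  )

  # raw cells: Poisson counts whose pure-pool sums have mean exp(E) - 1
  cell_type <- sample(rep_len(types, config$n_cells))
  centers <- cbind(10 * cos(2 * pi * seq_len(n_types) / n_types),
                   10 * sin(2 * pi * seq_len(n_types) / n_types))
  embedding <- centers[match(cell_type, types), ] +
    matrix(rnorm(2 * config$n_cells, 0, config$embedding_sd), config$n_cells, 2)
  colnames(embedding) <- c("dim1", "dim2")
  rate <- (exp(E) - 1) / config$pool_size            # genes x celltypes
  counts_mat <- matrix(0L, length(genes), config$n_cells)
  for (t in seq_len(n_types)) {
    cols <- which(cell_type == types[t])
    counts_mat[, cols] <- stats::rpois(length(genes) * length(cols), rate[, t])
  }
  cell_ids <- sprintf("cell_%04d", seq_len(config$n_cells))
  cells <- count_matrix(
    Matrix::Matrix(counts_mat, sparse = TRUE),
    feature_ids = genes, cell_ids = cell_ids,
    cell_meta = tibble::tibble(cell_id = cell_ids, cell_type = cell_type,
                               batch = "sim"),
    embedding = embedding
  )

  # TF proxies: expression tracks the magnitude of each motif's effect in
  # the pool's cell type, so activators correlate positively with influence
  # and the repressor negatively
  motifs <- rownames(W) %||% names(truth$motif_ppms)
  tf_ids <- paste0("TF_", sub("^planted_", "", motifs))
  tf_by_type <- 0.5 + abs(W)                         # motifs x celltypes
  tf_expression <- tf_by_type[, match(pool_type, types), drop = FALSE] +
    matrix(rnorm(length(motifs) * config$n_pools, 0, 0.05),
           length(motifs), config$n_pools)
  dimnames(tf_expression) <- list(tf_ids, colnames(values))

  rownames(tf_by_type) <- tf_ids
  family <- paste0("family_", sub("^planted_", "", motifs))
  list(targets = targets, cells = cells, expected = E,
       tf_expression = tf_expression, tf_by_type = tf_by_type,
       tf_table = tibble::tibble(tf = tf_ids, cluster = family),
       cluster_table = tibble::tibble(target = names(truth$motif_ppms),
                                      cluster = family),
       pool_celltype = pool_type)
}

#' Simulate a complete planted-motif study
#'
#' Generates the full fixture: planted-motif sequences, cells with a
#' blob embedding, and a pooled dataset produced by the actual pooling
#' pipeline ([geometric_sketch()] seeds + [pool_cells()]), aligned with the
#' sequences. The planted PPMs double as the motif database and the
#' cluster/TF tables give each planted motif its own family.
#'
#' @param config A [sim_config()].
#' @param seed Base RNG seed (default from config); stages use seed,
#'   seed + 1, seed + 2.
#' @return List with `seqs`, `truth`, `cells`, `pooled` (kNN-pooled,
#'   annotated), `targets` (analytic pooled targets), `tf_expression`,
#'   `tf_table`, `cluster_table`, `database` (planted PPMs), `config`.
#' @export
simulate_regulatory_dataset <- function(config = sim_config(), seed = config$seed) {
  sim <- simulate_sequences(config, seed = seed)
  cellsim <- simulate_pooled_targets(sim$truth, config, seed = seed + 1)
  set.seed(seed + 2)
  seeds <- geometric_sketch(cellsim$cells$embedding, config$n_pools)
  pooled <- pool_cells(cellsim$cells, seeds, pool_size = config$pool_size)
  list(seqs = sim$seqs, truth = sim$truth, cells = cellsim$cells,
       pooled = pooled, targets = cellsim$targets,
       tf_expression = cellsim$tf_expression, tf_by_type = cellsim$tf_by_type,
       tf_table = cellsim$tf_table,
       cluster_table = cellsim$cluster_table,
       database = sim$truth$motif_ppms, config = config)
}
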