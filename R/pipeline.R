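#' Default pipeline configuration
#'
#' The structured configuration consumed by [run_pipeline()]; any YAML file
#' with the same keys validates. `simulate` holds [sim_config()] arguments,
#' `train` the model/search settings, `motifs` alignment settings.
#'
#' @param seed Global seed; stages derive their seeds as seed + stage
#'   index.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(),                       # sim_config() overrides
    train = list(d = 50, m = 12, K = 3, num_calibrations = 8, epochs = 24),
    motifs = list(thresh = 0.05, n_shuffle = 1000)
  )
}

validate_pipeline_config <- function(config) {
  known <- c("seed", "simulate", "train", "motifs")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  }
  base <- default_pipeline_config(config$seed %||% 1)
  for (sec in c("train", "motifs")) {
    unknown <- setdiff(names(config[[sec]]), names(base[[sec]]))
    if (length(unknown) > 0) {
      stop("unknown key(s) in '", sec, "': ", paste(unknown, collapse = ", "))
    }
  }
  bad_sim <- setdiff(names(config$simulate), names(formals(sim_config)))
  if (length(bad_sim) > 0) {
    stop("unknown key(s) in 'simulate': ", paste(bad_sim, collapse = ", "))
  }
  cfg <- base
  cfg$simulate <- config$simulate %||% list()
  cfg$train <- modifyList(base$train, config$train %||% list())
  cfg$motifs <- modifyList(base$motifs, config$motifs %||% list())
  cfg
}

stage_hash <- function(...) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(list(...), tmp, digits = NA, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end workflow
#'
#' Orchestrates simulate, pool, train, motifs, influence and analyze as one
#' reproducible run. Each stage writes its outputs under
#' `out_dir/<stage>/` and records a content hash of its configuration in
#' `manifest.json`; on rerun, stages whose hash (including upstream
#' hashes) is unchanged are skipped and their outputs reused.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   a YAML file path.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  say <- function(...) if (!quiet) message(...)
  log_lines <- c(sprintf("run started %s; seed %d", format(Sys.time()), cfg$seed),
                 sprintf("scregmotif %s on R %s",
                         as.character(utils::packageVersion("scregmotif")),
                         paste(R.version$major, R.version$minor, sep = ".")))
  timings <- list()
  run_stage <- function(name, hash, fn) {
    t0 <- Sys.time()
    if (identical(manifest[[name]], hash) &&
        dir.exists(file.path(out_dir, name))) {
      say("stage ", name, ": up to date, skipped")
      log_lines <<- c(log_lines, sprintf("stage %s skipped (hash %s)", name, hash))
      return(FALSE)
    }
    say("stage ", name, ": running")
    dir.create(file.path(out_dir, name), showWarnings = FALSE)
    fn(file.path(out_dir, name))
    manifest[[name]] <<- hash
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    log_lines <<- c(log_lines, sprintf("stage %s ran in %.1fs (hash %s)",
                                       name, timings[[name]], hash))
    TRUE
  }

  results <- new.env()
  sim_cfg <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed + 1)))

  h_sim <- stage_hash(stage = "simulate", cfg = unclass(sim_cfg)[setdiff(names(sim_cfg), "motif_ppms")])
  run_stage("simulate", h_sim, function(dir) {
    ds <- simulate_regulatory_dataset(sim_cfg)
    results$ds <- ds
    write_sequence_fasta(ds$seqs, file.path(dir, "sequences.fa"))
    Matrix::writeMM(ds$cells$counts, file.path(dir, "counts.mtx"))
    writeLines(ds$cells$feature_ids, file.path(dir, "features.txt"))
    writeLines(ds$cells$cell_ids, file.path(dir, "cells.txt"))
    readr::write_tsv(ds$cells$cell_meta, file.path(dir, "cell_meta.tsv"))
    readr::write_tsv(tibble::as_tibble(ds$cells$embedding, rownames = "cell_id"),
                     file.path(dir, "embedding.tsv"))
    readr::write_tsv(ds$truth$instances, file.path(dir, "truth_instances.tsv"))
    write_meme(ds$database, file.path(dir, "database.meme"))
    readr::write_tsv(ds$cluster_table, file.path(dir, "cluster_table.tsv"))
    readr::write_tsv(ds$tf_table, file.path(dir, "tf_table.tsv"))
  })
  if (is.null(results$ds)) results$ds <- simulate_regulatory_dataset(sim_cfg)
  ds <- results$ds

  h_pool <- stage_hash(stage = "pool", upstream = h_sim)
  run_stage("pool", h_pool, function(dir) {
    write_matrix_tsv(ds$pooled$values, file.path(dir, "pooled_matrix.tsv"))
    readr::write_tsv(tibble::tibble(pool = colnames(ds$pooled$values),
                                    cell_type = ds$pooled$pool_celltype,
                                    purity = ds$pooled$pool_purity),
                     file.path(dir, "pool_annotation.tsv"))
    rep_ <- pooling_report(ds$pooled, ds$cells)
    readr::write_tsv(rep_$pools, file.path(dir, "pooling_report.tsv"))
  })

  h_train <- stage_hash(stage = "train", cfg = cfg$train, upstream = h_pool)
  train_dir <- file.path(out_dir, "train")
  priors <- hyper_priors(num_calibrations = cfg$train$num_calibrations,
                         epochs = cfg$train$epochs)
  run_stage("train", h_train, function(dir) {
    ens <- scover_train(ds$pooled, ds$seqs, d = cfg$train$d, m = cfg$train$m,
                        K = cfg$train$K, priors = priors, seed = cfg$seed + 3)
    results$ens <- ens
    readr::write_tsv(tidy(ens), file.path(dir, "ensemble_metrics.tsv"))
    for (ck in ens$checkpoints) {
      write_checkpoint(ck, file.path(dir, sprintf("fold_%02d.json", ck$fold)))
    }
  })
  if (is.null(results$ens)) {
    files <- sort(list.files(train_dir, pattern = "^fold_.*json$", full.names = TRUE))
    results$ens <- rebuild_ensemble(files, ds)
  }
  ens <- results$ens

  h_mot <- stage_hash(stage = "motifs", cfg = cfg$motifs, upstream = h_train)
  run_stage("motifs", h_mot, function(dir) {
    motifs <- ensemble_motifs(ens, ds$seqs)
    aln <- align_motifs(motifs, ds$database, thresh = cfg$motifs$thresh,
                        n_shuffle = cfg$motifs$n_shuffle, seed = cfg$seed + 4)
    assigned <- assign_clusters(motifs, aln, ds$cluster_table,
                                K = length(ens$checkpoints))
    results$assigned <- assigned
    write_meme(motifs, file.path(dir, "motifs.meme"))
    readr::write_tsv(aln, file.path(dir, "alignments.tsv"))
    readr::write_tsv(dplyr::select(assigned, -"pfm", -"ppm"),
                     file.path(dir, "cluster_assignment.tsv"))
  })
  if (is.null(results$assigned)) {
    motifs <- ensemble_motifs(ens, ds$seqs)
    aln <- align_motifs(motifs, ds$database, thresh = cfg$motifs$thresh,
                        n_shuffle = cfg$motifs$n_shuffle, seed = cfg$seed + 4)
    results$assigned <- assign_clusters(motifs, aln, ds$cluster_table,
                                        K = length(ens$checkpoints))
  }
  assigned <- results$assigned

  any_retained <- any(assigned$retained)
  if (!any_retained) {
    say("no reproducible aligned motif clusters; cluster-level outputs skipped")
  }
  h_infl <- stage_hash(stage = "influence", upstream = h_mot)
  run_stage("influence", h_infl, function(dir) {
    infl <- ensemble_influence(ens, ds$seqs)
    results$infl <- infl
    write_matrix_tsv(unclass(infl), file.path(dir, "influence_motif_pool.tsv"))
    if (any_retained) {
      agg <- aggregate_influence(infl, pool_celltype = ds$pooled$pool_celltype,
                                 clusters = assigned)
      results$agg <- agg
      write_matrix_tsv(unclass(agg), file.path(dir, "influence_cluster_celltype.tsv"))
      write_matrix_tsv(unclass(z_transform(agg)),
                       file.path(dir, "influence_cluster_celltype_z.tsv"))
    }
  })
  if (is.null(results$infl)) results$infl <- ensemble_influence(ens, ds$seqs)
  if (is.null(results$agg) && any_retained) {
    results$agg <- aggregate_influence(results$infl,
                                       pool_celltype = ds$pooled$pool_celltype,
                                       clusters = assigned)
  }

  h_ana <- stage_hash(stage = "analyze", upstream = h_infl)
  run_stage("analyze", h_ana, function(dir) {
    ms <- motif_space(ens, ds$seqs,
                      clusters = if (any_retained) assigned else NULL)
    if (!any_retained) return(invisible(NULL))
    infl_pool <- aggregate_influence(results$infl, clusters = assigned)
    types <- sub("^type_", "", colnames(results$agg))
    tf_expr <- ds$tf_by_type[, match(ds$pooled$pool_celltype,
                                     paste0("type_", types)), drop = FALSE]
    colnames(tf_expr) <- colnames(results$infl)
    tfc <- tf_correlation(infl_pool, tf_expr, ds$tf_table)
    readr::write_tsv(tfc, file.path(dir, "tf_correlation.tsv"))
    write_matrix_tsv(ms$cluster_scores, file.path(dir, "motif_space_cluster_scores.tsv"))
    co <- co_occurrence_sets(ms$cluster_scores)
    readr::write_tsv(co$intersections, file.path(dir, "co_occurrence.tsv"))
  })

  manifest$config <- NULL
  jsonlite::write_json(manifest, manifest_path, digits = NA, auto_unbox = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(dataset = ds, ensemble = ens, motifs = assigned,
                 influence = results$infl, aggregated = results$agg,
                 manifest = manifest, out_dir = out_dir))
}

# reload fold checkpoints written by the train stage and reattach the
# metadata scover_train() would have produced
rebuild_ensemble <- function(files, ds) {
  checkpoints <- lapply(files, read_checkpoint)
  cfg <- checkpoints[[1]]$params$config
  structure(
    list(checkpoints = checkpoints,
         metrics = tibble::tibble(fold = integer(), metric = character(),
                                  r_squared = numeric()),
         plan = NULL, ids = ds$seqs$ids, config = cfg,
         pool_names = colnames(ds$pooled$values), seed = NA),
    class = "scover_ensemble"
  )
}
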