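#' Extract position frequency matrices from a trained model
#'
#' For every convolutional filter, scans each sequence for the window of
#' width m with the highest post-ELU activation (ties break to the lowest
#' position). Windows whose activation is strictly positive contribute
#' their nucleotides to the filter's PFM; sequences with no positive
#' activation for a filter are skipped. PPMs are PFMs divided by their
#' column sums, with no pseudocount (a small pseudocount is added only at
#' MEME export).
#'
#' @param checkpoint A `scover_checkpoint`.
#' @param seqs The [sequence_set()] the model was trained on.
#' @param which_seqs Sequence indices to scan; defaults to the checkpoint's
#'   inner-training split (falling back to all sequences).
#' @param run Label for this model in motif names (default the checkpoint's
#'   fold, else 1); motifs are named `<run>_<filter>`.
#' @return A `motif_set` tibble: run, filter, motif, n_contributing, and
#'   list-columns pfm / ppm (NULL for filters with no contributing
#'   sequence, which are flagged `empty`).
#' @export
extract_pfms <- function(checkpoint, seqs, which_seqs = NULL, run = NULL) {
  stopifnot(inherits(checkpoint, "scover_checkpoint"),
            inherits(seqs, "sequence_set"))
  params <- checkpoint$params
  m <- params$config$m
  d <- params$config$d
  run <- run %||% checkpoint$fold %||% 1L
  which_seqs <- which_seqs %||% checkpoint$idx_train %||% seq_along(seqs$ids)
  fwd <- scover_forward(params, seqs, which_seqs = which_seqs)
  seq_chars <- strsplit(unname(seqs$sequences[which_seqs]), "")

  pfms <- vector("list", d)
  n_contrib <- integer(d)
  for (i in seq_len(d)) {
    contrib <- which(fwd$activations[, i] > 0)
    n_contrib[i] <- length(contrib)
    if (length(contrib) == 0L) next
    pfm <- matrix(0, 4L, m, dimnames = list(NUCLEOTIDES, NULL))
    for (k in contrib) {
      pos <- fwd$argmax[k, i]
      ii <- match(seq_chars[[k]][pos:(pos + m - 1L)], NUCLEOTIDES)
      ok <- !is.na(ii)
      pfm[cbind(ii[ok], which(ok))] <- pfm[cbind(ii[ok], which(ok))] + 1
    }
    pfms[[i]] <- pfm
  }
  ppms <- lapply(pfms, function(pfm) {
    if (is.null(pfm)) return(NULL)
    cs <- colSums(pfm)
    cs[cs == 0] <- 1
    sweep(pfm, 2L, cs, "/")
  })
  out <- tibble::tibble(
    run = run, filter = seq_len(d),
    motif = paste0(run, "_", seq_len(d)),
    n_contributing = n_contrib,
    empty = n_contrib == 0L,
    pfm = pfms, ppm = ppms
  )
  class(out) <- c("motif_set", class(out))
  out
}

#' Extract motifs from every model of an ensemble
#'
#' Runs [extract_pfms()] per fold model (each on its own inner-training
#' sequences) and row-binds the results.
#'
#' @param ensemble A `scover_ensemble`.
#' @param seqs The training [sequence_set()] (ids aligned with
#'   `ensemble$ids`).
#' @return A `motif_set` covering all `r * d` filters.
#' @export
ensemble_motifs <- function(ensemble, seqs) {
  stopifnot(inherits(ensemble, "scover_ensemble"))
  seqs <- align_ensemble_seqs(ensemble, seqs)
  out <- dplyr::bind_rows(lapply(ensemble$checkpoints, function(ck) {
    extract_pfms(ck, seqs, run = ck$fold)
  }))
  class(out) <- c("motif_set", class(out))
  out
}

align_ensemble_seqs <- function(ensemble, seqs) {
  if (identical(seqs$ids, ensemble$ids)) return(seqs)
  if (!all(ensemble$ids %in% seqs$ids)) {
    stop("sequence set does not contain all sequences the ensemble was trained on")
  }
  sequence_set(unname(seqs$sequences[ensemble$ids]), ids = ensemble$ids, drop_n = FALSE)
}

# reverse complement of a PPM: reverse the columns, swap A<->T and C<->G
revcomp_ppm <- function(ppm) {
  out <- ppm[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(ppm))), drop = FALSE]
  rownames(out) <- NUCLEOTIDES
  out
}

# Column-correlation matrix between two PPMs: entry [j, k] is the Pearson
# correlation of query column j with target column k (4-vectors).
ppm_col_cor <- function(q, t) {
  C <- suppressWarnings(cor(q, t))
  C[is.na(C)] <- 0
  C
}

# enumerate the ungapped offsets with >= min_overlap aligned columns;
# each element holds the aligned (query, target) column indices
alignment_offsets <- function(wq, wt, min_overlap = 4L) {
  offs <- seq(-(wq - min_overlap), wt - min_overlap)
  out <- lapply(offs, function(off) {
    qi <- seq_len(wq) + off
    ok <- qi >= 1L & qi <= wt
    if (sum(ok) < min_overlap) return(NULL)
    list(offset = off, q = which(ok), t = qi[ok])
  })
  out[!vapply(out, is.null, TRUE)]
}

# Best alignment band of C for one row permutation (identity =
# unshuffled query). Offsets are ranked by the summed column correlation,
# which rewards longer well-matching overlaps (short overlaps would
# otherwise dominate by chance); the mean per-column correlation of the
# winning band is reported as r.
band_best <- function(C, row_perm, offsets) {
  best <- list(r = -Inf, score = -Inf, offset = 0L)
  for (al in offsets) {
    vals <- C[cbind(row_perm[al$q], al$t)]
    sc <- sum(vals)
    if (sc > best$score) best <- list(r = mean(vals), score = sc, offset = al$offset)
  }
  best
}

# vectorized band score maxima for a matrix of row permutations (one per
# shuffle); returns the summed-correlation statistic used for the null
band_best_many <- function(C, Pm, offsets) {
  best <- rep(-Inf, nrow(Pm))
  for (al in offsets) {
    sub <- Pm[, al$q, drop = FALSE]
    vals <- matrix(C[cbind(as.vector(sub), rep(al$t, each = nrow(Pm)))], nrow(Pm))
    best <- pmax(best, rowSums(vals))
  }
  best
}

# Best mean per-column Pearson correlation between two PPMs over all
# ungapped offsets with at least `min_overlap` aligned columns, both
# orientations. Returns r, offset and orientation of the best alignment.
best_ppm_alignment <- function(query, target, min_overlap = 4L) {
  wq <- ncol(query); wt <- ncol(target)
  offsets <- alignment_offsets(wq, wt, min_overlap)
  # reverse-complement alignment scores come from the base-swapped query
  # with reversed row order, so both orientations reuse two matrices
  fwd <- band_best(ppm_col_cor(query, target), seq_len(wq), offsets)
  rev_ <- band_best(ppm_col_cor(query[c(4L, 3L, 2L, 1L), , drop = FALSE], target),
                    rev(seq_len(wq)), offsets)
  if (fwd$score >= rev_$score) c(fwd, orientation = "+") else c(rev_, orientation = "-")
}

#' Align motifs against a motif database
#'
#' Aligns query motifs to database motifs, preferring the Tomtom tool from
#' the MEME suite when its executable is available (invoked with
#' `-thresh 0.05` and default scoring). Without Tomtom, a built-in
#' comparator is used: the best mean per-column Pearson correlation of PPM
#' columns over all ungapped offsets and both orientations, with an
#' empirical p-value obtained from column-shuffled query motifs and
#' Benjamini-Hochberg q-values across all query-target pairs.
#'
#' @param query A `motif_set`, a named list of PPMs, or a MEME file path.
#' @param database A named list of PPMs or a MEME file path.
#' @param thresh Significance threshold on the q-value (default 0.05).
#' @param method "auto" (Tomtom if on PATH), "tomtom" or "correlation".
#' @param tomtom_path Path to the tomtom executable.
#' @param n_shuffle Shuffles for the empirical null (default 1000).
#' @param min_overlap Minimum aligned columns (default 4).
#' @param seed RNG seed for the shuffle null.
#' @return A tibble: query, target, r (correlation method only), offset,
#'   orientation, p_value, q_value, significant, method.
#' @export
align_motifs <- function(query, database, thresh = 0.05,
                         method = c("auto", "tomtom", "correlation"),
                         tomtom_path = Sys.which("tomtom"),
                         n_shuffle = 1000, min_overlap = 4L, seed = NULL) {
  method <- match.arg(method)
  have_tomtom <- nzchar(tomtom_path) && file.exists(tomtom_path)
  if (method == "tomtom" && !have_tomtom) stop("tomtom executable not found")
  if (method == "auto") {
    if (!have_tomtom) {
      message("tomtom not found on PATH; using the built-in correlation comparator")
    }
    method <- if (have_tomtom) "tomtom" else "correlation"
  }
  query_ppms <- as_ppm_list(query)
  if (method == "tomtom") {
    return(run_tomtom(query_ppms, database, thresh, tomtom_path))
  }
  db_ppms <- as_ppm_list(database)
  if (length(db_ppms) == 0) stop("motif database is empty or malformed")
  if (!is.null(seed)) set.seed(seed)

  rows <- vector("list", length(query_ppms) * length(db_ppms))
  ri <- 0L
  for (qn in names(query_ppms)) {
    q <- query_ppms[[qn]]
    if (is.null(q)) next
    wq <- ncol(q)
    # one permutation matrix per query, shared across targets
    Pm <- t(replicate(n_shuffle, sample.int(wq)))
    for (tn in names(db_ppms)) {
      t_ppm <- db_ppms[[tn]]
      offsets <- alignment_offsets(wq, ncol(t_ppm), min_overlap)
      C_f <- ppm_col_cor(q, t_ppm)
      C_b <- ppm_col_cor(q[c(4L, 3L, 2L, 1L), , drop = FALSE], t_ppm)
      obs_f <- band_best(C_f, seq_len(wq), offsets)
      obs_r <- band_best(C_b, rev(seq_len(wq)), offsets)
      obs <- if (obs_f$score >= obs_r$score) c(obs_f, orientation = "+") else c(obs_r, orientation = "-")
      # null: the same best-alignment statistic for column-shuffled queries
      null_score <- pmax(band_best_many(C_f, Pm, offsets),
                         band_best_many(C_b, Pm[, rev(seq_len(wq)), drop = FALSE], offsets))
      pval <- (1 + sum(null_score >= obs$score)) / (1 + n_shuffle)
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(
        query = qn, target = tn, r = obs$r, offset = obs$offset,
        orientation = obs$orientation, p_value = pval
      )
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(ri)])
  if (nrow(out) == 0) return(out)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < thresh
  out$method <- "correlation"
  out
}

as_ppm_list <- function(x) {
  if (inherits(x, "motif_set")) {
    return(setNames(x$ppm, x$motif)[!x$empty])
  }
  if (is.character(x) && length(x) == 1L) return(read_meme(x))
  if (is.list(x)) {
    if (is.null(names(x))) stop("PPM list must be named")
    return(x)
  }
  stop("cannot interpret motifs: expected motif_set, named list of PPMs, or MEME path")
}

run_tomtom <- function(query_ppms, database, thresh, tomtom_path) {
  qfile <- tempfile(fileext = ".meme")
  on.exit(unlink(qfile), add = TRUE)
  write_meme(lapply(query_ppms, meme_pseudocount), qfile)
  dbfile <- if (is.character(database) && length(database) == 1L) {
    database
  } else {
    f <- tempfile(fileext = ".meme")
    on.exit(unlink(f), add = TRUE)
    write_meme(lapply(as_ppm_list(database), meme_pseudocount), f)
    f
  }
  outdir <- tempfile("tomtom")
  on.exit(unlink(outdir, recursive = TRUE), add = TRUE)
  status <- system2(tomtom_path, c("-thresh", thresh, "-oc", outdir, qfile, dbfile))
  if (status != 0) stop("tomtom exited with status ", status)
  res <- readr::read_tsv(file.path(outdir, "tomtom.tsv"),
                         comment = "#", show_col_types = FALSE)
  tibble::tibble(
    query = res$Query_ID, target = res$Target_ID,
    r = NA_real_, offset = res$Optimal_offset,
    orientation = res$Orientation,
    p_value = res$`p-value`, q_value = res$`q-value`,
    significant = res$`q-value` < thresh, method = "tomtom"
  )
}

#' Assign motifs to database motif clusters
#'
#' Each aligned motif receives the cluster of its most significant hit
#' (lowest q-value, ties by lowest p-value then lexicographic target id);
#' motifs with no significant alignment are labeled "non-aligned". A
#' cluster is reproducible only when it contains motifs from at least
#' half of the K models (ceiling(K/2)); motifs in non-reproducible
#' clusters are masked out of downstream aggregation.
#'
#' @param motifs A `motif_set`.
#' @param alignments An [align_motifs()] result for these motifs.
#' @param cluster_table Tibble mapping database motif/TF ids to cluster
#'   names (columns `target`, `cluster`; a `tf` column may stand in for
#'   `target`).
#' @param K Number of models in the ensemble (default: number of distinct
#'   runs in `motifs`).
#' @return The `motif_set` with columns `cluster`, `best_target`,
#'   `best_q_value` and `retained` added.
#' @export
assign_clusters <- function(motifs, alignments, cluster_table,
                            K = length(unique(motifs$run))) {
  stopifnot(inherits(motifs, "motif_set"))
  cluster_table <- tibble::as_tibble(cluster_table)
  if (!"target" %in% names(cluster_table) && "tf" %in% names(cluster_table)) {
    cluster_table$target <- cluster_table$tf
  }
  if (!all(c("target", "cluster") %in% names(cluster_table))) {
    stop("cluster_table needs columns target (or tf) and cluster")
  }
  if (anyDuplicated(cluster_table$target)) stop("cluster_table maps a target to multiple clusters")

  sig <- dplyr::filter(alignments, .data$significant)
  unmapped <- setdiff(unique(sig$target), cluster_table$target)
  if (length(unmapped) > 0) {
    warning("alignment target(s) missing from cluster table, skipped: ",
            paste(unmapped, collapse = ", "))
    sig <- dplyr::filter(sig, .data$target %in% cluster_table$target)
  }
  best <- sig |>
    dplyr::arrange(.data$q_value, .data$p_value, .data$target) |>
    dplyr::distinct(.data$query, .keep_all = TRUE) |>
    dplyr::left_join(cluster_table[c("target", "cluster")], by = "target") |>
    dplyr::select(motif = "query", best_target = "target",
                  best_q_value = "q_value", cluster = "cluster")

  out <- dplyr::left_join(motifs, best, by = "motif")
  out$cluster[is.na(out$cluster)] <- "non-aligned"
  support <- out |>
    dplyr::filter(.data$cluster != "non-aligned") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_models = dplyr::n_distinct(.data$run))
  reproducible <- support$cluster[support$n_models >= ceiling(K / 2)]
  out$retained <- out$cluster %in% reproducible
  class(out) <- c("motif_set", class(tibble::tibble()))
  out
}
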