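# Shared fixtures, built in code. Expensive objects are memoized in this
# environment so several test files can reuse one computation.
.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small planted-motif dataset: quick enough for per-module tests
small_sim <- function() {
  memoize("small_sim", {
    suppressWarnings(
      simulate_regulatory_dataset(
        sim_config(n_sequences = 300, L = 80, n_pools = 20, n_cells = 200,
                   pool_size = 10, seed = 11))
    )
  })
}

# the reference fixture at full size, trained: used by the end-to-end
# recovery checks (motifs, influence, permutation controls)
flagship_run <- function() {
  memoize("flagship_run", {
    ds <- simulate_regulatory_dataset(sim_config(seed = 101))
    ens <- scover_train(ds$pooled, ds$seqs, d = 50, m = 12, K = 3,
                        priors = hyper_priors(num_calibrations = 8, epochs = 24),
                        seed = 101)
    motifs <- ensemble_motifs(ens, ds$seqs)
    aln <- suppressMessages(
      align_motifs(motifs, ds$database, n_shuffle = 1000, seed = 102))
    assigned <- assign_clusters(motifs, aln, ds$cluster_table, K = 3)
    infl <- ensemble_influence(ens, ds$seqs)
    agg <- aggregate_influence(infl, pool_celltype = ds$pooled$pool_celltype,
                               clusters = assigned)
    list(ds = ds, ens = ens, motifs = motifs, aln = aln, assigned = assigned,
         infl = infl, agg = agg)
  })
}

# mean per-column Pearson correlation between two equal-width PPMs
# (independent of the aligner; used to score recovery of planted motifs)
ppm_column_cor <- function(a, b) {
  mean(vapply(seq_len(ncol(a)), function(j) {
    if (sd(a[, j]) == 0 || sd(b[, j]) == 0) return(0)
    cor(a[, j], b[, j])
  }, 1))
}

# one-hot detector filter for a given word: weight +1 on the word's
# channels, -1 elsewhere, so only the exact word scores m
word_filter <- function(word, boost = 1) {
  m <- nchar(word)
  filt <- matrix(-boost, m, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ch <- strsplit(word, "")[[1]]
  for (j in seq_len(m)) filt[j, ch[j]] <- boost
  filt
}

# random tiny model + one-hot sequences for oracle comparisons
random_tiny_model <- function(d = 3, m = 4, p = 2, L = 30, n = 10, seed = 1,
                              sigma = 0.5) {
  set.seed(seed)
  cfg <- scover_config(d = d, m = m, p = p, L = L)
  params <- init_scover_params(cfg, sigma_motifs = sigma, sigma_net = sigma)
  seqs <- sequence_set(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, ""),
    ids = paste0("s", seq_len(n)), drop_n = FALSE
  )
  list(params = params, seqs = seqs, config = cfg)
}

# brute-force forward pass: explicit position-by-position dot products,
# no shared code with the package's vectorized path
brute_forward <- function(params, seqs) {
  cfg <- params$config
  n <- length(seqs$ids)
  acts <- matrix(NA_real_, n, cfg$d)
  arg <- matrix(NA_integer_, n, cfg$d)
  for (k in seq_len(n)) {
    X <- seqs$onehot[, , k]
    for (i in seq_len(cfg$d)) {
      filt <- params$conv[, , i]                 # m x 4
      scores <- vapply(seq_len(cfg$L - cfg$m + 1L), function(pos) {
        sum(filt * t(X[, pos:(pos + cfg$m - 1L)]))
      }, 1)
      best <- which.max(scores)                  # first max = lowest position
      s <- scores[best]
      acts[k, i] <- if (s >= 0) s else exp(s) - 1
      arg[k, i] <- best
    }
  }
  preds <- acts %*% params$fc_weights +
    matrix(params$fc_bias, n, cfg$p, byrow = TRUE)
  list(predictions = preds, activations = acts, argmax = arg)
}
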