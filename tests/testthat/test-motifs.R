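make_checkpoint <- function(params, idx_train = NULL, fold = 1L) {
  structure(list(params = params, idx_train = idx_train, fold = fold),
            class = "scover_checkpoint")
}

test_that("a matched filter yields the planted word's one-hot PFM", {
  word <- "ACGTACGTACGT"
  L <- 40
  s <- paste0(paste(rep("G", 12), collapse = ""), word,
              paste(rep("G", L - 24), collapse = ""))
  cfg <- scover_config(d = 2, m = 12, p = 1, L = L)
  params <- init_scover_params(cfg, 1e-9, 1e-9, seed = 1)
  params$conv[, , 1] <- word_filter(word)
  params$conv[, , 2] <- -1                       # never positive
  seqs <- sequence_set(c(x = s), drop_n = FALSE)
  ms <- extract_pfms(make_checkpoint(params), seqs)
  expect_equal(unname(ms$pfm[[1]]), unname(one_hot_encode(word)))
  expect_equal(ms$n_contributing, c(1L, 0L))
  expect_true(ms$empty[2])                       # all-negative filter excluded
  expect_identical(ms$motif, c("1_1", "1_2"))
})

test_that("PFM column sums equal the number of contributing sequences", {
  set.seed(2)
  tm <- random_tiny_model(d = 3, m = 4, p = 2, L = 30, n = 20, seed = 2)
  ms <- extract_pfms(make_checkpoint(tm$params), tm$seqs)
  for (i in seq_len(3)) {
    if (ms$empty[i]) next
    expect_true(all(colSums(ms$pfm[[i]]) == ms$n_contributing[i]))
    expect_equal(colSums(ms$ppm[[i]]), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("extracted windows equal the exhaustive per-position oracle", {
  for (seed in 1:5) {
    tm <- random_tiny_model(d = 3, m = 4, p = 2, L = 30, n = 20, seed = seed)
    oracle <- brute_forward(tm$params, tm$seqs)
    ms <- extract_pfms(make_checkpoint(tm$params), tm$seqs)
    for (i in 1:3) {
      contrib <- which(oracle$activations[, i] > 0)
      if (length(contrib) == 0) { expect_true(ms$empty[i]); next }
      pfm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
      for (k in contrib) {
        win <- substr(tm$seqs$sequences[k], oracle$argmax[k, i],
                      oracle$argmax[k, i] + 3)
        pfm <- pfm + one_hot_encode(win)
      }
      expect_equal(unname(ms$pfm[[i]]), unname(pfm))
    }
  }
})

test_that("self-alignment is the top hit at offset 0 on the forward strand", {
  set.seed(3)
  db <- list(mA = scregmotif:::sample_consensus_ppm(12, 0.85),
             mB = scregmotif:::sample_consensus_ppm(12, 0.85))
  aln <- align_motifs(list(q = db$mA), db, method = "correlation",
                      n_shuffle = 500, seed = 4)
  top <- aln[order(aln$p_value), ][1, ]
  expect_identical(top$target, "mA")
  expect_equal(top$offset, 0L)
  expect_identical(top$orientation, "+")
  expect_equal(top$r, 1, tolerance = 1e-12)
})

test_that("an information-free query aligns to nothing", {
  set.seed(5)
  db <- list(mA = scregmotif:::sample_consensus_ppm(12, 0.85))
  unif <- matrix(0.25, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
  aln <- align_motifs(list(flat = unif), db, method = "correlation",
                      n_shuffle = 300, seed = 6)
  expect_false(any(aln$significant))
})

test_that("shifted and reverse-complement constructions align as expected", {
  set.seed(7)
  db <- list(mA = scregmotif:::sample_consensus_ppm(12, 0.9))
  shifted <- db$mA[, 2:12]                        # query col j = target col j+1
  aln <- align_motifs(list(sh = shifted), db, method = "correlation",
                      n_shuffle = 200, seed = 8)
  expect_equal(aln$offset[1], 1L)
  expect_equal(aln$r[1], 1, tolerance = 1e-12)
  expect_identical(aln$orientation[1], "+")

  rc <- scregmotif:::revcomp_ppm(db$mA)
  aln2 <- align_motifs(list(rc = rc), db, method = "correlation",
                       n_shuffle = 200, seed = 9)
  expect_identical(aln2$orientation[1], "-")
  expect_equal(aln2$r[1], 1, tolerance = 1e-12)
})

test_that("cluster reproducibility keeps >= half of models and is monotone", {
  mk_motifs <- function(runs) {
    ms <- tibble::tibble(
      run = runs, filter = seq_along(runs),
      motif = paste0(runs, "_", seq_along(runs)),
      n_contributing = 5L, empty = FALSE,
      pfm = replicate(length(runs), matrix(1, 4, 2), simplify = FALSE),
      ppm = replicate(length(runs), matrix(0.25, 4, 2), simplify = FALSE)
    )
    class(ms) <- c("motif_set", class(ms))
    ms
  }
  mk_aln <- function(motifs) {
    tibble::tibble(query = motifs, target = "tfX", r = 0.95, offset = 0L,
                   orientation = "+", p_value = 0.001, q_value = 0.004,
                   significant = TRUE, method = "correlation")
  }
  ctab <- tibble::tibble(target = "tfX", cluster = "famX")

  # present in 4 of 10 models -> excluded
  m4 <- mk_motifs(runs = 1:4)
  a4 <- assign_clusters(m4, mk_aln(m4$motif), ctab, K = 10)
  expect_false(any(a4$retained))
  expect_true(all(a4$cluster == "famX"))

  # present in 5 of 10 models -> retained (boundary)
  m5 <- mk_motifs(runs = 1:5)
  a5 <- assign_clusters(m5, mk_aln(m5$motif), ctab, K = 10)
  expect_true(all(a5$retained))

  # monotone: adding another supporting model never drops the cluster
  m6 <- mk_motifs(runs = 1:6)
  a6 <- assign_clusters(m6, mk_aln(m6$motif), ctab, K = 10)
  expect_true(all(a6$retained))

  # K = 1: every aligned cluster is retained
  m1 <- mk_motifs(runs = 1L)
  a1 <- assign_clusters(m1, mk_aln(m1$motif), ctab, K = 1)
  expect_true(all(a1$retained))
})

test_that("cluster assignment picks the most significant hit and warns on gaps", {
  ms <- tibble::tibble(run = 1L, filter = 1L, motif = "1_1",
                       n_contributing = 3L, empty = FALSE,
                       pfm = list(matrix(1, 4, 2)), ppm = list(matrix(0.25, 4, 2)))
  class(ms) <- c("motif_set", class(ms))
  aln <- tibble::tibble(
    query = "1_1", target = c("tfA", "tfB", "tfC"),
    r = c(0.9, 0.95, 0.8), offset = 0L, orientation = "+",
    p_value = c(0.01, 0.001, 0.02), q_value = c(0.03, 0.004, 0.04),
    significant = TRUE, method = "correlation")
  ctab <- tibble::tibble(target = c("tfA", "tfB"), cluster = c("famA", "famB"))
  expect_warning(out <- assign_clusters(ms, aln, ctab, K = 1), "tfC")
  expect_identical(out$cluster, "famB")          # lowest q-value wins
  expect_identical(out$best_target, "tfB")

  # unaligned motifs get the non-aligned label
  none <- aln[0, ]
  out2 <- assign_clusters(ms, none, ctab, K = 1)
  expect_identical(out2$cluster, "non-aligned")
  expect_false(any(out2$retained))
})
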