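# step-up BH oracle written directly from the procedure's definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(ord)]
}

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(1)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("Spearman correlation is invariant under strictly monotone transforms", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    rho <- cor(x, y, method = "spearman")
    expect_equal(cor(exp(x), y, method = "spearman"), rho, tolerance = 1e-12)
    expect_equal(cor(x, 3 * y^3 + y, method = "spearman"), rho, tolerance = 1e-12)
    expect_equal(cor(rank(x), rank(y)), rho, tolerance = 1e-12)
  }
})

test_that("TF correlation reports monotone and anti-monotone associations", {
  set.seed(3)
  infl <- scregmotif:::influence_matrix(
    matrix(rnorm(20), 2, 10, dimnames = list(c("famA", "famB"), NULL)),
    level = "cluster_pool")
  # activator: expression is a monotone transform of famA influence;
  # repressor: anti-monotone in famB influence
  expr <- rbind(tf_act = exp(infl["famA", ]),
                tf_rep = -2 * unclass(infl)["famB", ]^3 - unclass(infl)["famB", ],
                tf_noise = rnorm(10))
  tbl <- tibble::tibble(tf = c("tf_act", "tf_rep", "tf_noise"),
                        cluster = c("famA", "famB", "famA"))
  res <- tf_correlation(infl, expr, tbl)
  expect_equal(res$rho[res$tf == "tf_act"], 1, tolerance = 1e-12)
  expect_equal(res$rho[res$tf == "tf_rep"], -1, tolerance = 1e-12)
  expect_true(all(res$q_value >= res$p_value - 1e-12))

  # constant expression: NA rho with a warning
  expr2 <- rbind(expr, tf_const = rep(2, 10))
  tbl2 <- dplyr::bind_rows(tbl, tibble::tibble(tf = "tf_const", cluster = "famB"))
  expect_warning(res2 <- tf_correlation(infl, expr2, tbl2), "constant")
  expect_true(is.na(res2$rho[res2$tf == "tf_const"]))

  # TFs absent from the expression matrix are dropped with a warning
  tbl3 <- dplyr::bind_rows(tbl, tibble::tibble(tf = "tf_gone", cluster = "famA"))
  expect_warning(tf_correlation(infl, expr, tbl3), "tf_gone")
})

test_that("gene-set screening applies the size filter and top-n rule", {
  set.seed(4)
  n_pools <- 12
  infl <- scregmotif:::influence_matrix(
    matrix(rnorm(n_pools), 1, n_pools, dimnames = list("famA", NULL)),
    level = "cluster_pool")
  program <- exp(unclass(infl)["famA", ])        # monotone in influence
  expr <- rbind(
    g1 = program, g2 = 2 * program, g3 = program + 5,
    g4 = rnorm(n_pools), g5 = rnorm(n_pools)
  )
  sets <- list(
    planted = c("g1", "g2", "g3"),
    noisy = c("g4", "g5"),
    too_big = paste0("x", 1:50),                 # exactly 50 genes -> excluded
    unmatched = c("zz1", "zz2")
  )
  expect_warning(res <- gene_set_correlation(expr, sets, infl, k_groups = 2),
                 "no matching")
  expect_false("too_big" %in% res$correlations$set)
  expect_false("unmatched" %in% res$correlations$set)
  planted_rho <- res$correlations$rho[res$correlations$set == "planted"]
  expect_equal(planted_rho, 1, tolerance = 1e-12)
  # fewer sets than top_n: all kept
  expect_setequal(unique(res$correlations$set), c("planted", "noisy"))
  expect_equal(nrow(res$groups), 2)
})

test_that("motif space concatenates per-model activations run-major", {
  sim <- small_sim()
  ens <- scover_train(sim$targets, sim$seqs, d = 3, m = 12, K = 2,
                      priors = hyper_priors(num_calibrations = 2, epochs = 2),
                      controls = FALSE, seed = 5)
  ms <- motif_space(ens, sim$seqs)
  expect_equal(ncol(ms$matrix), 2 * 3)
  expect_identical(colnames(ms$matrix), c("1_1", "1_2", "1_3", "2_1", "2_2", "2_3"))
  # single model: equals forward()'s activation output
  single <- scover_forward(ens$checkpoints[[1]]$params, sim$seqs)$activations
  expect_equal(unname(ms$matrix[, 1:3]), unname(single))
  # stability across invocations
  expect_equal(motif_space(ens, sim$seqs)$matrix, ms$matrix)
  # an all-zero filter gives an all-zero column
  ens$checkpoints[[1]]$params$conv[, , 2] <- 0
  ms2 <- motif_space(ens, sim$seqs)
  expect_true(all(ms2$matrix[, "1_2"] == 0))
})

test_that("co-occurrence sets apply the 75% of maximum rule", {
  scores <- cbind(famA = c(1, 2, 4), famB = c(1, 2, 4), famC = c(-1, -2, 0))
  rownames(scores) <- c("g1", "g2", "g3")
  expect_warning(res <- co_occurrence_sets(scores), "famC")
  expect_identical(res$sets$famA, "g3")          # threshold 3: only the 4
  expect_identical(res$sets$famA, res$sets$famB) # identical score vectors
  n_ab <- res$intersections$n[res$intersections$family_a == "famA" &
                                res$intersections$family_b == "famB"]
  expect_equal(n_ab, 1L)
  expect_length(res$sets$famC, 0)
})

test_that("disjoint planted programs give near-disjoint co-occurrence sets", {
  sim <- small_sim()
  # family scores straight from the planted instance counts: two motifs
  # that never co-occur by construction of the score should split genes
  counts <- sim$truth$counts
  fam <- cbind(famA = counts[, 1] * 5 + runif(nrow(counts), 0, 0.1),
               famB = counts[, 2] * 5 + runif(nrow(counts), 0, 0.1))
  rownames(fam) <- rownames(counts)
  res <- co_occurrence_sets(fam)
  jaccard <- length(intersect(res$sets$famA, res$sets$famB)) /
    length(union(res$sets$famA, res$sets$famB))
  expect_lt(jaccard, 0.5)   # planting is independent, overlap ~ plant_prob
})

test_that("signature scores are mean expression of present genes", {
  expr <- rbind(MKI67 = c(1, 2, 3), PLK1 = c(3, 2, 1), OTHER = c(5, 5, 5))
  colnames(expr) <- paste0("p", 1:3)
  one <- signature_score(expr, "MKI67")
  expect_equal(unname(one), c(1, 2, 3))
  const <- signature_score(rbind(a = c(2, 2), b = c(2, 2)), c("a", "b"))
  expect_true(all(const == 2))
  both <- signature_score(expr, c("MKI67", "PLK1", "MISSING"))
  expect_equal(unname(both), c(2, 2, 2))
  expect_error(signature_score(expr, c("NOPE")), "none")
  withr <- signature_score(expr, "MKI67", against = c(10, 20, 30))
  expect_equal(withr$rho, 1)
})
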