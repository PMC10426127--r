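toy_cells <- function(embedding, counts = NULL, types = NULL) {
  n <- nrow(embedding)
  if (is.null(counts)) counts <- matrix(1, 2, n)
  if (is.null(types)) types <- rep("T", n)
  count_matrix(Matrix::Matrix(counts, sparse = TRUE),
               feature_ids = paste0("g", seq_len(nrow(counts))),
               cell_ids = paste0("c", seq_len(n)),
               cell_meta = tibble::tibble(cell_type = types),
               embedding = embedding)
}

test_that("geometric sketching covers the embedding and handles edge cases", {
  set.seed(1)
  emb <- matrix(rnorm(40), 20, 2)
  expect_identical(unname(geometric_sketch(emb, 20)), 1:20)
  one <- geometric_sketch(emb, 1, seed = 3)
  expect_length(one, 1)
  expect_true(one %in% 1:20)
  expect_error(geometric_sketch(emb, 21), "exceeds")
})

test_that("sketching oversamples rare populations relative to density", {
  # two Gaussian blobs, 900 vs 100 cells: a density-proportional sampler
  # would give the minority blob 2 of 20 seeds in expectation; coverage
  # sampling should give it at least 4 nearly always
  set.seed(7)
  emb <- rbind(matrix(rnorm(1800, 0, 1), 900, 2),
               matrix(rnorm(200, 10, 1), 100, 2))
  hits <- vapply(1:100, function(i) {
    seeds <- geometric_sketch(emb, 20)
    sum(seeds > 900)
  }, 1)
  expect_gte(mean(hits >= 4), 0.95)
})

test_that("pooled values are log1p of exact member-count sums", {
  # 3 cells with counts 1, 2, 4 for one gene; q = 3 -> log(1 + 7)
  emb <- matrix(c(0, 1, 2, 0, 0, 0), 3, 2)
  cm <- toy_cells(emb, counts = rbind(c(1, 2, 4)))
  pooled <- pool_cells(cm, seeds = 1, pool_size = 3)
  expect_equal(unname(pooled$values[1, 1]), log(1 + 7))

  # q = 1: pools are the seeds themselves
  p1 <- pool_cells(cm, seeds = c(1, 3), pool_size = 1)
  expect_equal(unname(p1$values[1, ]), log1p(c(1, 4)))

  expect_error(pool_cells(cm, seeds = c(1, 1), pool_size = 2), "duplicate")
})

test_that("pool membership matches brute-force nearest neighbours", {
  emb <- matrix(c(0, 0, 1, 5, 5.2, 9,
                  0, 0.1, 0, 5, 5, 9), 6, 2)
  cm <- toy_cells(emb)
  pooled <- pool_cells(cm, seeds = c(1, 4), pool_size = 3)
  for (s in 1:2) {
    seed <- c(1, 4)[s]
    d <- sqrt(rowSums((emb - matrix(emb[seed, ], 6, 2, byrow = TRUE))^2))
    expected <- paste0("c", c(seed, setdiff(order(d), seed)[1:2]))
    expect_setequal(pooled$pool_members[[s]], expected)
  }
})

test_that("count conservation holds before the log transform", {
  set.seed(5)
  counts <- matrix(rpois(60, 2), 6, 10)
  emb <- matrix(rnorm(20), 10, 2)
  cm <- toy_cells(emb, counts = counts)
  pooled <- pool_cells(cm, seeds = c(2, 7), pool_size = 4)
  for (s in 1:2) {
    idx <- match(pooled$pool_members[[s]], cm$cell_ids)
    expect_equal(unname(expm1(pooled$values[, s])),
                 unname(rowSums(counts[, idx])))
    expect_length(idx, 4)
  }
})

test_that("pooled sparsity is non-increasing in pool size", {
  sim <- small_sim()
  seeds <- geometric_sketch(sim$cells$embedding, 15, seed = 2)
  sparsity <- vapply(c(1, 5, 20), function(q) {
    mean(pool_cells(sim$cells, seeds, pool_size = q)$values == 0)
  }, 1)
  expect_true(all(diff(sparsity) <= 0))
})

test_that("majority annotation gives pure pools on well-separated cell types", {
  sim <- small_sim()
  expect_gte(mean(sim$pooled$pool_purity > 0.8), 0.9)
  rep_ <- pooling_report(sim$pooled, sim$cells)
  expect_lte(rep_$sparsity_pooled, rep_$sparsity_raw)
})

test_that("modal cell-type ties break lexicographically", {
  emb <- matrix(c(0, 0.1, 5, 0, 0, 0), 3, 2)
  cm <- toy_cells(emb, types = c("beta", "alpha", "gamma"))
  pooled <- pool_cells(cm, seeds = 1, pool_size = 2)  # one beta, one alpha
  expect_identical(pooled$pool_celltype, "alpha")
  expect_equal(pooled$pool_purity, 0.5)
})

test_that("feature filtering applies detection and rescue rules exactly", {
  # 100 pools; rows engineered around the 5% / 16% / log10(3) preset
  p <- 100
  v <- rbind(
    low      = c(rep(0.6, 4), rep(0, 96)),    # 4% detected -> dropped
    rescue   = c(rep(0.6, 10), rep(0, 90)),   # 10%, mean 0.6 > log10(3) -> kept
    no_rescue = c(rep(0.3, 10), rep(0, 90)),  # 10%, mean 0.3 < log10(3) -> dropped
    common   = rep(1, 100)                    # kept outright
  )
  pooled <- structure(list(values = v, pool_members = as.list(seq_len(p)),
                           pool_celltype = rep("T", p),
                           pool_purity = rep(1, p), seeds = seq_len(p),
                           pool_size = 1, include_seed = TRUE),
                      class = "pooled_dataset")
  filtered <- filter_features(pooled, 0.05, 0.16, log10(3))
  expect_identical(rownames(filtered$values), c("rescue", "common"))

  # min = 0, rescue = 0 is the identity
  ident <- filter_features(pooled, 0, 0, 0)
  expect_identical(rownames(ident$values), rownames(v))

  sparse_only <- pooled
  sparse_only$values <- v[c("low", "no_rescue"), , drop = FALSE]
  expect_error(filter_features(sparse_only, 0.05, 0.16, log10(3)), "relax")
  expect_error(filter_features(pooled, 0.5, 0.2), "min_detect_frac")
})

test_that("pooling report summarizes purity, cell types and usage", {
  emb <- matrix(rnorm(20), 10, 2)
  cm <- toy_cells(emb)  # all the same type
  pooled <- pool_cells(cm, seeds = c(1, 5, 9), pool_size = 3)
  rep_ <- pooling_report(pooled, cm)
  expect_true(all(rep_$pools$purity == 1))
  q1 <- pooling_report(pool_cells(cm, seeds = c(1, 5), pool_size = 1), cm)
  expect_true(all(q1$pools$n_cell_types == 1))
  expect_true(all(rep_$cell_usage$n_pools >= 1))
})
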