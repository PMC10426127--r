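test_that("cross-validation plans partition the data correctly", {
  plan <- make_cv_plan(100, K = 10, seed = 3)
  tests <- lapply(plan$folds, `[[`, "outer_test")
  expect_true(all(lengths(tests) == 10))
  expect_identical(sort(unlist(tests)), 1:100)           # disjoint cover
  for (fold in plan$folds) {
    expect_length(fold$inner_train, 72)                  # 80% of the inner 90
    expect_length(fold$inner_val, 18)                    # 20% of the inner 90
    expect_length(intersect(fold$inner_train, fold$inner_val), 0)
    expect_length(intersect(fold$outer_test,
                            c(fold$inner_train, fold$inner_val)), 0)
  }
  expect_identical(make_cv_plan(100, K = 10, seed = 3), plan)
  expect_error(make_cv_plan(5, K = 10), "at least")
})

test_that("hyperparameter draws respect the priors", {
  priors <- hyper_priors()
  hp <- sample_hyperparams(priors, 2000, seed = 4)
  expect_true(all(hp$lr >= 5e-4 & hp$lr <= 5e-2))
  expect_true(all(hp$sigma_motifs >= 1e-7 & hp$sigma_motifs <= 1e-3))
  expect_true(all(hp$sigma_net >= 1e-5 & hp$sigma_net <= 1e-2))
  expect_true(all(hp$batch_size %in% c(64, 128, 256, 512)))
  # a log-uniform median is the geometric mean of the bounds
  expect_lt(abs(median(hp$lr) - sqrt(5e-4 * 5e-2)) / sqrt(5e-4 * 5e-2), 0.10)
  expect_error(hyper_priors(lr = c(0.1, 0.01)), "lr")
})

test_that("successive halving respects its budget and returns the best candidate", {
  sim <- small_sim()
  values <- sim$targets$values                  # analytic targets: clean signal
  cfg <- scover_config(d = 4, m = 12, p = ncol(values), L = sim$seqs$length)
  priors <- hyper_priors(num_calibrations = 5, epochs = 9)
  res <- hyperparameter_search(sim$seqs, values, idx_train = 1:220,
                               idx_val = 221:300, config = cfg,
                               priors = priors, seed = 8)
  expect_equal(nrow(res$results), 5)
  expect_equal(res$best_mse, min(res$results$mse, na.rm = TRUE))
  # budget: strictly fewer epoch-units than exhaustive full-length training
  expect_lt(res$epoch_units, 5 * 9)
  expect_gte(res$epoch_units, 5)                 # every candidate ran rung 1

  # a single candidate is returned unchanged
  one <- hyperparameter_search(sim$seqs, values, 1:220, 221:300, cfg,
                               hyper_priors(num_calibrations = 1, epochs = 3),
                               seed = 9)
  expect_equal(nrow(one$results), 1)
  expect_equal(one$best_hp$lr, one$results$lr[1])
})

test_that("training recovers a noiseless planted-model target", {
  # deterministic consensus motifs with zero target noise: the target
  # function (baseline + effect per planted word) is exactly representable
  # by word-detector filters plus the linear readout, so held-out R^2
  # should be high after training
  set.seed(20)
  words <- c("ACGTAAGGTTCC", "TTGACCAATGGC", "GAGAGCCTTACA")
  ppms <- setNames(lapply(words, one_hot_encode), paste0("w", 1:3))
  W <- matrix(c(2, .4, .3, .4, 1.6, .3, .3, .4, 1.2), 3, 3)
  cfg_sim <- sim_config(n_sequences = 500, L = 100, motif_ppms = ppms,
                        effect = W, n_pools = 10, n_celltypes = 3,
                        noise_sd = 0, seed = 21)
  sim <- suppressWarnings(simulate_sequences(cfg_sim))
  tgt <- simulate_pooled_targets(sim$truth, cfg_sim)
  values <- tgt$targets$values
  cfg <- scover_config(d = 20, m = 12, p = ncol(values), L = 100)
  set.seed(22)
  idx <- sample(500)
  ckpt <- train_scover(sim$seqs, values, idx_train = idx[1:400],
                       idx_val = idx[401:500], config = cfg,
                       hp = list(lr = 0.03, sigma_motifs = 1e-3,
                                 sigma_net = 1e-2, batch_size = 64),
                       epochs = 40, seed = 23)
  pred <- scover_forward(ckpt$params, sim$seqs, which_seqs = idx[401:500])$predictions
  obs <- values[idx[401:500], ]
  r2 <- mean(vapply(seq_len(ncol(obs)), function(j) cor(pred[, j], obs[, j])^2, 1))
  expect_gt(r2, 0.9)
})

test_that("early stopping has patience-1 semantics and training is reproducible", {
  sim <- small_sim()
  values <- sim$targets$values
  cfg <- scover_config(d = 5, m = 12, p = ncol(values), L = sim$seqs$length)
  hp <- list(lr = 0.02, sigma_motifs = 1e-4, sigma_net = 1e-3, batch_size = 64)
  ck1 <- train_scover(sim$seqs, values, 1:220, 221:300, cfg, hp,
                      epochs = 12, seed = 31)
  ck2 <- train_scover(sim$seqs, values, 1:220, 221:300, cfg, hp,
                      epochs = 12, seed = 31)
  expect_identical(ck1$params, ck2$params)
  expect_equal(ck1$best_val_mse, min(ck1$history))
  h <- ck1$history
  n <- length(h)
  if (n < 12 && n > 1) {
    # stopped early: the final epoch is the first non-improvement, so every
    # intermediate epoch must have improved on the best so far
    expect_gte(h[n], min(h[-n]))
    for (i in seq_len(n - 1)[-1]) expect_lt(h[i], min(h[seq_len(i - 1)]))
  }
})

test_that("evaluation reports explained variance and permutation controls", {
  # perfect predictions: targets generated by the model itself
  tm <- random_tiny_model(d = 3, m = 4, p = 3, L = 30, n = 40, seed = 41)
  targets <- scover_forward(tm$params, tm$seqs)$predictions +
    matrix(rnorm(40 * 3, 0, 1e-9), 40, 3)   # break exact ties for cor()
  ckpt <- structure(list(params = tm$params, idx_train = 1:30, idx_val = 31:40),
                    class = "scover_checkpoint")
  ev <- evaluate_checkpoint(ckpt, tm$seqs, targets, idx = 1:40)
  expect_equal(ev$r_squared[ev$metric == "intact"], 1, tolerance = 1e-6)
  ev2 <- evaluate_checkpoint(ckpt, tm$seqs, targets, idx = 1:40,
                             controls = TRUE, seed = 42)
  expect_setequal(ev2$metric, c("intact", "shuffled_sequences", "permuted_pools"))
})

test_that("the ensemble trainer never leaks outer-test data into training", {
  sim <- small_sim()
  ens <- scover_train(sim$targets, sim$seqs, d = 4, m = 12, K = 3,
                      priors = hyper_priors(num_calibrations = 2, epochs = 3),
                      controls = FALSE, seed = 51)
  expect_length(ens$checkpoints, 3)
  for (k in seq_along(ens$checkpoints)) {
    fold <- ens$plan$folds[[k]]
    ck <- ens$checkpoints[[k]]
    expect_length(intersect(ck$idx_train, fold$outer_test), 0)
    expect_length(intersect(ck$idx_val, fold$outer_test), 0)
  }
  td <- tidy(ens)
  expect_true(all(c("fold", "metric", "r_squared", "best_val_mse") %in% names(td)))
  expect_equal(nrow(glance(ens)), 1)
})
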