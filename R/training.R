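#' Build a nested cross-validation plan
#'
#' Randomly partitions sequences into K outer folds; each fold's outer test
#' set holds ~1/K of the data and the remaining "inner" set is split 80/20
#' into inner training and inner validation sets.
#'
#' @param n_seqs Number of sequences.
#' @param K Number of outer folds (default 10).
#' @param seed Optional RNG seed.
#' @return A `cv_plan`: list of K folds, each with `outer_test`,
#'   `inner_train`, `inner_val` integer index vectors.
#' @export
make_cv_plan <- function(n_seqs, K = 10, seed = NULL) {
  if (n_seqs < K) stop("need at least K sequences")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n_seqs)
  outer <- split(perm, cut(seq_len(n_seqs), K, labels = FALSE))
  folds <- lapply(seq_len(K), function(k) {
    test <- sort(outer[[k]])
    inner <- setdiff(perm, test)            # keep the permuted order
    n_train <- floor(0.8 * length(inner))
    list(outer_test = test,
         inner_train = sort(inner[seq_len(n_train)]),
         inner_val = sort(inner[(n_train + 1L):length(inner)]))
  })
  structure(list(folds = folds, K = K, n_seqs = n_seqs), class = "cv_plan")
}

#' Hyperparameter priors
#'
#' Search priors for the calibration stage: learning rate and the two
#' initialization scales are log-uniform over their intervals; batch size
#' is uniform over a discrete choice set.
#'
#' @param lr,sigma_motifs,sigma_net Length-2 intervals (low, high).
#' @param batch_size Discrete batch-size choices.
#' @param epochs Full training epoch budget (default 40).
#' @param num_calibrations Number of sampled configurations (default 100).
#' @return A `hyper_priors` list.
#' @export
hyper_priors <- function(lr = c(5e-4, 5e-2),
                         sigma_motifs = c(1e-7, 1e-3),
                         sigma_net = c(1e-5, 1e-2),
                         batch_size = c(64, 128, 256, 512),
                         epochs = 40,
                         num_calibrations = 100) {
  intervals <- list(lr = lr, sigma_motifs = sigma_motifs, sigma_net = sigma_net)
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    if (length(iv) != 2L || iv[1] <= 0 || iv[1] >= iv[2]) {
      stop("'", nm, "' must be an increasing positive interval (lo, hi)")
    }
  }
  structure(list(lr = lr, sigma_motifs = sigma_motifs, sigma_net = sigma_net,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 num_calibrations = as.integer(num_calibrations)),
            class = "hyper_priors")
}

#' Sample hyperparameter configurations from the priors
#'
#' Continuous values are drawn as `exp(Uniform(log lo, log hi))`; the batch
#' size uniformly from its choice set.
#'
#' @param priors A [hyper_priors()].
#' @param n Number of configurations (default 1).
#' @param seed Optional RNG seed.
#' @return A tibble with columns lr, sigma_motifs, sigma_net, batch_size.
#' @export
sample_hyperparams <- function(priors, n = 1, seed = NULL) {
  stopifnot(inherits(priors, "hyper_priors"))
  if (!is.null(seed)) set.seed(seed)
  log_unif <- function(iv) exp(runif(n, log(iv[1]), log(iv[2])))
  tibble::tibble(
    lr = log_unif(priors$lr),
    sigma_motifs = log_unif(priors$sigma_motifs),
    sigma_net = log_unif(priors$sigma_net),
    batch_size = sample(priors$batch_size, n, replace = TRUE)
  )
}

# One Adam-optimized training run over the inner split. Continues from
# `state` when given (used by the successive-halving rungs). Validation MSE
# is checked after every epoch; with patience = 1 training stops at the
# first epoch that fails to improve on the best so far, and the best-epoch
# parameters are kept.
adam_train <- function(windows, targets, idx_train, idx_val, config, hp,
                       epochs, seed = NULL, patience = 1, state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$p
  if (is.null(state)) {
    params <- init_scover_params(config, hp$sigma_motifs, hp$sigma_net)
    Wf <- flatten_conv(params$conv)
    Fw <- params$fc_weights
    bb <- params$fc_bias
    opt <- list(mW = Wf * 0, vW = Wf * 0, mF = Fw * 0, vF = Fw * 0,
                mb = bb * 0, vb = bb * 0, step = 0L)
  } else {
    Wf <- state$Wf; Fw <- state$Fw; bb <- state$bb; opt <- state$opt
  }
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  lr <- hp$lr; B <- hp$batch_size
  d <- config$d

  val_mse <- function(Wf, Fw, bb) {
    cm <- conv_maxpool(windows, Wf, idx_val)
    a <- elu(cm$smax)
    pred <- a %*% Fw + matrix(bb, length(idx_val), p, byrow = TRUE)
    mean((pred - targets[idx_val, , drop = FALSE])^2)
  }

  best <- state$best %||% list(mse = Inf, Wf = Wf, Fw = Fw, bb = bb)
  stale <- 0L
  history <- state$history %||% numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample(idx_train)
    for (bs in split(ord, ceiling(seq_along(ord) / B))) {
      nb <- length(bs)
      cm <- conv_maxpool(windows, Wf, bs)
      a <- elu(cm$smax)
      pred <- a %*% Fw + matrix(bb, nb, p, byrow = TRUE)
      resid <- pred - targets[bs, , drop = FALSE]
      if (anyNA(resid) || any(!is.finite(resid))) {
        stop("training diverged: non-finite loss (lr = ", signif(lr, 3), ")")
      }
      dy <- 2 * resid / (nb * p)
      gF <- crossprod(a, dy)
      gb <- colSums(dy)
      gs <- (dy %*% t(Fw)) * elu_grad(cm$smax)
      gW <- matrix(0, d, ncol(Wf))
      for (i in seq_len(d)) {
        rws <- cm$row_offset + cm$argmax[, i]
        gW[i, ] <- crossprod(windows[rws, , drop = FALSE], gs[, i])
      }
      opt$step <- opt$step + 1L
      opt$mW <- b1 * opt$mW + (1 - b1) * gW; opt$vW <- b2 * opt$vW + (1 - b2) * gW^2
      opt$mF <- b1 * opt$mF + (1 - b1) * gF; opt$vF <- b2 * opt$vF + (1 - b2) * gF^2
      opt$mb <- b1 * opt$mb + (1 - b1) * gb; opt$vb <- b2 * opt$vb + (1 - b2) * gb^2
      c1 <- 1 - b1^opt$step; c2 <- 1 - b2^opt$step
      Wf <- Wf - lr * (opt$mW / c1) / (sqrt(opt$vW / c2) + eps_adam)
      Fw <- Fw - lr * (opt$mF / c1) / (sqrt(opt$vF / c2) + eps_adam)
      bb <- bb - lr * (opt$mb / c1) / (sqrt(opt$vb / c2) + eps_adam)
    }
    vm <- val_mse(Wf, Fw, bb)
    history <- c(history, vm)
    if (vm < best$mse) {
      best <- list(mse = vm, Wf = Wf, Fw = Fw, bb = bb)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (!is.na(patience) && stale >= patience) break
    }
  }
  list(best = best, history = history,
       state = list(Wf = Wf, Fw = Fw, bb = bb, opt = opt,
                    best = best, history = history))
}

#' Train one model on a fold
#'
#' Minimizes the MSE between predicted and pooled observed values with the
#' Adam optimizer (moments 0.9/0.999, eps 1e-8), evaluating the inner
#' validation MSE after each epoch. Training stops early with patience 1
#' (the first epoch without improvement over the best so far) and the
#' parameters from the best epoch are returned.
#'
#' @param seqs A [sequence_set()] or precomputed window matrix.
#' @param targets Numeric matrix (sequences x pools), rows aligned with
#'   `seqs`.
#' @param idx_train,idx_val Inner-train / inner-validation indices.
#' @param config A [scover_config()].
#' @param hp One hyperparameter configuration (a row of
#'   [sample_hyperparams()], or any list with lr, sigma_motifs, sigma_net,
#'   batch_size).
#' @param epochs Maximum epochs (default 40).
#' @param seed Optional RNG seed (initialization + batch order).
#' @return A `scover_checkpoint`: `params`, `best_val_mse`, `history`,
#'   `hp`, `idx_train`, `idx_val`, `epochs_run`.
#' @export
train_scover <- function(seqs, targets, idx_train, idx_val, config, hp,
                         epochs = 40, seed = NULL) {
  windows <- as_window_matrix(seqs, config$m)
  hp <- as.list(hp)
  fit <- adam_train(windows, targets, idx_train, idx_val, config, hp,
                    epochs, seed = seed)
  params <- structure(
    list(conv = unflatten_conv(fit$best$Wf, config$m),
         fc_weights = fit$best$Fw, fc_bias = fit$best$bb, config = config),
    class = "scover_params"
  )
  structure(
    list(params = params, best_val_mse = fit$best$mse,
         history = fit$history, hp = hp[c("lr", "sigma_motifs", "sigma_net", "batch_size")],
         idx_train = idx_train, idx_val = idx_val,
         epochs_run = length(fit$history)),
    class = "scover_checkpoint"
  )
}

#' @export
print.scover_checkpoint <- function(x, ...) {
  cat("<scover_checkpoint> d = ", x$params$config$d, ", m = ", x$params$config$m,
      "; best validation MSE ", signif(x$best_val_mse, 4),
      " after ", x$epochs_run, " epoch(s)\n", sep = "")
  invisible(x)
}

#' Successive-halving hyperparameter search
#'
#' Samples `num_calibrations` configurations from the priors and runs
#' synchronous successive halving (eta = 3): all candidates train for a
#' small epoch budget, the top third continue (from their optimizer state)
#' at triple the budget, and so on for `n_rungs` rungs up to the full epoch
#' count. Returns the configuration with the lowest inner-validation MSE
#' observed anywhere in the schedule.
#'
#' @param seqs Sequences (or window matrix).
#' @param targets Sequences x pools target matrix.
#' @param idx_train,idx_val Inner split indices.
#' @param config A [scover_config()].
#' @param priors A [hyper_priors()].
#' @param eta Promotion factor (default 3).
#' @param n_rungs Number of rungs (default 3).
#' @param seed Optional RNG seed.
#' @return List: `best_hp` (one-row tibble), `best_mse`, `results` (tibble
#'   of all candidates with their last rung and MSE), `epoch_units` spent.
#' @export
hyperparameter_search <- function(seqs, targets, idx_train, idx_val, config,
                                  priors = hyper_priors(), eta = 3, n_rungs = 3,
                                  seed = NULL) {
  stopifnot(inherits(priors, "hyper_priors"), priors$num_calibrations >= 1)
  if (!is.null(seed)) set.seed(seed)
  windows <- as_window_matrix(seqs, config$m)
  cands <- sample_hyperparams(priors, priors$num_calibrations)
  # rung epoch budgets: full/eta^(n_rungs-1), ..., full
  budgets <- pmax(1L, as.integer(round(priors$epochs / eta^((n_rungs - 1):0))))
  budgets <- cummax(budgets)
  seeds <- sample.int(.Machine$integer.max, nrow(cands))

  alive <- seq_len(nrow(cands))
  states <- vector("list", nrow(cands))
  mse <- rep(NA_real_, nrow(cands))
  rung_of <- rep(0L, nrow(cands))
  epoch_units <- 0L
  done <- rep(0L, nrow(cands))          # epochs already trained per candidate
  for (r in seq_along(budgets)) {
    for (ci in alive) {
      extra <- budgets[r] - done[ci]
      if (extra <= 0) next
      if (is.null(states[[ci]])) set.seed(seeds[ci])
      fit <- adam_train(windows, targets, idx_train, idx_val, config,
                        as.list(cands[ci, ]), epochs = extra,
                        patience = NA, state = states[[ci]])
      states[[ci]] <- fit$state
      mse[ci] <- fit$best$mse
      done[ci] <- done[ci] + extra
      rung_of[ci] <- r
      epoch_units <- epoch_units + extra
    }
    if (r < length(budgets)) {
      n_keep <- max(1L, ceiling(length(alive) / eta))
      alive <- alive[order(mse[alive])][seq_len(n_keep)]
    }
  }
  best_i <- which.min(mse)
  list(best_hp = cands[best_i, ], best_mse = mse[best_i],
       results = dplyr::mutate(cands, mse = mse, rung = rung_of,
                               seed = seeds, candidate = dplyr::row_number()),
       epoch_units = epoch_units)
}

#' Evaluate a checkpoint on held-out sequences
#'
#' Reports the explained variance (squared Pearson correlation between
#' predicted and observed values per pool, averaged over pools) for the
#' intact data and, optionally, two negative controls: per-sequence
#' nucleotide shuffling (destroys motifs, keeps composition) and pool-order
#' permutation of the targets (destroys cell-type specificity).
#'
#' @param checkpoint A `scover_checkpoint`.
#' @param seqs A [sequence_set()] aligned with `targets` rows.
#' @param targets Sequences x pools matrix.
#' @param idx Indices of the held-out set (e.g., the fold's outer test).
#' @param controls Compute permutation controls? Default FALSE.
#' @param seed RNG seed for the permutations.
#' @return A tibble with columns `metric` ("intact", and with controls
#'   "shuffled_sequences", "permuted_pools") and `r_squared`.
#' @export
evaluate_checkpoint <- function(checkpoint, seqs, targets, idx,
                                controls = FALSE, seed = NULL) {
  stopifnot(inherits(checkpoint, "scover_checkpoint"))
  if (!is.null(seed)) set.seed(seed)
  params <- checkpoint$params
  obs <- targets[idx, , drop = FALSE]
  r2 <- function(pred, obs) {
    vals <- vapply(seq_len(ncol(obs)), function(j) {
      if (sd(pred[, j]) == 0 || sd(obs[, j]) == 0) return(0)
      cor(pred[, j], obs[, j])^2
    }, 1)
    mean(vals)
  }
  fwd <- scover_forward(params, seqs, which_seqs = idx)
  out <- tibble::tibble(metric = "intact", r_squared = r2(fwd$predictions, obs))
  if (controls) {
    shuf <- vapply(seqs$sequences[idx], function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, "")
    shuf_set <- sequence_set(unname(shuf), ids = seqs$ids[idx], drop_n = FALSE)
    fwd_shuf <- scover_forward(params, shuf_set)
    perm <- sample.int(ncol(obs))
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(metric = "shuffled_sequences",
                     r_squared = r2(fwd_shuf$predictions, obs)),
      tibble::tibble(metric = "permuted_pools",
                     r_squared = r2(fwd$predictions, obs[, perm, drop = FALSE]))
    )
  }
  out
}

#' Train the full cross-validated ensemble
#'
#' The top-level trainer: aligns pooled values with the sequence set,
#' builds the K-fold nested cross-validation plan, runs the
#' successive-halving hyperparameter search per fold on the inner split,
#' trains the final model for each fold with early stopping, and evaluates
#' each fold's outer test set (with permutation controls).
#'
#' @param pooled A `pooled_dataset` (or a plain features x pools matrix
#'   with rownames).
#' @param seqs A [sequence_set()]; ids are matched against pooled feature
#'   rownames, and only shared ids are used.
#' @param d,m Filter count / width (defaults 600 / 12).
#' @param K Number of outer folds = ensemble size r (default 10).
#' @param priors A [hyper_priors()]; set `num_calibrations` and `epochs`
#'   there to control the search budget.
#' @param controls Evaluate permutation controls per fold? Default TRUE.
#' @param seed RNG seed for plan, search and training.
#' @return A `scover_ensemble`: list of checkpoints, per-fold metrics
#'   tibble, the cv plan, and the aligned sequence ids.
#' @export
scover_train <- function(pooled, seqs, d = 600, m = 12, K = 10,
                         priors = hyper_priors(), controls = TRUE, seed = 1) {
  values <- if (inherits(pooled, "pooled_dataset")) pooled$values else pooled
  shared <- intersect(rownames(values), seqs$ids)
  if (length(shared) < K) stop("too few sequences shared between pooled data and sequence set")
  sub <- match(shared, seqs$ids)
  seqs_used <- sequence_set(unname(seqs$sequences[shared]), ids = shared, drop_n = FALSE)
  targets <- values[shared, , drop = FALSE]
  p <- ncol(targets)
  config <- scover_config(d = d, m = m, p = p, L = seqs_used$length)
  windows <- build_window_matrix(seqs_used$onehot, config$m)

  set.seed(seed)
  plan <- make_cv_plan(length(shared), K)
  checkpoints <- vector("list", K)
  metrics <- vector("list", K)
  for (k in seq_len(K)) {
    fold <- plan$folds[[k]]
    search <- hyperparameter_search(windows, targets, fold$inner_train,
                                    fold$inner_val, config, priors,
                                    seed = seed * 1000L + k)
    ckpt <- train_scover(windows, targets, fold$inner_train, fold$inner_val,
                         config, search$best_hp, epochs = priors$epochs,
                         seed = seed * 1000L + 500L + k)
    ckpt$fold <- k
    ckpt$search_mse <- search$best_mse
    checkpoints[[k]] <- ckpt
    ev <- evaluate_checkpoint(ckpt, seqs_used, targets, fold$outer_test,
                              controls = controls, seed = seed * 1000L + k)
    metrics[[k]] <- dplyr::mutate(ev, fold = k, .before = 1)
  }
  structure(
    list(checkpoints = checkpoints,
         metrics = dplyr::bind_rows(metrics),
         plan = plan, ids = shared, config = config,
         pool_names = colnames(targets), seed = seed),
    class = "scover_ensemble"
  )
}

#' @export
print.scover_ensemble <- function(x, ...) {
  r2 <- x$metrics$r_squared[x$metrics$metric == "intact"]
  cat("<scover_ensemble> ", length(x$checkpoints), " fold model(s), d = ",
      x$config$d, ", m = ", x$config$m, "; mean outer-test R^2 ",
      round(mean(r2), 3), "\n", sep = "")
  invisible(x)
}
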