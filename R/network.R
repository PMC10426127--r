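#' Exponential linear unit
#'
#' `elu(x) = x` for `x >= 0` and `exp(x) - 1` otherwise (alpha = 1), so
#' pooled activations are bounded below by -1.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
elu <- function(x) ifelse(x >= 0, x, exp(x) - 1)

# derivative of ELU at the pre-activation value
elu_grad <- function(x) ifelse(x >= 0, 1, exp(x))

#' Model configuration
#'
#' @param d Number of convolutional filters (default 600).
#' @param m Filter width in nt (default 12).
#' @param p Number of output pools.
#' @param L Input sequence length.
#' @return A `scover_config` list.
#' @export
scover_config <- function(d = 600, m = 12, p, L) {
  stopifnot(d >= 1, p >= 1, m >= 1, m <= L)
  structure(list(d = as.integer(d), m = as.integer(m),
                 p = as.integer(p), L = as.integer(L)),
            class = "scover_config")
}

#' Initialize model parameters
#'
#' Convolutional filter weights are drawn from N(0, sigma_motifs^2) and
#' linear-readout weights from N(0, sigma_net^2); readout biases start at
#' 1e-5. The convolution carries no bias term.
#'
#' @param config A [scover_config()].
#' @param sigma_motifs,sigma_net Initialization standard deviations.
#' @param seed Optional RNG seed for reproducible initialization.
#' @return A `scover_params` list with `conv` (m x 4 x d array; rows are
#'   filter positions, columns the A,C,G,T channels), `fc_weights` (d x p),
#'   `fc_bias` (length p), and the config.
#' @export
init_scover_params <- function(config, sigma_motifs = 1e-4, sigma_net = 1e-3,
                               seed = NULL) {
  stopifnot(inherits(config, "scover_config"), sigma_motifs > 0, sigma_net > 0)
  if (!is.null(seed)) set.seed(seed)
  conv <- array(rnorm(config$m * 4L * config$d, 0, sigma_motifs),
                dim = c(config$m, 4L, config$d),
                dimnames = list(NULL, NUCLEOTIDES, NULL))
  fc_weights <- matrix(rnorm(config$d * config$p, 0, sigma_net),
                       config$d, config$p)
  structure(
    list(conv = conv, fc_weights = fc_weights,
         fc_bias = rep(1e-5, config$p), config = config),
    class = "scover_params"
  )
}

# flatten the conv tensor to a d x 4m matrix whose column order matches the
# window matrix (position-major, A,C,G,T within each position)
flatten_conv <- function(conv) {
  d <- dim(conv)[3]
  t(matrix(aperm(conv, c(2, 1, 3)), ncol = d))
}

unflatten_conv <- function(flat, m) {
  d <- nrow(flat)
  aperm(array(t(flat), dim = c(4L, m, d)), c(2, 1, 3))
}

# Precompute the window-design matrix: one row per (position, sequence)
# pair (position fastest), one column block of 4 per filter offset. The
# convolution then becomes a single matrix product.
build_window_matrix <- function(onehot, m) {
  stopifnot(length(dim(onehot)) == 3L, dim(onehot)[1] == 4L)
  L <- dim(onehot)[2]; n <- dim(onehot)[3]
  if (m > L) stop("filter width exceeds sequence length")
  P <- L - m + 1L
  W <- matrix(0, P * n, 4L * m)
  for (k in seq_len(m)) {
    blk <- onehot[, k:(k + P - 1L), , drop = FALSE]       # 4 x P x n
    W[, (4L * (k - 1L) + 1L):(4L * k)] <- matrix(aperm(blk, c(2, 3, 1)), P * n, 4L)
  }
  structure(W, P = P, n = n, m = m)
}

# Convolve + max-pool for a subset of sequences given the precomputed
# window matrix. Ties in the argmax break toward the lowest position
# (strict > comparison while scanning upward).
conv_maxpool <- function(windows, conv_flat, which_seqs) {
  P <- attr(windows, "P")
  nb <- length(which_seqs)
  rows <- as.vector(outer(seq_len(P), (which_seqs - 1L) * P, "+"))
  S <- windows[rows, , drop = FALSE] %*% t(conv_flat)     # (P*nb) x d
  d <- ncol(S)
  M <- matrix(S, P, nb * d)
  mx <- M[1L, ]
  am <- rep(1L, nb * d)
  if (P > 1L) {
    for (q in 2:P) {
      u <- M[q, ] > mx
      mx[u] <- M[q, u]
      am[u] <- q
    }
  }
  list(smax = matrix(mx, nb, d), argmax = matrix(am, nb, d),
       row_offset = (which_seqs - 1L) * P)
}

#' Forward pass of the model
#'
#' Computes, for each sequence, the per-filter pooled activation
#' `a = max over positions of ELU(filter . window)` (valid convolution,
#' stride 1, forward strand, no padding) and the linear readout
#' `y = a fc_weights + fc_bias`.
#'
#' @param params A `scover_params` object.
#' @param seqs A [sequence_set()], a 4 x L x n one-hot array, or a
#'   precomputed window matrix from the internal builder.
#' @param which_seqs Optional subset of sequence indices.
#' @return List with `predictions` (n x p), `activations` (n x d, post-ELU)
#'   and `argmax` (n x d best window start positions).
#' @export
scover_forward <- function(params, seqs, which_seqs = NULL) {
  stopifnot(inherits(params, "scover_params"))
  windows <- as_window_matrix(seqs, params$config$m)
  n <- attr(windows, "n")
  if (is.null(which_seqs)) which_seqs <- seq_len(n)
  cm <- conv_maxpool(windows, flatten_conv(params$conv), which_seqs)
  a <- elu(cm$smax)
  pred <- a %*% params$fc_weights +
    matrix(params$fc_bias, nrow(a), params$config$p, byrow = TRUE)
  list(predictions = pred, activations = a, argmax = cm$argmax)
}

as_window_matrix <- function(seqs, m) {
  if (is.matrix(seqs) && !is.null(attr(seqs, "P"))) {
    if (attr(seqs, "m") != m) stop("window matrix was built for a different filter width")
    return(seqs)
  }
  onehot <- if (inherits(seqs, "sequence_set")) seqs$onehot else seqs
  build_window_matrix(onehot, m)
}

#' Mean squared error
#'
#' @param pred,target Equal-shaped numeric arrays.
#' @return Mean of squared elementwise differences.
#' @export
mse_loss <- function(pred, target) {
  if (!all(dim(as.matrix(pred)) == dim(as.matrix(target)))) {
    stop("prediction and target shapes differ")
  }
  mean((pred - target)^2)
}

#' Write a model checkpoint
#'
#' Serializes parameters, config, and training metadata to JSON at full
#' precision. Documented keys: `conv` (d x m x 4 nested arrays),
#' `fc_weights`, `fc_bias`, `config`, `meta` (fold split, best validation
#' MSE, hyperparameters, epochs run).
#'
#' @param checkpoint A `scover_checkpoint` (from [train_scover()]).
#' @param path Output JSON path.
#' @export
write_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "scover_checkpoint"))
  params <- checkpoint$params
  payload <- list(
    format = "scregmotif_checkpoint_v1",
    config = unclass(params$config),
    conv = lapply(seq_len(params$config$d), function(i) params$conv[, , i]),
    fc_weights = params$fc_weights,
    fc_bias = params$fc_bias,
    meta = checkpoint[setdiff(names(checkpoint), "params")]
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path JSON path written by [write_checkpoint()].
#' @return A `scover_checkpoint`.
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(scover_config, payload$config[c("d", "m", "p", "L")])
  conv <- array(0, dim = c(cfg$m, 4L, cfg$d),
                dimnames = list(NULL, NUCLEOTIDES, NULL))
  for (i in seq_len(cfg$d)) conv[, , i] <- payload$conv[i, , ]
  params <- structure(
    list(conv = conv, fc_weights = matrix(payload$fc_weights, cfg$d, cfg$p),
         fc_bias = as.numeric(payload$fc_bias), config = cfg),
    class = "scover_params"
  )
  ckpt <- c(list(params = params), payload$meta)
  class(ckpt) <- "scover_checkpoint"
  ckpt
}
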