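# The sleep-staging network: a 5-block residual CNN feature extractor over
# 76 x 60 x 3 spectrogram images (3x3 "same" convolutions with exact GELU,
# 2x2/2 max pooling, batch normalization, dropout; skip additions around
# blocks 2 and 4; a 3x3/1 average pool in block 5; global average pooling
# to a 64-d feature), a stacked bidirectional LSTM over 10-epoch sequences,
# a main softmax head on the concatenated directions, and an auxiliary
# softmax head on the per-epoch features used only during training.

#' Model configuration
#'
#' @param conv_channels five output-channel counts, one per convolutional
#'   block. Channels of blocks 1/2 and 3/4 must match so the skip additions
#'   need no projection; the last entry must equal `feature_dim`.
#' @param convs_per_block convolutions per block (default 1).
#' @param dropout_keep keep-probability of the per-block dropout (training
#'   only).
#' @param lstm_layers number of bidirectional LSTM layers: 2 is the default
#'   model; 0, 1 and 3 give the ablation variants (0 = per-epoch softmax
#'   directly on the 64-d feature, no sequence context).
#' @param lstm_hidden hidden units per direction.
#' @param seq_len epochs per training/scoring sequence.
#' @param n_classes number of stages (5).
#' @param aux_weight weight of the auxiliary-classifier loss term.
#' @param feature_dim length of the per-epoch feature vector.
#' @param input_shape image tensor shape (height, width, channels).
#' @return A `somnet_config` list.
#' @export
model_config <- function(conv_channels = c(16, 16, 32, 32, 64),
                         convs_per_block = 1,
                         dropout_keep = 0.5,
                         lstm_layers = 2,
                         lstm_hidden = 128,
                         seq_len = 10,
                         n_classes = 5,
                         aux_weight = 0.5,
                         feature_dim = 64,
                         input_shape = c(76, 60, 3)) {
  stopifnot(length(conv_channels) == 5, all(conv_channels > 0),
            convs_per_block >= 1, dropout_keep > 0, dropout_keep <= 1,
            lstm_hidden > 0, seq_len >= 1, n_classes >= 2)
  if (conv_channels[1] != conv_channels[2] ||
      conv_channels[3] != conv_channels[4]) {
    abort(paste("conv_channels[1] must equal conv_channels[2] and",
                "conv_channels[3] must equal conv_channels[4]:",
                "the residual additions require matching shapes."),
          class = "somnet_config_error")
  }
  if (conv_channels[5] != feature_dim) {
    abort("conv_channels[5] must equal feature_dim (the GAP output size).",
          class = "somnet_config_error")
  }
  if (!lstm_layers %in% 0:3) {
    abort("lstm_layers must be 0, 1, 2 or 3.", class = "somnet_config_error")
  }
  structure(
    list(conv_channels = as.integer(conv_channels),
         convs_per_block = as.integer(convs_per_block),
         dropout_keep = dropout_keep,
         lstm_layers = as.integer(lstm_layers),
         lstm_hidden = as.integer(lstm_hidden),
         seq_len = as.integer(seq_len),
         n_classes = as.integer(n_classes),
         aux_weight = aux_weight,
         feature_dim = as.integer(feature_dim),
         input_shape = as.integer(input_shape)),
    class = "somnet_config"
  )
}

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dims)
}

orthogonal <- function(n) {
  q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  q * sign(diag(q))[col(q)]  # fix sign ambiguity for determinism across BLAS
}

#' Initialize a model
#'
#' Glorot-uniform initialization for convolutional and dense weights,
#' per-gate orthogonal initialization for recurrent kernels, zero biases,
#' unit/zero batch-norm scale/shift.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed making the initialization reproducible.
#' @return A `somnet_model`: list with `cfg`, `params` (trainable arrays)
#'   and `state` (batch-norm running moments).
#' @export
init_model <- function(cfg = model_config(), seed = 42) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  state <- list()
  cin <- cfg$input_shape[3]
  for (b in seq_len(5)) {
    cout <- cfg$conv_channels[b]
    ci <- cin
    for (j in seq_len(cfg$convs_per_block)) {
      params[[sprintf("conv%d_%d_w", b, j)]] <-
        glorot(c(3, 3, ci, cout), 9 * ci, 9 * cout)
      params[[sprintf("conv%d_%d_b", b, j)]] <- numeric(cout)
      ci <- cout
    }
    params[[sprintf("bn%d_gamma", b)]] <- rep(1, cout)
    params[[sprintf("bn%d_beta", b)]] <- numeric(cout)
    state[[sprintf("bn%d_mean", b)]] <- numeric(cout)
    state[[sprintf("bn%d_var", b)]] <- rep(1, cout)
    cin <- cout
  }
  h <- cfg$lstm_hidden
  input_dim <- cfg$feature_dim
  for (l in seq_len(cfg$lstm_layers)) {
    for (d in c("f", "b")) {
      params[[sprintf("lstm%d_%s_W", l, d)]] <-
        glorot(c(4 * h, input_dim), input_dim, h)
      params[[sprintf("lstm%d_%s_U", l, d)]] <-
        do.call(rbind, replicate(4, orthogonal(h), simplify = FALSE))
      params[[sprintf("lstm%d_%s_b", l, d)]] <- numeric(4 * h)
    }
    input_dim <- 2 * h
  }
  main_in <- if (cfg$lstm_layers > 0) 2 * h else cfg$feature_dim
  params$head_main_w <- glorot(c(cfg$n_classes, main_in), main_in, cfg$n_classes)
  params$head_main_b <- numeric(cfg$n_classes)
  params$head_aux_w <- glorot(c(cfg$n_classes, cfg$feature_dim),
                              cfg$feature_dim, cfg$n_classes)
  params$head_aux_b <- numeric(cfg$n_classes)
  structure(list(cfg = cfg, params = params, state = state),
            class = "somnet_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Count trainable parameters
#'
#' Sums every trainable scalar: convolution kernels and biases, batch-norm
#' scale/shift, all LSTM gate weights in both directions and layers, and
#' both classifier heads. Batch-norm running moments are state, not
#' parameters.
#'
#' @param model a `somnet_model` or a [model_config()].
#' @return Integer parameter count.
#' @export
#' @examples
#' count_parameters(model_config())
count_parameters <- function(model) {
  if (inherits(model, "somnet_config")) model <- init_model(model, seed = 1)
  sum(vapply(model$params, length, numeric(1)))
}

#' @export
print.somnet_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<somnet_model> %d conv blocks (%s), %d Bi-LSTM layer(s) x %d,",
                     " seq_len %d, %d classes\n  trainable parameters: %s (%.1f M)\n"),
              5, paste(cfg$conv_channels, collapse = "-"), cfg$lstm_layers,
              cfg$lstm_hidden, cfg$seq_len, cfg$n_classes,
              format(count_parameters(x), big.mark = ","),
              round(count_parameters(x) / 1e6, 1)))
  invisible(x)
}

# --- CNN forward/backward -------------------------------------------------

# mode: "train" (dropout on, batch statistics, running-moment update),
# "calibrate" (dropout off, batch statistics, running-moment update; used
# to re-estimate batch-norm moments under the evaluation distribution) or
# "eval" (deterministic: running moments, no dropout).
cnn_forward <- function(model, x, training = FALSE,
                        mode = if (isTRUE(training)) "train" else "eval",
                        bn_momentum = 0.1) {
  cfg <- model$cfg
  p <- model$params
  st <- model$state
  use_batch_stats <- mode %in% c("train", "calibrate")
  dropout_on <- mode == "train"
  caches <- vector("list", 5)
  h <- x
  for (b in seq_len(5)) {
    block_in <- h
    convs <- vector("list", cfg$convs_per_block)
    for (j in seq_len(cfg$convs_per_block)) {
      cv <- conv_gelu_forward(h, p[[sprintf("conv%d_%d_w", b, j)]],
                              p[[sprintf("conv%d_%d_b", b, j)]])
      convs[[j]] <- list(x = h, pre = cv$pre, Phi = cv$Phi, M = cv$im2col)
      h <- cv$act
    }
    if (b %in% c(2, 4)) h <- h + block_in      # residual skip, shapes match
    mp <- maxpool2_forward(h)
    pooled_dim <- dim(h)
    h <- mp$y
    ap_in_dim <- NULL
    if (b == 5) {
      ap_in_dim <- dim(h)
      h <- avgpool3_forward(h)
    }
    bn <- bn_forward(h, p[[sprintf("bn%d_gamma", b)]],
                     p[[sprintf("bn%d_beta", b)]],
                     st[[sprintf("bn%d_mean", b)]],
                     st[[sprintf("bn%d_var", b)]], use_batch_stats,
                     momentum = bn_momentum)
    st[[sprintf("bn%d_mean", b)]] <- bn$run_mean
    st[[sprintf("bn%d_var", b)]] <- bn$run_var
    dr <- dropout_forward(bn$y, cfg$dropout_keep, dropout_on)
    caches[[b]] <- list(convs = convs, mp_idx = mp$idx, pre_pool_dim = pooled_dim,
                        ap_in_dim = ap_in_dim, bn = bn$cache, mask = dr$mask,
                        residual = b %in% c(2, 4))
    h <- dr$y
  }
  feat <- gap_forward(h)
  list(features = feat, caches = caches, final_dim = dim(h), state = st)
}

cnn_backward <- function(model, dfeat, fwd) {
  cfg <- model$cfg
  p <- model$params
  grads <- list()
  dh <- gap_backward(dfeat, fwd$final_dim)
  for (b in rev(seq_len(5))) {
    cc <- fwd$caches[[b]]
    dh <- dropout_backward(dh, cc$mask)
    bnb <- bn_backward(dh, p[[sprintf("bn%d_gamma", b)]], cc$bn)
    grads[[sprintf("bn%d_gamma", b)]] <- bnb$dgamma
    grads[[sprintf("bn%d_beta", b)]] <- bnb$dbeta
    dh <- bnb$dx
    if (b == 5) dh <- avgpool3_backward(dh)
    dh <- maxpool2_backward(cc$mp_idx, dh, as.integer(cc$pre_pool_dim))
    dres <- if (cc$residual) dh else NULL
    for (j in rev(seq_len(cfg$convs_per_block))) {
      cv <- cc$convs[[j]]
      g <- conv_gelu_backward(cv$x, p[[sprintf("conv%d_%d_w", b, j)]],
                              cv$pre, cv$Phi, cv$M, dh)
      grads[[sprintf("conv%d_%d_w", b, j)]] <- g$dw
      grads[[sprintf("conv%d_%d_b", b, j)]] <- g$db
      dh <- g$dx
    }
    if (!is.null(dres)) dh <- dh + dres        # gradient through the skip
  }
  list(dx = dh, grads = grads)
}

#' Re-estimate batch-normalization moments for evaluation
#'
#' During training the per-block dropout reshapes the activation
#' distribution that the batch-norm running moments are collected under;
#' with a keep-probability of 0.5 in every block the compounded variance
#' shift makes those moments unusable once dropout is switched off. This
#' function refreshes them under the evaluation distribution: it forwards
#' batches of (training) images with dropout disabled and batch statistics
#' active, replacing the running moments by the running average of the
#' clean batch moments. [train_fold()] calls it before every test-set
#' evaluation; call it yourself after any hand-rolled training loop.
#'
#' @param model a `somnet_model`.
#' @param images image batch to calibrate on (use training images).
#' @param batch_size images per calibration batch.
#' @param max_batches upper bound on calibration batches (evenly spaced
#'   through `images`).
#' @return The model with refreshed running moments.
#' @export
calibrate_bn <- function(model, images, batch_size = 50, max_batches = 12) {
  n <- dim(images)[4]
  starts <- seq(1, n, by = batch_size)
  if (length(starts) > max_batches) {
    starts <- starts[unique(round(seq(1, length(starts),
                                      length.out = max_batches)))]
  }
  for (b in seq_len(5)) {
    model$state[[sprintf("bn%d_mean", b)]][] <- 0
    model$state[[sprintf("bn%d_var", b)]][] <- 1
  }
  for (i in seq_along(starts)) {
    x <- images[, , , starts[i]:min(starts[i] + batch_size - 1, n),
                drop = FALSE]
    fwd <- cnn_forward(model, x, mode = "calibrate", bn_momentum = 1 / i)
    model$state <- fwd$state
  }
  model
}

# --- full model forward/backward -----------------------------------------

# x: (76, 60, 3, N) with N = n_seq * seq_len, sequence-major
# (column (s-1)*seq_len + t is epoch t of sequence s)
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  n <- dim(x)[4]
  if (n %% cfg$seq_len != 0) {
    abort(sprintf("Batch of %d images is not a multiple of seq_len = %d.",
                  n, cfg$seq_len), class = "somnet_shape_error")
  }
  s <- n %/% cfg$seq_len
  cnn <- cnn_forward(model, x, training)
  feat <- cnn$features                        # (feature_dim x N)
  if (cfg$lstm_layers > 0) {
    xs <- lapply(seq_len(cfg$seq_len), function(t) {
      feat[, (seq_len(s) - 1) * cfg$seq_len + t, drop = FALSE]
    })
    lst <- bilstm_forward(xs, model$params, cfg$lstm_layers)
    zcols <- matrix(0, cfg$n_classes, n)
    for (t in seq_len(cfg$seq_len)) {
      zcols[, (seq_len(s) - 1) * cfg$seq_len + t] <-
        dense_forward(model$params$head_main_w, model$params$head_main_b,
                      lst$out[[t]])
    }
  } else {
    lst <- NULL
    zcols <- dense_forward(model$params$head_main_w, model$params$head_main_b,
                           feat)
  }
  main_probs <- softmax_cols(zcols)
  aux_z <- dense_forward(model$params$head_aux_w, model$params$head_aux_b, feat)
  aux_probs <- softmax_cols(aux_z)
  list(main_probs = main_probs, aux_probs = aux_probs, features = feat,
       cnn = cnn, lstm = lst, n_seq = s, state = cnn$state)
}

# y: one-hot (n_classes x N). Returns grads for every parameter.
model_backward <- function(model, fwd, y) {
  cfg <- model$cfg
  n <- ncol(y)
  s <- fwd$n_seq
  dz_main <- (fwd$main_probs - y) / n
  dz_aux <- cfg$aux_weight * (fwd$aux_probs - y) / n
  grads <- list()

  if (cfg$lstm_layers > 0) {
    dout <- vector("list", cfg$seq_len)
    dw_main <- model$params$head_main_w * 0
    db_main <- numeric(cfg$n_classes)
    for (t in seq_len(cfg$seq_len)) {
      cols <- (seq_len(s) - 1) * cfg$seq_len + t
      dzt <- dz_main[, cols, drop = FALSE]
      ht <- fwd$lstm$out[[t]]
      dw_main <- dw_main + dzt %*% t(ht)
      db_main <- db_main + rowSums(dzt)
      dout[[t]] <- t(model$params$head_main_w) %*% dzt
    }
    grads$head_main_w <- dw_main
    grads$head_main_b <- db_main
    lb <- bilstm_backward(dout, model$params, fwd$lstm$caches)
    grads <- c(grads, lb$grads)
    dfeat <- matrix(0, cfg$feature_dim, n)
    for (t in seq_len(cfg$seq_len)) {
      dfeat[, (seq_len(s) - 1) * cfg$seq_len + t] <- lb$dxs[[t]]
    }
  } else {
    d <- dense_backward(model$params$head_main_w, fwd$features, dz_main)
    grads$head_main_w <- d$dw
    grads$head_main_b <- d$db
    dfeat <- d$dx
  }

  da <- dense_backward(model$params$head_aux_w, fwd$features, dz_aux)
  grads$head_aux_w <- da$dw
  grads$head_aux_b <- da$db
  dfeat <- dfeat + da$dx

  cb <- cnn_backward(model, dfeat, fwd$cnn)
  c(grads, cb$grads)
}

#' Composite cross-entropy loss with auxiliary classifier
#'
#' `loss_main` and `loss_aux` are mean cross-entropies of the main and
#' auxiliary softmax heads against one-hot labels; the total is
#' `loss_main + aux_weight * loss_aux`. Probabilities are clamped to
#' `[1e-12, 1]` before the log.
#'
#' @param main_probs,aux_probs `(n_classes x N)` probability matrices.
#' @param y one-hot `(n_classes x N)` matrix of reference labels.
#' @param aux_weight weight of the auxiliary term (default 0.5).
#' @return A list with `loss_main`, `loss_aux`, `loss_total`, `n`.
#' @export
#' @examples
#' y <- diag(5)
#' u <- matrix(0.2, 5, 5)
#' compute_loss(u, u, y)$loss_total  # 1.5 * log(5)
compute_loss <- function(main_probs, aux_probs, y, aux_weight = 0.5) {
  if (ncol(main_probs) != ncol(y) || ncol(aux_probs) != ncol(y)) {
    abort("main, aux and y must cover the same samples.",
          class = "somnet_shape_error")
  }
  n <- ncol(y)
  ce <- function(p) -sum(y * log(pmin(pmax(p, 1e-12), 1))) / n
  lm <- ce(main_probs)
  la <- ce(aux_probs)
  list(loss_main = lm, loss_aux = la, loss_total = lm + aux_weight * la, n = n)
}

one_hot <- function(labels, n_classes = 5) {
  idx <- as.integer(labels)
  y <- matrix(0, n_classes, length(idx))
  y[cbind(idx, seq_along(idx))] <- 1
  y
}

# --- user-facing single pieces -------------------------------------------

#' Extract the per-epoch feature vector
#'
#' Runs the convolutional feature extractor on one image (or a batch) in
#' the requested mode. Evaluation mode is deterministic: dropout disabled,
#' batch normalization using running moments.
#'
#' @param model a `somnet_model`.
#' @param img a 76 x 60 x 3 image or a 76 x 60 x 3 x n batch.
#' @param training logical; training mode uses batch statistics and
#'   dropout (requires an RNG state).
#' @return A `feature_dim x n` matrix (drop to a vector with `[ , 1]`).
#' @export
feature_extract <- function(model, img, training = FALSE) {
  d <- dim(img)
  if (length(d) == 3) dim(img) <- c(d, 1)
  d <- dim(img)
  expect <- model$cfg$input_shape
  if (any(d[1:3] != expect)) {
    abort(sprintf("Expected %s image(s), got %s.",
                  paste(expect, collapse = " x "),
                  paste(d[1:3], collapse = " x ")),
          class = "somnet_shape_error")
  }
  cnn_forward(model, img, training)$features
}

#' Predict stage probabilities for one epoch sequence
#'
#' Applies the bidirectional LSTM stack and main softmax head to a sequence
#' of per-epoch feature vectors. With `lstm_layers = 0` the head is applied
#' to each feature independently (no sequence context).
#'
#' @param model a `somnet_model`.
#' @param features `feature_dim x seq_len` matrix of epoch features.
#' @return `n_classes x seq_len` matrix of probabilities (columns sum to 1).
#' @export
sequence_predict <- function(model, features) {
  cfg <- model$cfg
  if (!is.matrix(features) || nrow(features) != cfg$feature_dim ||
      ncol(features) != cfg$seq_len) {
    abort(sprintf("Expected a %d x %d feature matrix.",
                  cfg$feature_dim, cfg$seq_len),
          class = "somnet_shape_error")
  }
  if (cfg$lstm_layers > 0) {
    xs <- lapply(seq_len(cfg$seq_len), function(t) features[, t, drop = FALSE])
    out <- bilstm_forward(xs, model$params, cfg$lstm_layers)$out
    z <- vapply(out, function(h) {
      as.numeric(dense_forward(model$params$head_main_w,
                               model$params$head_main_b, h))
    }, numeric(cfg$n_classes))
  } else {
    z <- dense_forward(model$params$head_main_w, model$params$head_main_b,
                       features)
  }
  softmax_cols(z)
}

#' Auxiliary-classifier prediction for one feature vector
#'
#' The training-only auxiliary head: a dense softmax over the five stages
#' applied directly to the 64-d feature. It regularizes training and is
#' absent from the evaluation path.
#'
#' @param model a `somnet_model`.
#' @param feature numeric vector of length `feature_dim` (or a matrix of
#'   column features).
#' @return Probability vector/matrix over the stages.
#' @export
aux_predict <- function(model, feature) {
  f <- if (is.matrix(feature)) feature else matrix(feature, ncol = 1)
  p <- softmax_cols(dense_forward(model$params$head_aux_w,
                                  model$params$head_aux_b, f))
  if (is.matrix(feature)) p else as.numeric(p)
}

#' Predict stages for a batch of images in evaluation mode
#'
#' Images must be sequence-major (`seq_len` consecutive epochs per
#' sequence). The auxiliary head plays no part; dropout is disabled and
#' batch normalization uses running moments.
#'
#' @param model a `somnet_model`.
#' @param images 76 x 60 x 3 x N array, N a multiple of `seq_len`.
#' @return A list with `probs` (`n_classes x N`) and `stage` (factor).
#' @export
predict_stages <- function(model, images) {
  fwd <- model_forward(model, images, training = FALSE)
  lab <- stage_levels()[apply(fwd$main_probs, 2, which.max)]
  list(probs = fwd$main_probs, stage = stage_factor(lab))
}
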