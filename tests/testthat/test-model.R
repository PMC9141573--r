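test_that("gelu is the exact x * Phi(x) form", {
  expect_identical(gelu(0), 0)
  expect_lt(abs(gelu(10) - 10), 1e-6)
  # Phi(-1) = 0.1586553..., via the independent erf-series value
  expect_equal(gelu(-1), -0.15865525393146, tolerance = 1e-10)
  # the compiled kernel uses the same exact form
  x <- array(rnorm(12), c(1, 1, 3, 4))
  w <- array(0, c(3, 3, 3, 2))
  w[2, 2, , ] <- diag(3)[, 1:2]          # identity tap: pre == input channel
  out <- somnet:::conv_gelu_forward(x, w, numeric(2))
  expect_equal(as.numeric(out$act), gelu(as.numeric(out$pre)),
               tolerance = 1e-12)
})

test_that("model configuration enforces the residual-shape invariants", {
  expect_error(model_config(conv_channels = c(16, 32, 32, 32, 64)),
               class = "somnet_config_error")
  expect_error(model_config(conv_channels = c(16, 16, 32, 32, 48)),
               class = "somnet_config_error")
  expect_error(model_config(lstm_layers = 5), class = "somnet_config_error")
  for (l in 0:3) expect_s3_class(model_config(lstm_layers = l),
                                 "somnet_config")
})

test_that("feature extraction yields a finite 64-d vector, deterministically", {
  mod <- init_model(model_config(), seed = 1)
  img <- array(runif(76 * 60 * 3), c(76, 60, 3))
  f1 <- feature_extract(mod, img)
  f2 <- feature_extract(mod, img)
  expect_equal(dim(f1), c(64, 1))
  expect_identical(f1, f2)
  expect_true(all(is.finite(feature_extract(mod, array(0, c(76, 60, 3))))))
  expect_error(feature_extract(mod, array(0, c(10, 10, 3))),
               class = "somnet_shape_error")
})

test_that("sequence predictions are proper distributions", {
  mod <- init_model(model_config(), seed = 2)
  feats <- matrix(rnorm(64 * 10), 64, 10)
  p <- sequence_predict(mod, feats)
  expect_equal(dim(p), c(5, 10))
  expect_true(all(abs(colSums(p) - 1) < 1e-6))
  expect_true(all(p > 0))
  expect_error(sequence_predict(mod, feats[, 1:5]),
               class = "somnet_shape_error")
})

test_that("without recurrence, predictions are position-independent", {
  mod <- init_model(model_config(lstm_layers = 0), seed = 3)
  feats <- matrix(rnorm(64 * 10), 64, 10)
  p <- sequence_predict(mod, feats)
  perm <- sample(10)
  expect_equal(sequence_predict(mod, feats[, perm]), p[, perm],
               tolerance = 1e-12)
})

test_that("the auxiliary head is a softmax absent from the evaluation path", {
  mod <- init_model(model_config(), seed = 4)
  f <- rnorm(64)
  expect_equal(sum(aux_predict(mod, f)), 1, tolerance = 1e-9)
  # zero-initialized head gives the uniform distribution
  mod0 <- mod
  mod0$params$head_aux_w[] <- 0
  mod0$params$head_aux_b[] <- 0
  expect_equal(aux_predict(mod0, f), rep(0.2, 5), tolerance = 1e-12)
  # evaluation output does not depend on the aux head at all
  ib <- small_images()
  x <- ib$images[, , , 1:10, drop = FALSE]
  p1 <- predict_stages(mod, x)$probs
  mod$params$head_aux_w[] <- rnorm(length(mod$params$head_aux_w))
  p2 <- predict_stages(mod, x)$probs
  expect_identical(p1, p2)
})

test_that("the composite loss matches its closed forms", {
  y <- diag(5)
  perfect <- compute_loss(y, y, y)
  expect_equal(perfect$loss_total, 0, tolerance = 1e-9)

  u <- matrix(0.2, 5, 5)
  expect_equal(compute_loss(u, u, y, aux_weight = 0.5)$loss_total,
               1.5 * log(5), tolerance = 1e-9)

  # N = 2, main true-class probs (0.5, 0.25), aux perfect
  y2 <- diag(5)[, 1:2]
  main <- matrix((1 - c(0.5, 0.25)) / 4, 5, 2, byrow = TRUE)
  main[1, 1] <- 0.5
  main[2, 2] <- 0.25
  aux <- y2
  l <- compute_loss(main, aux, y2, aux_weight = 0.5)
  expect_equal(l$loss_main, (log(2) + log(4)) / 2, tolerance = 1e-9)
  expect_equal(l$loss_aux, 0, tolerance = 1e-9)
  expect_equal(l$loss_total, l$loss_main + 0.5 * l$loss_aux, tolerance = 1e-12)

  expect_error(compute_loss(u, u, y2), class = "somnet_shape_error")
})

test_that("parameter counts follow the standard gate arithmetic", {
  mod <- init_model(model_config(), seed = 1)
  lstm_total <- sum(vapply(grep("^lstm", names(mod$params), value = TRUE),
                           function(nm) length(mod$params[[nm]]), numeric(1)))
  # 2 directions x 4 gates x (in + hidden + 1) x hidden, layers 1 and 2
  expect_equal(lstm_total, 2 * 4 * (64 + 128 + 1) * 128 +
                 2 * 4 * (256 + 128 + 1) * 128)
  expect_equal(length(mod$params$head_main_w) + length(mod$params$head_main_b),
               256 * 5 + 5)
  n <- count_parameters(mod)
  expect_gte(n, 550000)
  expect_lte(n, 650000)
})

test_that("softmax columns are strictly positive and normalized", {
  set.seed(8)
  z <- matrix(rnorm(5 * 50, sd = 10), 5, 50)
  p <- somnet:::softmax_cols(z)
  expect_true(all(p > 0))
  expect_true(all(abs(colSums(p) - 1) < 1e-12))
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(conv_channels = c(2, 2, 3, 3, 4), lstm_layers = 2,
                      lstm_hidden = 4, seq_len = 3, feature_dim = 4,
                      dropout_keep = 1)
  mod <- init_model(cfg, seed = 7)
  set.seed(3)
  n <- 2 * cfg$seq_len
  x <- array(rnorm(76 * 60 * 3 * n), c(76, 60, 3, n))
  y <- somnet:::one_hot(stage_factor(sample(stage_levels(), n, TRUE)), 5)
  lossfun <- function(m) {
    fwd <- somnet:::model_forward(m, x, training = TRUE)
    compute_loss(fwd$main_probs, fwd$aux_probs, y, cfg$aux_weight)$loss_total
  }
  fwd <- somnet:::model_forward(mod, x, training = TRUE)
  grads <- somnet:::model_backward(mod, fwd, y)
  eps <- 1e-5
  set.seed(4)
  for (nm in c("conv1_1_w", "conv4_1_w", "bn3_gamma", "bn5_beta",
               "lstm1_f_W", "lstm2_b_U", "head_main_w", "head_aux_b")) {
    i <- sample(length(grads[[nm]]), 1)
    up <- mod; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- mod; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    num <- (lossfun(up) - lossfun(dn)) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-5,
                 label = paste("gradient of", nm))
  }
})

test_that("gradient reaches every trainable tensor", {
  cfg <- model_config(conv_channels = c(2, 2, 3, 3, 4), lstm_layers = 1,
                      lstm_hidden = 3, seq_len = 2, feature_dim = 4)
  mod <- init_model(cfg, seed = 9)
  set.seed(10)
  x <- array(rnorm(76 * 60 * 3 * 4), c(76, 60, 3, 4))
  y <- somnet:::one_hot(stage_factor(sample(stage_levels(), 4, TRUE)), 5)
  fwd <- somnet:::model_forward(mod, x, training = TRUE)
  grads <- somnet:::model_backward(mod, fwd, y)
  expect_setequal(names(grads), names(mod$params))
  zero_tensors <- names(grads)[vapply(grads, function(g) all(g == 0),
                                      logical(1))]
  expect_length(zero_tensors, 0)
})

test_that("one Adam step on a batch strictly decreases the loss", {
  cfg <- model_config(conv_channels = c(2, 2, 3, 3, 4), lstm_layers = 1,
                      lstm_hidden = 4, seq_len = 2, feature_dim = 4,
                      dropout_keep = 1)
  mod <- init_model(cfg, seed = 11)
  set.seed(12)
  x <- array(rnorm(76 * 60 * 3 * 4), c(76, 60, 3, 4))
  y <- somnet:::one_hot(stage_factor(sample(stage_levels(), 4, TRUE)), 5)
  fwd <- somnet:::model_forward(mod, x, training = TRUE)
  l0 <- compute_loss(fwd$main_probs, fwd$aux_probs, y)$loss_total
  grads <- somnet:::model_backward(mod, fwd, y)
  opt <- list(m = lapply(mod$params, function(p) p * 0),
              v = lapply(mod$params, function(p) p * 0), t = 0)
  up <- somnet:::adam_update(mod$params, grads, opt, lr = 1e-3, clip = 5)
  mod$params <- up$params
  fwd1 <- somnet:::model_forward(mod, x, training = TRUE)
  l1 <- compute_loss(fwd1$main_probs, fwd1$aux_probs, y)$loss_total
  expect_lt(l1, l0)
})

test_that("evaluation forward passes are pure functions", {
  mod <- init_model(model_config(lstm_layers = 2), seed = 13)
  ib <- small_images()
  x <- ib$images[, , , 1:10, drop = FALSE]
  p1 <- predict_stages(mod, x)
  set.seed(999)  # unrelated RNG state must not matter
  p2 <- predict_stages(mod, x)
  expect_identical(p1$probs, p2$probs)
})
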