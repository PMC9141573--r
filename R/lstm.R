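# Stacked bidirectional LSTM over epoch-feature sequences, with full
# backpropagation through time. Sequences are lists of (input_dim x batch)
# matrices, one per time step; gates are stacked row-wise [i; f; g; o].

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_dir_forward <- function(xs, W, U, b, reverse = FALSE) {
  L <- length(xs)
  H <- ncol(U)
  S <- ncol(xs[[1]])
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  h <- matrix(0, H, S)
  cc <- matrix(0, H, S)
  hs <- vector("list", L)
  cache <- vector("list", L)
  ri <- seq_len(H); rf <- H + ri; rg <- 2 * H + ri; ro <- 3 * H + ri
  for (t in ord) {
    a <- W %*% xs[[t]] + U %*% h + b
    gi <- sigmoid(a[ri, , drop = FALSE])
    gf <- sigmoid(a[rf, , drop = FALSE])
    gg <- tanh(a[rg, , drop = FALSE])
    go <- sigmoid(a[ro, , drop = FALSE])
    cache[[t]] <- list(i = gi, f = gf, g = gg, o = go,
                       hprev = h, cprev = cc, x = xs[[t]])
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    cache[[t]]$tanhc <- tc
    hs[[t]] <- h
  }
  list(h = hs, cache = cache, ord = ord)
}

lstm_dir_backward <- function(dhs, W, U, cache, ord) {
  L <- length(dhs)
  H <- ncol(U)
  S <- ncol(dhs[[1]])
  dW <- W * 0; dU <- U * 0; db <- numeric(4 * H)
  dxs <- vector("list", L)
  dh_next <- matrix(0, H, S)
  dc_next <- matrix(0, H, S)
  for (t in rev(ord)) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tanhc^2)
    da <- rbind(
      (dc * cc$g) * cc$i * (1 - cc$i),
      (dc * cc$cprev) * cc$f * (1 - cc$f),
      (dc * cc$i) * (1 - cc$g^2),
      (dh * cc$tanhc) * cc$o * (1 - cc$o)
    )
    dW <- dW + da %*% t(cc$x)
    dU <- dU + da %*% t(cc$hprev)
    db <- db + rowSums(da)
    dxs[[t]] <- t(W) %*% da
    dh_next <- t(U) %*% da
    dc_next <- dc * cc$f
  }
  list(dxs = dxs, dW = dW, dU = dU, db = db)
}

# params: flat named list with lstm{l}_{f|b}_{W,U,b}
bilstm_forward <- function(xs, params, n_layers) {
  caches <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fw <- lstm_dir_forward(xs, params[[paste0("lstm", l, "_f_W")]],
                           params[[paste0("lstm", l, "_f_U")]],
                           params[[paste0("lstm", l, "_f_b")]], reverse = FALSE)
    bw <- lstm_dir_forward(xs, params[[paste0("lstm", l, "_b_W")]],
                           params[[paste0("lstm", l, "_b_U")]],
                           params[[paste0("lstm", l, "_b_b")]], reverse = TRUE)
    caches[[l]] <- list(fw = fw, bw = bw, x = xs)
    xs <- lapply(seq_along(xs), function(t) rbind(fw$h[[t]], bw$h[[t]]))
  }
  list(out = xs, caches = caches)
}

bilstm_backward <- function(dout, params, caches) {
  n_layers <- length(caches)
  grads <- list()
  for (l in rev(seq_len(n_layers))) {
    H <- ncol(params[[paste0("lstm", l, "_f_U")]])
    dhf <- lapply(dout, function(m) m[seq_len(H), , drop = FALSE])
    dhb <- lapply(dout, function(m) m[H + seq_len(H), , drop = FALSE])
    cf <- caches[[l]]$fw
    cb <- caches[[l]]$bw
    gf <- lstm_dir_backward(dhf, params[[paste0("lstm", l, "_f_W")]],
                            params[[paste0("lstm", l, "_f_U")]], cf$cache, cf$ord)
    gb <- lstm_dir_backward(dhb, params[[paste0("lstm", l, "_b_W")]],
                            params[[paste0("lstm", l, "_b_U")]], cb$cache, cb$ord)
    grads[[paste0("lstm", l, "_f_W")]] <- gf$dW
    grads[[paste0("lstm", l, "_f_U")]] <- gf$dU
    grads[[paste0("lstm", l, "_f_b")]] <- gf$db
    grads[[paste0("lstm", l, "_b_W")]] <- gb$dW
    grads[[paste0("lstm", l, "_b_U")]] <- gb$dU
    grads[[paste0("lstm", l, "_b_b")]] <- gb$db
    dout <- lapply(seq_along(dout), function(t) gf$dxs[[t]] + gb$dxs[[t]])
  }
  list(dxs = dout, grads = grads)
}
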