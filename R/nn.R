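# Minimal fully-connected network engine: ReLU hidden layers, sigmoid or
# identity output, L1 loss, Adam, step learning-rate schedule,
# lowest-validation-loss checkpointing. Everything is plain matrix algebra
# so gradients with respect to the *inputs* are available too -- that input
# gradient is what makes the surrogate usable inside gradient-based
# schedule optimization.

mlp_new <- function(n_in, hidden, n_out, out_act = c("sigmoid", "identity"),
                    seed = 1) {
  out_act <- match.arg(out_act)
  set.seed(seed)
  sizes <- c(n_in, hidden, n_out)
  L <- length(sizes) - 1
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes, out_act = out_act),
            class = "st_mlp")
}

# Forward pass; returns output and (optionally) the activations needed for
# backprop. The cache-free path goes through the compiled kernel.
mlp_forward <- function(net, X, keep_cache = FALSE) {
  if (!keep_cache) {
    return(list(out = mlp_forward_cpp(net$W, net$b, net$out_act == "sigmoid",
                                      X),
                cache = NULL))
  }
  L <- length(net$W)
  H <- X
  cache <- if (keep_cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (keep_cache) cache[[l]] <- H
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    H <- if (l < L) pmax(Z, 0)
         else if (net$out_act == "sigmoid") 1 / (1 + exp(-Z))
         else Z
  }
  list(out = H, cache = cache)
}

# Backward pass from an upstream gradient dOut (same shape as the output).
# Returns per-layer weight/bias gradients and the gradient w.r.t. X.
mlp_backward <- function(net, fwd, dOut) {
  L <- length(net$W)
  Y <- fwd$out
  dZ <- if (net$out_act == "sigmoid") dOut * Y * (1 - Y) else dOut
  gW <- gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    H <- fwd$cache[[l]]
    gW[[l]] <- crossprod(H, dZ)
    gb[[l]] <- colSums(dZ)
    dH <- tcrossprod(dZ, net$W[[l]])
    if (l > 1) {
      # ReLU mask: the stored activation H is already rectified
      dZ <- dH * (fwd$cache[[l]] > 0)
    } else dX <- dH
  }
  list(gW = gW, gb = gb, dX = dX)
}

adam_new <- function(net) {
  z <- lapply(net$W, function(w) w * 0)
  zb <- lapply(net$b, function(v) v * 0)
  list(mW = z, vW = z, mb = zb, vb = zb, t = 0)
}

adam_step <- function(net, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * grads$gW[[l]]
    st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * grads$gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * grads$gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * grads$gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, state = st)
}

# Generic supervised trainer (compiled hot loop). X, Y numeric matrices;
# 90/10 train/validation split (seeded), minibatch Adam on
# mean-absolute-error, learning rate decayed by `lr_factor` every
# `decay_every` epochs; the weights with the lowest validation loss are
# returned. `noise_cols > 0` adds white Gaussian noise to the leading
# columns afresh each pass, at a per-row SNR drawn uniformly from
# `snr_range` dB -- the measurement-noise model of quantifier training.
mlp_train <- function(net, X, Y, epochs = 30, batch = 256, lr0 = 1e-4,
                      decay_every = 20, lr_factor = 0.1, val_frac = 0.1,
                      seed = 1, noise_cols = 0, snr_range = c(Inf, Inf),
                      verbose = FALSE) {
  set.seed(seed)
  n <- nrow(X)
  idx <- sample(n)
  n_val <- max(1, round(val_frac * n))
  vi <- idx[seq_len(n_val)]; ti <- idx[-seq_len(n_val)]
  fit <- mlp_train_cpp(net$W, net$b, net$out_act == "sigmoid",
                       X[ti, , drop = FALSE], Y[ti, , drop = FALSE],
                       X[vi, , drop = FALSE], Y[vi, , drop = FALSE],
                       as.integer(epochs), as.integer(batch), lr0,
                       as.integer(decay_every), lr_factor,
                       as.integer(noise_cols),
                       if (is.finite(snr_range[1])) snr_range[1] else 300,
                       if (is.finite(snr_range[2])) snr_range[2] else 300,
                       as.integer(seed))
  net$W <- fit$W
  net$b <- lapply(fit$b, as.numeric)
  hist <- data.frame(epoch = seq_len(epochs),
                     train_loss = as.numeric(fit$train_loss),
                     val_loss = as.numeric(fit$val_loss_hist))
  if (verbose) print(utils::tail(hist, 3))
  list(net = net, val_loss = fit$val_loss, history = hist)
}

# Pure-R reference trainer (same contract, used to validate the compiled
# path on small problems).
mlp_train_ref <- function(net, X, Y, epochs = 30, batch = 256, lr0 = 1e-4,
                          decay_every = 20, lr_factor = 0.1, val_frac = 0.1,
                          seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  idx <- sample(n)
  n_val <- max(1, round(val_frac * n))
  vi <- idx[seq_len(n_val)]; ti <- idx[-seq_len(n_val)]
  Xv <- X[vi, , drop = FALSE]; Yv <- Y[vi, , drop = FALSE]
  Xt <- X[ti, , drop = FALSE]; Yt <- Y[ti, , drop = FALSE]
  st <- adam_new(net)
  best <- list(loss = Inf, net = net)
  hist <- data.frame()
  nt <- nrow(Xt)
  for (ep in seq_len(epochs)) {
    lr <- lr0 * lr_factor^((ep - 1) %/% decay_every)
    ord <- sample(nt)
    tl <- 0; nb <- 0
    for (s in seq(1, nt, by = batch)) {
      bi <- ord[s:min(s + batch - 1, nt)]
      fwd <- mlp_forward(net, Xt[bi, , drop = FALSE], keep_cache = TRUE)
      R <- fwd$out - Yt[bi, , drop = FALSE]
      tl <- tl + mean(abs(R)); nb <- nb + 1
      g <- mlp_backward(net, fwd, sign(R) / length(R))
      upd <- adam_step(net, g, st, lr)
      net <- upd$net; st <- upd$state
    }
    vl <- mean(abs(mlp_forward(net, Xv)$out - Yv))
    if (!is.finite(vl)) stop("training diverged (non-finite validation loss)")
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, net = net)
  }
  list(net = best$net, val_loss = best$loss, history = hist)
}
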