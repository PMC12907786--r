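# Learning-based optimization of the acquisition schedule (LOAS): scan
# parameters are unconstrained logits decoded through a sigmoid into their
# physical ranges, so decoded schedules always respect the bounds; the
# quantification loss is backpropagated through the frozen surrogate to the
# logits while the quantification network is co-trained, and SAR
# feasibility enters as a hinge penalty on B1*Ts.

#' SAR penalty of a schedule
#'
#' `sum(max(B1 * Ts - 4, 0))` over scans: zero exactly when every scan
#' respects the SAR bound.
#'
#' @param s an `st_schedule` or compatible data.frame.
#' @return non-negative scalar.
#' @export
sar_penalty <- function(s) {
  sum(pmax(s$B1_uT * s$Ts_s - st_constants$sar_bound, 0))
}

# Per-scan decoding bounds. Offsets are optimized within their band only;
# MTC scans keep the sign of their initial offset (magnitude 8-40 ppm).
loas_bounds <- function(schedule) {
  r <- scan_ranges()
  n <- nrow(schedule)
  lo <- hi <- matrix(0, n, 4, dimnames = list(NULL, c("b1", "offset", "ts", "td")))
  lo[, "b1"] <- r$b1[1]; hi[, "b1"] <- r$b1[2]
  lo[, "ts"] <- r$ts[1]; hi[, "ts"] <- r$ts[2]
  lo[, "td"] <- r$td[1]; hi[, "td"] <- r$td[2]
  for (i in seq_len(n)) {
    band <- schedule$band[i]
    rng <- if (band == "water") r$offset$water
           else if (band == "apt") r$offset$apt
           else if (schedule$offset_ppm[i] >= 0) r$offset$mtc_pos
           else r$offset$mtc_neg
    lo[i, "offset"] <- rng[1]; hi[i, "offset"] <- rng[2]
  }
  list(lo = lo, hi = hi)
}

# Schedule <-> logits maps. logit values are clamped to +/-6 so an
# initialization sitting on a range boundary stays finite.
schedule_to_logits <- function(schedule, bnd = loas_bounds(schedule)) {
  P <- as_scan_matrix(schedule)
  u <- (P - bnd$lo) / (bnd$hi - bnd$lo)
  u <- pmin(pmax(u, 1e-3), 1 - 1e-3)
  pmin(pmax(log(u / (1 - u)), -6), 6)
}

logits_to_schedule <- function(Z, band, bnd) {
  u <- 1 / (1 + exp(-Z))
  P <- bnd$lo + (bnd$hi - bnd$lo) * u
  new_schedule(band, P[, "b1"], P[, "offset"], P[, "ts"], P[, "td"])
}

# One differentiable pass of the optimization objective: decode logits ->
# surrogate synthesis -> (optional) noise -> quantifier -> L1 loss, with
# gradients for the quantifier weights (gq) and the schedule logits (dZ,
# quantification term only; the SAR hinge is added separately). The noise
# draw uses the caller's RNG state.
loas_loss_grad <- function(Z, qnet, dbes, Xt, Yt, rb1n, bnd,
                           snr_range = NULL, want_grad = TRUE) {
  grng <- scan_norm_ranges()
  gspan <- grng[, 2] - grng[, 1]
  n_scans <- nrow(Z)
  b <- nrow(Xt)
  snorm <- 1 / (1 + exp(-Z))
  xs <- sweep(sweep(bnd$lo + (bnd$hi - bnd$lo) * snorm, 2, grng[, 1], "-"),
              2, gspan, "/")
  Xbig <- cbind(Xt[rep(seq_len(b), n_scans), , drop = FALSE],
                xs[rep(seq_len(n_scans), each = b), , drop = FALSE])
  fwd_s <- dbes_forward_norm(dbes, Xbig, keep_cache = want_grad)
  S <- matrix(fwd_s$out, b, n_scans)
  if (!is.null(snr_range))
    S <- add_noise(S, runif(b, snr_range[1], snr_range[2]))
  Xq <- cbind(S, rb1n)
  fwd_q <- mlp_forward(qnet, Xq, keep_cache = want_grad)
  R <- fwd_q$out - Yt
  loss <- mean(abs(R))
  if (!want_grad) return(list(loss = loss))
  gq <- mlp_backward(qnet, fwd_q, sign(R) / length(R))
  dS <- gq$dX[, seq_len(n_scans), drop = FALSE]
  dXbig <- mlp_backward(dbes$net, fwd_s, matrix(as.vector(dS)))$dX
  dxs <- dXbig[, 12:15, drop = FALSE]
  dxs_sc <- t(vapply(seq_len(n_scans), function(j)
    colSums(dxs[((j - 1) * b + 1):(j * b), , drop = FALSE]), numeric(4)))
  colnames(dxs_sc) <- c("b1", "offset", "ts", "td")
  dZ <- sweep(dxs_sc, 2, gspan, "/") * (bnd$hi - bnd$lo) * snorm * (1 - snorm)
  list(loss = loss, dZ = dZ, gq = gq, signals = S)
}

# Gradient of the SAR hinge penalty with respect to the schedule logits.
sar_penalty_grad <- function(Z, bnd) {
  snorm <- 1 / (1 + exp(-Z))
  P <- bnd$lo + (bnd$hi - bnd$lo) * snorm
  over <- P[, "b1"] * P[, "ts"] > st_constants$sar_bound
  dP <- P * 0
  dP[, "b1"] <- over * P[, "ts"]
  dP[, "ts"] <- over * P[, "b1"]
  dP * (bnd$hi - bnd$lo) * snorm * (1 - snorm)
}

#' Quantification loss of a schedule/network pair
#'
#' Mean absolute error between normalized true tissue parameters and the
#' quantifier's estimates from surrogate-synthesized, noise-corrupted
#' signals: `L_t = |p_t - dTPQ(dBES(p_t, p_s; eta), rB1)|_1`.
#'
#' @param tissue tissue-parameter sets (rows).
#' @param schedule an `st_schedule`.
#' @param dbes trained `st_dbes` surrogate (or `NULL` to use the exact
#'   simulator).
#' @param dtpq an `st_dtpq`, or a function `(signals, rb1) -> normalized
#'   parameter matrix` (useful as an oracle stub).
#' @param snr_db SNR of the injected noise in dB (`Inf` for noiseless).
#' @param seed optional seed for the noise draw.
#' @param bounds bounds used to normalize the target parameters.
#' @return non-negative scalar loss.
#' @export
quantification_loss <- function(tissue, schedule, dbes, dtpq, snr_db = Inf,
                                seed = NULL, bounds = tissue_bounds()) {
  ptm <- as_tissue_matrix(tissue)
  S <- if (is.null(dbes)) simulate_signals(ptm, schedule)
       else dbes_signals(dbes, ptm, schedule)
  if (!is.null(seed)) set.seed(seed)
  if (any(is.finite(snr_db))) S <- add_noise(S, snr_db)
  Yn <- if (is.function(dtpq)) dtpq(S, ptm[, "rb1"])
        else {
          est <- dtpq_predict(dtpq, S, ptm[, "rb1"])
          normalize_params(as.matrix(est), dtpq$bounds)
        }
  Yt <- normalize_params(ptm[, colnames(Yn), drop = FALSE], bounds)
  mean(abs(Yt - Yn))
}

#' Optimize an acquisition schedule by gradient descent
#'
#' Jointly updates the 63 x 4 scan-parameter logits (Adam, learning rate
#' `lr_sched`) and a quantification network trained from scratch (Adam,
#' `lr_dtpq`), minimizing the L1 quantification loss plus the SAR hinge
#' penalty. Signals are synthesized by the *frozen* surrogate, whose input
#' gradient carries the loss back to the scan parameters; white Gaussian
#' noise at 40--46 dB SNR is injected afresh every pass. Tissue parameters
#' are sampled with the static-field offset restricted to `db0_range`
#' (narrower than quantifier training); 10% are held out and the
#' lowest-validation-loss schedule is returned.
#'
#' @param dbes trained `st_dbes` surrogate (full preset, 15 inputs).
#' @param init `"pr"`, `"linear"`, or an `st_schedule` to start from.
#' @param n_samples tissue-parameter sets used per epoch.
#' @param seed integer RNG seed.
#' @param epochs,batch optimization length and minibatch size.
#' @param lr_sched,lr_dtpq initial Adam learning rates for the scan logits
#'   and the co-trained quantifier.
#' @param decay_every_sched,decay_every_dtpq step-decay periods (factor 0.1).
#' @param snr_range training noise range in dB.
#' @param db0_range B0-offset sampling range during optimization, Hz.
#' @param hidden hidden-layer widths of the co-trained quantifier.
#' @param verbose print per-epoch losses.
#' @return list with the optimized `schedule`, the co-trained `dtpq`, the
#'   initial schedule, and a `history` data.frame (epoch, train/validation
#'   loss, SAR penalty).
#' @export
loas_optimize <- function(dbes, init = "pr", n_samples = 4096, seed = 1,
                          epochs = 40, batch = 256, lr_sched = 1e-2,
                          lr_dtpq = 1e-4, decay_every_sched = 60,
                          decay_every_dtpq = 30, snr_range = c(40, 46),
                          db0_range = c(-64, 64), hidden = rep(64, 4),
                          verbose = FALSE) {
  if (!is.null(dbes$free))
    stop("schedule optimization needs a full-input surrogate, not the slice preset")
  set.seed(seed)
  init_sched <- if (is.character(init)) {
    switch(init, pr = pseudo_random_schedule(seed), linear = linear_schedule(),
           stop("unknown init"))
  } else init
  band <- init_sched$band
  bnd <- loas_bounds(init_sched)
  Z <- schedule_to_logits(init_sched, bnd)
  n_scans <- nrow(Z)
  grng <- scan_norm_ranges()
  gspan <- grng[, 2] - grng[, 1]

  # sampling bounds: restricted dB0 for the optimization, but network
  # normalization stays on the quantifier's standard bounds
  bounds_n <- tissue_bounds()
  bounds_s <- tissue_bounds(db0_range = db0_range)
  tissue <- sample_tissue_parameters(n_samples, seed = NULL, bounds = bounds_s)
  ptm <- as_tissue_matrix(tissue)
  Xt <- normalize_params(ptm, bounds_n)
  Yt <- Xt[, .ptq_names, drop = FALSE]
  rb1n <- (ptm[, "rb1"] - .rb1_range[1]) / diff(.rb1_range)

  n_val <- max(1, round(0.1 * n_samples))
  vi <- seq_len(n_val); ti <- setdiff(seq_len(n_samples), vi)

  qnet <- mlp_new(n_scans + 1, hidden, length(.ptq_names),
                  out_act = "sigmoid", seed = seed)
  ad_q <- adam_new(qnet)
  ad_z <- list(m = Z * 0, v = Z * 0, t = 0)

  best <- list(loss = Inf, Z = Z, qnet = qnet)
  hist <- data.frame()
  nt <- length(ti)
  for (ep in seq_len(epochs)) {
    lrs <- lr_sched * 0.1^((ep - 1) %/% decay_every_sched)
    lrq <- lr_dtpq * 0.1^((ep - 1) %/% decay_every_dtpq)
    ord <- sample(ti)
    tl <- 0; nb <- 0
    for (s0 in seq(1, nt, by = batch)) {
      bi <- ord[s0:min(s0 + batch - 1, nt)]
      fw <- loas_loss_grad(Z, qnet, dbes, Xt[bi, , drop = FALSE],
                           Yt[bi, , drop = FALSE], rb1n[bi], bnd,
                           snr_range = snr_range)
      tl <- tl + fw$loss; nb <- nb + 1
      # quantifier update
      upd <- adam_step(qnet, fw$gq, ad_q, lrq)
      qnet <- upd$net; ad_q <- upd$state
      # schedule update: quantification gradient plus SAR hinge
      dZ <- fw$dZ + sar_penalty_grad(Z, bnd)
      ad_z$t <- ad_z$t + 1
      ad_z$m <- 0.9 * ad_z$m + 0.1 * dZ
      ad_z$v <- 0.999 * ad_z$v + 0.001 * dZ^2
      Z <- Z - lrs * (ad_z$m / (1 - 0.9^ad_z$t)) /
        (sqrt(ad_z$v / (1 - 0.999^ad_z$t)) + 1e-8)
    }
    # validation loss (quantification term only) with epoch-seeded noise
    set.seed(seed + 7919L * ep)
    fwv <- loas_loss_grad(Z, qnet, dbes, Xt[vi, , drop = FALSE],
                          Yt[vi, , drop = FALSE], rb1n[vi], bnd,
                          snr_range = snr_range, want_grad = FALSE)
    vl <- fwv$loss
    if (!is.finite(vl)) stop("optimization diverged")
    Pcur <- bnd$lo + (bnd$hi - bnd$lo) / (1 + exp(-Z))
    sarp <- sum(pmax(Pcur[, "b1"] * Pcur[, "ts"] - st_constants$sar_bound, 0))
    stopifnot(all(Pcur >= bnd$lo - 1e-9), all(Pcur <= bnd$hi + 1e-9))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl, sar_penalty = sarp))
    if (vl + sarp < best$loss)
      best <- list(loss = vl + sarp, Z = Z, qnet = qnet)
    if (verbose) message(sprintf("epoch %d  train %.4f  val %.4f  sar %.3f",
                                 ep, tl / nb, vl, sarp))
  }
  sched <- logits_to_schedule(best$Z, band, bnd)
  # clip any residual SAR excess of the best iterate to the feasible
  # boundary (the hinge penalty drives it to ~0; the deployed schedule must
  # be exactly feasible)
  sched$Ts_s <- pmin(sched$Ts_s, st_constants$sar_bound / sched$B1_uT)
  dtpq <- structure(list(net = best$qnet, bounds = bounds_n,
                         n_scans = n_scans, schedule_hash = schedule_hash(sched),
                         preset = "loas",
                         meta = list(n_samples = n_samples, epochs = epochs,
                                     hidden = hidden, seed = seed,
                                     forward = "dbes", snr_range = snr_range,
                                     val_loss = best$loss, history = hist)),
                    class = "st_dtpq")
  list(schedule = sched, dtpq = dtpq, init_schedule = init_sched,
       history = hist)
}
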