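# Deep Bloch-equation simulator (dBES): a fully-connected surrogate mapping
# normalized (tissue, scan) parameters to one normalized signal value. The
# surrogate is what makes the forward model differentiable for schedule
# optimization; the exact simulator remains the ground truth.

# Global scan-parameter normalization ranges for surrogate inputs (offset
# spans the union of the three bands).
scan_norm_ranges <- function() {
  r <- scan_ranges()
  rbind(b1 = r$b1, offset = c(-40, 40), ts = r$ts, td = r$td)
}

normalize_scans <- function(psm) {
  rng <- scan_norm_ranges()
  sweep(sweep(psm, 2, rng[, 1], "-"), 2, rng[, 2] - rng[, 1], "/")
}

#' Sample (tissue, scan) parameter pairs for surrogate training
#'
#' Tissue parameters are uniform within the sampling bounds; scan
#' parameters are uniform within the generator ranges, with the frequency
#' offset drawn by band (water/MTC/APT with probability 3/20/40) and then
#' uniformly within the band. Deterministic given the seed.
#'
#' @param n number of pairs.
#' @param seed integer RNG seed.
#' @param bounds tissue bounds table.
#' @return list with data.frames `tissue` (n x 12, incl. `t2w`) and
#'   `scan` (n x 4: `b1`, `offset`, `ts`, `td`).
#' @export
sample_parameters <- function(n, seed = 1, bounds = tissue_bounds()) {
  stopifnot(n >= 1)
  set.seed(seed)
  tissue <- sample_tissue_parameters(n, seed = NULL, bounds = bounds)
  r <- scan_ranges()
  band <- sample(names(.band_counts), n, replace = TRUE,
                 prob = .band_counts / sum(.band_counts))
  offset <- numeric(n)
  w <- band == "water"; a <- band == "apt"; m <- band == "mtc"
  offset[w] <- runif(sum(w), r$offset$water[1], r$offset$water[2])
  offset[a] <- runif(sum(a), r$offset$apt[1], r$offset$apt[2])
  sgn <- sample(c(-1, 1), sum(m), replace = TRUE)
  offset[m] <- sgn * runif(sum(m), r$offset$mtc_pos[1], r$offset$mtc_pos[2])
  scan <- data.frame(b1 = runif(n, r$b1[1], r$b1[2]), offset = offset,
                     ts = runif(n, r$ts[1], r$ts[2]),
                     td = runif(n, r$td[1], r$td[2]))
  list(tissue = tissue, scan = scan)
}

#' Build a surrogate training set
#'
#' Inputs are the 15 normalized values (11 tissue + 4 scan); targets are the
#' exact Bloch-McConnell signals for each pair.
#'
#' @param params a list as returned by [sample_parameters()].
#' @param bounds tissue bounds used for normalization.
#' @return list with matrix `X` (n x 15) and matrix `Y` (n x 1).
#' @export
build_training_set <- function(params, bounds = tissue_bounds()) {
  ptm <- as_tissue_matrix(params$tissue)
  psm <- as_scan_matrix(params$scan)
  X <- cbind(normalize_params(ptm, bounds), normalize_scans(psm))
  y <- simulate_signal_pairs(ptm, psm)
  list(X = X, Y = matrix(y, ncol = 1))
}

# Architecture presets. "full" is the full-scale reference configuration
# (7x256, lr 1e-4, decay 0.1 every 20 epochs); the desk presets run far
# fewer optimizer steps, so they start at a higher learning rate, and are
# recorded in the model metadata.
dbes_presets <- function(preset) {
  switch(preset,
    full = list(hidden = rep(256, 7), epochs = 100, decay_every = 20,
                 lr0 = 1e-4),
    small = list(hidden = rep(128, 5), epochs = 45, decay_every = 18,
                 lr0 = 1e-3),
    slice = list(hidden = rep(64, 4), epochs = 40, decay_every = 15,
                 lr0 = 1e-3),
    stop("unknown preset"))
}

#' Train the deep Bloch-equation simulator
#'
#' Fits the fully-connected surrogate (ReLU hidden layers, sigmoid output)
#' on exact-simulator targets with Adam, batch 256, L1 loss, the preset's
#' step learning-rate schedule, and a 90/10 train/validation split; the
#' lowest-validation-loss weights are kept.
#'
#' The `slice` preset reproduces the two-parameter sweep setting: only
#' `ksw` and `m0s` vary (inputs are those two normalized values), the other
#' tissue parameters are fixed (`T1w = T2w = 1 s`, remaining at bound
#' midpoints, `dB0 = 0`, `rB1 = 1`) and the scan is fixed at 1.5 uT /
#' 3.5 ppm / Ts 2 s / Td 5 s.
#'
#' @param n_samples training-set size.
#' @param seed integer RNG seed.
#' @param preset `"full"`, `"small"` or `"slice"`.
#' @param epochs,hidden optional overrides of the preset.
#' @param bounds tissue bounds table.
#' @param verbose print per-epoch losses.
#' @return an `st_dbes` model object.
#' @export
train_dbes <- function(n_samples = 1e5, seed = 1, preset = "small",
                       epochs = NULL, hidden = NULL,
                       bounds = tissue_bounds(), verbose = FALSE) {
  cfg <- dbes_presets(preset)
  if (!is.null(epochs)) cfg$epochs <- epochs
  if (!is.null(hidden)) cfg$hidden <- hidden
  if (preset == "slice") {
    ds <- slice_training_set(n_samples, seed, bounds)
  } else {
    ds <- build_training_set(sample_parameters(n_samples, seed, bounds), bounds)
  }
  net <- mlp_new(ncol(ds$X), cfg$hidden, 1, out_act = "sigmoid", seed = seed)
  fit <- mlp_train(net, ds$X, ds$Y, epochs = cfg$epochs, batch = 256,
                   lr0 = cfg$lr0, decay_every = cfg$decay_every, seed = seed,
                   verbose = verbose)
  structure(list(net = fit$net, bounds = bounds, preset = preset,
                 free = if (preset == "slice") c("ksw", "m0s") else NULL,
                 meta = list(n_samples = n_samples, epochs = cfg$epochs,
                             hidden = cfg$hidden, seed = seed,
                             val_loss = fit$val_loss, history = fit$history)),
            class = "st_dbes")
}

# Fixed context of the two-parameter (ksw, m0s) slice study.
slice_context <- function(bounds = tissue_bounds()) {
  pt <- tissue_midpoint(bounds)
  pt$t1w <- 1; pt$t1t2_ratio <- 1; pt$db0 <- 0; pt$rb1 <- 1
  list(tissue = pt, scan = data.frame(b1 = 1.5, offset = 3.5, ts = 2, td = 5))
}

slice_training_set <- function(n, seed, bounds = tissue_bounds()) {
  set.seed(seed)
  ctx <- slice_context(bounds)
  bi <- match(c("ksw", "m0s"), bounds$param)
  ksw <- runif(n, bounds$lower[bi[1]], bounds$upper[bi[1]])
  m0s <- runif(n, bounds$lower[bi[2]], bounds$upper[bi[2]])
  pt <- ctx$tissue[rep(1, n), ]
  pt$ksw <- ksw; pt$m0s <- m0s
  ps <- ctx$scan[rep(1, n), ]
  X <- cbind(ksw = (ksw - bounds$lower[bi[1]]) / diff(c(bounds$lower[bi[1]], bounds$upper[bi[1]])),
             m0s = (m0s - bounds$lower[bi[2]]) / diff(c(bounds$lower[bi[2]], bounds$upper[bi[2]])))
  list(X = X, Y = matrix(simulate_signal_pairs(pt, ps), ncol = 1))
}

# Internal fast path: forward on an already-normalized input matrix.
dbes_forward_norm <- function(model, Xn, keep_cache = FALSE) {
  mlp_forward(model$net, Xn, keep_cache = keep_cache)
}

#' Predict signals with the surrogate
#'
#' Normalizes the inputs (clamping out-of-range values to the training
#' bounds with a warning -- a sigmoid network extrapolates silently
#' otherwise) and evaluates the network. For the `slice` preset only `ksw`
#' and `m0s` of `pt` are read.
#'
#' @param model an `st_dbes`.
#' @param pt tissue parameters (n rows or 1 row recycled against `ps`).
#' @param ps scan parameters (n rows or 1 row).
#' @return numeric vector of predicted normalized signals in (0, 1).
#' @export
dbes_predict <- function(model, pt, ps) {
  ptm <- as_tissue_matrix(pt); psm <- as_scan_matrix(ps)
  n <- max(nrow(ptm), nrow(psm))
  if (nrow(ptm) == 1) ptm <- ptm[rep(1, n), , drop = FALSE]
  if (nrow(psm) == 1) psm <- psm[rep(1, n), , drop = FALSE]
  stopifnot(nrow(ptm) == nrow(psm))
  Xt <- normalize_params(ptm, model$bounds)
  Xs <- normalize_scans(psm)
  X <- if (!is.null(model$free)) Xt[, model$free, drop = FALSE]
       else cbind(Xt, Xs)
  if (any(X < -1e-9 | X > 1 + 1e-9)) {
    warning("inputs outside training bounds were clamped")
    X <- pmin(pmax(X, 0), 1)
  }
  drop(dbes_forward_norm(model, X)$out)
}

# Gradient of the surrogate output with respect to its normalized inputs,
# weighted by an upstream gradient dOut (n x 1). Returns an n x n_in matrix.
dbes_input_grad <- function(model, Xn, dOut) {
  fwd <- dbes_forward_norm(model, Xn, keep_cache = TRUE)
  mlp_backward(model$net, fwd, dOut)$dX
}

#' Evaluate surrogate fidelity against the exact simulator
#'
#' @param model an `st_dbes`.
#' @param params a list as from [sample_parameters()] (for the slice preset
#'   only `ksw`/`m0s` are honored, the rest is fixed to the slice context).
#' @return list with `mae_pct` (mean absolute error in percent of the
#'   normalized signal scale) and a per-case `errors` vector.
#' @export
evaluate_surrogate <- function(model, params) {
  ptm <- as_tissue_matrix(params$tissue)
  if (!is.null(model$free)) {
    ctx <- slice_context(model$bounds)
    fixed <- as_tissue_matrix(ctx$tissue)
    full <- fixed[rep(1, nrow(ptm)), , drop = FALSE]
    full[, model$free] <- ptm[, model$free]
    ptm <- full
    psm <- as_scan_matrix(ctx$scan)[rep(1, nrow(ptm)), , drop = FALSE]
  } else psm <- as_scan_matrix(params$scan)
  truth <- simulate_signal_pairs(ptm, psm)
  pred <- dbes_predict(model, ptm, psm)
  err <- pred - truth
  list(mae_pct = 100 * mean(abs(err)), errors = err)
}

#' Save / load model checkpoints
#'
#' Single-file container holding the model object plus an integrity hash of
#' its configuration; the hash is verified on load.
#'
#' @param object an `st_dbes` or `st_dtpq`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(object, path) {
  object$hash <- checkpoint_hash(object)
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  object <- readRDS(path)
  h <- object$hash
  object$hash <- NULL
  if (!identical(h, checkpoint_hash(object)))
    stop("checkpoint integrity check failed")
  object$hash <- h
  object
}

checkpoint_hash <- function(object) {
  object$hash <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f)
  unname(tools::md5sum(f))
}
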