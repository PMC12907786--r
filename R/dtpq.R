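# Deep tissue-parameter quantification network (dTPQ): 63-scan signal
# vector plus the measured relative B1 -> eight tissue/field parameters
# (T1w, kmw, M0m, T2m, dmw, ksw, M0s, dB0). A trained network is bound to
# the schedule it was trained for via a content hash.

.rb1_range <- c(0.5, 1.5)

# "full" is the full-scale reference configuration; the desk preset
# compensates for far fewer optimizer steps with a higher initial
# learning rate.
dtpq_presets <- function(preset) {
  switch(preset,
    full = list(hidden = rep(256, 7), epochs = 100, decay_every = 30,
                 lr0 = 1e-4),
    small = list(hidden = rep(128, 4), epochs = 35, decay_every = 15,
                 lr0 = 1e-3),
    stop("unknown preset"))
}

#' Train the tissue-parameter quantification network
#'
#' Samples tissue-parameter sets, synthesizes their signal vectors under a
#' fixed schedule with a selectable forward model (exact Bloch-McConnell
#' simulator or a trained surrogate), and fits a fully-connected network
#' (ReLU hidden layers, sigmoid output over normalized parameters, L1 loss,
#' Adam, step learning-rate schedule from 1e-4). White Gaussian noise at a
#' per-example SNR drawn uniformly from `snr_range` dB is added to the
#' signal inputs afresh at every pass; the lowest-validation-loss weights
#' are kept.
#'
#' @param schedule an `st_schedule` the network will be bound to.
#' @param forward `"exact"` or `"dbes"`.
#' @param dbes trained `st_dbes` (required when `forward = "dbes"`).
#' @param n_samples number of tissue-parameter sets.
#' @param seed integer RNG seed.
#' @param preset `"full"` or `"small"`.
#' @param epochs optional override of the preset epoch count.
#' @param snr_range training noise range in dB.
#' @param db0_range static-field offset sampling range (Hz); the quantifier
#'   is trained over a wider range than the schedule optimizer uses.
#' @param bounds tissue bounds (with `db0_range` substituted).
#' @param verbose print per-epoch losses.
#' @return an `st_dtpq` model object.
#' @export
train_dtpq <- function(schedule, forward = c("exact", "dbes"), dbes = NULL,
                       n_samples = 2e4, seed = 1, preset = "small",
                       epochs = NULL, snr_range = c(40, 46),
                       db0_range = c(-128, 128),
                       bounds = tissue_bounds(db0_range = db0_range),
                       verbose = FALSE) {
  forward <- match.arg(forward)
  cfg <- dtpq_presets(preset)
  if (!is.null(epochs)) cfg$epochs <- epochs
  set.seed(seed)
  tissue <- sample_tissue_parameters(n_samples, seed = NULL, bounds = bounds)
  ptm <- as_tissue_matrix(tissue)
  S <- if (forward == "exact") {
    simulate_signals(ptm, schedule)
  } else {
    if (is.null(dbes)) stop("forward = 'dbes' needs a trained surrogate")
    dbes_signals(dbes, ptm, schedule)
  }
  n_scans <- nrow(schedule)
  X <- cbind(S, rb1 = (ptm[, "rb1"] - .rb1_range[1]) / diff(.rb1_range))
  Y <- normalize_params(ptm[, .ptq_names, drop = FALSE], bounds)
  net <- mlp_new(ncol(X), cfg$hidden, length(.ptq_names),
                 out_act = "sigmoid", seed = seed)
  fit <- mlp_train(net, X, Y, epochs = cfg$epochs, batch = 256,
                   lr0 = cfg$lr0, decay_every = cfg$decay_every, seed = seed,
                   noise_cols = n_scans, snr_range = snr_range,
                   verbose = verbose)
  structure(list(net = fit$net, bounds = bounds, n_scans = n_scans,
                 schedule_hash = schedule_hash(schedule), preset = preset,
                 meta = list(n_samples = n_samples, epochs = cfg$epochs,
                             hidden = cfg$hidden, seed = seed,
                             forward = forward, snr_range = snr_range,
                             val_loss = fit$val_loss, history = fit$history)),
            class = "st_dtpq")
}

# Surrogate-based batch synthesis of full signal vectors (n tissues x m
# scans) -- the fast forward path for large training sets.
dbes_signals <- function(dbes, ptm, schedule) {
  psm <- as_scan_matrix(schedule)
  n <- nrow(ptm); m <- nrow(psm)
  Xt <- normalize_params(ptm, dbes$bounds)
  Xs <- normalize_scans(psm)
  X <- cbind(Xt[rep(seq_len(n), m), , drop = FALSE],
             Xs[rep(seq_len(m), each = n), , drop = FALSE])
  matrix(dbes_forward_norm(dbes, X)$out, n, m)
}

#' Quantify tissue parameters from a signal vector
#'
#' Denormalizes the network outputs to physical units (always inside the
#' training bounds, by construction of the bounded output layer). The
#' signal length and the schedule binding are checked hard: predicting with
#' the wrong schedule would be silently wrong otherwise.
#'
#' @param net an `st_dtpq`.
#' @param signals numeric vector (one signal per scan) or matrix (rows =
#'   voxels/examples).
#' @param rb1 relative B1 value(s), clamped to \[0.5, 1.5\] with a warning.
#' @param schedule optional `st_schedule`; when given, its hash must match
#'   the one the network was trained on.
#' @return data.frame of the eight estimated parameters in native units.
#' @export
dtpq_predict <- function(net, signals, rb1 = 1, schedule = NULL) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != net$n_scans)
    stop("signal length ", ncol(signals), " does not match the schedule (",
         net$n_scans, " scans) this network was trained for")
  if (!is.null(schedule) && !identical(schedule_hash(schedule),
                                       net$schedule_hash))
    stop("schedule hash mismatch: this network was trained for a different schedule")
  if (any(rb1 < .rb1_range[1] | rb1 > .rb1_range[2])) {
    warning("rb1 outside [0.5, 1.5] clamped")
    rb1 <- pmin(pmax(rb1, .rb1_range[1]), .rb1_range[2])
  }
  rb1n <- (rb1 - .rb1_range[1]) / diff(.rb1_range)
  X <- cbind(signals, rb1 = rep_len(rb1n, nrow(signals)))
  Yn <- mlp_forward(net$net, X)$out
  colnames(Yn) <- .ptq_names
  as.data.frame(denormalize_params(Yn, net$bounds))
}

#' Shift-correct APT-band signals for a known B0 offset
#'
#' Re-interpolates the APT-band signals onto frequency offsets shifted by
#' `-dB0` (linear interpolation over the sorted band offsets, edge values
#' held), leaving the other bands untouched. Optional preprocessing before
#' [dtpq_predict()]; the default pipeline feeds raw signals.
#'
#' @param signals numeric vector, one value per scan of `schedule`.
#' @param schedule the `st_schedule` the signals were acquired with.
#' @param db0 static field offset in Hz.
#' @return corrected signal vector.
#' @export
b0_shift_correction <- function(signals, schedule, db0) {
  stopifnot(length(signals) == nrow(schedule))
  idx <- which(schedule$band == "apt")
  offs <- schedule$offset_ppm[idx]
  if (length(unique(offs)) < 2) {
    warning("fewer than two distinct APT offsets; no correction applied")
    return(signals)
  }
  if (db0 == 0) return(signals)
  db0_ppm <- db0 / st_constants$hz_per_ppm
  ord <- order(offs)
  signals[idx] <- approx(offs[ord], signals[idx][ord],
                         xout = offs - db0_ppm, rule = 2)$y
  signals
}
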