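# End-to-end digital-phantom experiments and the schedule comparison study.

#' Run a digital-phantom quantification experiment
#'
#' For each phantom: synthesize per-voxel signal vectors under the given
#' schedule (exact simulator by default, or the surrogate), add white
#' Gaussian noise at `snr_db`, quantify with the network, and score the
#' phantom's varied parameter with nRMSE (percent of the sampling range)
#' and MAE (native units).
#'
#' @param phantoms list of `st_phantom` (or a single one).
#' @param schedule an `st_schedule`.
#' @param dtpq trained `st_dtpq` bound to `schedule`, or a function
#'   `(signals, rb1) -> data.frame` (oracle stubs in tests).
#' @param snr_db noise level in dB.
#' @param seed integer seed for the noise draw.
#' @param forward `"exact"` or `"dbes"`.
#' @param dbes surrogate for `forward = "dbes"`.
#' @return `MetricTable` data.frame: one row per phantom with `param`,
#'   `nrmse`, `mae`; per-voxel estimates attached as attribute
#'   `"estimates"`.
#' @export
run_phantom_experiment <- function(phantoms, schedule, dtpq, snr_db = 46,
                                   seed = 1, forward = c("exact", "dbes"),
                                   dbes = NULL) {
  forward <- match.arg(forward)
  if (inherits(phantoms, "st_phantom")) phantoms <- list(phantoms)
  set.seed(seed)
  rows <- list(); est_all <- list()
  for (ph in phantoms) {
    tr <- phantom_truth(ph)
    S <- if (forward == "exact") simulate_signals(tr$tissue, schedule)
         else dbes_signals(dbes, tr$tissue, schedule)
    S <- add_noise(S, snr_db)
    est <- if (is.function(dtpq)) dtpq(S, tr$tissue[, "rb1"])
           else dtpq_predict(dtpq, S, tr$tissue[, "rb1"], schedule = schedule)
    e <- est[[ph$param]]
    t <- tr$tissue[, ph$param]
    rows[[ph$param]] <- data.frame(param = ph$param,
                                   nrmse = nrmse(e, t, param = ph$param),
                                   mae = mae(e, t))
    est_all[[ph$param]] <- list(estimates = est, truth = tr)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "estimates") <- est_all
  out
}

#' Synthesize signal maps from estimated parameter maps
#'
#' Forward-simulates every voxel of a set of estimated parameter maps under
#' a new schedule (the synthetic-MRI validation workflow). Parameters
#' missing from `maps` are filled from `defaults`.
#'
#' @param maps data.frame of per-voxel parameters (any subset of the 11
#'   canonical columns).
#' @param schedule the new `st_schedule` (any length).
#' @param defaults named list/1-row data.frame of fill-in values; defaults
#'   to the bound midpoints with `db0 = 0`, `rb1 = 1`.
#' @return matrix, one row per voxel and one column per scan.
#' @export
synthesize_from_maps <- function(maps, schedule, defaults = NULL) {
  if (is.null(defaults)) {
    defaults <- tissue_midpoint()
    defaults$db0 <- 0; defaults$rb1 <- 1
  }
  defaults <- as.data.frame(defaults)
  missing <- setdiff(.pt_names, names(maps))
  bad <- setdiff(missing, names(defaults))
  if (length(bad))
    stop("incomplete maps without defaults for: ", paste(bad, collapse = ", "))
  for (p in missing) maps[[p]] <- defaults[[p]]
  simulate_signals(maps, schedule)
}

#' End-to-end schedule comparison study
#'
#' The full desk-scale pipeline: train a surrogate, optimize a schedule
#' from a pseudo-random initialization, retrain an identical quantifier for
#' the optimized / pseudo-random / linear schedules (exact-simulator
#' forward model for fairness), and score all three on the eight digital
#' phantoms at a given SNR.
#'
#' @param seed integer master seed.
#' @param snr_db evaluation noise level in dB.
#' @param dbes_samples,dtpq_samples,loas_samples training-set sizes.
#' @param loas_epochs,dtpq_epochs training lengths.
#' @param dbes optionally a pre-trained surrogate to reuse.
#' @param verbose print progress.
#' @return list with the trained `dbes`, named `schedules`, `dtpqs`,
#'   per-schedule `metrics` (one MetricTable each), the LOAS `history`,
#'   and `summary` (average nRMSE per schedule).
#' @export
run_schedule_comparison <- function(seed = 1, snr_db = 46,
                                    dbes_samples = 1.5e5, dtpq_samples = 12000,
                                    loas_samples = 3072, loas_epochs = 32,
                                    dtpq_epochs = NULL, dbes = NULL,
                                    verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  if (is.null(dbes)) {
    say("training surrogate ...")
    dbes <- train_dbes(n_samples = dbes_samples, seed = seed,
                       preset = "small")
  }
  say("optimizing schedule ...")
  opt <- loas_optimize(dbes, init = "pr", n_samples = loas_samples,
                       seed = seed, epochs = loas_epochs)
  schedules <- list(loas = opt$schedule,
                    pr = pseudo_random_schedule(seed),
                    linear = linear_schedule())
  dtpqs <- lapply(names(schedules), function(nm) {
    say("training quantifier for ", nm, " ...")
    train_dtpq(schedules[[nm]], forward = "exact",
               n_samples = dtpq_samples, seed = seed, preset = "small",
               epochs = dtpq_epochs)
  })
  names(dtpqs) <- names(schedules)
  phantoms <- build_digital_phantoms(seed = seed)
  metrics <- lapply(names(schedules), function(nm) {
    say("evaluating ", nm, " ...")
    run_phantom_experiment(phantoms, schedules[[nm]], dtpqs[[nm]],
                           snr_db = snr_db, seed = seed + 17L)
  })
  names(metrics) <- names(schedules)
  summary <- data.frame(
    schedule = names(metrics),
    mean_nrmse = vapply(metrics, function(m) mean(m$nrmse), numeric(1)))
  list(dbes = dbes, schedules = schedules, dtpqs = dtpqs,
       metrics = metrics, history = opt$history, summary = summary)
}

#' Export parameter maps as NIfTI
#'
#' Writes per-voxel parameter estimates back onto a phantom grid and saves
#' one NIfTI volume per parameter (requires the RNifti package).
#'
#' @param estimates data.frame of per-voxel estimates.
#' @param voxels linear voxel indices into the grid.
#' @param dim grid dimensions (length 2).
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_parameter_maps <- function(estimates, voxels, dim, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(estimates), function(p) {
    img <- array(0, dim = c(dim, 1))
    img[cbind(arrayInd(voxels, dim), 1)] <- estimates[[p]]
    f <- file.path(dir, paste0(p, ".nii.gz"))
    RNifti::writeNifti(img, f)
    f
  }, character(1))
  invisible(paths)
}
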