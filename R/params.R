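# Tissue-parameter bounds, sampling and [0,1] normalization.

# Canonical tissue-parameter column order used everywhere in the package.
.pt_names <- c("t1w", "t1t2_ratio", "kmw", "m0m", "t2m", "dmw",
               "ksw", "m0s", "t2s", "db0", "rb1")

# Parameters estimated by the quantification network, in output order.
.ptq_names <- c("t1w", "kmw", "m0m", "t2m", "dmw", "ksw", "m0s", "db0")

#' Tissue-parameter sampling bounds
#'
#' Lower/upper bounds of the 11-entry tissue/field parameter vector used for
#' simulation, network training and normalization. Water T2 is represented
#' through the ratio T1w/T2w. T2s has no tabulated range and defaults to
#' 1--100 ms; the static-field offset range is narrower during schedule
#' optimization than during quantifier training, hence both are arguments.
#'
#' @param t2s_range length-2 numeric, solute T2 bounds in seconds.
#' @param db0_range length-2 numeric, static field offset bounds in Hz.
#' @return data.frame with columns `param`, `lower`, `upper`, `unit`.
#' @export
tissue_bounds <- function(t2s_range = c(0.001, 0.1),
                          db0_range = c(-128, 128)) {
  data.frame(
    param = .pt_names,
    lower = c(0.2, 1, 5, 0, 1, 0, 5, 0, t2s_range[1], db0_range[1], 0.5),
    upper = c(3.0, 30, 100, 27.5, 100, 5, 500, 550, t2s_range[2],
              db0_range[2], 1.5),
    unit = c("s", "-", "Hz", "M", "us", "ppm", "Hz", "mM", "s", "Hz", "-"),
    stringsAsFactors = FALSE
  )
}

#' Sample tissue-parameter sets
#'
#' Draws `n` tissue parameter vectors uniformly within the sampling bounds.
#' T2w is derived from the sampled T1w/T2w ratio and returned as an extra
#' `t2w` column for convenience.
#'
#' @param n number of parameter sets.
#' @param seed integer RNG seed (sampling is deterministic given the seed).
#' @param bounds bounds table from [tissue_bounds()].
#' @return data.frame with the 11 canonical columns plus `t2w` (seconds).
#' @export
sample_tissue_parameters <- function(n, seed = NULL, bounds = tissue_bounds()) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(lapply(seq_len(nrow(bounds)), function(i) {
    runif(n, bounds$lower[i], bounds$upper[i])
  }))
  names(out) <- bounds$param
  out$t2w <- out$t1w / out$t1t2_ratio
  out
}

# Coerce a tissue-parameter input (named vector, list, or data.frame) to an
# n x 11 numeric matrix in canonical column order.
as_tissue_matrix <- function(pt) {
  if (is.numeric(pt) && !is.matrix(pt)) pt <- as.data.frame(as.list(pt))
  pt <- as.data.frame(pt)
  missing <- setdiff(.pt_names, names(pt))
  if (length(missing))
    stop("missing tissue parameters: ", paste(missing, collapse = ", "))
  m <- as.matrix(pt[, .pt_names, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m[, "t1w"] <= 0) || any(m[, "t2s"] <= 0) || any(m[, "t2m"] <= 0))
    stop("relaxation times must be positive")
  if (any(m[, c("ksw", "kmw")] < 0) || any(m[, c("m0s", "m0m")] < 0))
    stop("exchange rates and pool sizes must be non-negative")
  m
}

# Midpoint of every bound: a convenient representative parameter set.
tissue_midpoint <- function(bounds = tissue_bounds()) {
  mid <- (bounds$lower + bounds$upper) / 2
  names(mid) <- bounds$param
  as.data.frame(as.list(mid))
}

#' Normalize / denormalize parameters to the unit interval
#'
#' Linear map of each column onto \[0, 1\] using the sampling bounds; used for
#' all network inputs and outputs.
#'
#' @param x matrix or data.frame whose columns are named parameters.
#' @param bounds bounds table from [tissue_bounds()].
#' @return numeric matrix of the same shape.
#' @export
normalize_params <- function(x, bounds = tissue_bounds()) {
  x <- as.matrix(as.data.frame(x))
  idx <- match(colnames(x), bounds$param)
  if (anyNA(idx)) stop("unknown parameter column")
  lo <- bounds$lower[idx]; hi <- bounds$upper[idx]
  sweep(sweep(x, 2, lo, "-"), 2, hi - lo, "/")
}

#' @rdname normalize_params
#' @export
denormalize_params <- function(x, bounds = tissue_bounds()) {
  x <- as.matrix(as.data.frame(x))
  idx <- match(colnames(x), bounds$param)
  if (anyNA(idx)) stop("unknown parameter column")
  lo <- bounds$lower[idx]; hi <- bounds$upper[idx]
  sweep(sweep(x, 2, hi - lo, "*"), 2, lo, "+")
}
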