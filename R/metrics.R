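# Accuracy metrics and compartment statistics.

#' Normalized root-mean-square error
#'
#' `100 * RMSE / norm`, where the normalizer defaults to the parameter's
#' sampling range (upper - lower); `norm = "truth"` uses the spread of the
#' ground-truth values instead.
#'
#' @param est,truth numeric vectors/matrices of equal shape.
#' @param param parameter name used to look up the range normalizer.
#' @param norm `"range"` or `"truth"`, or a positive number.
#' @param bounds tissue bounds table.
#' @return nRMSE in percent.
#' @export
nrmse <- function(est, truth, param = NULL, norm = "range",
                  bounds = tissue_bounds()) {
  stopifnot(length(est) == length(truth))
  denom <- if (is.numeric(norm)) norm
  else if (norm == "range") {
    i <- match(param, bounds$param)
    if (is.na(i)) stop("unknown parameter '", param, "'")
    bounds$upper[i] - bounds$lower[i]
  } else diff(range(truth))
  if (!is.finite(denom) || denom <= 0) stop("zero or invalid normalization range")
  100 * sqrt(mean((est - truth)^2)) / denom
}

#' Mean absolute error in native units
#'
#' @param est,truth numeric vectors/matrices of equal shape.
#' @return mean absolute deviation.
#' @export
mae <- function(est, truth) {
  stopifnot(length(est) == length(truth))
  mean(abs(est - truth))
}

#' Two-sample t-tests between adjacent compartments
#'
#' Two-sided Student's t-test for each pair of adjacent compartments of a
#' phantom estimate (significance conventionally at p < 0.05). Degenerate
#' zero-variance pairs are flagged with `NA`.
#'
#' @param values per-voxel estimates.
#' @param labels integer compartment label per voxel.
#' @return data.frame with `a`, `b` (compartment labels) and `p`.
#' @export
compare_adjacent_compartments <- function(values, labels) {
  comps <- sort(unique(labels))
  out <- data.frame(a = head(comps, -1), b = comps[-1], p = NA_real_)
  for (i in seq_len(nrow(out))) {
    x <- values[labels == out$a[i]]
    y <- values[labels == out$b[i]]
    if (sd(x) == 0 && sd(y) == 0) {
      warning("zero-variance compartments ", out$a[i], "/", out$b[i])
      next
    }
    out$p[i] <- t.test(x, y)$p.value
  }
  out
}
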