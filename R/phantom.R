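# Digital phantoms: 2-D ground-truth parameter maps with compartment masks.

# Compartment values of the eight single-parameter phantoms.
.phantom_values <- list(
  ksw = c(50, 150, 250, 350, 500),    # Hz
  m0s = c(1, 125, 250, 375, 500),     # mM
  kmw = c(5, 25, 50, 75, 100),        # Hz
  m0m = c(5, 10, 15, 20, 25),         # M
  t2m = c(1, 25, 50, 75, 100),        # us
  dmw = c(1, 2, 3, 4, 5),             # ppm
  t1w = c(0.2, 0.9, 1.6, 2.3, 3.0),   # s
  db0 = c(-80, -40, 0, 40, 80)        # Hz
)

# Five-disk mask on an n x n grid (geometry is cosmetic; metrics only use
# the labels).
disk_mask <- function(n = 64, radius = 10) {
  centers <- rbind(c(16, 16), c(48, 16), c(32, 32), c(16, 48), c(48, 48)) *
    n / 64
  mask <- matrix(0L, n, n)
  for (k in seq_len(nrow(centers))) {
    dx <- outer(seq_len(n) - centers[k, 1], rep(1, n))
    dy <- outer(rep(1, n), seq_len(n) - centers[k, 2])
    mask[dx^2 + dy^2 <= radius^2] <- k
  }
  mask
}

new_phantom <- function(param, values, mask, nuisance) {
  structure(list(param = param, values = values, mask = mask,
                 nuisance = nuisance), class = "st_phantom")
}

#' Build the eight single-parameter digital phantoms
#'
#' One phantom per quantified parameter (`ksw`, `m0s`, `kmw`, `m0m`, `t2m`,
#' `dmw`, `t1w`, `db0`). Each has five circular compartments carrying the
#' printed ground-truth values (e.g. 50/150/250/350/500 Hz for `ksw`,
#' -80..80 Hz for `db0`); the remaining tissue parameters are drawn once
#' per phantom from the sampling bounds (seeded) and held constant across
#' compartments. `rb1` is fixed at 1.
#'
#' @param seed integer RNG seed for the nuisance draws.
#' @param n grid side length.
#' @param radius compartment disk radius in pixels.
#' @param bounds tissue bounds table.
#' @return named list of eight `st_phantom` objects.
#' @export
build_digital_phantoms <- function(seed = 1, n = 64, radius = 10,
                                   bounds = tissue_bounds()) {
  set.seed(seed)
  mask <- disk_mask(n, radius)
  lapply(stats::setNames(nm = names(.phantom_values)), function(p) {
    nuis <- sample_tissue_parameters(1, seed = NULL, bounds = bounds)
    nuis$rb1 <- 1
    new_phantom(p, .phantom_values[[p]], mask, nuis)
  })
}

#' Build a precision phantom with finely stepped compartments
#'
#' Exchange rate from 50 to 500 Hz in 10 Hz increments (46 compartments) or
#' solute concentration from 10 to 500 mM in 10 mM increments (50
#' compartments); all other tissue parameters are randomized per
#' compartment within the sampling bounds (`rb1` fixed at 1). Compartments
#' are laid out as square blocks on a grid.
#'
#' @param param `"ksw"` or `"m0s"`.
#' @param seed integer RNG seed.
#' @param block compartment block side length in pixels.
#' @param bounds tissue bounds table.
#' @return an `st_phantom` whose `nuisance` has one row per compartment.
#' @export
build_precision_phantom <- function(param = c("ksw", "m0s"), seed = 1,
                                    block = 6, bounds = tissue_bounds()) {
  param <- match.arg(param)
  set.seed(seed)
  values <- if (param == "ksw") seq(50, 500, by = 10) else seq(10, 500, by = 10)
  k <- length(values)
  ncols <- ceiling(sqrt(k))
  nrows <- ceiling(k / ncols)
  mask <- matrix(0L, nrows * block, ncols * block)
  for (i in seq_len(k)) {
    r0 <- ((i - 1) %/% ncols) * block
    c0 <- ((i - 1) %% ncols) * block
    mask[r0 + seq_len(block), c0 + seq_len(block)] <- i
  }
  nuis <- sample_tissue_parameters(k, seed = NULL, bounds = bounds)
  nuis$rb1 <- 1
  new_phantom(param, values, mask, nuis)
}

# Ground-truth tissue matrix for every in-compartment voxel of a phantom.
# Returns the voxel linear indices, compartment labels and an n_voxel x 11
# tissue matrix.
phantom_truth <- function(ph) {
  vox <- which(ph$mask > 0)
  lab <- ph$mask[vox]
  nuis <- if (nrow(ph$nuisance) == 1)
    ph$nuisance[rep(1, length(ph$values)), , drop = FALSE] else ph$nuisance
  comp <- nuis
  comp[[ph$param]] <- ph$values
  comp$t2w <- comp$t1w / comp$t1t2_ratio
  list(voxels = vox, labels = lab,
       tissue = as_tissue_matrix(comp[lab, , drop = FALSE]),
       compartments = comp)
}
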