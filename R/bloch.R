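# Exact three-pool Bloch-McConnell forward model (transient closed form).

# Coerce scan parameters (named vector/list/data.frame with columns
# B1_uT, offset_ppm, Ts_s, Td_s -- or b1, offset, ts, td) to an m x 4 matrix.
as_scan_matrix <- function(ps) {
  if (is.numeric(ps) && !is.matrix(ps)) ps <- as.data.frame(as.list(ps))
  ps <- as.data.frame(ps)
  alias <- c(B1_uT = "b1", offset_ppm = "offset", Ts_s = "ts", Td_s = "td")
  for (a in names(alias))
    if (a %in% names(ps)) names(ps)[names(ps) == a] <- alias[[a]]
  need <- c("b1", "offset", "ts", "td")
  if (!all(need %in% names(ps)))
    stop("scan parameters need columns b1/offset/ts/td (or B1_uT/offset_ppm/Ts_s/Td_s)")
  m <- as.matrix(ps[, need, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m[, "ts"] <= 0) || any(m[, "td"] <= 0)) stop("Ts and Td must be positive")
  if (any(m[, "b1"] < 0)) stop("B1 must be non-negative")
  m
}

# RF offset from the semisolid resonance (Hz): semisolid sits at -dmw ppm
# and the whole spectrum is displaced by dB0.
semisolid_delta_hz <- function(offset_ppm, dmw_ppm, db0_hz) {
  (offset_ppm + dmw_ppm) * st_constants$hz_per_ppm - db0_hz
}

#' Build the Bloch-McConnell evolution system
#'
#' Assembles the 7x7 evolution matrix `A` (s^-1) and constant vector `B` for
#' one tissue/scan pair. State order: water x,y,z; solute x,y,z; semisolid z.
#' Exchange entries obey detailed balance (`kws = ksw * fs`, `kwm = kmw *
#' fm` with pool fractions relative to water at 111 M); the semisolid RF
#' saturation enters through the super-Lorentzian absorption rate.
#'
#' @param pt tissue parameters (named vector or 1-row data.frame with the
#'   canonical 11 columns, see [tissue_bounds()]).
#' @param ps scan parameters (`b1` uT, `offset` ppm, `ts` s, `td` s).
#' @return list with `A` (7x7 matrix), `B` (length-7 vector), `Meq`
#'   (equilibrium vector, water normalized to 1).
#' @export
build_system <- function(pt, ps) {
  ptm <- as_tissue_matrix(pt); psm <- as_scan_matrix(ps)
  stopifnot(nrow(ptm) == 1, nrow(psm) == 1)
  g <- super_lorentzian_lineshape(
    semisolid_delta_hz(psm[1, "offset"], ptm[1, "dmw"], ptm[1, "db0"]),
    ptm[1, "t2m"] * 1e-6)
  out <- bm_system_cpp(ptm[1, ], psm[1, ], g, st_constants$r1s, st_constants$r1m)
  ev <- eigen(out$A, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("evolution matrix is not stable; degenerate parameters")
  names(out$B) <- names(out$Meq) <-
    c("xw", "yw", "zw", "xs", "ys", "zs", "zm")
  dimnames(out$A) <- list(names(out$B), names(out$B))
  out
}

#' Magnetization at the end of saturation
#'
#' Exact transient solution
#' `M = expm(A Ts) (M0 (1 - exp(-R1w Td)) + A^-1 B) - A^-1 B`:
#' each dynamic scan starts from post-readout saturation recovery of the
#' longitudinal components (transverse spoiled to zero) and evolves under
#' continuous RF for `Ts` seconds via the matrix exponential.
#'
#' @inheritParams build_system
#' @return named length-7 magnetization vector (water Mz normalized so that
#'   equilibrium is 1).
#' @export
evolve <- function(pt, ps) {
  ptm <- as_tissue_matrix(pt); psm <- as_scan_matrix(ps)
  stopifnot(nrow(ptm) == 1, nrow(psm) == 1)
  g <- super_lorentzian_lineshape(
    semisolid_delta_hz(psm[1, "offset"], ptm[1, "dmw"], ptm[1, "db0"]),
    ptm[1, "t2m"] * 1e-6)
  M <- drop(bm_evolve_cpp(ptm[1, ], psm[1, ], g,
                          st_constants$r1s, st_constants$r1m))
  names(M) <- c("xw", "yw", "zw", "xs", "ys", "zs", "zm")
  M
}

#' Steady-state magnetization under continuous saturation
#'
#' The `-A^-1 B` term of the closed form: the fixed point of the evolution,
#' independent of the relaxation delay.
#'
#' @inheritParams build_system
#' @return named length-7 magnetization vector.
#' @export
steady_state <- function(pt, ps) {
  sys <- build_system(pt, ps)
  M <- drop(-solve(sys$A, sys$B))
  names(M) <- names(sys$B)
  M
}

#' Simulate a normalized ST-MRF signal vector
#'
#' Runs the exact transient solution independently for every scan of a
#' schedule and returns the magnitude of the water longitudinal
#' magnetization divided by its equilibrium value (S/S0 normalization; the
#' magnitude reflects magnitude-reconstructed images and matters only for
#' near-resonance scans, where strong RF can nutate water Mz through zero).
#'
#' @param pt a single tissue-parameter set.
#' @param schedule an `st_schedule` (or any scan-parameter table).
#' @return numeric vector of per-scan signals in \[0, 1\].
#' @seealso [simulate_signals()] for the batched many-tissues path.
#' @export
simulate_signal <- function(pt, schedule) {
  drop(simulate_signals(pt, schedule))
}

#' Batched signal synthesis
#'
#' @param pt tissue parameters, n rows.
#' @param schedule scan-parameter table, m rows.
#' @return n x m matrix of normalized signals.
#' @export
simulate_signals <- function(pt, schedule) {
  ptm <- as_tissue_matrix(pt); psm <- as_scan_matrix(schedule)
  offs <- matrix(psm[, "offset"], nrow(ptm), nrow(psm), byrow = TRUE)
  D <- semisolid_delta_hz(offs, ptm[, "dmw"], ptm[, "db0"])
  G <- sl_g_matrix(D, ptm[, "t2m"])
  abs(bm_signal_batch_cpp(ptm, psm, G, st_constants$r1s, st_constants$r1m))
}

# Paired synthesis: tissue row i with scan row i (network training sets).
simulate_signal_pairs <- function(pt, ps) {
  ptm <- as_tissue_matrix(pt); psm <- as_scan_matrix(ps)
  stopifnot(nrow(ptm) == nrow(psm))
  d <- semisolid_delta_hz(psm[, "offset"], ptm[, "dmw"], ptm[, "db0"])
  g <- drop(sl_g_matrix(matrix(d, ncol = 1), ptm[, "t2m"]))
  abs(drop(bm_signal_pairs_cpp(ptm, psm, g, st_constants$r1s, st_constants$r1m)))
}
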