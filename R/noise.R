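# Measurement-noise model for normalized ST-MRF signals.

# Noise standard deviation for an SNR in dB, relative to the unit
# (unsaturated S0) reference: sigma = 10^(-snr/20).
noise_sigma <- function(snr_db) 10^(-snr_db / 20)

#' Add white Gaussian noise to signal vectors
#'
#' Additive zero-mean Gaussian noise at a given SNR (dB) relative to the
#' unit-normalized S0 reference, i.e. `sigma = 10^(-snr_db/20)`; 40 dB maps
#' to sigma 0.01. An infinite SNR returns the input unchanged. When
#' `signals` is a matrix and `snr_db` a vector, each row gets its own noise
#' level.
#'
#' @param signals numeric vector or matrix (rows = signal vectors).
#' @param snr_db signal-to-noise ratio in dB (scalar or per-row vector).
#' @param seed optional integer seed for reproducibility.
#' @return object of the same shape with noise added.
#' @export
add_noise <- function(signals, snr_db, seed = NULL) {
  stopifnot(all(is.finite(snr_db) | is.infinite(snr_db)))
  if (!is.null(seed)) set.seed(seed)
  sig <- noise_sigma(snr_db)
  if (is.matrix(signals)) {
    sd_mat <- matrix(sig, nrow(signals), ncol(signals))
    signals + rnorm(length(signals), sd = 1) * sd_mat
  } else {
    signals + rnorm(length(signals), sd = 1) * sig
  }
}
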