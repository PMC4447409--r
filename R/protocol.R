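#' Default acquisition protocol
#'
#' Mirrors the emulated acquisitions: a 16-b-value single-shot EPI diffusion
#' protocol (0-800 s/mm^2 in steps of 50, skipping 750), a TWIST DCE series
#' of 75 frames with 5 pre-contrast baseline frames (3 s spacing, so 3.75 min
#' total), and a cine CT series of 90 frames at 1 s with 10 baseline frames.
#'
#' @param b_values diffusion weightings, s/mm^2; strictly increasing from 0.
#' @param dce_dt,dce_n_frames,dce_baseline_frames DCE grid: frame spacing
#'   (seconds), frame count, number of pre-contrast frames.
#' @param ct_dt,ct_n_frames,ct_baseline_frames CT grid, same meaning.
#' @param snr_dwi b=0 signal-to-noise ratio of the DWI acquisition; Rician
#'   noise is added with sigma = S0/snr_dwi. Use `Inf` to disable noise.
#' @param noise_sd_dce Gaussian noise SD on DCE tissue concentration (mM);
#'   `NA` (default) means 1 percent of each curve's peak.
#' @param noise_sd_ct Gaussian noise SD on CT enhancement curves (HU).
#' @return A list of class `acquisition_protocol`.
#' @export
#' @examples
#' p <- default_protocol()
#' length(p$b_values)   # 16
default_protocol <- function(b_values = c(seq(0, 700, by = 50), 800),
                             dce_dt = 3, dce_n_frames = 75,
                             dce_baseline_frames = 5,
                             ct_dt = 1, ct_n_frames = 90,
                             ct_baseline_frames = 10,
                             snr_dwi = 50,
                             noise_sd_dce = NA_real_,
                             noise_sd_ct = 2) {
  p <- list(
    b_values = as.numeric(b_values),
    dce_times = dce_dt * (seq_len(dce_n_frames) - 1L),
    dce_baseline_frames = as.integer(dce_baseline_frames),
    ct_times = ct_dt * (seq_len(ct_n_frames) - 1L),
    ct_baseline_frames = as.integer(ct_baseline_frames),
    snr_dwi = snr_dwi,
    noise_sd_dce = noise_sd_dce,
    noise_sd_ct = noise_sd_ct
  )
  class(p) <- "acquisition_protocol"
  validate_protocol(p)
}

validate_protocol <- function(p) {
  b <- p$b_values
  if (length(b) < 4 || b[1] != 0 || any(diff(b) <= 0))
    stop("b_values must be strictly increasing and start at 0")
  for (g in c("dce_times", "ct_times"))
    if (any(diff(p[[g]]) <= 0)) stop(g, " must be strictly increasing")
  if (p$dce_baseline_frames >= length(p$dce_times) ||
      p$ct_baseline_frames >= length(p$ct_times))
    stop("baseline frame counts must be smaller than the grid length")
  if (!(p$snr_dwi > 0)) stop("snr_dwi must be positive")
  if (!is.na(p$noise_sd_ct) && p$noise_sd_ct < 0)
    stop("noise_sd_ct must be non-negative")
  if (!is.na(p$noise_sd_dce) && p$noise_sd_dce < 0)
    stop("noise_sd_dce must be non-negative")
  invisible(p)
}

#' Rician magnitude noise
#'
#' Replaces each noise-free magnitude s by sqrt((s + n1)^2 + n2^2) with n1,
#' n2 independent zero-mean Gaussians of standard deviation `sigma` -- the
#' magnitude of a complex Gaussian, the noise model of magnitude MR images.
#' `sigma = 0` returns the input unchanged.
#'
#' @param signal non-negative numeric array or vector.
#' @param sigma noise standard deviation, >= 0.
#' @return Array of the same shape, all values >= 0.
#' @export
#' @examples
#' set.seed(1)
#' mean(rician(rep(0, 1e5), 1))  # ~ sqrt(pi / 2)
rician <- function(signal, sigma) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a single non-negative number")
  if (any(signal < 0)) stop("signal must be non-negative")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  attributes(out) <- attributes(signal)
  out
}
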