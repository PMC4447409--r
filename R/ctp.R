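# CT perfusion on time-density curves (baseline-subtracted enhancement, HU).
# The vendor kinetic model is a black box; this module defines one
# self-consistent scheme shared by simulator and estimators:
#   tissue(t) = (BV/100) * cp(t) + k * integral_0^t cp dtau,
#   k = (PMB/100) * BF / 100   [1/min]
# i.e. a blood-pool term plus unidirectional leakage (Patlak form). BF is
# estimated by the maximum-slope method, BV and k by the Patlak plot, and
# PMB back-solved from k given BF. PMB is carried on the percent-like scale
# of the ground-truth table (0-100), entering the model as PMB/100.

#' Gamma-variate CT arterial input (time-density) function
#'
#' Same functional form as [population_aif()] but on a seconds grid with HU
#' units. Defaults (onset 10 s after the baseline frames, alpha = 3,
#' beta = 6 s, peak 300 HU) describe a compact first-pass bolus whose
#' normalized maximum upslope max(cp')/max(cp) is ~0.097/s; the maximum-slope
#' BF estimator is consistent with the forward model for tumor-like
#' parameters under this shape (see the methods vignette).
#'
#' @param times seconds grid, strictly increasing from 0.
#' @param onset,alpha,beta,peak gamma-variate parameters (seconds / HU).
#' @return List of class `time_density_curve` with `times` (s), `hu`.
#' @export
ct_aif <- function(times, onset = 10, alpha = 3, beta = 6, peak = 300) {
  g <- population_aif(times, onset = onset, alpha = alpha, beta = beta,
                      peak = peak)
  structure(list(times = g$times, hu = g$cp), class = "time_density_curve")
}

#' CT perfusion parameter set
#'
#' @param BF blood flow, mL/100 mL/min, >= 0.
#' @param BV blood volume, mL/100 mL, >= 0.
#' @param PMB capillary permeability-surface measure on the reported 0-100
#'   scale, >= 0 (`PMB/100` is the extraction fraction in the model).
#' @return List of class `ct_perfusion_params`.
#' @export
ct_perfusion_params <- function(BF, BV, PMB) {
  if (any(c(BF, BV, PMB) < 0)) stop("BF, BV and PMB must be non-negative")
  structure(list(BF = BF, BV = BV, PMB = PMB), class = "ct_perfusion_params")
}

#' Forward CT tissue time-density curve
#'
#' tissue(t) = (BV/100) cp(t) + k * int_0^t cp dtau with the integral in
#' HU*min and k = (PMB/100)*BF/100 per minute. Deterministic.
#'
#' @param aif a [ct_aif()] time-density curve.
#' @param params a [ct_perfusion_params()].
#' @return A `time_density_curve`.
#' @export
ct_forward <- function(aif, params) {
  if (!inherits(params, "ct_perfusion_params"))
    params <- do.call(ct_perfusion_params, params)
  k <- leakage_constant(params$BF, params$PMB)
  cumint <- cumtrapz(aif$times, aif$hu) / 60  # HU * min
  hu <- (params$BV / 100) * aif$hu + k * cumint
  structure(list(times = aif$times, hu = hu), class = "time_density_curve")
}

leakage_constant <- function(BF, PMB) (PMB / 100) * BF / 100

#' Maximum-slope blood flow estimate
#'
#' BF = 100 * 60 * max(d tissue/dt) / max(cp), with the derivative taken by
#' central finite differences after 3-point moving-average smoothing of the
#' tissue curve. A flat (or decaying-only) tissue curve gives BF = 0.
#'
#' @param tissue,aif `time_density_curve`s on one shared seconds grid.
#' @return BF in mL/100 mL/min.
#' @export
estimate_bf_maxslope <- function(tissue, aif) {
  if (!isTRUE(all.equal(tissue$times, aif$times)))
    stop("tissue and aif must share one time grid")
  peak <- max(aif$hu)
  if (peak <= 0) stop("aif peak must be positive")
  y <- stats::filter(tissue$hu, rep(1 / 3, 3), sides = 2)
  y[is.na(y)] <- tissue$hu[is.na(y)]  # endpoints: unsmoothed
  t <- tissue$times
  n <- length(t)
  slope <- (y[-(1:2)] - y[1:(n - 2)]) / (t[-(1:2)] - t[1:(n - 2)])
  as.numeric(100 * 60 * max(0, max(slope)) / peak)
}

#' Patlak plot fit of a CT time-density curve
#'
#' Ordinary least squares of y = tissue(t)/cp(t) against
#' x = int_0^t cp dtau / cp(t) (integral in minutes) for t >= `t_start`
#' (default: the AIF peak time, where leakage dominates). Under the
#' [ct_forward()] model the plot is exactly linear: intercept = BV/100 and
#' slope = leakage constant k.
#'
#' @inheritParams estimate_bf_maxslope
#' @param t_start first time (seconds) used in the regression.
#' @return List with `BV` (mL/100 mL), `slope` (k, 1/min) and `r_squared`.
#' @export
fit_patlak <- function(tissue, aif, t_start = NULL) {
  if (!isTRUE(all.equal(tissue$times, aif$times)))
    stop("tissue and aif must share one time grid")
  if (is.null(t_start)) t_start <- aif$times[which.max(aif$hu)]
  keep <- tissue$times >= t_start & aif$hu > 0
  if (sum(keep) < 5) stop("need >= 5 frames after t_start with positive aif")
  cumint <- cumtrapz(aif$times, aif$hu) / 60
  x <- cumint[keep] / aif$hu[keep]
  y <- tissue$hu[keep] / aif$hu[keep]
  if (stats::sd(x) == 0) stop("singular Patlak design: constant regressor")
  fit <- stats::lm.fit(cbind(1, x), y)
  co <- fit$coefficients
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(BV = max(0, 100 * co[[1]]), slope = max(0, co[[2]]), r_squared = r2)
}

#' Estimate BF, BV and PMB from one tissue curve
#'
#' Combines [estimate_bf_maxslope()] (BF) and [fit_patlak()] (BV and the
#' leakage constant k); PMB = 1e4 * k / BF, 0 when BF is 0. All estimates
#' are clamped to be non-negative.
#'
#' @inheritParams fit_patlak
#' @return A [ct_perfusion_params()] plus `patlak_r_squared`.
#' @export
fit_ct_perfusion <- function(tissue, aif, t_start = NULL) {
  bf <- estimate_bf_maxslope(tissue, aif)
  pk <- fit_patlak(tissue, aif, t_start)
  pmb <- if (bf > 0) 1e4 * pk$slope / bf else 0
  out <- ct_perfusion_params(BF = bf, BV = pk$BV, PMB = pmb)
  out$patlak_r_squared <- pk$r_squared
  out
}
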