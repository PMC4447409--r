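# Standard (non-extended) Tofts two-compartment model of contrast exchange:
#   Ct(t) = Ktrans * integral_0^t Cp(tau) exp(-Kep (t - tau)) dtau,
#   Kep = Ktrans / Ve.
# The pipeline works on concentration curves directly; signal-to-
# concentration conversion (T1 mapping, relaxivity) is out of scope.

.tofts_bounds <- list(ktrans = c(0, 5), ve = c(1e-3, 1))

#' Population arterial input function (gamma-variate bolus)
#'
#' cp(t) = A (t - t0)^alpha exp(-(t - t0)/beta) for t > t0, else 0, with A
#' chosen so the peak (at t0 + alpha*beta) equals `peak`. Defaults describe a
#' typical small-animal gadolinium bolus: onset 0.25 min (15 s, after the 5
#' baseline frames), alpha = 3, beta = 0.15 min, peak plasma concentration
#' 5 mM.
#'
#' @param times time grid in minutes, strictly increasing from 0.
#' @param onset bolus arrival t0, minutes, within the grid.
#' @param alpha,beta gamma-variate shape (unitless) and scale (minutes), > 0.
#' @param peak peak plasma concentration, mM.
#' @return List of class `input_function` with `times` (min) and `cp` (mM).
#' @export
#' @examples
#' aif <- population_aif(seq(0, 3.7, by = 0.05))
#' aif$times[which.max(aif$cp)]  # ~ onset + alpha * beta
population_aif <- function(times, onset = 0.25, alpha = 3, beta = 0.15,
                           peak = 5) {
  if (alpha <= 0 || beta <= 0 || peak <= 0)
    stop("alpha, beta and peak must be positive")
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing starting at 0")
  if (onset < 0 || onset >= max(times)) stop("onset must lie within the grid")
  a_scale <- peak / ((alpha * beta)^alpha * exp(-alpha))
  dt <- pmax(times - onset, 0)
  cp <- a_scale * dt^alpha * exp(-dt / beta)
  cp[times <= onset] <- 0
  structure(list(times = times, cp = cp), class = "input_function")
}

# cumulative trapezoidal integral of y over x, same length as x
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Tofts forward model: tissue concentration from an AIF
#'
#' Computes Ct(t) = Ktrans * conv(Cp, exp(-Kep t)) by trapezoidal discrete
#' convolution on the AIF grid.
#'
#' @param aif an [population_aif()] object (times in minutes, cp in mM).
#' @param ktrans transfer constant, 1/min, >= 0.
#' @param ve extravascular extracellular volume fraction in (0, 1].
#' @return List of class `concentration_curve` with `times` and `ct`.
#' @export
tofts_concentration <- function(aif, ktrans, ve) {
  if (ve <= 0 || ve > 1) stop("ve must lie in (0, 1]")
  if (ktrans < 0) stop("ktrans must be non-negative")
  kep <- ktrans / ve
  t <- aif$times
  cp <- aif$cp
  n <- length(t)
  # Trapezoidal convolution via the exponential-kernel recursion
  #   I_i = e^{-kep dt} I_{i-1} + dt (cp_{i-1} e^{-kep dt} + cp_i) / 2,
  # algebraically identical to the full O(n^2) trapezoid but O(n).
  ct <- numeric(n)
  acc <- 0
  for (i in seq_len(n)[-1]) {
    dt <- t[i] - t[i - 1]
    ek <- exp(-kep * dt)
    acc <- acc * ek + dt * (cp[i - 1] * ek + cp[i]) / 2
    ct[i] <- acc
  }
  structure(list(times = t, ct = ktrans * ct), class = "concentration_curve")
}

#' Reflux constant from Ktrans and Ve
#'
#' @param ktrans transfer constant, 1/min.
#' @param ve EES volume fraction, > 0.
#' @return Kep = Ktrans / Ve, 1/min.
#' @export
kep_from <- function(ktrans, ve) {
  if (any(ve <= 0)) stop("ve must be positive")
  ktrans / ve
}

#' Fit the standard Tofts model to a tissue concentration curve
#'
#' Bounded two-parameter (Ktrans, Ve) nonlinear least squares against
#' [tofts_concentration()]; Kep is derived as Ktrans/Ve so the identity
#' Kep = Ktrans/Ve holds for every fitted result. Initialization: coarse
#' grid search over plausible (Ktrans, Ve). Non-convergence returns the best
#' point found with `converged = FALSE`.
#'
#' @param curve a `concentration_curve` sharing the AIF grid.
#' @param aif the driving [population_aif()].
#' @return List with `params` (list Ktrans, Ve, Kep) and `quality`.
#' @export
#' @examples
#' aif <- population_aif(seq(0, 3.7, by = 0.05))
#' cv <- tofts_concentration(aif, 0.13, 0.29)
#' fit_tofts(cv, aif)$params
fit_tofts <- function(curve, aif) {
  if (!isTRUE(all.equal(curve$times, aif$times)))
    stop("curve and aif must share one time grid")
  y <- curve$ct
  rss_fun <- function(kt, ve)
    sum((y - tofts_concentration(aif, kt, ve)$ct)^2)

  grid <- expand.grid(kt = c(0.01, 0.05, 0.1, 0.3, 1),
                      ve = c(0.05, 0.15, 0.3, 0.6))
  g_rss <- mapply(rss_fun, grid$kt, grid$ve)
  st <- grid[which.min(g_rss), ]

  model_fun <- function(kt, ve) tofts_concentration(aif, kt, ve)$ct
  # port reports non-convergence via convInfo; its warnings add nothing
  fit <- tryCatch(suppressWarnings(
    stats::nls(y ~ model_fun(kt, ve),
               data = list(y = y),
               start = list(kt = st$kt, ve = st$ve),
               lower = c(.tofts_bounds$ktrans[1], .tofts_bounds$ve[1]),
               upper = c(.tofts_bounds$ktrans[2], .tofts_bounds$ve[2]),
               algorithm = "port",
               control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                            minFactor = 1e-12,
                                            warnOnly = TRUE,
                                            scaleOffset = 1))),
    error = function(e) NULL)

  if (is.null(fit)) {
    kt <- st$kt; ve <- st$ve; ok <- FALSE
  } else {
    cf <- stats::coef(fit)
    kt <- cf[["kt"]]; ve <- cf[["ve"]]
    ok <- fit$convInfo$isConv
  }
  rss <- rss_fun(kt, ve)
  list(params = list(Ktrans = kt, Ve = ve, Kep = kep_from(kt, ve)),
       quality = new_fit_quality(rss, length(y), ok, "FULL"))
}
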