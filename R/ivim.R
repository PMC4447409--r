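# Bi-exponential intravoxel incoherent motion (IVIM) model:
#   S(b) = S0 * ( f * exp(-b * D*) + (1 - f) * exp(-b * D) )
# where f is the perfusion (pseudodiffusion) signal fraction, D the true
# tissue diffusion coefficient and D* the pseudodiffusion coefficient, both
# in mm^2/s with b in s/mm^2.

# Fit bounds (mm^2/s). D* lower bound sits just above the D upper bound so
# the two compartments cannot swap roles.
.ivim_bounds <- list(
  f = c(0, 1), D = c(1e-6, 3e-3), D_star = c(3e-3, 0.5)
)

#' IVIM parameter set
#'
#' @param S0 non-diffusion-weighted signal, > 0 (arbitrary units).
#' @param f perfusion fraction in \[0, 1\].
#' @param D true diffusion coefficient, mm^2/s, > 0.
#' @param D_star pseudodiffusion coefficient, mm^2/s, must exceed `D`.
#' @return A list of class `ivim_params`.
#' @export
ivim_params <- function(S0, f, D, D_star) {
  S0 <- unname(S0); f <- unname(f); D <- unname(D); D_star <- unname(D_star)
  p <- list(S0 = S0, f = f, D = D, D_star = D_star)
  if (!(is.finite(S0) && S0 > 0)) stop("S0 must be positive")
  if (!(f >= 0 && f <= 1)) stop("f must lie in [0, 1]")
  if (!(D > 0)) stop("D must be positive")
  if (!(D_star > D)) stop("D* must exceed D")
  structure(p, class = "ivim_params")
}

#' Evaluate the bi-exponential IVIM signal
#'
#' @param b b-value(s), s/mm^2, >= 0; vectorized.
#' @param params an [ivim_params()] object.
#' @return Signal at each `b`.
#' @export
#' @examples
#' ivim_signal(0, ivim_params(100, 0.2, 1e-3, 0.05))    # = S0
#' ivim_signal(800, ivim_params(100, 0, 1e-3, 0.05))    # = 100 * exp(-0.8)
ivim_signal <- function(b, params) {
  if (!inherits(params, "ivim_params"))
    params <- do.call(ivim_params, params)
  if (any(b < 0)) stop("b must be non-negative")
  params$S0 * (params$f * exp(-b * params$D_star) +
                 (1 - params$f) * exp(-b * params$D))
}

new_fit_quality <- function(rss, n_points, converged, algorithm) {
  structure(list(rss = rss, n_points = n_points, converged = converged,
                 algorithm = algorithm), class = "ivim_fit_quality")
}

ivim_rss <- function(theta, signals, b) {
  pred <- theta[1] * (theta[2] * exp(-b * theta[4]) +
                        (1 - theta[2]) * exp(-b * theta[3]))
  sum((signals - pred)^2)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Segmented (two-step) IVIM fit
#'
#' Classic segmented estimation: (1) log-linear fit of the high-b portion
#' (`b >= b_threshold`), where the pseudodiffusion compartment has decayed
#' away, gives `D` and the extrapolated intercept; (2) the perfusion fraction
#' is `f = 1 - intercept / S(0)`; (3) a one-dimensional bounded
#' least-squares search over the full curve, holding `S0`, `f`, `D`, gives
#' `D_star`. Degenerate input (flat or non-decaying signal) yields clamped
#' parameters with `converged = FALSE` rather than an error.
#'
#' @param signals positive signal at each b-value.
#' @param b_values s/mm^2, same length as `signals`.
#' @param b_threshold split point, s/mm^2 (default 200: a perfusion
#'   compartment with D* >= 0.06 mm^2/s has decayed by e^-12 there).
#' @return List with elements `params` ([ivim_params()]) and `quality`.
#' @export
fit_ivim_segmented <- function(signals, b_values, b_threshold = 200) {
  if (length(signals) != length(b_values))
    stop("signals and b_values must have equal length")
  if (any(signals <= 0))
    stop("fit error: signals must be positive (log-linear step)")
  hi <- b_values >= b_threshold
  lo <- !hi
  if (sum(hi) < 3 || sum(lo) < 2)
    stop("fit error: need >= 3 b-values above and >= 2 below b_threshold")

  s0_meas <- mean(signals[b_values == 0])
  if (!is.finite(s0_meas)) s0_meas <- signals[which.min(b_values)]

  ls <- log(signals[hi])
  co <- stats::lm.fit(cbind(1, b_values[hi]), ls)$coefficients
  d_hat <- clip(-co[2], .ivim_bounds$D[1], .ivim_bounds$D[2])
  converged <- is.finite(co[2]) && -co[2] > .ivim_bounds$D[1] &&
    -co[2] < .ivim_bounds$D[2]

  f_hat <- clip(1 - exp(co[1]) / s0_meas, .ivim_bounds$f[1], .ivim_bounds$f[2])

  ds_rng <- .ivim_bounds$D_star
  ds_rng[1] <- max(ds_rng[1], d_hat * (1 + 1e-6))
  if (f_hat > 0) {
    opt <- stats::optimize(function(ds)
      ivim_rss(c(s0_meas, f_hat, d_hat, ds), signals, b_values),
      interval = ds_rng, tol = 1e-12)
    ds_hat <- opt$minimum
  } else {
    ds_hat <- ds_rng[1] * 2  # f = 0: D* unidentifiable, any valid value
  }

  params <- ivim_params(s0_meas, f_hat, d_hat, ds_hat)
  rss <- ivim_rss(c(s0_meas, f_hat, d_hat, ds_hat), signals, b_values)
  list(params = params,
       quality = new_fit_quality(rss, length(signals), converged, "SEGMENTED"))
}

# Variable-projection grid search: for fixed (D, D*) the model is linear in
# the amplitudes (S0*f, S0*(1-f)); solving that 2x2 system over a coarse
# (D, D*) grid gives a robust global starting point when the segmented
# initializer fails (e.g. D* close to D, where the high-b log-linear step is
# contaminated by the perfusion compartment).
ivim_vp_candidate <- function(signals, b) {
  d_grid <- c(0.2, 0.4, 0.7, 1.0, 1.5, 2.2, 2.9) * 1e-3
  ds_grid <- c(3.5e-3, 6e-3, 0.01, 0.02, 0.04, 0.07, 0.12, 0.25, 0.45)
  best <- NULL
  for (d in d_grid) {
    e2 <- exp(-b * d)
    for (ds in ds_grid) {
      if (ds <= d) next
      e1 <- exp(-b * ds)
      xtx <- rbind(c(sum(e1 * e1), sum(e1 * e2)),
                   c(sum(e1 * e2), sum(e2 * e2)))
      xty <- c(sum(e1 * signals), sum(e2 * signals))
      a <- tryCatch(solve(xtx, xty), error = function(e) NULL)
      if (is.null(a)) next
      a <- pmax(a, 0)
      if (sum(a) <= 0) next
      rss <- sum((signals - a[1] * e1 - a[2] * e2)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, S0 = sum(a), f = a[1] / sum(a),
                     D = d, D_star = ds)
    }
  }
  best
}

# Projected Levenberg-Marquardt on the scaled parameter vector
# theta = (S0/s_ref, f, D*1e3, D**10) with analytic Jacobian; box bounds are
# enforced by clipping trial steps. Returns list(th, rss, ok) with th on the
# natural scale (S0, f, D, D*), or NULL on degenerate input.
ivim_lm <- function(signals, b, start, maxit = 200) {
  s_ref <- max(signals)
  if (!(s_ref > 0)) return(NULL)
  sc <- c(s_ref, 1, 1e-3, 0.1)                 # natural = theta * sc
  lower <- c(1e-9, .ivim_bounds$f[1], .ivim_bounds$D[1], .ivim_bounds$D_star[1]) / sc
  upper <- c(Inf, .ivim_bounds$f[2], .ivim_bounds$D[2], .ivim_bounds$D_star[2]) / sc
  th <- clip(start / sc, lower, upper)
  resid_j <- function(th) {
    S0 <- th[1] * sc[1]; f <- th[2]; D <- th[3] * sc[3]; Ds <- th[4] * sc[4]
    e1 <- exp(-b * Ds); e2 <- exp(-b * D)
    pred <- S0 * (f * e1 + (1 - f) * e2)
    J <- cbind((f * e1 + (1 - f) * e2) * sc[1],
               S0 * (e1 - e2),
               -b * S0 * (1 - f) * e2 * sc[3],
               -b * S0 * f * e1 * sc[4])
    list(r = signals - pred, J = J)
  }
  rj <- resid_j(th)
  rss <- sum(rj$r^2)
  lambda <- 1e-3
  ok <- FALSE
  for (it in seq_len(maxit)) {
    g <- crossprod(rj$J, rj$r)                  # gradient/2 of -rss
    A <- crossprod(rj$J)
    step <- tryCatch(solve(A + lambda * diag(diag(A) + 1e-12), g),
                     error = function(e) NULL)
    if (is.null(step)) { lambda <- lambda * 10; next }
    th_new <- clip(th + as.numeric(step), lower, upper)
    rj_new <- resid_j(th_new)
    rss_new <- sum(rj_new$r^2)
    if (rss_new < rss) {
      moved <- max(abs(th_new - th) / pmax(abs(th), 1e-8))
      improved <- rss - rss_new
      th <- th_new; rj <- rj_new; rss <- rss_new
      lambda <- max(lambda * 0.3, 1e-12)
      if (improved <= 1e-14 * (rss + 1e-300) || moved < 1e-12) { ok <- TRUE; break }
    } else {
      lambda <- lambda * 5
      if (lambda > 1e12) { ok <- TRUE; break }  # stationary within bounds
    }
  }
  list(th = th * sc, rss = rss, ok = ok)
}

#' Full four-parameter IVIM fit
#'
#' Bounded nonlinear least squares on all of (S0, f, D, D*), initialized from
#' `init` (typically the segmented result), via a projected
#' Levenberg-Marquardt descent with analytic Jacobian on internally scaled
#' parameters, followed by a variable-projection grid restart whenever the
#' grid finds a basin the local descent missed. On non-convergence the best
#' iterate is returned with `converged = FALSE`; the returned RSS is never
#' worse than that of `init`.
#'
#' @inheritParams fit_ivim_segmented
#' @param init an [ivim_params()] starting point.
#' @return List with `params` and `quality` as in [fit_ivim_segmented()].
#' @export
fit_ivim_full <- function(signals, b_values, init) {
  if (!inherits(init, "ivim_params")) init <- do.call(ivim_params, init)
  rss0 <- ivim_rss(c(init$S0, init$f, init$D, init$D_star), signals, b_values)
  best <- list(th = c(init$S0, init$f, init$D, init$D_star), rss = rss0,
               ok = FALSE)
  r1 <- ivim_lm(signals, b_values, best$th)
  if (!is.null(r1) && r1$rss <= best$rss) best <- r1
  # global restart from the variable-projection grid when it finds a
  # basin the local descent missed
  cand <- ivim_vp_candidate(signals, b_values)
  if (!is.null(cand) && cand$rss < best$rss) {
    r2 <- ivim_lm(signals, b_values, c(cand$S0, cand$f, cand$D, cand$D_star))
    if (!is.null(r2) && r2$rss < best$rss) best <- r2
  }
  th <- best$th
  rss <- best$rss
  ok <- best$ok && rss <= rss0 + 1e-12
  # keep D* strictly above D even when both hit adjacent bounds
  if (th[4] <= th[3]) th[4] <- th[3] * (1 + 1e-9)
  params <- ivim_params(th[1], th[2], th[3], th[4])
  list(params = params,
       quality = new_fit_quality(rss, length(signals), ok, "FULL"))
}

#' Segmented-then-full IVIM fit of one signal decay curve
#'
#' @inheritParams fit_ivim_segmented
#' @return As [fit_ivim_full()].
#' @export
fit_ivim <- function(signals, b_values, b_threshold = 200) {
  seg <- fit_ivim_segmented(signals, b_values, b_threshold)
  full <- fit_ivim_full(signals, b_values, seg$params)
  if (!seg$quality$converged) full$quality$converged <- full$quality$converged && seg$quality$converged
  full
}

#' Voxelwise IVIM fitting of a 4D volume
#'
#' Applies [fit_ivim()] to every voxel where `mask` is `TRUE`, producing
#' parameter maps on a pixel-by-pixel basis. Degenerate voxels yield clamped
#' values (never an abort); unmasked voxels are `NA`.
#'
#' @param dwi 4D array (x, y, z, b).
#' @param b_values b-values matching the 4th dimension.
#' @param mask 3D logical (or 0/1) array matching the spatial dimensions.
#' @param b_threshold see [fit_ivim_segmented()].
#' @return List of class `ivim_maps` with 3D arrays `f_map`, `D_map`,
#'   `Dstar_map`, `S0_map`, logical `mask`, and `n_converged`.
#' @export
fit_ivim_volume <- function(dwi, b_values, mask, b_threshold = 200) {
  dm <- dim(dwi)
  if (length(dm) != 4 || dm[4] != length(b_values))
    stop("dwi must be 4D with 4th dimension matching b_values (",
         dm[4], " vs ", length(b_values), ")")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dm[1:3]))
    stop("mask shape must match the spatial dimensions of dwi")
  shp <- dm[1:3]
  empty <- array(NA_real_, dim = shp)
  maps <- list(f_map = empty, D_map = empty, Dstar_map = empty,
               S0_map = empty, mask = mask, n_converged = 0L)
  idx <- which(mask)
  if (length(idx)) {
    nvox <- prod(shp)
    sig <- matrix(dwi, nrow = nvox)[idx, , drop = FALSE]
    for (k in seq_along(idx)) {
      fit <- tryCatch(fit_ivim(sig[k, ], b_values, b_threshold),
                      error = function(e) NULL)
      if (is.null(fit)) next
      i <- idx[k]
      maps$f_map[i] <- fit$params$f
      maps$D_map[i] <- fit$params$D
      maps$Dstar_map[i] <- fit$params$D_star
      maps$S0_map[i] <- fit$params$S0
      maps$n_converged <- maps$n_converged + as.integer(fit$quality$converged)
    }
  }
  class(maps) <- "ivim_maps"
  maps
}
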