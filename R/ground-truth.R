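#' Tissue classes and mask codes
#'
#' Four region-of-interest classes are analysed: the coagulation-necrosis
#' core created by radiofrequency ablation (`T_RFA`), the residual unablated
#' tumor rim (`T_RESIDUAL`), the contralateral untreated tumor (`T_CONTROL`)
#' and normal muscle (`NORMAL`). Integer mask codes 1-4 identify them in
#' label volumes.
#'
#' @return Named integer vector of mask codes.
#' @export
#' @examples
#' tissue_classes()
tissue_classes <- function() {
  c(T_RFA = 1L, T_RESIDUAL = 2L, T_CONTROL = 3L, NORMAL = 4L)
}

#' @rdname tissue_classes
#' @export
time_phases <- function() c("BEFORE", "AFTER")

#' Parameter names carried by the ground-truth table
#' @keywords internal
gt_parameters <- function() {
  c("f", "D", "D_star", "Ktrans", "Ve", "Kep", "BF", "BV", "PMB")
}

#' Default ground-truth parameter table
#'
#' Per-class, per-phase means and standard deviations of the nine imaging
#' parameters in the rabbit VX2 ablation experiment the generator emulates:
#' IVIM perfusion fraction `f`, true diffusion coefficient `D` (mm^2/s,
#' stored already scaled by 1e-3 from its conventional printed units),
#' pseudodiffusion coefficient `D_star` (mm^2/s), Tofts `Ktrans` (1/min),
#' `Ve` (fraction), `Kep` (1/min), CT-perfusion blood flow `BF`
#' (mL/100 mL/min), blood volume `BV` (mL/100 mL) and the capillary
#' permeability-surface measure `PMB` (percent-like scale as reported; the
#' CT forward model uses `PMB/100` as an extraction fraction).
#'
#' @return A data.frame with columns `class`, `phase`, `param`, `mean`, `sd`.
#' @export
#' @examples
#' gt <- default_ground_truth()
#' gt_lookup(gt, "T_RFA", "AFTER", "f")
default_ground_truth <- function() {
  cls <- names(tissue_classes())
  # rows: parameter; columns: T_RFA.B, T_RFA.A, T_RES.B, T_RES.A,
  #                           T_CTRL.B, T_CTRL.A, NORM.B, NORM.A
  mean_tab <- rbind(
    f      = c(0.29, 0.15, 0.29, 0.42, 0.31, 0.30, 0.12, 0.12),
    D      = c(0.61, 0.92, 0.75, 0.79, 0.70, 0.71, 0.94, 0.90) * 1e-3,
    D_star = c(0.13, 0.06, 0.12, 0.11, 0.11, 0.10, 0.11, 0.11),
    Ktrans = c(0.13, 0.02, 0.11, 0.14, 0.13, 0.11, 0.05, 0.04),
    Ve     = c(0.29, 0.06, 0.28, 0.49, 0.31, 0.30, 0.18, 0.17),
    Kep    = c(0.50, 0.12, 0.49, 0.51, 0.53, 0.49, 0.20, 0.24),
    BF     = c(33.48, 0.87, 33.31, 35.91, 34.20, 33.10, 0.56, 0.03),
    BV     = c(5.61, 0.93, 4.91, 8.03, 5.66, 5.88, 3.98, 3.41),
    PMB    = c(17.72, 0.68, 15.53, 16.23, 17.37, 16.18, 1.06, 0.91)
  )
  sd_tab <- rbind(
    f      = c(0.05, 0.04, 0.04, 0.03, 0.03, 0.02, 0.04, 0.02),
    D      = c(0.15, 0.04, 0.15, 0.40, 0.01, 0.01, 0.03, 0.02) * 1e-3,
    D_star = c(0.03, 0.02, 0.09, 0.08, 0.07, 0.08, 0.06, 0.04),
    Ktrans = c(0.05, 0.02, 0.05, 0.09, 0.12, 0.10, 0.01, 0.02),
    Ve     = c(0.08, 0.71, 0.06, 0.02, 0.14, 0.16, 0.02, 0.04),
    Kep    = c(0.14, 0.22, 0.12, 0.09, 0.20, 0.18, 0.05, 0.27),
    BF     = c(18.12, 1.87, 9.92, 3.33, 16.34, 8.54, 0.15, 0.27),
    BV     = c(1.10, 1.10, 1.17, 2.72, 1.88, 1.49, 0.67, 0.57),
    PMB    = c(7.97, 1.20, 3.22, 6.57, 7.30, 6.29, 0.75, 0.43)
  )
  grid <- expand.grid(phase = time_phases(), class = cls,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(rownames(mean_tab), function(p) {
    data.frame(class = grid$class, phase = grid$phase, param = p,
               mean = mean_tab[p, ], sd = sd_tab[p, ],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  validate_ground_truth(out)
  class(out) <- c("ground_truth", "data.frame")
  out
}

validate_ground_truth <- function(gt) {
  stopifnot(all(c("class", "phase", "param", "mean", "sd") %in% names(gt)))
  if (!all(is.finite(gt$mean)) || !all(is.finite(gt$sd)) || any(gt$sd < 0))
    stop("ground truth means/SDs must be finite with non-negative SDs")
  frac <- gt$param %in% c("f", "Ve")
  if (any(gt$mean[frac] < 0 | gt$mean[frac] > 1))
    stop("f and Ve means must lie in [0, 1]")
  if (any(gt$mean[gt$param %in% c("PMB", "Kep", "D", "D_star", "BF", "BV")] < 0))
    stop("scale parameters must have non-negative means")
  tumor <- gt$class %in% c("T_RFA", "T_RESIDUAL", "T_CONTROL")
  d <- gt[gt$param == "D" & tumor, ]
  ds <- gt[gt$param == "D_star" & tumor, ]
  key <- function(x) paste(x$class, x$phase)
  if (!all(ds$mean[match(key(d), key(ds))] > d$mean))
    stop("D* mean must exceed D mean in tumor classes")
  invisible(gt)
}

#' Look up one ground-truth entry
#'
#' @param gt table from [default_ground_truth()].
#' @param class one of `names(tissue_classes())`.
#' @param phase `"BEFORE"` or `"AFTER"`.
#' @param param parameter name; see [default_ground_truth()].
#' @return A list with elements `mean` and `sd`.
#' @export
gt_lookup <- function(gt, class, phase, param) {
  i <- which(gt$class == class & gt$phase == phase & gt$param == param)
  if (length(i) != 1L)
    stop(sprintf("no ground-truth entry for (%s, %s, %s)", class, phase, param))
  list(mean = gt$mean[i], sd = gt$sd[i])
}

# Validity range used both when clipping Gaussian draws and as fit bounds.
param_clip_range <- function(param) {
  switch(param,
    f = , Ve = c(0.001, 0.999),
    D = c(1e-6, 3e-3),
    D_star = c(3.001e-3, 0.5),
    c(1e-6, Inf)
  )
}

#' Draw subject-level parameter values from the ground-truth table
#'
#' Values are Gaussian(mean, SD), then clipped to the parameter's validity
#' range (`f`, `Ve` to \[0.001, 0.999\]; `D` to \[1e-6, 3e-3\]; `D_star` to
#' \[3.001e-3, 0.5\] mm^2/s; other positive-scale parameters to >= 1e-6).
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @inheritParams gt_lookup
#' @param n number of independent draws.
#' @return Numeric vector of length `n`.
#' @export
draw_parameter <- function(gt, class, phase, param, n) {
  e <- gt_lookup(gt, class, phase, param)
  r <- param_clip_range(param)
  pmin(pmax(stats::rnorm(n, e$mean, e$sd), r[1]), r[2])
}
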