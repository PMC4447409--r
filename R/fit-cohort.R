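# Subject-level fitting: turn a simulated (or loaded) subject into tidy
# ROI-level parameter estimates, the unit of analysis for all statistics.

#' Fit the IVIM model to an ROI-averaged signal decay
#'
#' Averages the DWI signal over all voxels of one labelled region at each
#' b-value, then runs the segmented-then-full fit on that single decay.
#' Averaging ~100 voxels raises the effective SNR by an order of magnitude,
#' which is what makes the pseudodiffusion coefficient D* estimable at
#' acquisition SNR; per-voxel D* estimates at SNR ~50 are medians-stable but
#' mean-unstable (see the methods vignette).
#'
#' @param dwi 4D array (x, y, z, b).
#' @param b_values b-values matching the 4th dimension.
#' @param labels 3D integer label volume.
#' @param code mask code of the region to average.
#' @param b_threshold segmented-fit split point, s/mm^2.
#' @return As [fit_ivim()], plus `n_voxels`.
#' @export
fit_ivim_roi <- function(dwi, b_values, labels, code, b_threshold = 200) {
  dm <- dim(dwi)
  if (length(dm) != 4 || dm[4] != length(b_values))
    stop("dwi must be 4D with 4th dimension matching b_values")
  idx <- which(labels == code)
  if (!length(idx)) stop("mask code ", code, " absent from labels")
  m <- matrix(dwi, nrow = prod(dm[1:3]))[idx, , drop = FALSE]
  fit <- fit_ivim(colMeans(m), b_values, b_threshold)
  fit$n_voxels <- length(idx)
  fit
}

#' Fit all modalities of one subject
#'
#' IVIM parameters are fitted per phase on the ROI-averaged decay of each
#' labelled class ([fit_ivim_roi()]; the ROI-based analysis the low SNR of
#' multi-b DWI dictates); Tofts and CT-perfusion parameters are fitted on
#' the per-class ROI curves. Returns one row per class x phase x parameter.
#'
#' @param subject a `subject_dataset` from [simulate_subject()].
#' @param b_threshold segmented-fit split point, s/mm^2.
#' @return Tidy data.frame: `subject`, `class`, `phase`, `param`, `value`.
#' @export
fit_subject <- function(subject, b_threshold = 200) {
  codes <- tissue_classes()
  present <- names(codes)[codes %in% unique(as.vector(subject$labels))]
  proto <- subject$protocol
  rows <- list()
  add <- function(cl, ph, param, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = subject$subject_id, class = cl, phase = ph,
      param = param, value = as.numeric(value), stringsAsFactors = FALSE)
  }

  for (ph in names(subject$dwi)) {
    for (cl in present) {
      fit <- fit_ivim_roi(subject$dwi[[ph]], proto$b_values, subject$labels,
                          codes[[cl]], b_threshold)
      add(cl, ph, "f", fit$params$f)
      add(cl, ph, "D", fit$params$D)
      add(cl, ph, "D_star", fit$params$D_star)
    }
  }

  for (i in seq_len(nrow(unique(subject$dce_curves[, c("class", "phase")])))) {
    key <- unique(subject$dce_curves[, c("class", "phase")])[i, ]
    sel <- subject$dce_curves$class == key$class &
      subject$dce_curves$phase == key$phase
    cv <- structure(list(times = subject$dce_curves$time_s[sel] / 60,
                         ct = subject$dce_curves$value[sel]),
                    class = "concentration_curve")
    fit <- fit_tofts(cv, subject$aif_mr)
    for (p in c("Ktrans", "Ve", "Kep")) add(key$class, key$phase, p,
                                            fit$params[[p]])
  }

  keys <- unique(subject$ct_curves[, c("class", "phase")])
  for (i in seq_len(nrow(keys))) {
    key <- keys[i, ]
    sel <- subject$ct_curves$class == key$class &
      subject$ct_curves$phase == key$phase
    tdc <- structure(list(times = subject$ct_curves$time_s[sel],
                          hu = subject$ct_curves$value[sel]),
                     class = "time_density_curve")
    fit <- fit_ct_perfusion(tdc, subject$aif_ct)
    for (p in c("BF", "BV", "PMB")) add(key$class, key$phase, p, fit[[p]])
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit every subject of a cohort
#'
#' @param cohort a `phantom_cohort` from [simulate_cohort()].
#' @inheritParams fit_subject
#' @return Row-bound tidy fits of all subjects (see [fit_subject()]).
#' @export
fit_cohort <- function(cohort, b_threshold = 200) {
  out <- do.call(rbind, lapply(cohort, fit_subject, b_threshold = b_threshold))
  rownames(out) <- NULL
  out
}
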