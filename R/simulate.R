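# Synthetic phantom cohort: one simulated animal carries a shared label
# volume, a 4D DWI stack per phase (BEFORE/AFTER ablation), and per-class
# ROI-level DCE concentration and CT time-density curves per phase, all
# generated from the ground-truth table by the package's own forward models.

.default_s0 <- 100  # arbitrary b=0 signal units, identical across classes

#' Simulate one phantom subject
#'
#' For each tissue class and phase, parameters are either fixed at the
#' ground-truth means (`FIXED_MEAN`) or drawn Gaussian(mean, SD) and clipped
#' to validity ranges (`SAMPLED`, see [draw_parameter()]). DWI voxel signals
#' follow the bi-exponential IVIM model with Rician noise at
#' sigma = S0/snr_dwi; DCE curves follow the Tofts forward model driven by
#' the shared MR input function plus Gaussian noise; CT curves follow the
#' Patlak-type forward model plus Gaussian noise. Kep is derived as
#' Ktrans/Ve from the realized draws. The realized parameters are recorded
#' in `$truth`.
#'
#' @param truth ground-truth table, see [default_ground_truth()].
#' @param protocol an [default_protocol()] object.
#' @param geometry list of [ellipsoid_spec()]; see [default_geometry()].
#' @param shape 3D grid dimensions for the label volume.
#' @param sampling_mode `"FIXED_MEAN"` or `"SAMPLED"`.
#' @param seed integer seed; required in `SAMPLED` mode, also used for the
#'   noise draws. `NULL` is allowed only in FIXED_MEAN mode with noise
#'   disabled.
#' @param subject_id identifier stored in the dataset.
#' @return A list of class `subject_dataset` with elements `subject_id`,
#'   `labels`, `dwi` (list BEFORE/AFTER of 4D arrays), `dce_curves` and
#'   `ct_curves` (tidy data.frames), `aif_mr`, `aif_ct`, `truth` (realized
#'   per class x phase parameter data.frame) and `protocol`.
#' @export
simulate_subject <- function(truth = default_ground_truth(),
                             protocol = default_protocol(),
                             geometry = default_geometry(),
                             shape = c(32L, 32L, 16L),
                             sampling_mode = c("FIXED_MEAN", "SAMPLED"),
                             seed = NULL,
                             subject_id = "subj01") {
  sampling_mode <- match.arg(sampling_mode)
  validate_protocol(protocol)
  noisy <- is.finite(protocol$snr_dwi) ||
    (!is.na(protocol$noise_sd_ct) && protocol$noise_sd_ct > 0)
  if (is.null(seed)) {
    if (sampling_mode == "SAMPLED")
      stop("seed is required in SAMPLED mode")
    if (noisy) stop("seed is required when noise is enabled")
    seed <- 0L
  }

  withr::with_seed(as.integer(seed), {
    labels <- make_label_volume(shape, geometry)
    codes <- tissue_classes()
    present <- names(codes)[codes %in% unique(as.vector(labels))]

    # realized per-class x phase parameters
    realized <- do.call(rbind, lapply(present, function(cl) {
      do.call(rbind, lapply(time_phases(), function(ph) {
        vals <- vapply(gt_parameters(), function(p) {
          if (sampling_mode == "FIXED_MEAN") gt_lookup(truth, cl, ph, p)$mean
          else draw_parameter(truth, cl, ph, p, 1)
        }, numeric(1))
        # IVIM validity and the Tofts identity on the realized values
        rng <- param_clip_range("D_star")
        vals["D_star"] <- max(vals["D_star"], vals["D"] * (1 + 1e-6), rng[1])
        vals["Kep"] <- kep_from(vals["Ktrans"], vals["Ve"])
        data.frame(subject = subject_id, class = cl, phase = ph,
                   t(vals), S0 = .default_s0,
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    }))

    mr_times_min <- protocol$dce_times / 60
    onset_mr <- protocol$dce_times[protocol$dce_baseline_frames + 1L] / 60
    aif_mr <- population_aif(mr_times_min, onset = onset_mr)
    onset_ct <- protocol$ct_times[protocol$ct_baseline_frames + 1L]
    aif_ct <- ct_aif(protocol$ct_times, onset = onset_ct)

    sigma_dwi <- if (is.finite(protocol$snr_dwi)) .default_s0 / protocol$snr_dwi else 0

    dwi <- lapply(stats::setNames(time_phases(), time_phases()), function(ph) {
      vol <- array(0, dim = c(dim(labels), length(protocol$b_values)))
      nvox <- prod(dim(labels))
      m <- matrix(vol, nrow = nvox)
      for (cl in present) {
        r <- realized[realized$class == cl & realized$phase == ph, ]
        sig <- ivim_signal(protocol$b_values,
                           ivim_params(r$S0, r$f, r$D, r$D_star))
        idx <- which(labels == codes[[cl]])
        m[idx, ] <- matrix(sig, nrow = length(idx), ncol = length(sig),
                           byrow = TRUE)
      }
      m <- rician(m, sigma_dwi)
      array(m, dim = c(dim(labels), length(protocol$b_values)))
    })

    curve_rows <- function(cl, ph, times, value, modality) {
      data.frame(subject = subject_id, class = cl, phase = ph,
                 time_s = times, value = value, modality = modality,
                 stringsAsFactors = FALSE)
    }
    dce_curves <- do.call(rbind, lapply(seq_len(nrow(realized)), function(i) {
      r <- realized[i, ]
      ct <- tofts_concentration(aif_mr, r$Ktrans, r$Ve)$ct
      sd_dce <- protocol$noise_sd_dce
      if (is.na(sd_dce)) sd_dce <- 0.01 * max(ct)
      if (sd_dce > 0) ct <- ct + stats::rnorm(length(ct), 0, sd_dce)
      curve_rows(r$class, r$phase, protocol$dce_times, ct, "DCE")
    }))
    ct_curves <- do.call(rbind, lapply(seq_len(nrow(realized)), function(i) {
      r <- realized[i, ]
      tdc <- ct_forward(aif_ct, ct_perfusion_params(r$BF, r$BV, r$PMB))$hu
      if (!is.na(protocol$noise_sd_ct) && protocol$noise_sd_ct > 0)
        tdc <- tdc + stats::rnorm(length(tdc), 0, protocol$noise_sd_ct)
      curve_rows(r$class, r$phase, protocol$ct_times, tdc, "CT")
    }))

    structure(list(subject_id = subject_id, labels = labels, dwi = dwi,
                   dce_curves = dce_curves, ct_curves = ct_curves,
                   aif_mr = aif_mr, aif_ct = aif_ct,
                   truth = realized, protocol = protocol),
              class = "subject_dataset")
  })
}

#' Simulate a phantom cohort
#'
#' `n_subjects` independent subjects with per-subject seeds derived
#' deterministically from `master_seed` (seed_i = master_seed + 7919 * i,
#' kept below 2^31).
#'
#' @inheritParams simulate_subject
#' @param n_subjects number of animals (default 10, the emulated cohort).
#' @param master_seed integer master seed.
#' @return List of class `phantom_cohort` of `subject_dataset`s.
#' @export
simulate_cohort <- function(n_subjects = 10,
                            truth = default_ground_truth(),
                            protocol = default_protocol(),
                            geometry = default_geometry(),
                            shape = c(32L, 32L, 16L),
                            sampling_mode = "SAMPLED",
                            master_seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  subjects <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(truth, protocol, geometry, shape, sampling_mode,
                     seed = subject_seed(master_seed, i),
                     subject_id = sprintf("subj%02d", i))
  })
  structure(subjects, class = "phantom_cohort",
            master_seed = as.integer(master_seed))
}

#' Derive a per-subject seed from a master seed
#' @keywords internal
subject_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * i) %% 2147483647)
}
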