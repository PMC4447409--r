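# One reproducible run: simulate -> fit -> stats, file-based between stages
# so each stage can also be run alone on a pre-populated directory.

pipeline_error <- function(stage, msg, class_ = "ivimablate_stage_error") {
  stop(structure(class = c(class_, "error", "condition"),
                 list(message = sprintf("[%s] %s", stage, msg),
                      call = sys.call(-1))))
}

#' Run the full phantom analysis pipeline
#'
#' Executes the stages selected in `config$stages`:
#' \describe{
#'   \item{simulate}{[simulate_cohort()]; writes per-subject label and DWI
#'     NIfTI volumes with bval sidecars, tidy DCE/CT curve CSVs, the AIFs
#'     and the realized ground truth (JSON).}
#'   \item{fit}{loads those files back and runs [fit_subject()] on every
#'     subject; writes `fits.csv`.}
#'   \item{stats}{[build_parameter_tables()] and
#'     [build_correlation_table()]; writes `table2.csv` (perfusion),
#'     `table3.csv` (IVIM), `table4.csv` (correlations) and
#'     `stats_report.json`.}
#' }
#' A `manifest.json` with MD5 checksums of every written file is produced at
#' the end. Rerunning with the same configuration reproduces byte-identical
#' tables.
#'
#' @param config a `run_config` from [read_config()] (or a plain list passed
#'   through it).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- read_config(overrides = config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- config$output_dir
  written <- character()
  note <- function(p) written <<- c(written, p)
  log_stage <- function(...) message(sprintf("[ivimablate] %s", sprintf(...)))

  if ("simulate" %in% config$stages) {
    log_stage("simulate: n=%d mode=%s seed=%d", config$n_subjects,
              config$sampling_mode, config$master_seed)
    proto <- config_protocol(config)
    cohort <- simulate_cohort(config$n_subjects,
                              protocol = proto,
                              geometry = default_geometry(config$shape,
                                                          config$roi_radii),
                              shape = config$shape,
                              sampling_mode = config$sampling_mode,
                              master_seed = config$master_seed)
    for (s in cohort) {
      id <- s$subject_id
      note(write_nifti(s$labels, file.path(out, sprintf("labels_%s.nii.gz", id)),
                       datatype = "int32"))
      note(write_bvals(proto$b_values, file.path(out, sprintf("dwi_%s.bval", id))))
      for (ph in names(s$dwi))
        note(write_nifti(s$dwi[[ph]],
                         file.path(out, sprintf("dwi_%s_%s.nii.gz", id, ph))))
    }
    note(write_curves(do.call(rbind, lapply(cohort, `[[`, "dce_curves")),
                      file.path(out, "dce_curves.csv")))
    note(write_curves(do.call(rbind, lapply(cohort, `[[`, "ct_curves")),
                      file.path(out, "ct_curves.csv")))
    aif <- cohort[[1]]$aif_mr
    utils::write.csv(data.frame(time_s = aif$times * 60, value = aif$cp),
                     file.path(out, "aif_mr.csv"), row.names = FALSE)
    note(file.path(out, "aif_mr.csv"))
    aifc <- cohort[[1]]$aif_ct
    utils::write.csv(data.frame(time_s = aifc$times, value = aifc$hu),
                     file.path(out, "aif_ct.csv"), row.names = FALSE)
    note(file.path(out, "aif_ct.csv"))
    note(write_truth_json(do.call(rbind, lapply(cohort, `[[`, "truth")),
                          file.path(out, "truth.json")))
  }

  if ("fit" %in% config$stages) {
    log_stage("fit: loading subjects from %s", out)
    subjects <- tryCatch(load_subjects(out),
                         error = function(e) pipeline_error("fit", conditionMessage(e)))
    fits <- do.call(rbind, lapply(subjects, function(s) {
      tryCatch(fit_subject(s),
               error = function(e)
                 pipeline_error("fit", sprintf("subject %s: %s", s$subject_id,
                                               conditionMessage(e))))
    }))
    utils::write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
    note(file.path(out, "fits.csv"))
  }

  if ("stats" %in% config$stages) {
    fp <- file.path(out, "fits.csv")
    if (!file.exists(fp)) pipeline_error("stats", "fits.csv not found; run the fit stage first")
    fits <- utils::read.csv(fp, stringsAsFactors = FALSE)
    n_sub <- length(unique(fits$subject))
    if (n_sub < 3)
      pipeline_error("stats",
                     sprintf("insufficient n: %d subject(s), need >= 3", n_sub),
                     class_ = "ivimablate_insufficient_n")
    log_stage("stats: n=%d subjects", n_sub)
    comp <- build_parameter_tables(fits)
    ivim_p <- c("f", "D", "D_star")
    utils::write.csv(comp[!comp$param %in% ivim_p, ],
                     file.path(out, "table2.csv"), row.names = FALSE)
    utils::write.csv(comp[comp$param %in% ivim_p, ],
                     file.path(out, "table3.csv"), row.names = FALSE)
    corr <- build_correlation_table(fits)
    utils::write.csv(corr, file.path(out, "table4.csv"), row.names = FALSE)
    note(file.path(out, "table2.csv")); note(file.path(out, "table3.csv"))
    note(file.path(out, "table4.csv"))
    report <- list(
      n_subjects = n_sub,
      significant = comp[comp$flag != "", c("class", "param", "p")],
      max_abs_correlation = max(abs(corr$r))
    )
    jsonlite::write_json(report, file.path(out, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note(file.path(out, "stats_report.json"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ivimablate")),
    config = unclass(config),
    config_hash = unname(tools::md5sum(write_tmp_config(config))),
    timestamp = format(Sys.time(), tz = "UTC"),
    files = lapply(stats::setNames(nm = basename(written)), function(b) {
      unname(tools::md5sum(file.path(out, b)))
    })
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

write_tmp_config <- function(config) {
  f <- tempfile(fileext = ".yaml")
  cfg <- unclass(config)
  cfg$noise_sd_dce <- if (is.na(cfg$noise_sd_dce)) NULL else cfg$noise_sd_dce
  yaml::write_yaml(cfg, f)
  f
}

#' Load simulated subjects back from a pipeline output directory
#'
#' @param dir directory written by the simulate stage.
#' @return List of `subject_dataset`-compatible objects.
#' @export
load_subjects <- function(dir) {
  dce <- read_curves(file.path(dir, "dce_curves.csv"))
  ctc <- read_curves(file.path(dir, "ct_curves.csv"))
  aif_mr_df <- utils::read.csv(file.path(dir, "aif_mr.csv"))
  aif_ct_df <- utils::read.csv(file.path(dir, "aif_ct.csv"))
  aif_mr <- structure(list(times = aif_mr_df$time_s / 60, cp = aif_mr_df$value),
                      class = "input_function")
  aif_ct <- structure(list(times = aif_ct_df$time_s, hu = aif_ct_df$value),
                      class = "time_density_curve")
  ids <- sort(unique(dce$subject))
  lapply(ids, function(id) {
    labels <- read_nifti(file.path(dir, sprintf("labels_%s.nii.gz", id)))
    b <- read_bvals(file.path(dir, sprintf("dwi_%s.bval", id)))
    dwi <- lapply(stats::setNames(nm = time_phases()), function(ph) {
      d <- read_dwi(file.path(dir, sprintf("dwi_%s_%s.nii.gz", id, ph)),
                    file.path(dir, sprintf("dwi_%s.bval", id)))
      d$dwi
    })
    structure(list(subject_id = id, labels = labels, dwi = dwi,
                   dce_curves = dce[dce$subject == id, ],
                   ct_curves = ctc[ctc$subject == id, ],
                   aif_mr = aif_mr, aif_ct = aif_ct, truth = NULL,
                   protocol = list(b_values = b)),
              class = "subject_dataset")
  })
}
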