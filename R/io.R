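# Plain-text interchange: FSL-style bval sidecars, tidy curve CSVs,
# ground-truth JSON and YAML run configuration.

#' Write / read a b-value sidecar file
#'
#' Written one value per line; the reader also accepts the single-line
#' whitespace-separated FSL layout.
#'
#' @param b_values numeric b-values, s/mm^2.
#' @param path text file path.
#' @return `read_bvals` returns a numeric vector.
#' @export
write_bvals <- function(b_values, path) {
  writeLines(format(b_values, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' @rdname write_bvals
#' @export
read_bvals <- function(path) {
  as.numeric(scan(path, what = numeric(), quiet = TRUE))
}

#' Read a 4D DWI volume with its b-value sidecar
#'
#' @param path NIfTI path of the 4D stack.
#' @param bval_path text sidecar; entry count must match the 4th dimension.
#' @return List with `dwi` (4D array) and `b_values`.
#' @export
read_dwi <- function(path, bval_path) {
  dwi <- read_nifti(path)
  b <- read_bvals(bval_path)
  if (length(dim(dwi)) != 4)
    stop("format error: expected a 4D volume in ", path)
  if (dim(dwi)[4] != length(b))
    stop(sprintf("format error: %d volumes but %d b-values",
                 dim(dwi)[4], length(b)))
  list(dwi = dwi, b_values = b)
}

#' Write fitted parameter maps as NIfTI volumes
#'
#' @param maps an `ivim_maps` object from [fit_ivim_volume()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_maps <- function(maps, dir, prefix = "ivim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in c("f_map", "D_map", "Dstar_map", "S0_map")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, sub("_map", "", nm)))
    x <- maps[[nm]]
    x[is.na(x)] <- 0
    write_nifti(x, p)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Write / read tidy curve tables
#'
#' Schema: `subject`, `class`, `phase`, `time_s`, `value` (plus an optional
#' `modality` column). Class labels are validated against
#' [tissue_classes()].
#'
#' @param curves data.frame in the tidy schema.
#' @param path CSV path.
#' @return `read_curves` returns the validated data.frame.
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  cv <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "class", "phase", "time_s", "value")
  miss <- setdiff(need, names(cv))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(cv$class), names(tissue_classes()))
  if (length(bad))
    stop("format error: unknown class label(s) ", paste(bad, collapse = ", "),
         "; valid labels are ", paste(names(tissue_classes()), collapse = ", "))
  cv
}

#' Write / read a realized ground-truth record as JSON
#'
#' @param truth realized-parameter data.frame (`subject_dataset$truth`).
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read a YAML run configuration
#'
#' Recognised keys (all optional, defaults in parentheses): `master_seed`
#' (1), `n_subjects` (10), `sampling_mode` ("SAMPLED"), `output_dir`,
#' `shape` (32 32 16), `roi_radii` (4 4 2.5), `snr_dwi` (50),
#' `noise_sd_ct` (2), `noise_sd_dce` (null = 1% of peak), `b_values`,
#' `stages` (simulate, fit, stats).
#'
#' @param path YAML file.
#' @param overrides named list merged over the file contents (CLI flags).
#' @return A `run_config` list, validated.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg[names(overrides)] <- overrides
  defaults <- list(master_seed = 1L, n_subjects = 10L,
                   sampling_mode = "SAMPLED", output_dir = "ivimablate_run",
                   shape = c(32L, 32L, 16L), roi_radii = c(4, 4, 2.5),
                   snr_dwi = 50, noise_sd_ct = 2, noise_sd_dce = NA_real_,
                   b_values = NULL,
                   stages = c("simulate", "fit", "stats"))
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg$master_seed <- as.integer(cfg$master_seed)
  cfg$n_subjects <- as.integer(cfg$n_subjects)
  if (!cfg$sampling_mode %in% c("SAMPLED", "FIXED_MEAN"))
    stop("sampling_mode must be SAMPLED or FIXED_MEAN")
  bad <- setdiff(cfg$stages, c("simulate", "fit", "stats"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

config_protocol <- function(cfg) {
  args <- list(snr_dwi = cfg$snr_dwi, noise_sd_ct = cfg$noise_sd_ct,
               noise_sd_dce = cfg$noise_sd_dce)
  if (!is.null(cfg$b_values)) args$b_values <- cfg$b_values
  do.call(default_protocol, args)
}
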