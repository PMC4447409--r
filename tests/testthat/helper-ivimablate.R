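# Shared fixtures, all generated in code.

# noise-free protocol for round-trip oracles
noiseless_protocol <- function(...) {
  default_protocol(snr_dwi = Inf, noise_sd_ct = 0, noise_sd_dce = 0, ...)
}

# small, fast phantom for pipeline-level tests (~20 voxels per class)
tiny_config <- function(dir, n_subjects = 2, master_seed = 11L, ...) {
  read_config(overrides = c(list(
    output_dir = dir, n_subjects = n_subjects, master_seed = master_seed,
    shape = c(16L, 16L, 8L), roi_radii = c(2, 2, 1.5)), list(...)))
}

default_mr_aif <- function(protocol = default_protocol()) {
  population_aif(protocol$dce_times / 60,
                 onset = protocol$dce_times[protocol$dce_baseline_frames + 1] / 60)
}

default_ct_aif <- function(protocol = default_protocol()) {
  ct_aif(protocol$ct_times,
         onset = protocol$ct_times[protocol$ct_baseline_frames + 1])
}

read_file_bytes <- function(path) readBin(path, "raw", file.size(path))

config_protocol_for_tests <- function(cfg) ivimablate:::config_protocol(cfg)

rel_err <- function(x, truth) abs(x - truth) / pmax(abs(truth), 1e-300)
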