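#' Default pipeline configuration
#'
#' One flat list of every tunable the pipeline exposes. Defaults describe the
#' study conditions the phantom emulates: a 96^3 grid of 2 mm isotropic
#' voxels (the conventional DTI acquisition resolution), quadripolar leads
#' with 2 mm contact spacing, streamline-count maps peaking at 5000 samples,
#' candidate thresholds 400/600/800/1000% of the robust range, the 10 mm
#' step-down cutoff, deterministic (jitter-free) manual emulation, ~1 mm
#' residual normalization warp, and a 5 mm outlier cutoff for excluded
#' normalizations.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    n_patients = 10L,
    grid_dim = c(96L, 96L, 96L),
    spacing_mm = c(2, 2, 2),
    n_contacts = 4L,
    contact_spacing_mm = 2,
    lead_max_offset_mm = 8,
    sigma_mm = 2,
    n_samples = 5000L,
    noise_fraction = 0.05,
    percents = c(400, 600, 800, 1000),
    step_down_cutoff_mm = 10,
    jitter_mm = 0,
    warp_amplitude_mm = 1,
    warp_wavelength_mm = 60,
    atlas_rn_offset_mm = 0,
    misnormalized_fraction = 0.05,
    outlier_cutoff_mm = 5,
    robust_range_nonzero_only = FALSE
  )
}

#' Validate (and normalize) a pipeline configuration
#'
#' Rejects unknown keys outright (typo safety) and checks every numeric
#' parameter's documented range, reporting all offending keys at once.
#' Missing keys are filled from [default_config()].
#'
#' @param config Named list of configuration values (possibly partial).
#' @return The completed, validated configuration list.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  config <- modifyList(defaults, config)
  config$grid_dim <- rep_len(as.integer(config$grid_dim), 3L)
  config$spacing_mm <- rep_len(as.numeric(config$spacing_mm), 3L)
  bad <- character(0)
  chk <- function(ok, key) if (!all(ok)) bad <<- c(bad, key)
  chk(is.numeric(config$n_patients) && config$n_patients >= 1, "n_patients")
  chk(all(config$grid_dim >= 4), "grid_dim")
  chk(all(config$spacing_mm > 0), "spacing_mm")
  chk(config$n_contacts >= 1, "n_contacts")
  chk(config$contact_spacing_mm > 0, "contact_spacing_mm")
  chk(config$lead_max_offset_mm >= 0, "lead_max_offset_mm")
  chk(config$sigma_mm > 0, "sigma_mm")
  chk(config$n_samples >= 1, "n_samples")
  chk(config$noise_fraction >= 0 && config$noise_fraction < 1,
      "noise_fraction")
  chk(length(config$percents) >= 1 && all(config$percents > 0) &&
        all(diff(config$percents) > 0), "percents")
  chk(config$step_down_cutoff_mm > 0, "step_down_cutoff_mm")
  chk(config$jitter_mm >= 0, "jitter_mm")
  chk(config$warp_amplitude_mm >= 0, "warp_amplitude_mm")
  chk(config$warp_wavelength_mm > 0, "warp_wavelength_mm")
  chk(config$atlas_rn_offset_mm >= 0, "atlas_rn_offset_mm")
  chk(config$misnormalized_fraction >= 0 && config$misnormalized_fraction < 1,
      "misnormalized_fraction")
  chk(config$outlier_cutoff_mm > 0, "outlier_cutoff_mm")
  chk(is.logical(config$robust_range_nonzero_only),
      "robust_range_nonzero_only")
  if (length(bad)) {
    stop("invalid configuration values for: ", paste(bad, collapse = ", "))
  }
  config$n_patients <- as.integer(config$n_patients)
  config$n_contacts <- as.integer(config$n_contacts)
  config
}

#' Load a configuration from a YAML file
#'
#' The file holds a flat key-value mapping; keys not present fall back to
#' [default_config()], unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  validate_config(yaml::read_yaml(path) %||% list())
}
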