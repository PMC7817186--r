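# Core domain containers: RI tomograms, acquisition metadata, run
# configuration, and cell mask pairs.

#' Refractive-index tomogram
#'
#' A 3D refractive-index (RI) volume together with the physical metadata the
#' rest of the pipeline needs: per-axis voxel pitch and the RI of the
#' surrounding medium. Axis order is (z, y, x).
#'
#' @param values 3D numeric array of RI values (dimensionless).
#' @param pitch voxel size in nm, either a scalar (isotropic) or a length-3
#'   vector in (z, y, x) order.
#' @param medium_ri RI of the immersion medium, must lie in \[1.30, 1.40\].
#' @param timestamp optional acquisition time in seconds.
#' @return An object of class `tomogram`.
#' @export
tomogram <- function(values, pitch = 218.5, medium_ri = 1.337,
                     timestamp = NULL) {
  assert_volume(values, "values")
  if (any(!is.finite(values)))
    stop_istomo("tomogram values must all be finite", "istomo_value_error")
  pitch <- expand_pitch(pitch)
  if (!is.numeric(medium_ri) || length(medium_ri) != 1L ||
      medium_ri < 1.30 || medium_ri > 1.40)
    stop_istomo("medium_ri must be a scalar in [1.30, 1.40]",
                "istomo_value_error")
  structure(list(values = values, pitch = pitch,
                 medium_ri = as.numeric(medium_ri),
                 timestamp = timestamp),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  cat(sprintf("<tomogram> %s voxels, pitch (%s) nm, medium RI %.4f\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$pitch, trim = TRUE), collapse = ", "),
              x$medium_ri))
  cat(sprintf("  RI range [%.4f, %.4f]%s\n", min(x$values), max(x$values),
              if (is.null(x$timestamp)) ""
              else sprintf(", t = %.1f s", x$timestamp)))
  invisible(x)
}

#' Acquisition metadata for an angle-scanned tomographic measurement
#'
#' @param wavelength vacuum wavelength in nm.
#' @param na_illumination,na_detection numerical apertures of the
#'   illumination cone and the detection objective.
#' @param n_illuminations number of illumination angles (1 normal-incidence
#'   plus the rest laid out on a cone).
#' @return An object of class `volume_metadata`.
#' @export
volume_metadata <- function(wavelength = 532, na_illumination = 1.2,
                            na_detection = 1.2, n_illuminations = 49L) {
  if (wavelength <= 0)
    stop_istomo("wavelength must be > 0", "istomo_value_error")
  for (na in c(na_illumination, na_detection))
    if (na < 0 || na > 1.49)
      stop_istomo("NA values must lie in (0, 1.49]", "istomo_value_error")
  if (n_illuminations < 1L)
    stop_istomo("n_illuminations must be >= 1", "istomo_value_error")
  structure(list(wavelength = wavelength,
                 na_illumination = na_illumination,
                 na_detection = na_detection,
                 n_illuminations = as.integer(n_illuminations)),
            class = "volume_metadata")
}

#' Pair of effector/target cell masks
#'
#' Two voxelwise-disjoint binary volumes of one shape, keyed by cell role.
#'
#' @param effector,target logical 3D arrays.
#' @param pitch voxel size in nm (scalar or (z, y, x)).
#' @return An object of class `cell_mask_pair`.
#' @export
cell_mask_pair <- function(effector, target, pitch = 218.5) {
  assert_volume(effector, "effector")
  assert_volume(target, "target")
  assert_same_shape(effector, target, "effector and target masks")
  effector <- array(as.logical(effector), dim(effector))
  target <- array(as.logical(target), dim(target))
  if (any(effector & target))
    stop_istomo("effector and target masks must be voxelwise disjoint",
                "istomo_invariant_error")
  structure(list(effector = effector, target = target,
                 pitch = expand_pitch(pitch)),
            class = "cell_mask_pair")
}

#' Pipeline run configuration
#'
#' A validated, nested list of stage parameters with sensible defaults for
#' every pipeline stage. `run_config()` returns the defaults, optionally
#' overridden; [read_run_config()] loads the same structure from a YAML file.
#'
#' @param ... named overrides; nested lists are merged field-by-field.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    volume = list(pitch_nm = 218.5, medium_ri = 1.337),
    acquisition = list(wavelength_nm = 532, na_illumination = 1.2,
                       na_detection = 1.2, n_illuminations = 49L),
    annotation = list(ri_threshold = 1.345, dilation_size = 1L,
                      gaussian_sigma = 1),
    reconstruction = list(iterations = 100L, tolerance = 1e-6),
    density = list(alpha_ml_per_g = 0.185),
    postprocess = list(threshold_nm = 54.5, is_dilation_voxels = 2L,
                       erosion_voxels = 1L, keep_largest = TRUE),
    training = list(learning_rate = 1e-3, beta1 = 0.5, beta2 = 0.99,
                    lr_decay = 0.5, lr_decay_every = 50L, max_epochs = 400L,
                    patience = 5L, batch_size = 1L, val_fraction = 36 / 234),
    seed = 1L)
  over <- list(...)
  if (length(over)) cfg <- modifyList(cfg, over)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_istomo(sprintf("config file not found: %s", path),
                "istomo_io_error")
  do.call(run_config, yaml::read_yaml(path))
}

validate_run_config <- function(cfg) {
  chk <- function(ok, what)
    if (!isTRUE(ok)) stop_istomo(paste("invalid config:", what),
                                 "istomo_config_error")
  chk(all(cfg$volume$pitch_nm > 0), "volume$pitch_nm must be > 0")
  chk(cfg$volume$medium_ri >= 1.30 && cfg$volume$medium_ri <= 1.40,
      "volume$medium_ri must lie in [1.30, 1.40]")
  chk(cfg$acquisition$wavelength_nm > 0, "wavelength must be > 0")
  chk(cfg$acquisition$n_illuminations >= 1, "n_illuminations must be >= 1")
  chk(cfg$annotation$ri_threshold > cfg$volume$medium_ri,
      "annotation$ri_threshold must exceed the medium RI")
  chk(cfg$annotation$dilation_size >= 0, "dilation_size must be >= 0")
  chk(cfg$annotation$gaussian_sigma >= 0, "gaussian_sigma must be >= 0")
  chk(cfg$reconstruction$iterations >= 0, "iterations must be >= 0")
  chk(cfg$reconstruction$tolerance > 0, "tolerance must be > 0")
  chk(cfg$density$alpha_ml_per_g > 0, "alpha must be > 0")
  chk(cfg$postprocess$threshold_nm > 0, "threshold_nm must be > 0")
  chk(cfg$postprocess$is_dilation_voxels >= 0, "is dilation must be >= 0")
  chk(cfg$postprocess$erosion_voxels >= 1, "erosion must be >= 1")
  tr <- cfg$training
  chk(tr$learning_rate > 0 && tr$learning_rate < 1,
      "learning_rate must lie in (0, 1)")
  chk(tr$beta1 > 0 && tr$beta1 < 1 && tr$beta2 > 0 && tr$beta2 < 1,
      "Adam moment decays must lie in (0, 1)")
  chk(tr$patience >= 1, "patience must be >= 1")
  invisible(cfg)
}
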