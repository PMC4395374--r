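# File interchange (NIfTI + JSON sidecars), run configuration, and the
# end-to-end pipeline.
#
# Complex series are stored as paired float64 NIfTI volumes (<prefix>_real.nii,
# <prefix>_imag.nii; axes row, col, coil, echo) with a <prefix>.json sidecar
# holding the echo-time table, coil ids and domain ("image" or "kspace").
# ROI sets are stored as a multi-volume 0/1 NIfTI plus a JSON name->plane map.

# Read a NIfTI volume as a bare numeric array (no image metadata attributes).
nifti_array <- function(file) {
  x <- RNifti::readNifti(file)
  array(as.numeric(x), dim(x))
}

#' Write / read a complex multi-echo series
#'
#' @param x an [echo_series()] or [kspace_series()].
#' @param prefix output path prefix; writes `<prefix>_real.nii`,
#'   `<prefix>_imag.nii` and `<prefix>.json`.
#' @return `write_complex_series()` returns `prefix` invisibly;
#'   `read_complex_series()` returns the series (echoes sorted ascending,
#'   with a message if the on-disk table was unsorted).
#' @export
write_complex_series <- function(x, prefix) {
  stopifnot(inherits(x, "mri_series"))
  RNifti::writeNifti(Re(x$data), paste0(prefix, "_real.nii"),
                     datatype = "double")
  RNifti::writeNifti(Im(x$data), paste0(prefix, "_imag.nii"),
                     datatype = "double")
  jsonlite::write_json(
    list(domain = if (inherits(x, "kspace_series")) "kspace" else "image",
         echo_times_ms = x$echo_times, coil_ids = x$coil_ids),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_complex_series
#' @export
read_complex_series <- function(prefix) {
  side_file <- paste0(prefix, ".json")
  if (!file.exists(side_file))
    stop("missing sidecar: ", side_file, call. = FALSE)
  side <- jsonlite::read_json(side_file, simplifyVector = TRUE)
  if (is.null(side$echo_times_ms))
    stop("sidecar lacks the echo-time table (echo_times_ms)", call. = FALSE)
  re <- nifti_array(paste0(prefix, "_real.nii"))
  im <- nifti_array(paste0(prefix, "_imag.nii"))
  if (!identical(dim(re), dim(im)))
    stop("real and imaginary volumes have inconsistent shapes", call. = FALSE)
  if (length(dim(re)) == 3L) dim(re) <- dim(im) <- c(dim(re)[1:2], 1L, dim(re)[3L])
  if (length(side$echo_times_ms) != dim(re)[4L])
    stop(sprintf("sidecar lists %d echo times but volumes hold %d echoes",
                 length(side$echo_times_ms), dim(re)[4L]), call. = FALSE)
  data <- array(complex(real = re, imaginary = im), dim(re))
  if (any(!is.finite(re)) || any(!is.finite(im)))
    stop("non-finite values in complex series", call. = FALSE)
  et <- as.numeric(side$echo_times_ms)
  if (is.unsorted(et, strictly = TRUE)) {
    message("echo-time table was not sorted on disk; reordering echoes")
    o <- order(et)
    et <- et[o]
    data <- data[, , , o, drop = FALSE]
  }
  ctor <- if (identical(side$domain, "kspace")) kspace_series else echo_series
  ctor(data, et, side$coil_ids)
}

#' Write / read a real-valued image stack
#'
#' @param stack an `image_stack`.
#' @param file output `.nii` path; a `.json` sidecar is written next to it.
#' @return `write_image_stack()` returns `file` invisibly;
#'   `read_image_stack()` returns the `image_stack`.
#' @export
write_image_stack <- function(stack, file) {
  stopifnot(inherits(stack, "image_stack"))
  RNifti::writeNifti(stack$data, file, datatype = "float")
  side <- list(kind = stack$kind, echo_times_ms = stack$echo_times,
               n_multiplies = stack$n_multiplies)
  side <- side[!vapply(side, is.null, logical(1))]
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", file),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(file) {
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", file),
                              simplifyVector = TRUE)
  data <- nifti_array(file)
  n_mult <- side$n_multiplies                # jsonlite null round-trip
  image_stack(data, side$echo_times_ms, side$kind,
              n_multiplies = if (length(n_mult)) as.integer(n_mult) else NULL)
}

#' Write / read ROI masks
#'
#' Masks are stacked along the third axis as 0/1 volumes; the JSON sidecar
#' maps each mask name to its plane index.
#'
#' @param rois a [roi_set()].
#' @param file output `.nii` path.
#' @return `write_roi_set()` returns `file` invisibly; `read_roi_set()`
#'   returns the [roi_set()].
#' @export
write_roi_set <- function(rois, file) {
  stopifnot(inherits(rois, "roi_set"))
  arr <- array(0L, c(dim(rois[[1L]]), length(rois)))
  for (i in seq_along(rois)) arr[, , i] <- rois[[i]] * 1L
  RNifti::writeNifti(arr, file, datatype = "uint8")
  jsonlite::write_json(as.list(stats::setNames(seq_along(rois), names(rois))),
                       sub("\\.nii(\\.gz)?$", ".json", file),
                       auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(file) {
  planes <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", file),
                                simplifyVector = TRUE)
  arr <- nifti_array(file)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  masks <- lapply(planes, function(i) arr[, , i] != 0)
  roi_set(masks)
}

config_defaults <- function() {
  list(phantom = list(), hpf_n_points = 64L, n_multiplies = c(3L, 6L),
       n_te = 9L, seed = NULL, rv_insertion_angle = 0, level = "mid")
}

#' Read and validate a pipeline run configuration
#'
#' YAML or JSON (chosen by extension). Recognised keys: `phantom` (arguments
#' for [phantom_spec()]), `hpf_n_points`, `n_multiplies`, `n_te`, `seed`,
#' `rv_insertion_angle`, `level`. Unknown keys are rejected.
#'
#' @param path config file path.
#' @return a validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  bad <- setdiff(names(cfg$phantom), names(formals(phantom_spec)))
  if (length(bad))
    stop("unknown phantom key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (cfg$n_te < 1L) stop("n_te must be >= 1", call. = FALSE)
  cfg
}

#' Run the full phantom-to-metrics pipeline
#'
#' simulate -> reconstruct -> high-pass phase -> SWI -> TE-average sweep ->
#' contrast/SDNR metrics and per-sector T2* fits. Deterministic given the
#' configured seed; every run writes a provenance JSON holding the resolved
#' configuration and package version.
#'
#' @param config a config list (see [read_run_config()]) or a path to a
#'   YAML/JSON config file.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the `sweep` and `segments` tibbles and
#'   the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  if (!is.null(cfg$seed)) cfg$phantom$seed <- cfg$seed
  spec <- do.call(phantom_spec, cfg$phantom)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  k <- simulate_kspace(spec)
  es <- reconstruct(k)
  mag <- sos_magnitude(es)
  ph <- hpf_phase(es, cfg$hpf_n_points)
  rois <- phantom_rois(spec)

  sweep <- sweep_report(mag, ph, rois, cfg$n_multiplies)
  swi_main <- swi_series(mag, ph, max(cfg$n_multiplies))
  te_mag <- te_average(mag, cfg$n_te)
  te_swi <- te_average(swi_main, cfg$n_te)
  win <- c(0, stats::quantile(te_swi$data[rois$lv], 0.99, names = FALSE))
  inv <- invert_grayscale(te_swi, win)

  sectors <- aha_sectors(rois$lv, cfg$rv_insertion_angle, cfg$level)
  segments <- segment_t2star(mag, sectors)

  paths <- list(
    kspace = write_complex_series(k, file.path(out_dir, "kspace")),
    magnitude = write_image_stack(mag, file.path(out_dir, "magnitude.nii")),
    phase = write_image_stack(ph, file.path(out_dir, "hpf_phase.nii")),
    swi = write_image_stack(swi_main, file.path(out_dir, "swi.nii")),
    rois = write_roi_set(rois, file.path(out_dir, "rois.nii")))
  RNifti::writeNifti(te_mag$data, file.path(out_dir, "te_avg_magnitude.nii"),
                     datatype = "float")
  RNifti::writeNifti(te_swi$data, file.path(out_dir, "te_avg_swi.nii"),
                     datatype = "float")
  RNifti::writeNifti(inv$data, file.path(out_dir, "te_avg_swi_inverted.nii"),
                     datatype = "float")
  utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
  utils::write.csv(segments, file.path(out_dir, "segments.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = cfg[setdiff(names(cfg), "phantom")],
         phantom = spec[setdiff(names(spec), "tissues")],
         tissues = lapply(spec$tissues, unclass),
         package_version = as.character(utils::packageVersion("cardioswi")),
         display_only_outputs = "te_avg_swi_inverted.nii"),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(sweep = sweep, segments = segments, out_dir = out_dir,
                 paths = paths))
}
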