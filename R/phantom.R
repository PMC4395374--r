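# Synthetic short-axis left-ventricle phantom.
#
# The phantom provides exact ground truth for every downstream stage: a
# blood pool inside an annular myocardium, a focal short-T2* lesion with a
# locally negative phase offset (the intramyocardial-hemorrhage model), and
# air/lung background. Complex signal per pixel at echo time TE (ms):
#
#   rho * exp(-TE / T2*) * exp(i * (2*pi*df*TE/1000 + focal_phase * w))
#
# with w = 1 inside the lesion and 0 elsewhere. Multi-coil k-space is the
# centered orthonormal 2-D FFT of (image x coil sensitivity) plus i.i.d.
# circular complex Gaussian noise.

#' Tissue signal parameters
#'
#' @param proton_density signal amplitude at TE = 0 (arbitrary units, >= 0).
#' @param t2_star effective transverse relaxation time in ms (> 0).
#' @param off_resonance off-resonance frequency in Hz; contributes the smooth
#'   (low-spatial-frequency) phase `2*pi*off_resonance*TE`.
#' @param focal_phase additional phase in radians applied only inside the
#'   lesion; hemorrhage corresponds to negative values in `[-pi, 0]`.
#' @return a `tissue_params` list.
#' @export
tissue_params <- function(proton_density, t2_star, off_resonance = 0,
                          focal_phase = 0) {
  if (proton_density < 0) stop("proton_density must be >= 0", call. = FALSE)
  if (t2_star <= 0) stop("t2_star must be > 0 ms", call. = FALSE)
  if (abs(focal_phase) > pi)
    stop("focal_phase must lie in [-pi, pi] radians", call. = FALSE)
  structure(list(proton_density = proton_density, t2_star = t2_star,
                 off_resonance = off_resonance, focal_phase = focal_phase),
            class = "tissue_params")
}

#' Default multi-echo gradient-echo echo-time table
#'
#' Twelve echoes with 1.2 ms spacing ending at 15.5 ms (2.3, 3.5, ..., 15.5),
#' the dark-blood multi-echo protocol the package's defaults emulate.
#'
#' @return numeric vector of 12 echo times in ms.
#' @export
default_echo_times <- function() seq(2.3, by = 1.2, length.out = 12L)

#' Default phantom tissue parameters
#'
#' Myocardium (T2* 34.1 ms), blood pool (brighter, long T2*), a hemorrhagic
#' lesion (T2* 16.2 ms, focal phase -1 rad) and signal-free background.
#'
#' @return named list of [tissue_params()].
#' @export
default_tissues <- function() {
  list(
    myocardium = tissue_params(1.0, 34.1, off_resonance = 3),
    blood      = tissue_params(1.2, 150, off_resonance = 3),
    lesion     = tissue_params(1.0, 16.2, off_resonance = 3,
                               focal_phase = -1.0),
    background = tissue_params(0, 1)
  )
}

#' Specify the left-ventricle phantom
#'
#' Defines the full ground truth: geometry (annular myocardium, blood pool,
#' focal lesion), per-tissue signal parameters, echo-time table, coil count
#' and noise level. All geometry is in pixels on the `grid_shape` grid.
#'
#' @param grid_shape `(rows, cols)` of the image grid.
#' @param pixel_size pixel edge length in mm (metadata only).
#' @param lv_center `(row, col)` of the LV axis; defaults to the grid center.
#' @param lv_inner_radius,lv_outer_radius endo-/epicardial radii in pixels.
#' @param lesion_center `(row, col)` of the lesion; must keep the whole
#'   lesion inside the myocardial annulus. Defaults to mid-wall in the
#'   inferior wall.
#' @param lesion_radius lesion radius in pixels. Kept compact by default
#'   (3 px) so its focal phase largely survives the homodyne high-pass
#'   filter.
#' @param tissues named list of [tissue_params()] for `myocardium`, `blood`,
#'   `lesion` and `background`.
#' @param echo_times echo-time table in ms, strictly increasing.
#' @param n_coils number of synthetic receive coils (>= 1).
#' @param noise_sigma standard deviation of the complex Gaussian noise per
#'   real/imaginary channel, in signal units. The default gives first-echo
#'   myocardial SNR of about 30.
#' @param noise_block edge length (px) of the background corner block used
#'   as the noise ROI.
#' @param guard_px guard ring (px) separating the lesion from the remote
#'   myocardium ROI.
#' @param seed integer seed making [simulate_kspace()] deterministic.
#' @return a validated `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(192L, 192L),
                         pixel_size = 1.5,
                         lv_center = NULL,
                         lv_inner_radius = 20,
                         lv_outer_radius = 28,
                         lesion_center = NULL,
                         lesion_radius = 3,
                         tissues = default_tissues(),
                         echo_times = default_echo_times(),
                         n_coils = 4L,
                         noise_sigma = 0.03,
                         noise_block = 64L,
                         guard_px = 2L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (is.null(lv_center)) lv_center <- grid_shape %/% 2L + 1L
  if (is.null(lesion_center))
    lesion_center <- c(lv_center[1L] + (lv_inner_radius + lv_outer_radius) / 2,
                       lv_center[2L])
  spec <- structure(list(
    grid_shape = grid_shape, pixel_size = pixel_size,
    lv_center = lv_center, lv_inner_radius = lv_inner_radius,
    lv_outer_radius = lv_outer_radius,
    lesion_center = lesion_center, lesion_radius = lesion_radius,
    tissues = tissues, echo_times = as.numeric(echo_times),
    n_coils = as.integer(n_coils), noise_sigma = noise_sigma,
    noise_block = as.integer(noise_block), guard_px = as.integer(guard_px),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (lv_inner_radius >= lv_outer_radius)
      stop("lv_inner_radius must be smaller than lv_outer_radius",
           call. = FALSE)
    if (any(diff(echo_times) <= 0) || any(echo_times <= 0))
      stop("echo_times must be positive and strictly increasing",
           call. = FALSE)
    if (n_coils < 1L) stop("n_coils must be >= 1", call. = FALSE)
    if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
    needed <- c("myocardium", "blood", "lesion", "background")
    missing <- setdiff(needed, names(tissues))
    if (length(missing))
      stop("tissues must define: ", paste(missing, collapse = ", "),
           call. = FALSE)
    d <- sqrt(sum((lesion_center - lv_center)^2))
    if (d - lesion_radius < lv_inner_radius ||
        d + lesion_radius > lv_outer_radius)
      stop(sprintf(paste0(
        "lesion (center distance %.1f px, radius %.1f px) must lie entirely ",
        "inside the myocardial annulus [%.1f, %.1f] px"),
        d, lesion_radius, lv_inner_radius, lv_outer_radius), call. = FALSE)
  })
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d grid, annulus [%.1f, %.1f] px, lesion r=%.1f px\n",
    x$grid_shape[1L], x$grid_shape[2L], x$lv_inner_radius, x$lv_outer_radius,
    x$lesion_radius))
  cat(sprintf("  %d echoes %.1f-%.1f ms, %d coil(s), sigma=%.3g, seed=%d\n",
              length(x$echo_times), min(x$echo_times), max(x$echo_times),
              x$n_coils, x$noise_sigma, x$seed))
  invisible(x)
}

# Distance-from-point map over the grid.
radius_map <- function(grid_shape, center) {
  r <- matrix(seq_len(grid_shape[1L]), grid_shape[1L], grid_shape[2L])
  cl <- matrix(seq_len(grid_shape[2L]), grid_shape[1L], grid_shape[2L],
               byrow = TRUE)
  sqrt((r - center[1L])^2 + (cl - center[2L])^2)
}

#' Ground-truth ROI masks for a phantom
#'
#' @param spec a [phantom_spec()].
#' @return a [roi_set()] with masks `lesion`, `remote` (annulus minus the
#'   lesion plus its guard ring), `lv` (whole myocardial annulus, lesion
#'   included), `blood` and `noise` (background corner block).
#' @export
phantom_rois <- function(spec) {
  rad <- radius_map(spec$grid_shape, spec$lv_center)
  dles <- radius_map(spec$grid_shape, spec$lesion_center)
  annulus <- rad >= spec$lv_inner_radius & rad <= spec$lv_outer_radius
  lesion <- dles <= spec$lesion_radius
  noise <- matrix(FALSE, spec$grid_shape[1L], spec$grid_shape[2L])
  nb <- min(spec$noise_block, spec$grid_shape)
  noise[seq_len(nb), seq_len(nb)] <- TRUE
  noise <- noise & rad > spec$lv_outer_radius + spec$guard_px
  roi_set(lesion = lesion,
          remote = annulus & dles > spec$lesion_radius + spec$guard_px,
          lv = annulus,
          blood = rad < spec$lv_inner_radius,
          noise = noise)
}

#' Noiseless ground-truth complex image at one echo
#'
#' Evaluates the phantom's signal model exactly (no coils, no noise).
#'
#' @param spec a [phantom_spec()].
#' @param echo_index 1-based index into `spec$echo_times`.
#' @return a list with `image` (complex matrix), `rois` ([phantom_rois()])
#'   and `echo_time` (ms).
#' @export
ground_truth_image <- function(spec, echo_index) {
  stopifnot(echo_index >= 1L, echo_index <= length(spec$echo_times))
  te <- spec$echo_times[echo_index]
  rois <- phantom_rois(spec)
  rad <- radius_map(spec$grid_shape, spec$lv_center)
  region <- matrix("background", spec$grid_shape[1L], spec$grid_shape[2L])
  region[rois$blood] <- "blood"
  region[rois$lv] <- "myocardium"
  region[rois$lesion] <- "lesion"
  img <- matrix(0i, spec$grid_shape[1L], spec$grid_shape[2L])
  for (nm in unique(as.vector(region))) {
    tp <- spec$tissues[[nm]]
    sel <- region == nm
    phase <- 2 * pi * tp$off_resonance * te / 1000 +
      if (nm == "lesion") tp$focal_phase else 0
    img[sel] <- tp$proton_density * exp(-te / tp$t2_star) * exp(1i * phase)
  }
  list(image = img, rois = rois, echo_time = te)
}

#' Synthetic coil sensitivity profiles
#'
#' Smooth positive Gaussian-falloff profiles centered at `n_coils` points
#' around the field of view, normalized pointwise so that their
#' sum-of-squares is exactly 1 everywhere (a single coil therefore has unit
#' sensitivity).
#'
#' @param spec a [phantom_spec()].
#' @return real array `[row, col, coil]`.
#' @export
coil_sensitivities <- function(spec) {
  gs <- spec$grid_shape
  sens <- array(0, c(gs[1L], gs[2L], spec$n_coils))
  ctr <- (gs + 1) / 2
  ring <- 0.55 * min(gs)
  width <- 0.6 * min(gs)
  ang <- 2 * pi * (seq_len(spec$n_coils) - 1L) / spec$n_coils
  for (j in seq_len(spec$n_coils)) {
    pos <- ctr + ring * c(cos(ang[j]), sin(ang[j]))
    sens[, , j] <- exp(-radius_map(gs, pos)^2 / (2 * width^2))
  }
  sos <- sqrt(apply(sens^2, c(1, 2), sum))
  sweep(sens, c(1, 2), sos, "/")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate multi-coil multi-echo k-space from a phantom
#'
#' For each echo and coil, k-space is the centered orthonormal 2-D FFT of
#' (ground-truth image times coil sensitivity) plus i.i.d. circular complex
#' Gaussian noise (`noise_sigma` per real/imaginary channel). Deterministic
#' given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return a [kspace_series()].
#' @export
simulate_kspace <- function(spec) {
  gs <- spec$grid_shape
  nes <- length(spec$echo_times)
  sens <- coil_sensitivities(spec)
  k <- array(0i, c(gs[1L], gs[2L], spec$n_coils, nes))
  with_seed(spec$seed, {
    for (e in seq_len(nes)) {
      gt <- ground_truth_image(spec, e)$image
      for (j in seq_len(spec$n_coils)) {
        kj <- fft2c(gt * sens[, , j])
        if (spec$noise_sigma > 0) {
          n <- length(kj)
          kj <- kj + complex(real = stats::rnorm(n, sd = spec$noise_sigma),
                             imaginary = stats::rnorm(n, sd = spec$noise_sigma))
        }
        k[, , j, e] <- kj
      }
    }
  })
  kspace_series(k, spec$echo_times)
}
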