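# Reconstruction class (2): susceptibility-weighted imaging.
#
# The phase mask emphasizes negative phase:
#   mask = (pi + phi) / pi   for  -pi <= phi < 0
#   mask = 1                 otherwise
# and the SWI image is magnitude * mask^N, pixelwise. More multiplies (N)
# darken negative-phase tissue more strongly; N = 6 is the default.

#' Negative-phase mask
#'
#' Linear ramp from 0 at `phi = -pi` to 1 at `phi = 0`; unity for
#' non-negative phase, so only negative-phase tissue is attenuated.
#'
#' @param phase phase image in radians, values in `[-pi, pi]` (wrapped).
#' @param valid optional logical matrix; invalid pixels receive mask 1
#'   (no attenuation) and stay flagged.
#' @return a `phase_mask` object: list of `values` in `[0, 1]` and `valid`.
#' @export
phase_mask <- function(phase, valid = NULL) {
  if (any(phase < -pi - 1e-12 | phase > pi + 1e-12, na.rm = TRUE))
    stop("phase values outside [-pi, pi]: wrap phase upstream", call. = FALSE)
  m <- ifelse(phase < 0, (pi + pmax(phase, -pi)) / pi, 1)
  if (!is.null(valid)) m[!valid] <- 1
  structure(list(values = m,
                 valid = if (is.null(valid)) array(TRUE, dim(m)) else valid),
            class = "phase_mask")
}

#' Apply a phase mask to a magnitude image
#'
#' @param magnitude non-negative magnitude image (matrix).
#' @param mask a [phase_mask()] on the same grid.
#' @param n_multiplies number of mask multiplications `N >= 0`; the SWI
#'   image is `magnitude * mask^N`. The protocol default is 6 (3 is the
#'   common alternative); `N = 0` returns the magnitude unchanged.
#' @return numeric matrix, pixelwise `<=` magnitude.
#' @export
apply_mask <- function(magnitude, mask, n_multiplies = 6L) {
  stopifnot(inherits(mask, "phase_mask"), n_multiplies >= 0)
  if (!all(dim(magnitude) == dim(mask$values)))
    stop("magnitude and mask grids differ", call. = FALSE)
  magnitude * mask$values^n_multiplies
}

#' Susceptibility-weighted image series
#'
#' Builds the per-echo phase mask from each echo's own high-pass filtered
#' phase and applies it to that echo's combined magnitude.
#'
#' @param es_magnitude `image_stack` of kind `"magnitude"`
#'   (see [sos_magnitude()]).
#' @param es_phase `image_stack` of kind `"phase"` (see [hpf_phase()]),
#'   same echo table.
#' @param n_multiplies mask multiplications per echo (default 6).
#' @return an `image_stack` of kind `"swi"` carrying `n_multiplies`; the
#'   phase validity plane is propagated.
#' @export
swi_series <- function(es_magnitude, es_phase, n_multiplies = 6L) {
  stopifnot(inherits(es_magnitude, "image_stack"),
            inherits(es_phase, "image_stack"))
  if (!identical(es_magnitude$echo_times, es_phase$echo_times))
    stop("magnitude and phase stacks have different echo tables",
         call. = FALSE)
  d <- dim(es_magnitude$data)
  out <- array(0, d)
  for (e in seq_len(d[3L])) {
    pm <- phase_mask(es_phase$data[, , e],
                     valid = if (is.null(es_phase$valid)) NULL
                             else es_phase$valid[, , e])
    out[, , e] <- apply_mask(es_magnitude$data[, , e], pm, n_multiplies)
  }
  image_stack(out, es_magnitude$echo_times, "swi",
              valid = es_phase$valid, n_multiplies = n_multiplies)
}
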