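# Reconstruction class (1): per-echo per-coil inverse FFT, sum-of-squares
# magnitude combination, and homodyne high-pass filtered phase.
#
# The high-pass phase image is the angle of the full-resolution complex image
# divided by its low-pass filtered version. The division cancels smooth
# (low-spatial-frequency) phase — off-resonance, coil phase — while focal
# phase features such as a hemorrhagic lesion survive.

#' Reconstruct images from k-space
#'
#' Centered inverse 2-D FFT per echo and coil; exact inverse of the forward
#' transform used by [simulate_kspace()].
#'
#' @param k a [kspace_series()].
#' @return an [echo_series()].
#' @export
reconstruct <- function(k) {
  stopifnot(inherits(k, "kspace_series"))
  img <- k$data
  for (e in seq_len(n_echoes(k)))
    for (j in seq_len(n_coils(k)))
      img[, , j, e] <- ifft2c(k$data[, , j, e])
  echo_series(img, k$echo_times, k$coil_ids)
}

# Radial squared-Hanning low-pass window on an nr x nc DC-centered grid:
# W(r) = [0.5 * (1 + cos(2*pi*r / (n_points - 1)))]^2  for r <= (n_points-1)/2,
# 0 beyond. W(0) = 1 so DC passes; W reaches 0 at r ~ n_points/2 samples.
hanning2_window <- function(nr, nc, n_points) {
  if (n_points < 4L || n_points %% 2L != 0L)
    stop("`n_points` must be an even integer >= 4", call. = FALSE)
  if (n_points / 2 > min(nr, nc) / 2)
    stop(sprintf(
      "filter support (n_points/2 = %d samples) exceeds half the smallest grid dimension (%d)",
      n_points %/% 2L, min(nr, nc) %/% 2L), call. = FALSE)
  r <- matrix(seq_len(nr), nr, nc) - dc_index(nr)
  cl <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dc_index(nc)
  kr <- sqrt(r^2 + cl^2)
  w <- (0.5 * (1 + cos(2 * pi * kr / (n_points - 1))))^2
  w[kr > (n_points - 1) / 2] <- 0
  w
}

#' Complex low-pass filter an image series
#'
#' Per echo and coil: forward FFT, multiply k-space by an `n_points`-point
#' radial squared-Hanning window (unity at DC, zero beyond `n_points/2`
#' samples), inverse FFT.
#'
#' @param es an [echo_series()].
#' @param n_points filter size in k-space samples (even, >= 4; default 64).
#' @return the low-pass filtered [echo_series()].
#' @export
lowpass_filter_image <- function(es, n_points = 64L) {
  stopifnot(inherits(es, "echo_series"))
  d <- dim(es$data)
  w <- hanning2_window(d[1L], d[2L], n_points)
  out <- es$data
  for (e in seq_len(n_echoes(es)))
    for (j in seq_len(n_coils(es)))
      out[, , j, e] <- ifft2c(fft2c(es$data[, , j, e]) * w)
  echo_series(out, es$echo_times, es$coil_ids)
}

#' Sum-of-squares magnitude combination
#'
#' Standard phased-array magnitude reconstruction: per pixel, the square
#' root of the sum over coils of squared magnitudes.
#'
#' @param es an [echo_series()].
#' @return an `image_stack` of kind `"magnitude"`, `[row, col, echo]`.
#' @export
sos_magnitude <- function(es) {
  stopifnot(inherits(es, "echo_series"))
  d <- dim(es$data)
  mag <- array(0, c(d[1L], d[2L], d[4L]))
  for (e in seq_len(d[4L]))
    mag[, , e] <- sqrt(apply(Mod(es$data[, , , e, drop = FALSE])^2, c(1, 2), sum))
  image_stack(mag, es$echo_times, "magnitude")
}

#' Homodyne high-pass filtered phase
#'
#' Per coil, the full-resolution complex image is divided by its low-pass
#' filtered version; the per-coil ratios are combined by a
#' magnitude-squared-weighted complex sum and the phase of the combination is
#' returned, in `(-pi, pi]`. Pixels whose low-pass magnitude falls below
#' `1e-6` of the per-echo maximum (e.g. air) are flagged invalid and carry
#' phase 0.
#'
#' @inheritParams lowpass_filter_image
#' @return an `image_stack` of kind `"phase"` with a `valid` plane.
#' @export
hpf_phase <- function(es, n_points = 64L) {
  stopifnot(inherits(es, "echo_series"))
  if (all(Mod(es$data) == 0)) {
    warning("all-zero input: high-pass phase undefined everywhere")
    d <- dim(es$data)
    return(image_stack(array(0, c(d[1L], d[2L], d[4L])), es$echo_times,
                       "phase", valid = array(FALSE, c(d[1L], d[2L], d[4L]))))
  }
  lpf <- lowpass_filter_image(es, n_points)
  d <- dim(es$data)
  phase <- array(0, c(d[1L], d[2L], d[4L]))
  valid <- array(FALSE, c(d[1L], d[2L], d[4L]))
  for (e in seq_len(d[4L])) {
    lmag <- array(Mod(lpf$data[, , , e]), d[1:3])
    ok <- lmag > 1e-6 * max(lmag)
    combined <- matrix(0i, d[1L], d[2L])
    for (j in seq_len(d[3L])) {
      full <- es$data[, , j, e]
      ratio <- matrix(0i, d[1L], d[2L])
      okj <- ok[, , j]
      ratio[okj] <- full[okj] / lpf$data[, , j, e][okj]
      combined <- combined + Mod(full)^2 * ratio
    }
    any_ok <- apply(ok, c(1, 2), any)
    phase[, , e][any_ok] <- Arg(combined[any_ok])
    valid[, , e] <- any_ok
  }
  image_stack(phase, es$echo_times, "phase", valid = valid)
}
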