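# Centered, orthonormal 2-D FFT helpers.
#
# Convention used throughout the package (phantom and recon share it, so the
# simulate -> reconstruct roundtrip is exact): the DC sample sits at the array
# center (floor(n/2) + 1 along each axis) and both directions carry a
# 1/sqrt(n_pixels) factor, so Parseval's identity holds exactly.

circ_shift_idx <- function(n, k) ((seq_len(n) - 1 - k) %% n) + 1L

fftshift2 <- function(x) {
  x[circ_shift_idx(nrow(x), nrow(x) %/% 2L),
    circ_shift_idx(ncol(x), ncol(x) %/% 2L), drop = FALSE]
}

ifftshift2 <- function(x) {
  x[circ_shift_idx(nrow(x), -(nrow(x) %/% 2L)),
    circ_shift_idx(ncol(x), -(ncol(x) %/% 2L)), drop = FALSE]
}

#' Centered orthonormal 2-D Fourier transforms
#'
#' `fft2c()` maps an image-domain matrix to DC-centered k-space;
#' `ifft2c()` is its exact inverse. Both are unitary (orthonormal scaling),
#' so image-domain and k-space energies agree.
#'
#' @param x a numeric or complex matrix.
#' @return a complex matrix of the same dimensions.
#' @examples
#' x <- matrix(rnorm(16), 4)
#' max(Mod(ifft2c(fft2c(x)) - x)) < 1e-12
#' @export
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# Index (1-based) of the DC sample on an n-point centered axis.
dc_index <- function(n) n %/% 2L + 1L
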