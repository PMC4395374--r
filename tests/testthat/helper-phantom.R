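# Shared fixtures, built in code.

# Default-geometry phantom with overridable noise/coils/seed.
make_spec <- function(noise_sigma = 0, n_coils = 1L, seed = 1L, ...) {
  phantom_spec(noise_sigma = noise_sigma, n_coils = n_coils, seed = seed, ...)
}

# Simulate -> reconstruct -> combined magnitude (+ optionally HPF phase).
recon_products <- function(spec, with_phase = FALSE, n_points = 64L) {
  es <- reconstruct(simulate_kspace(spec))
  out <- list(es = es, mag = sos_magnitude(es), rois = phantom_rois(spec))
  if (with_phase) out$phase <- hpf_phase(es, n_points)
  out
}

# Wrap a single matrix as a 1-coil 1-echo series.
as_series <- function(img, te = 5) {
  echo_series(array(img, c(dim(img), 1L, 1L)), te)
}

# Per-echo lesion/remote contrast of a stack (matrix route, no TE-averaging).
per_echo_contrast <- function(stack, rois) {
  vapply(seq_along(stack$echo_times), function(e) {
    contrast_sdnr(stack$data[, , e], rois)$contrast
  }, numeric(1))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
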