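test_that("reconstruction inverts the centered FFT and is linear", {
  # delta at the DC sample in k-space -> constant image
  n <- 32L
  k <- array(0i, c(n, n, 1L, 1L))
  k[n %/% 2L + 1L, n %/% 2L + 1L, 1L, 1L] <- 1 + 0i
  img <- reconstruct(kspace_series(k, 5))$data[, , 1L, 1L]
  expect_lt(max(Mod(img - img[1L, 1L])), 1e-12)

  # linearity on random small arrays
  set.seed(1)
  ka <- array(complex(real = rnorm(8 * 8 * 2 * 2),
                      imaginary = rnorm(8 * 8 * 2 * 2)), c(8, 8, 2, 2))
  kb <- array(complex(real = rnorm(8 * 8 * 2 * 2),
                      imaginary = rnorm(8 * 8 * 2 * 2)), c(8, 8, 2, 2))
  te <- c(1, 2)
  lhs <- reconstruct(kspace_series(2 * ka - 3 * kb, te))$data
  rhs <- 2 * reconstruct(kspace_series(ka, te))$data -
    3 * reconstruct(kspace_series(kb, te))$data
  expect_lt(max(Mod(lhs - rhs)), 1e-12)

  expect_error(kspace_series(array(NaN + 0i, c(4, 4, 1, 1)), 5), "finite")
})

test_that("radial squared-Hanning window passes DC, kills high frequencies, and is monotone", {
  w <- cardioswi:::hanning2_window(192L, 192L, 64L)
  expect_equal(w[97L, 97L], 1)                       # W(0) = 1
  r <- 0:96
  wr <- ifelse(r <= 31.5, (0.5 * (1 + cos(2 * pi * r / 63)))^2, 0)
  expect_true(all(diff(wr) <= 1e-12))                # radially non-increasing
  expect_true(all(w[cbind(97L + 32:95, rep(97L, 64))] == 0))

  # constant image passes unchanged; beyond-cutoff sinusoid is annihilated
  const <- as_series(matrix(1 + 0i, 64, 64))
  expect_lt(max(Mod(lowpass_filter_image(const, 32L)$data - 1)), 1e-10)
  x <- matrix(seq_len(64), 64, 64)
  hi <- as_series(exp(2i * pi * 24 * x / 64))        # radius 24 > cutoff 16
  out <- lowpass_filter_image(hi, 32L)$data
  expect_lt(sum(Mod(out)^2) / sum(Mod(hi$data)^2), 1e-6)

  expect_error(lowpass_filter_image(as_series(matrix(1 + 0i, 16, 16)), 64L),
               "support")
  expect_error(cardioswi:::hanning2_window(64L, 64L, 7L), "even")
})

test_that("sum-of-squares combination reduces correctly and dominates single coils", {
  set.seed(2)
  img <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  one <- sos_magnitude(echo_series(array(img, c(16, 16, 1, 1)), 5))
  expect_equal(one$data[, , 1L], Mod(img), tolerance = 1e-12)

  two <- sos_magnitude(echo_series(array(c(img, img), c(16, 16, 2, 1)), 5))
  expect_equal(two$data[, , 1L], sqrt(2) * Mod(img), tolerance = 1e-12)

  img2 <- matrix(complex(real = rnorm(256), imaginary = rnorm(256)), 16, 16)
  both <- sos_magnitude(echo_series(array(c(img, img2), c(16, 16, 2, 1)), 5))
  expect_true(all(both$data[, , 1L] >= Mod(img) - 1e-12))
  expect_true(all(both$data[, , 1L] >= Mod(img2) - 1e-12))
})

test_that("high-pass phase cancels smooth phase and keeps focal features", {
  # smooth (low-frequency) phase only (no focal lesion phase):
  # HPF phase ~ 0 over the whole annulus
  tis0 <- default_tissues()
  tis0$lesion$focal_phase <- 0
  pr_s <- recon_products(make_spec(tissues = tis0), with_phase = TRUE)
  expect_lt(max(abs(pr_s$phase$data[, , 12L][pr_s$rois$lv])), 0.05)

  # focal -1 rad lesion: strongly negative inside, ~0 away from the rim
  spec <- make_spec()
  pr <- recon_products(spec, with_phase = TRUE)
  dles <- cardioswi:::radius_map(spec$grid_shape, spec$lesion_center)
  lesion_core <- dles <= spec$lesion_radius - 1
  away <- pr$rois$lv & dles > spec$lesion_radius + 4
  expect_lt(mean(pr$phase$data[, , 12L][lesion_core]), -0.5)
  expect_lt(max(abs(pr$phase$data[, , 12L][away])), 0.1)

  # a ~1-px focal feature (extent << grid/n_points) is preserved within 10%
  img <- matrix(1 + 0i, 192, 192)
  img[96, 96] <- exp(-1i)
  ph1 <- hpf_phase(as_series(img))
  expect_rel_equal(ph1$data[96, 96, 1L], -1, 0.1)
})

test_that("high-pass phase is invariant to global complex scaling", {
  spec <- make_spec(noise_sigma = 0.02, seed = 3L)
  es <- reconstruct(simulate_kspace(spec))
  ph0 <- hpf_phase(es)
  scaled <- echo_series(es$data * (2.5 * exp(1.3i)), es$echo_times)
  ph1 <- hpf_phase(scaled)
  expect_equal(ph1$data, ph0$data, tolerance = 1e-10)
  expect_identical(ph1$valid, ph0$valid)
})

test_that("all-zero input yields all-invalid phase with a warning, not a crash", {
  es <- echo_series(array(0i, c(16, 16, 1, 1)), 5)
  expect_warning(ph <- hpf_phase(es), "all-zero")
  expect_true(all(!ph$valid))
})
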