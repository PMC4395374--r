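make_rois <- function(n = 10L) {
  lesion <- remote <- noise <- matrix(FALSE, n, n)
  lesion[1:3, 1:3] <- TRUE
  remote[1:3, 5:7] <- TRUE
  noise[8:10, 1:10] <- TRUE
  roi_set(lesion = lesion, remote = remote, noise = noise)
}

test_that("ROI statistics are plain means/STDs over valid pixels", {
  rois <- make_rois()
  img <- matrix(3.7, 10, 10)
  st <- roi_stats(img, rois)
  expect_equal(st$mean, rep(3.7, 3))
  expect_equal(st$sd, rep(0, 3))
  expect_equal(st$n_pixels, c(9L, 9L, 30L))

  # required-ROI contract: the missing ROI is named
  expect_error(contrast_sdnr(img, roi_set(lesion = rois$lesion,
                                          noise = rois$noise)), "remote")

  # phantom at sigma = 0, longest TE: ROI means equal closed-form decay
  pr <- recon_products(make_spec())
  st12 <- roi_stats(pr$mag$data[, , 12L], pr$rois)
  expect_equal(st12$mean[st12$roi == "lesion"], exp(-15.5 / 16.2),
               tolerance = 1e-10)
  expect_equal(st12$mean[st12$roi == "remote"], exp(-15.5 / 34.1),
               tolerance = 1e-10)
})

test_that("contrast and SDNR follow the printed formulas", {
  rois <- make_rois()
  img <- matrix(0, 10, 10)
  img[rois$remote] <- 1.0
  img[rois$lesion] <- 0.4
  z <- seq(-1, 1, length.out = 30)
  img[rois$noise] <- 0.1 * (z - mean(z)) / stats::sd(z)  # STD exactly 0.1
  res <- contrast_sdnr(img, rois)
  expect_equal(res$contrast, 0.6)
  expect_equal(res$sdnr, 6.0)

  # s1 = s2 -> both zero
  img2 <- img; img2[rois$lesion] <- 1.0
  res2 <- contrast_sdnr(img2, rois)
  expect_equal(res2$contrast, 0)
  expect_equal(res2$sdnr, 0)

  # scale invariance of both quantities
  res3 <- contrast_sdnr(10 * img, rois)
  expect_equal(res3$contrast, res$contrast, tolerance = 1e-12)
  expect_equal(res3$sdnr, res$sdnr, tolerance = 1e-12)

  # s1 = 0 flagged; loud noise ROI warned
  img4 <- img; img4[rois$remote] <- 0
  expect_warning(res4 <- contrast_sdnr(img4, rois), "undefined")
  expect_true(is.na(res4$contrast))
  img5 <- img; img5[rois$noise] <- img5[rois$noise] + 0.5
  expect_warning(contrast_sdnr(img5, rois), "signal-free")
})

test_that("half-max volume rule counts hyperintense pixels plus enclosed cores", {
  lv <- matrix(FALSE, 20, 20)
  lv[3:18, 3:18] <- TRUE                          # 256-px "LV"
  img <- matrix(0.1, 20, 20)

  # uniform LV -> whole mask selected
  img_u <- img; img_u[lv] <- 1
  expect_equal(threshold_volume(img_u, lv)$percent_lv, 100)

  # half the LV above threshold, no holes
  img_h <- img; img_h[lv] <- 0.2; img_h[3:10, 3:18] <- 1
  expect_equal(threshold_volume(img_h, lv)$percent_lv, 50)

  # bright region with an enclosed dark core: core pixels are included
  img_c <- img; img_c[lv] <- 0.2
  img_c[5:12, 5:12] <- 1                          # 64 bright px
  img_c[8:9, 8:9] <- 0.2                          # 4-px enclosed core
  res <- threshold_volume(img_c, lv)
  expect_equal(res$lesion_pixels, 64L)            # 60 bright + 4 core
  expect_equal(res$lv_pixels, 256L)
  expect_equal(res$percent_lv, 100 * 64 / 256)

  # a dark bay opening into sub-threshold LV is NOT included
  img_b <- img_c; img_b[8:9, 8:12] <- 0.2         # bay reaches the block edge
  expect_equal(threshold_volume(img_b, lv)$lesion_pixels, 54L)

  # idempotence: thresholding the binary selection returns the same set
  sel <- matrix(0, 20, 20); sel[5:12, 5:12] <- 1
  expect_equal(threshold_volume(sel, lv)$lesion_pixels, 64L)

  # positive rescaling leaves the half-max selection unchanged
  expect_equal(threshold_volume(3.2 * img_c, lv)$lesion_pixels, 64L)

  # manual hypo-intensity rule
  res_m <- threshold_volume(img_c, lv, rule = "manual_hypo", threshold = 0.25)
  expect_equal(res_m$lesion_pixels, 256L - 64L + 4L)
  expect_error(threshold_volume(img_c, lv, rule = "manual_hypo"), "threshold")
  expect_error(threshold_volume(img_c, matrix(FALSE, 20, 20)), "empty")
})

test_that("sweep report orders sources and shrinks contrast with averaging", {
  spec <- make_spec(noise_sigma = 0.03, n_coils = 4L, seed = 2L)
  pr <- recon_products(spec, with_phase = TRUE)
  rep_tbl <- sweep_report(pr$mag, pr$phase, pr$rois)
  expect_s3_class(rep_tbl, "swi_sweep")
  expect_identical(nrow(rep_tbl), 36L)
  expect_setequal(unique(rep_tbl$source), c("magnitude", "swi3", "swi6"))

  wide <- split(rep_tbl, rep_tbl$source)
  # swi6 >= swi3 >= magnitude at every nTE
  expect_true(all(wide$swi6$contrast >= wide$swi3$contrast))
  expect_true(all(wide$swi3$contrast > wide$magnitude$contrast))

})

test_that("a lesion-free phantom shows no contrast beyond the noise bound", {
  # the deterministic part (homodyne edge ripple) is measured at sigma = 0;
  # the noise part, averaged over independent realizations, must stay within
  # twice the single-realization noise-propagated bound
  tis <- default_tissues()
  tis$lesion <- tis$myocardium
  pr_det <- recon_products(make_spec(tissues = tis), with_phase = TRUE)
  det <- sweep_report(pr_det$mag, pr_det$phase, pr_det$rois)
  expect_true(all(abs(det$contrast[det$source == "magnitude"]) < 1e-10))

  seeds <- c(21L, 22L, 23L, 24L)
  reps <- lapply(seeds, function(sd) {
    pr <- recon_products(make_spec(noise_sigma = 0.03, seed = sd,
                                   tissues = tis), with_phase = TRUE)
    sweep_report(pr$mag, pr$phase, pr$rois)
  })
  avg_contrast <- Reduce(`+`, lapply(reps, `[[`, "contrast")) / length(seeds)
  n_les <- sum(pr_det$rois$lesion); n_rem <- sum(pr_det$rois$remote)
  bound <- 2 * reps[[1L]]$noise_std * sqrt(1 / n_les + 1 / n_rem) /
    reps[[1L]]$s1
  expect_true(all(abs(avg_contrast - det$contrast) < bound))
})

test_that("sweep plots build without error", {
  spec <- make_spec(noise_sigma = 0.02, seed = 4L)
  pr <- recon_products(spec, with_phase = TRUE)
  rep_tbl <- sweep_report(pr$mag, pr$phase, pr$rois, n_multiplies = 6L)
  p <- plot_sweep(rep_tbl, "sdnr")
  expect_s3_class(p, "ggplot")
  expect_s3_class(ggplot2::autoplot(rep_tbl), "ggplot")
  expect_s3_class(plot_image(te_average(pr$mag, 9L)), "ggplot")
})
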