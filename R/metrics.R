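# Image-analysis quantities: ROI statistics, contrast, SDNR, and
# threshold-based lesion volumetry.
#
#   Contrast = (S1 - S2) / S1        SDNR = (S1 - S2) / STD
#
# with S1 the adjacent (remote) myocardium mean, S2 the lesion mean, and STD
# the raw standard deviation of magnitude values in a signal-free noise ROI
# (no Rayleigh correction).

as_image_plane <- function(img) {
  if (inherits(img, "te_image")) list(data = img$data, valid = img$valid,
                                      source_kind = img$source_kind,
                                      n_te = img$n_te,
                                      n_multiplies = img$n_multiplies)
  else if (is.matrix(img)) list(data = img, valid = NULL,
                                source_kind = NA_character_,
                                n_te = NA_integer_, n_multiplies = NA_integer_)
  else stop("`img` must be a matrix or a te_image", call. = FALSE)
}

#' Per-ROI means and standard deviations
#'
#' Statistics are taken over valid pixels only (a `te_image` carries its
#' validity plane; invalid pixels are excluded).
#'
#' @param img numeric matrix or `te_image`.
#' @param rois a [roi_set()] on the same grid.
#' @return a tibble with columns `roi`, `n_pixels`, `mean`, `sd`.
#' @export
roi_stats <- function(img, rois) {
  stopifnot(inherits(rois, "roi_set"))
  pl <- as_image_plane(img)
  if (!all(dim(pl$data) == dim(rois[[1L]])))
    stop("image and ROI grids differ", call. = FALSE)
  rows <- lapply(names(rois), function(nm) {
    sel <- rois[[nm]] & (if (is.null(pl$valid)) TRUE else pl$valid)
    v <- pl$data[sel]
    tibble::tibble(roi = nm, n_pixels = length(v),
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Lesion contrast and signal-difference-to-noise ratio
#'
#' Applies `contrast = (S1 - S2)/S1` and `sdnr = (S1 - S2)/STD` with S1 the
#' reference-ROI mean, S2 the lesion-ROI mean, and STD the raw standard
#' deviation of the noise ROI. Warns when the noise ROI mean exceeds 20% of
#' S1 (noise ROI not signal-free) and flags S1 = 0 as undefined contrast.
#'
#' @param img numeric matrix or `te_image`.
#' @param rois a [roi_set()] containing `lesion`, `remote` and `noise`
#'   masks (names configurable).
#' @param lesion,reference,noise ROI names for S2, S1 and the noise region.
#' @return one-row tibble: `source`, `n_te`, `n_multiplies`, `s1`, `s2`,
#'   `noise_std`, `contrast`, `sdnr`.
#' @export
contrast_sdnr <- function(img, rois, lesion = "lesion",
                          reference = "remote", noise = "noise") {
  require_rois(rois, c(lesion, reference, noise))
  st <- roi_stats(img, rois)
  s1 <- st$mean[st$roi == reference]
  s2 <- st$mean[st$roi == lesion]
  nstd <- st$sd[st$roi == noise]
  nmean <- st$mean[st$roi == noise]
  if (is.finite(nmean) && is.finite(s1) && s1 != 0 && nmean > 0.2 * s1)
    warning("noise ROI mean exceeds 20% of the reference signal; ",
            "it may not be signal-free")
  contrast <- if (is.finite(s1) && s1 != 0) (s1 - s2) / s1 else {
    warning("reference mean S1 is zero: contrast undefined")
    NA_real_
  }
  scale_floor <- 1e-12 * max(abs(s1), abs(s2), .Machine$double.xmin)
  sdnr <- if (is.finite(nstd) && nstd > scale_floor) (s1 - s2) / nstd
          else NA_real_
  pl <- as_image_plane(img)
  tibble::tibble(source = pl$source_kind, n_te = pl$n_te,
                 n_multiplies = if (length(pl$n_multiplies)) pl$n_multiplies
                                else NA_integer_,
                 s1 = s1, s2 = s2, noise_std = nstd,
                 contrast = contrast, sdnr = sdnr)
}

#' Threshold-based lesion volume as a fraction of LV myocardium
#'
#' Rule `"half_max_hyper"` (hyperenhancement, LGE-style): selects LV pixels
#' at or above 50% of the maximum myocardial signal, then adds enclosed
#' hypointense cores — 4-connected components of below-threshold pixels
#' whose neighbourhood stays inside the above-threshold/LV region
#' (microvascular-obstruction inclusion). Rule `"manual_hypo"`: selects LV
#' pixels at or below a user-supplied threshold (hemorrhage/MVO-style
#' hypointensity).
#'
#' @param img numeric matrix or `te_image`.
#' @param lv_mask logical matrix of the LV myocardium.
#' @param rule `"half_max_hyper"` or `"manual_hypo"`.
#' @param threshold signal threshold, required for `"manual_hypo"`.
#' @return one-row tibble: `rule`, `threshold`, `lesion_pixels`,
#'   `lv_pixels`, `percent_lv`.
#' @export
threshold_volume <- function(img, lv_mask,
                             rule = c("half_max_hyper", "manual_hypo"),
                             threshold = NULL) {
  rule <- match.arg(rule)
  pl <- as_image_plane(img)
  if (!any(lv_mask)) stop("empty LV mask", call. = FALSE)
  x <- pl$data
  if (rule == "half_max_hyper") {
    thr <- 0.5 * max(x[lv_mask])
    sel <- lv_mask & x >= thr
    below <- lv_mask & !sel
    labs <- label_components4(below)
    nr <- nrow(x); nc <- ncol(x)
    for (lab in seq_len(max(labs, 0L))) {
      comp <- which(labs == lab)
      nb <- setdiff(neighbours4(comp, nr, nc), comp)
      if (all(sel[nb])) sel[comp] <- TRUE  # enclosed hypointense core
    }
  } else {
    if (is.null(threshold))
      stop("rule 'manual_hypo' needs an explicit `threshold`", call. = FALSE)
    thr <- threshold
    sel <- lv_mask & x <= thr
  }
  tibble::tibble(rule = rule, threshold = thr,
                 lesion_pixels = sum(sel), lv_pixels = sum(lv_mask),
                 percent_lv = 100 * sum(sel) / sum(lv_mask))
}

#' Contrast/SDNR sweep over reconstruction and TE-averaging
#'
#' Evaluates [contrast_sdnr()] for every combination of source image
#' (magnitude, and SWI at each requested mask-multiply count) and
#' `n_te = 1..n_echoes` TE-averages.
#'
#' @param mag_stack `image_stack` of kind `"magnitude"`.
#' @param phase_stack `image_stack` of kind `"phase"` (high-pass filtered).
#' @param rois a [roi_set()] with `lesion`, `remote` and `noise` masks.
#' @param n_multiplies integer vector of mask-multiply counts for the SWI
#'   sources (default `c(3, 6)`).
#' @return a `swi_sweep` tibble: one row per source x n_te, columns as in
#'   [contrast_sdnr()] with `source` in `"magnitude"`, `"swi3"`, `"swi6"`, ...
#' @export
sweep_report <- function(mag_stack, phase_stack, rois,
                         n_multiplies = c(3L, 6L)) {
  stacks <- c(list(magnitude = mag_stack),
              stats::setNames(
                lapply(n_multiplies,
                       function(n) swi_series(mag_stack, phase_stack, n)),
                paste0("swi", n_multiplies)))
  rows <- lapply(names(stacks), function(src) {
    sweep <- te_average_sweep(stacks[[src]])
    do.call(rbind, lapply(sweep, function(ti) {
      row <- contrast_sdnr(ti, rois)
      row$source <- src
      row
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("swi_sweep", class(out))
  out
}
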