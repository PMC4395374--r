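# ROI-based T2* estimation and the AHA-style sector partition.
#
# Decay curves are ROI means of the magnitude signal at each echo, fitted
# with the three-parameter offset exponential
#   S(TE) = So * exp(-TE / T2*) + C
# where C absorbs the magnitude noise floor. Fits are bounded nonlinear
# least squares (Levenberg-Marquardt), T2* constrained to (0.1, 500] ms.

#' ROI decay curve
#'
#' @param echo_times echo times in ms, strictly increasing.
#' @param mean_signal per-echo ROI mean signal, same length.
#' @param roi_name optional label carried into fit output.
#' @return a `decay_curve`.
#' @export
decay_curve <- function(echo_times, mean_signal, roi_name = NULL) {
  echo_times <- as.numeric(echo_times)
  mean_signal <- as.numeric(mean_signal)
  if (length(echo_times) != length(mean_signal))
    stop("echo_times and mean_signal lengths differ", call. = FALSE)
  if (any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing", call. = FALSE)
  structure(list(echo_times = echo_times, mean_signal = mean_signal,
                 roi_name = roi_name), class = "decay_curve")
}

#' Fit the offset-exponential T2* decay model
#'
#' Fits `S = So * exp(-TE/T2*) + C` by bounded Levenberg-Marquardt least
#' squares. Initialization: `C0 = min(S)`, `So0 = max(S) - C0`, and `T2*`
#' from a log-linear fit of the first half of the echoes after subtracting
#' `C0`. Non-convergence (including unidentifiable flat curves) is reported
#' through the `converged` flag, never as an error.
#'
#' @param x a [decay_curve()], or a data frame with columns `echo_time`
#'   (or `te`) and `signal`, or a numeric vector of echo times (ms).
#' @param signal per-echo signal when `x` is the echo-time vector.
#' @return a `t2star_fit`: `t2_star` (ms), `s_o`, `c_offset`,
#'   `residual_rms`, `converged`, `n_echoes`, `roi_name`.
#'   Use [tidy.t2star_fit()] / [glance.t2star_fit()] for tabular access.
#' @export
fit_t2star <- function(x, signal = NULL) {
  if (inherits(x, "decay_curve")) {
    te <- x$echo_times; s <- x$mean_signal; nm <- x$roi_name
  } else if (is.data.frame(x)) {
    te_col <- intersect(c("echo_time", "te"), names(x))[1L]
    if (is.na(te_col) || !"signal" %in% names(x))
      stop("data frame must have columns echo_time (or te) and signal",
           call. = FALSE)
    te <- x[[te_col]]; s <- x$signal; nm <- NULL
  } else {
    te <- as.numeric(x); s <- as.numeric(signal); nm <- NULL
  }
  if (length(te) < 4L)
    stop("need at least 4 echoes to fit the 3-parameter model", call. = FALSE)
  if (length(te) != length(s))
    stop("echo-time and signal lengths differ", call. = FALSE)

  out <- list(t2_star = NA_real_, s_o = NA_real_, c_offset = NA_real_,
              residual_rms = NA_real_, converged = FALSE,
              n_echoes = length(te), roi_name = nm)
  class(out) <- "t2star_fit"

  c0 <- min(s)
  so0 <- max(s) - c0
  if (so0 <= 1e-12 * max(abs(s), 1)) return(out)  # flat curve: unidentifiable

  half <- seq_len(max(2L, length(te) %/% 2L))
  y <- s[half] - c0
  pos <- y > 0
  t20 <- if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ te[half][pos]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else stats::median(te)
  } else stats::median(te)
  t20 <- min(max(t20, 0.2), 400)

  # the offset-exponential SSE surface can be multimodal when the echo train
  # is short relative to T2*; a small multi-start over T2* keeps the global
  # least-squares solution
  starts <- unique(c(t20, 5, 15, 40, 120))
  fit <- NULL
  for (t2s in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = c(so = so0, t2 = t2s, cc = c0),
        lower = c(0, 0.1, -Inf), upper = c(Inf, 500, Inf),
        fn = function(p) p[1L] * exp(-te / p[2L]) + p[3L] - s,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) fit <- cand
  }
  if (is.null(fit)) return(out)

  out$t2_star <- unname(fit$par["t2"])
  out$s_o <- unname(fit$par["so"])
  out$c_offset <- unname(fit$par["cc"])
  out$residual_rms <- sqrt(mean(fit$fvec^2))
  # a fit pinned to the T2* bounds is not a credible estimate
  out$converged <- out$t2_star > 0.1 + 1e-9 && out$t2_star < 500 - 1e-9
  out
}

#' @export
print.t2star_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<t2star_fit%s> T2* = %.2f ms, So = %.4g, C = %.4g (rms %.3g)\n",
                if (is.null(x$roi_name)) "" else paste0(":", x$roi_name),
                x$t2_star, x$s_o, x$c_offset, x$residual_rms))
  else
    cat("<t2star_fit> not converged / unidentifiable\n")
  invisible(x)
}

#' Tidy a T2* fit
#'
#' broom-style accessors: `tidy()` returns one row per parameter,
#' `glance()` one row of fit-level summaries.
#'
#' @param x a `t2star_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.t2star_fit <- function(x, ...) {
  tibble::tibble(term = c("t2_star", "s_o", "c_offset"),
                 estimate = c(x$t2_star, x$s_o, x$c_offset))
}

#' @rdname tidy.t2star_fit
#' @export
glance.t2star_fit <- function(x, ...) {
  tibble::tibble(t2_star = x$t2_star, s_o = x$s_o, c_offset = x$c_offset,
                 residual_rms = x$residual_rms, converged = x$converged,
                 n_echoes = x$n_echoes)
}

#' Turn a fitted object into a tidy tibble
#'
#' Generics in the broom style; see [tidy.t2star_fit()].
#'
#' @param x a fitted object.
#' @param ... passed to methods.
#' @return a tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' AHA-style sector partition of a myocardial annulus
#'
#' Partitions the annulus by polar angle about its centroid into 6 equal
#' sectors (basal and mid levels) or 4 (apical), numbered counterclockwise
#' from the reference angle, following the 16-segment convention
#' (one short-axis slice per level; no apex cap).
#'
#' @param annulus_mask logical matrix: the LV myocardium ring.
#' @param rv_insertion_angle reference angle in radians (anterior RV
#'   insertion), measured counterclockwise from the image +x (column) axis.
#' @param level `"basal"`, `"mid"` or `"apical"`.
#' @return a [roi_set()] of disjoint masks `sector1..sectorN` whose union
#'   is the annulus.
#' @export
aha_sectors <- function(annulus_mask, rv_insertion_angle = 0,
                        level = c("basal", "mid", "apical")) {
  level <- match.arg(level)
  n_sec <- if (level == "apical") 4L else 6L
  if (!any(annulus_mask)) stop("empty annulus mask", call. = FALSE)
  idx <- which(annulus_mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  ctr_px <- c(round(ctr[1L]), round(ctr[2L]))
  if (annulus_mask[ctr_px[1L], ctr_px[2L]])
    stop("mask is not annular: centroid pixel lies inside the mask",
         call. = FALSE)
  # image row axis points down; use y-up so angles are counterclockwise
  theta <- atan2(ctr[1L] - idx[, 1L], idx[, 2L] - ctr[2L])
  sec <- floor(((theta - rv_insertion_angle) %% (2 * pi)) / (2 * pi / n_sec)) + 1L
  sec[sec > n_sec] <- n_sec  # guard against rounding at exactly 2*pi
  masks <- lapply(seq_len(n_sec), function(k) {
    m <- matrix(FALSE, nrow(annulus_mask), ncol(annulus_mask))
    m[idx[sec == k, , drop = FALSE]] <- TRUE
    m
  })
  names(masks) <- paste0("sector", seq_len(n_sec))
  roi_set(masks)
}

#' Per-sector T2* fits
#'
#' Builds a decay curve (per-echo mean over each sector, valid pixels only)
#' from a magnitude stack and fits the offset exponential in every sector.
#'
#' @param mag_stack an `image_stack` of kind `"magnitude"`.
#' @param sectors a [roi_set()] of sector masks (see [aha_sectors()]).
#' @return a tibble with one row per sector: `sector`, `n_pixels`,
#'   `t2star_ms`, `so`, `c`, `residual_rms`, `converged`,
#'   `low_confidence` (fewer than 5 pixels; still fitted).
#' @export
segment_t2star <- function(mag_stack, sectors) {
  stopifnot(inherits(mag_stack, "image_stack"),
            inherits(sectors, "roi_set"))
  rows <- lapply(names(sectors), function(nm) {
    mask <- sectors[[nm]]
    means <- vapply(seq_along(mag_stack$echo_times), function(e) {
      pl <- stack_plane(mag_stack, e)
      sel <- mask & (if (is.null(pl$valid)) TRUE else pl$valid)
      mean(pl$data[sel])
    }, numeric(1))
    fit <- fit_t2star(decay_curve(mag_stack$echo_times, means, nm))
    tibble::tibble(sector = nm, n_pixels = sum(mask),
                   t2star_ms = fit$t2_star, so = fit$s_o, c = fit$c_offset,
                   residual_rms = fit$residual_rms, converged = fit$converged,
                   low_confidence = sum(mask) < 5L)
  })
  do.call(rbind, rows)
}
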