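# Reconstruction class (3): TE-averaging over the longest echoes, plus the
# inverted-grayscale display transform.
#
# Averaging the nTE longest-echo images trades susceptibility contrast
# (strongest at long TE) against noise (the average's noise STD falls as
# 1/sqrt(nTE)); with 12 echoes, nTE = 1 is the longest-TE image alone and
# nTE = 2..12 give the 11 multi-echo averages.

#' Average the longest-echo images
#'
#' Arithmetic mean over the `n_te` highest-TE planes of the stack;
#' `n_te = 1` returns the longest-TE image unchanged.
#'
#' @param stack an `image_stack` (kind `"magnitude"` or `"swi"`).
#' @param n_te number of longest echoes to average, `1 <= n_te <= n_echoes`.
#' @return a `te_image`: list with `data` (matrix), `n_te`, `echo_indices`
#'   (the averaged echoes, ascending), `source_kind`, `n_multiplies`,
#'   `valid`, and `display_only = FALSE`.
#' @export
te_average <- function(stack, n_te) {
  stopifnot(inherits(stack, "image_stack"))
  ne <- dim(stack$data)[3L]
  if (n_te < 1L || n_te > ne)
    stop(sprintf("n_te must be in [1, %d]", ne), call. = FALSE)
  idx <- seq.int(ne - n_te + 1L, ne)
  planes <- stack$data[, , idx, drop = FALSE]
  avg <- apply(planes, c(1, 2), mean)
  valid <- if (!is.null(stack$valid))
    apply(stack$valid[, , idx, drop = FALSE], c(1, 2), all)
  structure(list(data = avg, n_te = as.integer(n_te), echo_indices = idx,
                 source_kind = stack$kind, n_multiplies = stack$n_multiplies,
                 valid = valid, display_only = FALSE),
            class = "te_image")
}

#' @export
print.te_image <- function(x, ...) {
  cat(sprintf("<te_image:%s> nTE = %d (echoes %s)%s\n", x$source_kind, x$n_te,
              paste(range(x$echo_indices), collapse = "-"),
              if (isTRUE(x$display_only)) " [display only]" else ""))
  invisible(x)
}

#' All TE-averaged images of a stack
#'
#' @param stack an `image_stack`.
#' @return list of [te_average()] results for `n_te = 1..n_echoes`,
#'   in that order.
#' @export
te_average_sweep <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  ne <- dim(stack$data)[3L]
  if (ne < 1L) stop("empty stack", call. = FALSE)
  lapply(seq_len(ne), function(n) te_average(stack, n))
}

#' Inverted-grayscale display transform
#'
#' Clips to `window = (low, high)` and maps linearly to `[0, 1]` with the
#' sense reversed, so short-T2*/negative-phase tissue (dark on SWI) displays
#' bright, as on late-gadolinium-enhancement images. Display-only: the
#' result is flagged and must not feed back into metrics.
#'
#' @param img numeric matrix or `te_image`.
#' @param window length-2 numeric `(low, high)`, `high > low`. Default:
#'   `c(0, max(img))`.
#' @return for a matrix input, a matrix in `[0, 1]`; for a `te_image`, a
#'   `te_image` with `display_only = TRUE`.
#' @export
invert_grayscale <- function(img, window = NULL) {
  x <- if (inherits(img, "te_image")) img$data else img
  if (is.null(window)) window <- c(0, max(x))
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("`window` must be (low, high) with high > low", call. = FALSE)
  v <- pmin(pmax(x, window[1L]), window[2L])
  out <- (window[2L] - v) / (window[2L] - window[1L])
  if (inherits(img, "te_image")) {
    img$data <- out
    img$display_only <- TRUE
    img
  } else out
}
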