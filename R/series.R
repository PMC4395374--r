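# Multi-echo multi-coil series containers.
#
# Both containers hold a complex 4-D array indexed [row, col, coil, echo]
# plus the echo-time table in milliseconds. `kspace_series` data are
# DC-centered spatial-frequency samples; `echo_series` data are image-domain.

new_series <- function(data, echo_times, coil_ids, class) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-D array [row, col, coil, echo]", call. = FALSE)
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("`data` contains non-finite values", call. = FALSE)
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) != dim(data)[4L])
    stop("length(echo_times) must equal the number of echoes in `data`",
         call. = FALSE)
  if (length(echo_times) > 1L && any(diff(echo_times) <= 0))
    stop("`echo_times` must be strictly increasing", call. = FALSE)
  if (is.null(coil_ids)) coil_ids <- paste0("coil", seq_len(dim(data)[3L]))
  structure(list(data = data, echo_times = echo_times, coil_ids = coil_ids),
            class = class)
}

#' Multi-echo multi-coil complex series containers
#'
#' `echo_series()` wraps image-domain complex data; `kspace_series()` wraps
#' DC-centered spatial-frequency data. Both are indexed
#' `[row, col, coil, echo]` and carry the echo-time table (ms).
#'
#' @param data complex 4-D array `[row, col, coil, echo]`.
#' @param echo_times numeric vector of echo times in ms, strictly increasing,
#'   one per echo.
#' @param coil_ids optional character vector naming the coil elements.
#' @return an object of class `echo_series` or `kspace_series`.
#' @export
echo_series <- function(data, echo_times, coil_ids = NULL) {
  new_series(data, echo_times, coil_ids, c("echo_series", "mri_series"))
}

#' @rdname echo_series
#' @export
kspace_series <- function(data, echo_times, coil_ids = NULL) {
  new_series(data, echo_times, coil_ids, c("kspace_series", "mri_series"))
}

#' @export
print.mri_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d grid, %d coil(s), %d echo(es)\n",
              class(x)[1L], d[1L], d[2L], d[3L], d[4L]))
  cat("  echo times (ms):", paste(format(x$echo_times), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mri_series <- function(x) dim(x$data)

n_echoes <- function(x) dim(x$data)[4L]
n_coils  <- function(x) dim(x$data)[3L]

#' Real-valued per-echo image stack
#'
#' Container for co-registered real images `[row, col, echo]` with
#' provenance: `kind` is `"magnitude"`, `"phase"` or `"swi"`; `valid` is an
#' optional logical array flagging pixels excluded from ROI statistics;
#' `n_multiplies` records the mask-multiply count of an SWI stack.
#'
#' @param data numeric 3-D array `[row, col, echo]`.
#' @param echo_times echo times in ms, one per plane.
#' @param kind source kind string.
#' @param valid optional logical array, same shape as `data`.
#' @param n_multiplies optional integer (SWI stacks).
#' @return an `image_stack`.
#' @export
image_stack <- function(data, echo_times, kind,
                        valid = NULL, n_multiplies = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[3L] == length(echo_times))
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 kind = kind, valid = valid, n_multiplies = n_multiplies),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack:%s> %d x %d grid, %d echo(es)%s\n", x$kind,
              d[1L], d[2L], d[3L],
              if (is.null(x$n_multiplies)) "" else
                sprintf(", %d mask multiplies", x$n_multiplies)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

# Extract one echo plane (matrix) together with its validity plane.
stack_plane <- function(x, echo) {
  list(data = x$data[, , echo],
       valid = if (is.null(x$valid)) NULL else x$valid[, , echo])
}
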