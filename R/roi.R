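# Named ROI masks on the image grid.
#
# A roi_set is a named list of logical matrices, all on the same grid. Masks
# may overlap (the LV myocardium mask contains both the lesion and the remote
# myocardium), which is why the container is a list of masks rather than a
# single integer label image.

#' Create a set of named ROI masks
#'
#' @param ... named logical matrices, all with identical dimensions. Typical
#'   names in this package: `lesion`, `remote`, `lv`, `blood`, `noise`.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1L]]) && !is.matrix(masks[[1L]]))
    masks <- masks[[1L]]
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("all ROI masks must be named", call. = FALSE)
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1L)
    stop("all ROI masks must share the same grid dimensions", call. = FALSE)
  masks <- lapply(masks, function(m) {
    if (!is.logical(m)) m <- m != 0
    m
  })
  structure(masks, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  d <- dim(x[[1L]])
  cat(sprintf("<roi_set> %d mask(s) on a %d x %d grid\n", length(x), d[1L], d[2L]))
  for (nm in names(x)) cat(sprintf("  %-10s %6d px\n", nm, sum(x[[nm]])))
  invisible(x)
}

require_rois <- function(rois, needed) {
  missing <- setdiff(needed, names(rois))
  if (length(missing))
    stop("roi_set is missing required ROI(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(rois)
}

# Label 4-connected components of a logical mask. Returns an integer matrix
# (0 = background). Vectorised frontier expansion; masks here are small
# (a few hundred px on a <=256^2 grid) so this stays fast in plain R.
label_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  todo <- which(mask)
  lab <- 0L
  while (length(todo)) {
    lab <- lab + 1L
    frontier <- todo[1L]
    labels[frontier] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cl <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[cl > 1L] - nr, frontier[cl < nc] + nr)
      nb <- unique(nb[mask[nb] & labels[nb] == 0L])
      labels[nb] <- lab
      frontier <- nb
    }
    todo <- todo[labels[todo] == 0L]
  }
  labels
}

# Linear indices of the 4-neighbours of `idx` (clipped at the grid edge).
neighbours4 <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  cl <- (idx - 1L) %/% nr + 1L
  c(idx[r > 1L] - 1L, idx[r < nr] + 1L, idx[cl > 1L] - nr, idx[cl < nc] + nr)
}
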