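#' Convex-hull observation window
#'
#' TMA cores and ROIs are rarely clean rectangles, so Ripley's K is
#' estimated over the convex hull of *all* measured cells in the sample
#' (any marker status): the tissue region is defined by where cells were
#' observed. The window carries its vertex polygon (counter-clockwise) and
#' area in square microns.
#'
#' @param x a [cell_table()], a two-column matrix of coordinates, or a
#'   numeric vector of x coordinates.
#' @param y numeric vector of y coordinates when `x` is a vector.
#' @return an object of class `tissue_window` with elements `vertices`
#'   (n x 2 matrix, counter-clockwise) and `area` (square microns).
#' @export
convex_hull_window <- function(x, y = NULL) {
  if (inherits(x, "cell_table")) {
    pts <- cbind(x$x, x$y)
  } else if (is.matrix(x) || is.data.frame(x)) {
    pts <- as.matrix(x)[, 1:2, drop = FALSE]
  } else {
    pts <- cbind(x, y)
  }
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3L) stop("degenerate window: need at least 3 points",
                           call. = FALSE)
  idx <- grDevices::chull(pts[, 1L], pts[, 2L])
  verts <- pts[idx, , drop = FALSE]
  if (nrow(verts) < 3L) stop("degenerate window: points are collinear",
                             call. = FALSE)
  a <- .cpp_poly_area(verts[, 1L], verts[, 2L])
  if (a < 0) {           # chull returns clockwise; flip to counter-clockwise
    verts <- verts[rev(seq_len(nrow(verts))), , drop = FALSE]
    a <- -a
  }
  if (a <= 0) stop("degenerate window: points are collinear", call. = FALSE)
  colnames(verts) <- c("x", "y")
  structure(list(vertices = verts, area = a), class = "tissue_window")
}

#' @export
print.tissue_window <- function(x, ...) {
  cat(sprintf("<tissue_window> convex polygon, %d vertices, area %.1f um^2\n",
              nrow(x$vertices), x$area))
  invisible(x)
}

#' Window area
#' @param window a `tissue_window`.
#' @return area in square microns.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "tissue_window"))
  window$area
}

# TRUE for points inside (or within `tol` of) the convex window.
points_in_window <- function(pts, window, tol = 1e-9) {
  v <- window$vertices
  n <- nrow(v)
  inside <- rep(TRUE, nrow(pts))
  scale <- sqrt(window$area)
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1L else i + 1L, ]
    s <- (b[1L] - a[1L]) * (pts[, 2L] - a[2L]) -
         (b[2L] - a[2L]) * (pts[, 1L] - a[1L])
    inside <- inside & (s >= -tol * scale)
  }
  inside
}
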