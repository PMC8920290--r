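#' Theoretical K under complete spatial randomness
#'
#' Under a homogeneous Poisson process the expected Ripley's K is
#' `pi * r^2`, independent of intensity.
#'
#' @param r numeric vector of radii (microns), each >= 0.
#' @return `pi * r^2` per radius.
#' @export
theoretical_csr <- function(r) {
  if (any(!is.finite(r)) || any(r < 0)) stop("radii must be finite and >= 0",
                                             call. = FALSE)
  pi * r^2
}

correction_code <- function(correction) {
  switch(correction, none = 0L, translation = 1L, isotropic = 2L)
}

#' Edge-correction weight for a point pair
#'
#' Cells near the window boundary lose neighbours outside the tissue, so
#' each counted pair (i, j) is up-weighted by `w_ij >= 1`. The translation
#' weight is `|W| / |W intersect (W + (p_j - p_i))|`; the isotropic weight
#' is the reciprocal of the fraction of the circle centred at `p_i` with
#' radius `d(p_i, p_j)` whose circumference lies inside the window. Both
#' are computed exactly for the convex polygon window; weights are capped
#' at `cap` to guard against near-zero overlap or arc fractions at extreme
#' boundary configurations.
#'
#' @param p_i,p_j numeric length-2 points (microns), inside the window.
#' @param window a [convex_hull_window()].
#' @param correction `"translation"`, `"isotropic"` or `"none"`.
#' @param cap upper bound on the weight (the K estimators use the number
#'   of points).
#' @return a scalar weight >= 1.
#' @export
edge_weight <- function(p_i, p_j, window,
                        correction = c("translation", "isotropic", "none"),
                        cap = Inf) {
  correction <- match.arg(correction)
  stopifnot(inherits(window, "tissue_window"))
  pts <- rbind(p_i, p_j)
  if (!all(points_in_window(pts, window, tol = 1e-7))) {
    stop("point outside window", call. = FALSE)
  }
  .cpp_edge_weight(p_i[1L], p_i[2L], p_j[1L], p_j[2L],
                   window$vertices[, 1L], window$vertices[, 2L],
                   correction_code(correction), cap)
}

new_k_estimate <- function(r, k, correction, n, area, type, estimable = TRUE) {
  structure(list(r = r, k = k, correction = correction, n = n,
                 area = area, type = type, estimable = estimable),
            class = "k_estimate")
}

#' Ripley's K for a single point pattern
#'
#' Estimates `K(r) = A / (n (n - 1)) * sum_{i != j} w_ij 1{d_ij < r}` on an
#' ascending radius grid, where `A` is the window area and `w_ij` the edge
#' correction weight. The indicator is strict (`d < r`). With fewer than
#' two points K is not estimable (distinct from zero): the estimate is
#' returned with `estimable = FALSE` and `NA` values.
#'
#' @param points two-column matrix of coordinates (microns).
#' @param window a [convex_hull_window()]; typically the hull of all cells
#'   in the sample, not only the positive ones.
#' @param r ascending positive radius grid (microns); default 30.
#' @param correction `"translation"` (default), `"isotropic"` or `"none"`.
#' @return a `k_estimate` with elements `r`, `k`, `correction`, `n`,
#'   `area`, `estimable`.
#' @export
ripley_k <- function(points, window, r = 30,
                     correction = c("translation", "isotropic", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(window, "tissue_window"))
  points <- as.matrix(points)
  r <- as.numeric(r)
  if (any(!is.finite(r)) || any(r < 0) || is.unsorted(r, strictly = TRUE) &&
      length(r) > 1L) {
    stop("r must be a strictly ascending grid of finite radii >= 0",
         call. = FALSE)
  }
  n <- nrow(points)
  if (n < 2L) {
    return(new_k_estimate(r, rep(NA_real_, length(r)), correction, n,
                          window$area, "univariate", estimable = FALSE))
  }
  k <- .cpp_ripley_k(points[, 1L], points[, 2L],
                     window$vertices[, 1L], window$vertices[, 2L],
                     r, correction_code(correction))
  new_k_estimate(r, k, correction, n, window$area, "univariate")
}

#' Bivariate (cross) Ripley's K
#'
#' `K12(r) = A / (n1 n2) * sum_i sum_j w_ij 1{d(a_i, b_j) < r}` where the
#' sum runs over anchor points `a_i` and points `b_j` of the second type.
#' The anchor centres every ring and, under the isotropic correction, the
#' circle used for the weight — so the statistic is not symmetric in its
#' two point sets under that correction (it is under translation).
#'
#' @param anchors,others two-column coordinate matrices (microns); each
#'   must contain at least one point, otherwise the estimate is flagged
#'   not estimable.
#' @inheritParams ripley_k
#' @return a `k_estimate` with `n = c(n1, n2)`.
#' @export
ripley_k_cross <- function(anchors, others, window, r = 30,
                           correction = c("translation", "isotropic", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(window, "tissue_window"))
  anchors <- as.matrix(anchors)
  others <- as.matrix(others)
  r <- as.numeric(r)
  n1 <- nrow(anchors); n2 <- nrow(others)
  if (n1 < 1L || n2 < 1L) {
    return(new_k_estimate(r, rep(NA_real_, length(r)), correction,
                          c(n1 = n1, n2 = n2), window$area, "cross",
                          estimable = FALSE))
  }
  k <- .cpp_ripley_k_cross(anchors[, 1L], anchors[, 2L],
                           others[, 1L], others[, 2L],
                           window$vertices[, 1L], window$vertices[, 2L],
                           r, correction_code(correction))
  new_k_estimate(r, k, correction, c(n1 = n1, n2 = n2), window$area, "cross")
}

#' @export
print.k_estimate <- function(x, ...) {
  lbl <- if (x$type == "cross") {
    sprintf("cross K (n1 = %d, n2 = %d)", x$n[1L], x$n[2L])
  } else {
    sprintf("K (n = %d)", x$n)
  }
  cat(sprintf("<k_estimate> %s, %s correction, area %.1f um^2\n",
              lbl, x$correction, x$area))
  if (!x$estimable) {
    cat("  not estimable (too few points)\n")
  } else if (length(x$r) <= 6L) {
    cat(sprintf("  r = %s\n  K = %s\n",
                paste(signif(x$r, 4), collapse = ", "),
                paste(signif(x$k, 6), collapse = ", ")))
  } else {
    cat(sprintf("  %d radii in [%g, %g]\n", length(x$r), min(x$r), max(x$r)))
  }
  invisible(x)
}

#' @export
plot.k_estimate <- function(x, ...) {
  if (!x$estimable) stop("K estimate is not estimable", call. = FALSE)
  plot(x$r, x$k, type = "l", xlab = "r (microns)", ylab = "K(r)", ...)
  lines(x$r, theoretical_csr(x$r), lty = 2, col = "red")
  legend("topleft", legend = c("observed", expression(pi * r^2)),
         lty = c(1, 2), col = c("black", "red"), bty = "n")
  invisible(x)
}
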