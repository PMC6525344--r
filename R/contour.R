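# Closed-polygon geometry: shoelace area, perimeter, point-in-polygon,
# equal arc-length resampling, convex hull deficit. Vertices are n x 2
# matrices (x, y) in the y-up image frame; polygons are implicitly closed
# (first vertex is not repeated).

poly_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_perimeter <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# even-odd ray casting; pt = c(x, y)
point_in_polygon <- function(pt, v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crosses <- ((y > pt[2]) != (yn > pt[2])) &
    (pt[1] < (xn - x) * (pt[2] - y) / (yn - y) + x)
  sum(crosses) %% 2 == 1
}

#' Closed contour polygon
#'
#' Wraps an ordered vertex list as a validated closed contour: vertices are
#' reordered counterclockwise if needed, zero-length edges dropped, and the
#' shoelace area `area_S` and perimeter `perimeter_L` attached. The
#' isoperimetric inequality `4*pi*S/L^2 <= 1` is checked as a sanity bound.
#'
#' @param vertices n x 2 matrix of (x, y) vertices, first vertex not
#'   repeated at the end; n >= 8.
#' @param validate skip validation for diagnostic (e.g. border-clipped)
#'   contours when `FALSE`.
#' @return An object of class `onl_contour` with fields `vertices`,
#'   `area_S`, `perimeter_L`.
#' @export
contour_polygon <- function(vertices, validate = TRUE) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2)
  # drop a duplicated closing vertex and zero-length edges
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  a <- poly_signed_area(v)
  if (a < 0) { v <- v[rev(seq_len(nrow(v))), , drop = FALSE]; a <- -a }
  L <- poly_perimeter(v)
  if (validate) {
    if (nrow(v) < 8)
      stop_onlshape("contour must have at least 8 distinct vertices",
                    "onlshape_geometry_error")
    if (a <= 0 || L <= 0)
      stop_onlshape("contour is degenerate (zero area or perimeter)",
                    "onlshape_geometry_error")
    if (4 * pi * a / L^2 > 1 + 1e-6)
      stop_onlshape("contour violates the isoperimetric bound", "onlshape_geometry_error")
  }
  structure(list(vertices = v, area_S = a, perimeter_L = L),
            class = "onl_contour")
}

#' @export
print.onl_contour <- function(x, ...) {
  cat(sprintf("<onl_contour> %d vertices, S = %.1f px^2, L = %.1f px\n",
              nrow(x$vertices), x$area_S, x$perimeter_L))
  invisible(x)
}

#' Resample a contour at equal arc-length spacing
#'
#' @param contour an `onl_contour`.
#' @param n_points number of output vertices.
#' @return An `onl_contour` with `n_points` vertices equally spaced along
#'   the original polygon's boundary (the first output vertex is the first
#'   input vertex).
#' @export
resample_contour <- function(contour, n_points) {
  v <- contour$vertices
  q <- rbind(v, v[1, ])
  d <- sqrt(diff(q[, 1])^2 + diff(q[, 2])^2)
  s <- c(0, cumsum(d))
  keep <- !duplicated(s)          # edges below float resolution collapse
  q <- q[keep, , drop = FALSE]; s <- s[keep]
  st <- seq(0, s[length(s)], length.out = n_points + 1)[-(n_points + 1)]
  contour_polygon(cbind(stats::approx(s, q[, 1], st)$y,
                        stats::approx(s, q[, 2], st)$y),
                  validate = FALSE)
}

#' Convex-hull deficit of a contour
#'
#' Measures the concave portion of the region: the area by which the
#' convex hull of the vertices exceeds the enclosed area. `hull_ratio` is
#' hull area over region area (A/A0; 1 for a convex region).
#'
#' @param contour an `onl_contour`.
#' @return list with `concave_area_px` (hull area minus region area, px^2)
#'   and `hull_ratio` (hull area / region area, >= 1 up to tracing noise).
#' @export
convex_hull_deficit <- function(contour) {
  v <- contour$vertices
  idx <- grDevices::chull(v[, 1], v[, 2])
  if (length(idx) < 3)
    stop_onlshape("contour vertices are collinear", "onlshape_geometry_error")
  hull <- v[idx, , drop = FALSE]
  a_hull <- abs(poly_signed_area(hull))
  list(concave_area_px = a_hull - contour$area_S,
       hull_ratio = a_hull / contour$area_S)
}
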