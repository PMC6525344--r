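#' Exact region moments of a polygon
#'
#' Area, centroid, and normalized second central moments of the region
#' enclosed by a simple closed polygon, computed analytically from the
#' vertices via Green's-theorem line integrals (no rasterization bias).
#'
#' @param contour an `onl_contour`.
#' @return list with `S` (area), `centroid` (x, y), and the normalized
#'   central moments `mu20`, `mu02`, `mu11` (second moments divided by S).
#' @export
region_moments <- function(contour) {
  v <- contour$vertices
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100)
    stop_onlshape("polygon has zero area", "onlshape_geometry_error")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  m20 <- sum((x^2 + x * xn + xn^2) * cr) / 12
  m02 <- sum((y^2 + y * yn + yn^2) * cr) / 12
  m11 <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(S = A, centroid = c(x = cx, y = cy),
       mu20 = m20 / A - cx^2, mu02 = m02 / A - cy^2,
       mu11 = m11 / A - cx * cy)
}

#' Moment-method equivalent ellipse
#'
#' The ellipse whose second central moments match the region's: with
#' eigenvalues `lambda+- = ((mu20+mu02) +- sqrt((mu20-mu02)^2 + 4 mu11^2))/2`
#' of the covariance, the full axis lengths are `a = 4 sqrt(lambda+)` and
#' `b = 4 sqrt(lambda-)` (so a disk of radius r yields a = b = 2r), and the
#' major-axis angle is `theta = atan2(2 mu11, mu20 - mu02) / 2`, reported in
#' degrees, counterclockwise positive, wrapped to (-90, 90].
#'
#' @param moments output of [region_moments()].
#' @return list of class `ellipse_fit`: `center_O`, `major_axis_a`,
#'   `minor_axis_b` (full lengths, px), `theta_deg`.
#' @export
fit_ellipse_moments <- function(moments) {
  tr <- moments$mu20 + moments$mu02
  dd <- sqrt((moments$mu20 - moments$mu02)^2 + 4 * moments$mu11^2)
  lam_p <- (tr + dd) / 2
  lam_m <- (tr - dd) / 2
  if (lam_m <= 0)
    stop_onlshape("degenerate region: minor moment is not positive",
                  "onlshape_geometry_error")
  theta <- 0.5 * atan2(2 * moments$mu11, moments$mu20 - moments$mu02) * 180 / pi
  structure(list(center_O = moments$centroid,
                 major_axis_a = 4 * sqrt(lam_p),
                 minor_axis_b = 4 * sqrt(lam_m),
                 theta_deg = wrap_angle_deg(theta)),
            class = "ellipse_fit")
}

# wrap to (-90, 90]
wrap_angle_deg <- function(theta) {
  w <- ((theta + 90) %% 180) - 90
  ifelse(w <= -90, w + 180, w)
}

#' Signed axis angle in the left-eye fundus frame
#'
#' The study convention reports the major-axis angle on the left-eye
#' fundus, counterclockwise positive. Left eyes (OS) pass through
#' unchanged; right eyes (OD) are mirrored about the vertical meridian,
#' which negates the angle. The result is wrapped to (-90, 90].
#'
#' @param theta_deg major-axis angle from [fit_ellipse_moments()].
#' @param laterality `"OD"` or `"OS"`.
#' @param mirror_od set `FALSE` to report per-eye raw angles instead.
#' @return signed axis angle in degrees.
#' @export
apply_laterality <- function(theta_deg, laterality, mirror_od = TRUE) {
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (laterality == "OD" && mirror_od) wrap_angle_deg(-theta_deg)
  else wrap_angle_deg(theta_deg)
}

#' Circularity 4*pi*S/L^2 of the smoothed contour
#'
#' Computed on the elliptic-Fourier reconstruction of the contour (five
#' harmonics by default, densely resampled), which removes tracing
#' staircase noise; the quantity is scale-free, so size normalization of
#' the coefficients leaves it unchanged. Equals 1 for a circle and
#' decreases with elongation and irregularity.
#'
#' @param contour an `onl_contour`.
#' @param coeffs optional precomputed [efd_fit()] coefficients.
#' @param n_harmonics,n_points smoothing settings (defaults 5 and 512).
#' @return circularity in (0, 1].
#' @export
circularity <- function(contour, coeffs = NULL, n_harmonics = 5L,
                        n_points = 512L) {
  if (is.null(coeffs)) coeffs <- efd_fit(contour, n_harmonics)
  rec <- efd_reconstruct(coeffs, n_points)
  4 * pi * rec$area_S / rec$perimeter_L^2
}

#' Area ratio S/(ab)
#'
#' Region area over the product of the fitted full axis lengths; pi/4 for
#' a perfect ellipse, smaller for regions with deep concavities relative
#' to their equivalent ellipse.
#'
#' @param S region area in px^2 (raw contour area).
#' @param fit an `ellipse_fit`.
#' @return dimensionless area ratio.
#' @export
area_ratio <- function(S, fit) {
  S / (fit$major_axis_a * fit$minor_axis_b)
}

#' Axis ratio a/b
#'
#' Elongation of the fitted equivalent ellipse (>= 1).
#'
#' @param fit an `ellipse_fit`.
#' @return dimensionless axis ratio.
#' @export
axis_ratio <- function(fit) {
  fit$major_axis_a / fit$minor_axis_b
}

#' Shape parameters of an ONL-Base contour
#'
#' Convenience wrapper computing the moment-ellipse fit and the three
#' characteristic shape parameters plus the laterality-adjusted signed
#' axis angle for a selected contour.
#'
#' @param contour an `onl_contour` (the selected ONL-Base).
#' @param laterality `"OD"` or `"OS"`.
#' @param n_harmonics elliptic Fourier terms for circularity smoothing.
#' @param mirror_od see [apply_laterality()].
#' @return list of class `shape_params`: `circularity`, `area_ratio`,
#'   `axis_ratio`, `axis_deg`, `theta_raw_deg`, `fit`.
#' @export
shape_params <- function(contour, laterality, n_harmonics = 5L,
                         mirror_od = TRUE) {
  fit <- fit_ellipse_moments(region_moments(contour))
  structure(list(
    circularity = circularity(contour, n_harmonics = n_harmonics),
    area_ratio = area_ratio(contour$area_S, fit),
    axis_ratio = axis_ratio(fit),
    axis_deg = apply_laterality(fit$theta_deg, laterality, mirror_od),
    theta_raw_deg = fit$theta_deg,
    fit = fit), class = "shape_params")
}
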