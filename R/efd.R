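#' Elliptic Fourier descriptors of a closed contour
#'
#' Kuhl-Giardina elliptic Fourier coefficients of the closed polygon,
#' parameterized by cumulative arc length. Harmonic n contributes
#' `a_n cos + b_n sin` to x(t) and `c_n cos + d_n sin` to y(t); the DC
#' terms `A0`, `C0` carry the contour's locus offset. Truncating the
#' series smooths the boundary: five harmonics carry an ellipse-like
#' outline but cannot follow many-lobed crenellation.
#'
#' @param contour an `onl_contour` with at least `2*n_harmonics + 1` vertices.
#' @param n_harmonics number of frequency terms (default 5).
#' @return An object of class `efd_coefficients`: list with `harmonics`
#'   (`n_harmonics x 4` matrix, columns `a, b, c, d`), `dc` (`A0`, `C0`),
#'   `n_harmonics`, `period` (total arc length).
#' @export
efd_fit <- function(contour, n_harmonics = 5L) {
  stopifnot(inherits(contour, "onl_contour"))
  if (n_harmonics < 1)
    stop_onlshape("n_harmonics must be >= 1", "onlshape_parameter_error")
  v <- contour$vertices
  if (nrow(v) < 2 * n_harmonics + 1)
    stop_onlshape(sprintf("contour needs >= %d vertices for %d harmonics",
                          2 * n_harmonics + 1, n_harmonics),
                  "onlshape_parameter_error")
  dx <- diff(c(v[, 1], v[1, 1])); dy <- diff(c(v[, 2], v[1, 2]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)]); T <- t1[length(t1)]
  H <- matrix(0, n_harmonics, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / T
    k <- T / (2 * n^2 * pi^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    H[n, ] <- k * c(sum(dx / dt * dcos), sum(dx / dt * dsin),
                    sum(dy / dt * dcos), sum(dy / dt * dsin))
  }
  xi <- cumsum(dx) - dx / dt * t1
  dl <- cumsum(dy) - dy / dt * t1
  A0 <- sum(dx / (2 * dt) * (t1^2 - t0^2) + xi * (t1 - t0)) / T + v[1, 1]
  C0 <- sum(dy / (2 * dt) * (t1^2 - t0^2) + dl * (t1 - t0)) / T + v[1, 2]
  structure(list(harmonics = H, dc = c(A0 = A0, C0 = C0),
                 n_harmonics = n_harmonics, period = T),
            class = "efd_coefficients")
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values and returns the resulting closed polygon.
#'
#' @param coeffs an `efd_coefficients` object.
#' @param n_points number of boundary points (>= 8).
#' @return An `onl_contour`.
#' @export
efd_reconstruct <- function(coeffs, n_points = 512L) {
  stopifnot(inherits(coeffs, "efd_coefficients"))
  if (n_points < 8)
    stop_onlshape("n_points must be >= 8", "onlshape_parameter_error")
  tt <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  x <- rep(coeffs$dc[["A0"]], n_points)
  y <- rep(coeffs$dc[["C0"]], n_points)
  for (n in seq_len(coeffs$n_harmonics)) {
    cn <- cos(2 * pi * n * tt); sn <- sin(2 * pi * n * tt)
    x <- x + coeffs$harmonics[n, "a"] * cn + coeffs$harmonics[n, "b"] * sn
    y <- y + coeffs$harmonics[n, "c"] * cn + coeffs$harmonics[n, "d"] * sn
  }
  contour_polygon(cbind(x, y), validate = FALSE)
}

#' Elliptic Fourier restorability ratio (A1/A0)
#'
#' For each boundary point count `m`, the contour is resampled to `m`
#' equally spaced points, fitted with `n_harmonics` Fourier terms,
#' reconstructed densely, and the restored area A1 is compared with the
#' original area A0. The minimum ratio over the point counts is returned
#' (raw, unclamped: smoothing of concavities can push individual ratios
#' slightly above 1). A contour that five harmonics cannot carry restores
#' to a visibly different area and fails the 0.95 admissibility bound.
#'
#' @param contour an `onl_contour`.
#' @param point_counts boundary point counts to test (default 100, 50, 25).
#' @param n_harmonics Fourier terms (default 5).
#' @param n_reconstruct dense reconstruction point count (default 512).
#' @return minimum A1/A0 over `point_counts`.
#' @export
restore_ratio <- function(contour, point_counts = c(100L, 50L, 25L),
                          n_harmonics = 5L, n_reconstruct = 512L) {
  a0 <- contour$area_S
  ratios <- vapply(point_counts, function(m) {
    r <- resample_contour(contour, m)
    rec <- efd_reconstruct(efd_fit(r, n_harmonics), n_reconstruct)
    rec$area_S / a0
  }, numeric(1))
  min(ratios)
}
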