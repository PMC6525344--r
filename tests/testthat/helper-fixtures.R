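# Parametric contour fixtures and independent oracles shared across tests.

ellipse_contour <- function(a, b, theta = 0, center = c(0, 0), n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- a * cos(t); v <- b * sin(t)
  th <- theta * pi / 180
  contour_polygon(cbind(center[1] + cos(th) * u - sin(th) * v,
                        center[2] + sin(th) * u + cos(th) * v))
}

flower_contour <- function(r0, amp, lobes, n = 720, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r0 * (1 + amp * cos(lobes * t))
  contour_polygon(cbind(center[1] + r * cos(t), center[2] + r * sin(t)))
}

ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# smallest angular difference modulo 180 degrees
angdiff_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# dense pixel-rasterization covariance oracle for the moment-ellipse fit:
# grid-sample the polygon interior and eigen-decompose the point covariance
raster_ellipse_oracle <- function(contour, step = 0.5) {
  v <- contour$vertices
  xs <- seq(min(v[, 1]) - step, max(v[, 1]) + step, by = step)
  ys <- seq(min(v[, 2]) - step, max(v[, 2]) + step, by = step)
  P <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  crossings <- rep(0L, nrow(P))
  for (k in seq_along(x)) {
    hit <- ((y[k] > P[, 2]) != (yn[k] > P[, 2])) &
      (P[, 1] < (xn[k] - x[k]) * (P[, 2] - y[k]) / (yn[k] - y[k]) + x[k])
    crossings <- crossings + hit
  }
  pts <- P[crossings %% 2L == 1L, , drop = FALSE]
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  e <- eigen(cv, symmetric = TRUE)
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  w <- ((ang + 90) %% 180) - 90
  list(a = 4 * sqrt(e$values[1]), b = 4 * sqrt(e$values[2]),
       theta_deg = if (w <= -90) w + 180 else w)
}

# random convex polygon with controlled anisotropy (hull of gaussian points)
random_convex_contour <- function(stretch = 1.8, scale = 40) {
  repeat {
    p <- matrix(stats::rnorm(80, sd = scale), ncol = 2)
    p[, 1] <- p[, 1] * stretch
    idx <- grDevices::chull(p)
    if (length(idx) >= 8) return(contour_polygon(p[idx, , drop = FALSE]))
  }
}

# full single-eye pipeline on a bump model; returns measured shape + level
measure_bump <- function(model, cfg = run_config()) {
  sim <- generate_surfaces(model)
  hi <- build_height_image(sim$stack, axial_scale_um = cfg$axial_scale_um)
  res <- select_onlb(hi, reference_level(hi, cfg$bin_width_px),
                     step_px = cfg$step_px, max_level_frac = cfg$max_level_frac)
  sp <- shape_params(res$contour, model$laterality, mirror_od = cfg$mirror_od)
  list(truth = sim$truth, onlb = res, shape = sp)
}

# minimal valid 49 x 512 stack with constant thickness
constant_stack <- function(thickness = 14, rpe = 200, subject_id = "c",
                           laterality = "OS") {
  surface_stack(matrix(rpe - thickness, 49, 512), matrix(rpe, 49, 512),
                subject_id = subject_id, laterality = laterality)
}
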