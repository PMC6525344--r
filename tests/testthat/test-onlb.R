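gauss_hi <- function(cx = 256.5, cy = 256.5, sigma = 40, peak = 100,
                     base = 0, n = 512) {
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)   # generated directly in the y-up frame
  height_image(base + peak * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
}

test_that("level contour of a radial Gaussian is the analytic circle", {
  hi <- gauss_hi(sigma = 40, peak = 100)
  ctr <- extract_level_contour(hi, 50)
  r <- 40 * sqrt(2 * log(2))     # closed-form half-maximum radius
  expect_false(attr(ctr, "border_touching"))
  expect_equal(ctr$area_S, pi * r^2, tolerance = 0.01)
  expect_equal(ctr$perimeter_L, 2 * pi * r, tolerance = 0.01)
  # counterclockwise orientation
  expect_gt(onlshape:::poly_signed_area(ctr$vertices), 0)
})

test_that("empty superlevel sets and off-peak components are handled", {
  hi <- gauss_hi()
  expect_error(extract_level_contour(hi, 150),
               class = "onlshape_no_contour_error")
  expect_error(extract_level_contour(hi, 0), class = "onlshape_parameter_error")
  # two disjoint bumps: only the component holding the global peak is kept
  x <- matrix(seq_len(512), 512, 512, byrow = TRUE)
  y <- matrix(seq_len(512), 512, 512)
  h <- 100 * exp(-((x - 150)^2 + (y - 256)^2) / (2 * 30^2)) +
       60 * exp(-((x - 380)^2 + (y - 256)^2) / (2 * 30^2))
  ctr <- extract_level_contour(height_image(h), 30)
  cx <- mean(ctr$vertices[, 1])
  expect_lt(abs(cx - 150), 5)
  r <- 30 * sqrt(2 * log(100 / 30))
  expect_equal(ctr$area_S, pi * r^2, tolerance = 0.02)
})

test_that("border-clipped components are flagged", {
  hi <- gauss_hi(cx = 10, sigma = 60)
  ctr <- extract_level_contour(hi, 50)
  expect_true(attr(ctr, "border_touching"))
  crit <- evaluate_criteria(hi, ctr)
  expect_false(crit$inside_hi)
  expect_false(crit$passed)
})

test_that("convex hull deficit matches exact polygon areas", {
  # 100x100 square with a 20x20 notch cut into the top edge
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(60, 100), c(60, 80),
              c(40, 80), c(40, 100), c(0, 100))
  ctr <- contour_polygon(sq)
  expect_equal(ctr$area_S, 9600)
  d <- convex_hull_deficit(ctr)
  expect_equal(d$concave_area_px, 400)
  expect_equal(d$hull_ratio, 10000 / 9600)
  # hull of a convex contour is itself
  e <- convex_hull_deficit(ellipse_contour(50, 30))
  expect_equal(e$concave_area_px, 0, tolerance = 1e-6)
  expect_equal(e$hull_ratio, 1, tolerance = 1e-9)
  # strongly star-shaped contour exceeds the 1.2 hull-ratio bound
  star <- flower_contour(80, 0.35, 5)
  expect_gt(convex_hull_deficit(star)$hull_ratio, 1.2)
})

test_that("elliptic Fourier fit matches closed forms", {
  circ <- ellipse_contour(5, 5, center = c(3, -2), n = 200)
  f <- efd_fit(circ)
  # circle of radius r: first-harmonic energy a1^2+b1^2+c1^2+d1^2 = 2 r^2
  expect_equal(sum(f$harmonics[1, ]^2), 2 * 25, tolerance = 1e-3)
  expect_equal(unname(f$dc), c(3, -2), tolerance = 1e-6)
  # translation moves only the DC term
  f2 <- efd_fit(ellipse_contour(5, 5, center = c(10, 20), n = 200))
  expect_equal(f2$harmonics, f$harmonics, tolerance = 1e-9)
  expect_equal(unname(f2$dc), c(10, 20), tolerance = 1e-6)
  # arc-length-parameterized ellipses are strongly harmonic-1 dominated
  energy_tail <- function(ar) {
    h <- efd_fit(ellipse_contour(ar, 1, n = 400), 10)$harmonics
    sum(h[-1, ]^2) / sum(h^2)
  }
  expect_lt(energy_tail(1.25), 1e-3)
  expect_lt(energy_tail(2), 1e-2)
  expect_error(efd_fit(circ, 0), class = "onlshape_parameter_error")
  expect_error(efd_fit(contour_polygon(ellipse_contour(5, 5, n = 9)$vertices), 5),
               class = "onlshape_parameter_error")
})

test_that("elliptic Fourier reconstruction converges to the source contour", {
  circ <- ellipse_contour(20, 20, n = 300)
  rec <- efd_reconstruct(efd_fit(circ), 100)
  expect_equal(rec$area_S, pi * 400, tolerance = 0.005)
  # inscribed octagon from harmonic-1 coefficients has smaller area
  oct8 <- efd_reconstruct(efd_fit(circ, 1), 8)
  expect_lt(oct8$area_S, pi * 400)
  # area error decreases with harmonic count on ellipse + ripple once each
  # added band covers a full sideband pair of the 4-lobe ripple (k -/+ 1)
  target <- flower_contour(50, 0.08, 4, n = 1024)
  errs <- vapply(c(2, 6, 10), function(H) {
    abs(efd_reconstruct(efd_fit(target, H), 1024)$area_S - target$area_S)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_error(efd_reconstruct(efd_fit(circ), 4), class = "onlshape_parameter_error")
})

test_that("restorability ratio separates smooth from crenellated contours", {
  ell <- ellipse_contour(90, 60, theta = 20, n = 600)
  rr_ell <- restore_ratio(ell)
  expect_gt(rr_ell, 0.98)
  # 5 harmonics cannot carry a deep 12-lobe crenellation: the restored
  # area collapses towards the mean circle and the ratio drops below 0.95
  crn <- flower_contour(80, 0.4, 12, n = 1440)
  expect_lt(restore_ratio(crn), 0.95)
  # ratio is scale-invariant
  crn2 <- contour_polygon(crn$vertices * 2)
  expect_equal(restore_ratio(crn2), restore_ratio(crn), tolerance = 1e-6)
  ell2 <- contour_polygon(ell$vertices * 2)
  expect_equal(restore_ratio(ell2), rr_ell, tolerance = 1e-6)
})

test_that("admissibility criteria pass on a smooth bump and fail as designed", {
  hi <- gauss_hi(sigma = 50)
  ctr <- extract_level_contour(hi, 40)
  crit <- evaluate_criteria(hi, ctr)
  expect_true(crit$inside_hi)
  expect_lt(crit$concave_area_px, 20000)
  expect_lt(crit$hull_ratio, 1.2)
  expect_gt(crit$restore_ratio_min, 0.95)
  expect_true(crit$passed)
  # criterion 2: a synthetic report with a 25000 px^2 concave deficit fails
  m <- bump_model(base_height_px = 0, sigma_major_px = 90, sigma_minor_px = 90,
                  ripple_amp = 0.35, ripple_lobes = 5, subject_id = "star")
  sim <- generate_surfaces(m)
  hi2 <- build_height_image(sim$stack, axial_scale_um = 1)
  ctr2 <- extract_level_contour(hi2, 10)
  crit2 <- evaluate_criteria(hi2, ctr2)
  expect_gt(crit2$concave_area_px, 20000)
  expect_gt(crit2$hull_ratio, 1.2)
  expect_false(crit2$passed)
})

test_that("level search returns the lowest admissible level", {
  # noiseless smooth bump with zero base: the first searched level passes
  m <- bump_model(base_height_px = 0, peak_height_px = 60,
                  sigma_major_px = 60, sigma_minor_px = 45,
                  theta_true_deg = 15, subject_id = "low")
  hi <- build_height_image(generate_surfaces(m)$stack)
  ref <- reference_level(hi)
  res <- select_onlb(hi, ref)
  expect_equal(res$level_px, max(ref$level_px, 1))
  expect_true(res$criteria$passed)
  expect_gte(res$level_px, ref$level_px)
  expect_equal(res$distance_rpe_um, res$level_px * 3.87)
  # re-evaluating the selected contour reproduces a pass (idempotence)
  expect_true(evaluate_criteria(hi, res$contour)$passed)
})

test_that("level search matches an exhaustive brute-force criteria scan", {
  for (seed in 1:3) {
    m <- bump_model(base_height_px = 14, peak_height_px = 55,
                    sigma_major_px = 58, sigma_minor_px = 41,
                    theta_true_deg = -25, noise_sd_px = 1.5, seed = seed,
                    subject_id = paste0("bf", seed))
    hi <- build_height_image(generate_surfaces(m)$stack)
    ref <- reference_level(hi)
    res <- select_onlb(hi, ref)
    # oracle: scan every level on the same ladder and take the first pass
    levels <- seq(max(ref$level_px, 1), 0.95 * max(hi$heights_px), by = 1)
    oracle <- NA_real_
    for (lev in levels) {
      ok <- tryCatch(
        evaluate_criteria(hi, extract_level_contour(hi, lev))$passed,
        onlshape_error = function(e) FALSE)
      if (ok) { oracle <- lev; break }
    }
    expect_equal(res$level_px, oracle)
  }
})

test_that("unsatisfiable criteria produce a selection failure with diagnostics", {
  # monotone ramp: the superlevel set touches the border at every level
  h <- matrix(seq_len(512) / 10, 512, 512, byrow = TRUE)
  hi <- height_image(h)
  err <- expect_error(select_onlb(hi, reference_level(hi)),
                      class = "onlshape_selection_failure")
  expect_true(!is.null(err$search))
  expect_true(all(!err$search$passed))
})

test_that("contour area is non-increasing in level on unimodal maps", {
  hi <- gauss_hi(sigma = 45)
  areas <- vapply(seq(20, 90, by = 10), function(lev)
    extract_level_contour(hi, lev)$area_S, numeric(1))
  expect_true(all(diff(areas) < 0))
})
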