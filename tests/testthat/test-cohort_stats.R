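test_that("MH/MV ratio applies the zero-score substitution exactly", {
  expect_equal(mh_mv_ratio(0.7, 0.35), 2)
  expect_equal(mh_mv_ratio(0, 0.5), 0.1)     # 0.05 / 0.5
  expect_equal(mh_mv_ratio(1.3, 0), 26)      # 1.3 / 0.05
  expect_equal(mh_mv_ratio(0, 0), 1)
  expect_equal(mh_mv_ratio(c(0.7, 0), c(0.35, 0.5)), c(2, 0.1))
  expect_error(mh_mv_ratio(2.5, 1), class = "onlshape_range_error")
})

test_that("Pearson correlation matches the brute-force t-transform", {
  r <- pearson(1:10, 2 * (1:10) + 1)
  expect_equal(r$r, 1)
  expect_lt(r$p, 1e-10)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  pr <- pearson(x, y)
  # hand computation from sums of products
  r_hand <- sum((x - 3) * (y - 3)) / sqrt(sum((x - 3)^2) * sum((y - 3)^2))
  expect_equal(pr$r, 0.8)
  expect_equal(pr$r, r_hand)
  t_stat <- r_hand * sqrt((5 - 2) / (1 - r_hand^2))
  expect_equal(pr$p, 2 * stats::pt(-abs(t_stat), df = 3))
  expect_equal(pr$p, 0.104, tolerance = 1e-2)
  expect_equal(pr$n, 5)
  expect_error(pearson(rep(1, 5), 1:5),
               class = "onlshape_undefined_correlation_error")
  expect_error(pearson(1:2, 2:3), class = "onlshape_sample_size_error")
})

test_that("Pearson correlation is symmetric and affine-equivariant", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    a <- pearson(x, y); b <- pearson(y, x)
    expect_equal(a$r, b$r)
    expect_equal(a$p, b$p)
    s <- pearson(3 * x + 7, y)
    expect_equal(s$r, a$r, tolerance = 1e-12)
    flip <- pearson(-2 * x, y)
    expect_equal(flip$r, -a$r, tolerance = 1e-12)
  }
})

test_that("two-group comparison is a Welch t-test with n-1 SDs", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  cmp <- two_group_compare(a, b)
  expect_equal(cmp$mean_b - cmp$mean_a, 10)
  expect_equal(cmp$sd_a, 1)
  expect_lt(cmp$p, 0.01)
  # closed-form Welch statistic
  expect_equal(cmp$t, (mean(a) - mean(b)) / sqrt(1 / 3 + 1 / 3))
  same <- two_group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_group_compare(c(1, 1, 1), c(2, 2, 2)),
               class = "onlshape_degenerate_test_error")
  expect_error(two_group_compare(1, c(1, 2)), class = "onlshape_sample_size_error")
})

make_records <- function(n_erm = 20, n_ctl = 15, seed = 1) {
  set.seed(seed)
  n <- n_erm + n_ctl
  data.frame(
    subject_id = sprintf("r%02d", 1:n),
    group = rep(c("ERM", "control"), c(n_erm, n_ctl)),
    onl_height_um = c(rnorm(n_erm, 84.1, 12.9), rnorm(n_ctl, 54.1, 5.3)),
    axis_deg = c(rnorm(n_erm, -1.3, 29), rnorm(n_ctl, -6.3, 22)),
    circularity = c(rnorm(n_erm, 0.79, 0.09), rnorm(n_ctl, 0.85, 0.07)),
    area_ratio = c(rnorm(n_erm, 0.74, 0.03), rnorm(n_ctl, 0.75, 0.02)),
    axis_ratio = c(rnorm(n_erm, 1.54, 0.37), rnorm(n_ctl, 1.51, 0.35)),
    mh = c(pmin(pmax(rnorm(n_erm, 0.71, 0.61), 0), 2), rep(0, n_ctl)),
    mv = c(pmin(pmax(rnorm(n_erm, 0.53, 0.5), 0), 2), rep(0, n_ctl)))
}

test_that("cohort summary reports group means, SDs and comparisons", {
  rec <- make_records(21, 21, seed = 3)
  rec$mh_mv <- mh_mv_ratio(rec$mh, rec$mv)
  tab <- table1_summary(rec)
  expect_setequal(
    tab$variable,
    c("onl_height_um", "axis_deg", "circularity", "area_ratio", "axis_ratio",
      "mh", "mv"))
  circ <- tab[tab$variable == "circularity", ]
  # control circularity mean lies within 2 SE of its generating mean 0.85
  expect_lt(abs(circ$mean_control - 0.85), 2 * 0.07 / sqrt(21))
  expect_equal(circ$n_control, 21)
  # group comparison p agrees with a direct Welch test
  direct <- stats::t.test(rec$circularity[rec$group == "ERM"],
                          rec$circularity[rec$group == "control"])
  expect_equal(circ$p, direct$p.value)
  # MCHART rows summarize the ERM group only
  expect_true(is.na(tab$mean_control[tab$variable == "mh"]))
  # deterministic: identical input, identical output
  expect_identical(tab, table1_summary(rec))
  # single-group input leaves comparison columns empty
  solo <- table1_summary(rec[rec$group == "ERM", ])
  expect_true(all(is.na(solo$p)))
  expect_error(table1_summary(rec[0, ]), class = "onlshape_composition_error")
})

test_that("correlation table covers full cohort and axis-window subset", {
  rec <- make_records(30, 10, seed = 8)
  rec$mh_mv <- mh_mv_ratio(rec$mh, rec$mv)
  tab <- table2_correlations(rec, axis_window_deg = 10)
  expect_setequal(unique(tab$subset), c("all", "axis_within_window"))
  full <- tab[tab$subset == "all", ]
  expect_true(all(full$n == 30))
  expect_true(all(abs(full$r) <= 1, na.rm = TRUE))
  # subset rows are reproducible by filtering externally
  erm <- rec[rec$group == "ERM", ]
  sub <- erm[abs(erm$axis_deg) <= 10, ]
  redo <- table2_correlations(rbind(sub, rec[rec$group == "control", ]),
                              axis_window_deg = 180)
  for (v in unique(tab$variable)) {
    expect_equal(tab$r[tab$variable == v & tab$subset == "axis_within_window"],
                 redo$r[redo$variable == v & redo$subset == "all"])
  }
  # significance gate is p < 0.05 exactly
  expect_equal(tab$significant, !is.na(tab$p) & tab$p < 0.05)
  # window covering everything duplicates the full rows
  wide <- table2_correlations(rec, axis_window_deg = 90)
  expect_equal(wide$r[wide$subset == "all"],
               wide$r[wide$subset == "axis_within_window"])
  # constant MH/MV yields flagged undefined rows
  rec2 <- rec; rec2$mh_mv <- 1
  tab2 <- table2_correlations(rec2)
  expect_true(all(is.na(tab2$r)))
  expect_true(all(tab2$note == "undefined"))
  expect_error(table2_correlations(rec[rec$group == "control", ]),
               class = "onlshape_sample_size_error")
})
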