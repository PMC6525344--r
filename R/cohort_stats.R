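#' MCHART anisotropy ratio MH/MV
#'
#' Ratio of the horizontal to the vertical MCHART score. A score of 0
#' (no detectable distortion) is recorded as 0.05 -- one quantization step
#' below the chart's 0.2-degree floor -- before forming the ratio, so the
#' ratio is always defined and positive.
#'
#' @param mh,mv MCHART scores in viewing-angle degrees, in \[0, 2\];
#'   vectorized.
#' @return MH/MV after zero substitution.
#' @export
mh_mv_ratio <- function(mh, mv) {
  if (any(mh < 0 | mh > 2, na.rm = TRUE) || any(mv < 0 | mv > 2, na.rm = TRUE))
    stop_onlshape("MCHART scores must lie in [0, 2]", "onlshape_range_error")
  mh <- ifelse(mh == 0, 0.05, mh)
  mv <- ifelse(mv == 0, 0.05, mv)
  mh / mv
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation with the two-sided p-value from the
#' t-transform `t = r * sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop_onlshape("need at least 3 complete pairs", "onlshape_sample_size_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_onlshape("correlation undefined for a constant vector",
                  "onlshape_undefined_correlation_error")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Two-group parametric comparison
#'
#' Welch's two-sided t-test (unequal variances) by default; Student's
#' pooled-variance t is selectable. Group SDs use the n-1 denominator.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student t when `TRUE`.
#' @return list with `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `t`, `p`.
#' @export
two_group_compare <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_onlshape("each group needs at least 2 observations",
                  "onlshape_sample_size_error")
  tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                 error = function(e)
                   stop_onlshape(paste0("degenerate t-test: ", conditionMessage(e)),
                                 "onlshape_degenerate_test_error"))
  list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
       mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
       t = unname(tt$statistic), p = tt$p.value)
}

table1_vars <- c("onl_height_um", "axis_deg", "circularity", "area_ratio",
                 "axis_ratio")

#' Cohort summary table (group means, SDs and comparisons)
#'
#' Per-group mean and SD of the ONL morphometric parameters with the
#' ERM-vs-control parametric comparison, plus MCHART MH and MV summaries
#' for the ERM group (controls have no metamorphopsia scores to compare).
#'
#' @param records per-subject results data frame (from [analyze_subject()]
#'   rows or equivalent) with columns `group`, the morphometric variables,
#'   and `mh`, `mv`; excluded subjects (`excluded == TRUE`) are dropped.
#' @param var_equal passed to [two_group_compare()].
#' @return data frame with one row per variable: group means, SDs, ns and
#'   the comparison `t` and `p` (NA when a group is absent).
#' @export
table1_summary <- function(records, var_equal = FALSE) {
  if ("excluded" %in% names(records)) records <- records[!records$excluded, ]
  erm <- records[records$group == "ERM", ]
  ctl <- records[records$group == "control", ]
  if (nrow(erm) == 0 && nrow(ctl) == 0)
    stop_onlshape("no analyzable subjects in either group",
                  "onlshape_composition_error")
  row_for <- function(var, a, b) {
    cmp <- if (length(a) >= 2 && length(b) >= 2)
      tryCatch(two_group_compare(a, b, var_equal),
               onlshape_error = function(e) NULL) else NULL
    data.frame(
      variable = var,
      mean_erm = if (length(a)) mean(a) else NA_real_,
      sd_erm = if (length(a) >= 2) stats::sd(a) else NA_real_,
      n_erm = length(a),
      mean_control = if (length(b)) mean(b) else NA_real_,
      sd_control = if (length(b) >= 2) stats::sd(b) else NA_real_,
      n_control = length(b),
      t = if (is.null(cmp)) NA_real_ else cmp$t,
      p = if (is.null(cmp)) NA_real_ else cmp$p)
  }
  out <- do.call(rbind, lapply(table1_vars, function(v)
    row_for(v, erm[[v]][is.finite(erm[[v]])], ctl[[v]][is.finite(ctl[[v]])])))
  for (v in c("mh", "mv")) {
    if (v %in% names(records))
      out <- rbind(out, row_for(v, erm[[v]][is.finite(erm[[v]])], numeric(0)))
  }
  out$significant <- !is.na(out$p) & out$p < 0.05
  out
}

#' Correlations of MH/MV with the ONL parameters
#'
#' Pearson correlations of the MCHART anisotropy ratio against each
#' morphometric variable, for (i) all ERM subjects and (ii) the subset
#' whose signed axis lies within `axis_window_deg` of horizontal -- eyes
#' whose long axis is nearly horizontal, where the MH/MV direction
#' contrast is cleanest.
#'
#' @param records per-subject results data frame with columns `group`,
#'   `mh_mv`, `axis_deg` and the morphometric variables.
#' @param axis_window_deg half-width of the axis window (default 10).
#' @return data frame with columns `variable`, `subset`, `n`, `r`, `p`,
#'   `significant`; correlation rows that are undefined (constant input)
#'   carry NA with `note = "undefined"`.
#' @export
table2_correlations <- function(records, axis_window_deg = 10) {
  if ("excluded" %in% names(records)) records <- records[!records$excluded, ]
  erm <- records[records$group == "ERM", ]
  if (nrow(erm) < 3)
    stop_onlshape("need at least 3 ERM subjects", "onlshape_sample_size_error")
  subsets <- list(all = erm,
                  axis_within_window = erm[abs(erm$axis_deg) <= axis_window_deg, ])
  rows <- list()
  for (sname in names(subsets)) {
    sub <- subsets[[sname]]
    if (nrow(sub) < 3) {
      warning(sprintf("subset '%s' has fewer than 3 subjects; skipped", sname))
      next
    }
    for (v in table1_vars) {
      pr <- tryCatch(pearson(sub$mh_mv, sub[[v]]),
                     onlshape_error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, subset = sname,
        n = nrow(sub),
        r = if (is.null(pr)) NA_real_ else pr$r,
        p = if (is.null(pr)) NA_real_ else pr$p,
        note = if (is.null(pr)) "undefined" else "")
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < 0.05
  out
}
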