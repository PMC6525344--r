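#' Extract the iso-height contour at a level
#'
#' Thresholds the height image at `level_px` and traces the sub-pixel
#' iso-contour (marching-squares style linear interpolation along grid
#' edges) of the connected region containing the global height maximum --
#' the foveal peak, the only landmark available from the height map alone.
#' Interior holes are ignored (filled) because only the outer boundary
#' enclosing the peak is kept. If the peak's region reaches the image
#' border the traced boundary is clipped and the returned contour carries
#' `attr(, "border_touching") = TRUE`; admissibility criterion 1 fails
#' downstream.
#'
#' Contours are returned in the y-up frame (x = column, y = n_rows + 1 -
#' row), oriented counterclockwise.
#'
#' @param hi a `height_image`.
#' @param level_px height level in axial pixels; `0 < level_px < max(heights)`.
#' @return An `onl_contour`.
#' @export
extract_level_contour <- function(hi, level_px) {
  stopifnot(inherits(hi, "height_image"))
  H <- hi$heights_px
  nr <- nrow(H); nc <- ncol(H)
  if (!(level_px > 0))
    stop_onlshape("level_px must be > 0", "onlshape_parameter_error")
  if (level_px >= max(H))
    stop_onlshape("level is at or above the height maximum: empty contour",
                  "onlshape_no_contour_error")
  peak <- which(H == max(H), arr.ind = TRUE)[1, ]
  peak_xy <- c(peak[["col"]], nr + 1 - peak[["row"]])
  # z[i, j] is the value at x = i (column), y = j (y-up row)
  z <- t(H[nr:1, , drop = FALSE])
  cl <- grDevices::contourLines(x = seq_len(nc), y = seq_len(nr), z = z,
                                levels = level_px)
  if (length(cl) == 0)
    stop_onlshape("no iso-contour found at this level", "onlshape_no_contour_error")
  closed <- vapply(cl, function(p) {
    n <- length(p$x)
    p$x[1] == p$x[n] && p$y[1] == p$y[n]
  }, logical(1))
  containing <- vapply(seq_along(cl), function(i) {
    if (!closed[i]) return(FALSE)
    v <- cbind(cl[[i]]$x, cl[[i]]$y)
    point_in_polygon(peak_xy, v[-nrow(v), , drop = FALSE])
  }, logical(1))
  if (any(containing)) {
    # outermost loop around the peak = largest enclosed area
    areas <- vapply(which(containing), function(i)
      abs(poly_signed_area(cbind(cl[[i]]$x, cl[[i]]$y))), numeric(1))
    best <- which(containing)[which.max(areas)]
    out <- contour_polygon(cbind(cl[[best]]$x, cl[[best]]$y))
    attr(out, "border_touching") <- FALSE
    attr(out, "level_px") <- level_px
    return(out)
  }
  # the peak's superlevel component is clipped by the image border: close
  # the longest open polyline for diagnostics only
  open_idx <- which(!closed)
  if (length(open_idx) == 0)
    stop_onlshape("no contour encloses the height maximum", "onlshape_no_contour_error")
  lens <- vapply(open_idx, function(i) length(cl[[i]]$x), numeric(1))
  p <- cl[[open_idx[which.max(lens)]]]
  out <- contour_polygon(cbind(p$x, p$y), validate = FALSE)
  attr(out, "border_touching") <- TRUE
  attr(out, "level_px") <- level_px
  out
}

#' Evaluate the four ONL-Base admissibility criteria
#'
#' A candidate iso-contour is admissible as the ONL-Base when
#' (1) its boundary lies within the height image (closed, not clipped by
#' the border), (2) the concave portion (convex-hull deficit) is at most
#' `concave_max_px2` square pixels, (3) the hull-to-region area ratio
#' A/A0 is at most `hull_ratio_max`, and (4) the elliptic Fourier
#' restorability ratio A1/A0 (minimum over the boundary point counts) is
#' at least `restore_min`.
#'
#' @param hi the `height_image` the contour was extracted from.
#' @param contour an `onl_contour` from [extract_level_contour()].
#' @param concave_max_px2 criterion-2 bound (default 20000 px^2).
#' @param hull_ratio_max criterion-3 bound (default 1.2).
#' @param restore_min criterion-4 bound (default 0.95).
#' @param n_harmonics,point_counts elliptic Fourier settings (default 5
#'   harmonics; 100, 50, 25 boundary points).
#' @return list of class `criteria_report`: `inside_hi`, `concave_area_px`,
#'   `hull_ratio`, `restore_ratio_min`, `passed`.
#' @export
evaluate_criteria <- function(hi, contour,
                              concave_max_px2 = 20000,
                              hull_ratio_max = 1.2,
                              restore_min = 0.95,
                              n_harmonics = 5L,
                              point_counts = c(100L, 50L, 25L)) {
  nr <- nrow(hi$heights_px); nc <- ncol(hi$heights_px)
  v <- contour$vertices
  clipped <- isTRUE(attr(contour, "border_touching"))
  on_border <- any(v[, 1] <= 1 | v[, 1] >= nc | v[, 2] <= 1 | v[, 2] >= nr)
  inside <- !clipped && !on_border
  hull <- tryCatch(convex_hull_deficit(contour),
                   onlshape_geometry_error = function(e)
                     list(concave_area_px = Inf, hull_ratio = Inf))
  rr <- tryCatch(
    restore_ratio(contour, point_counts = point_counts, n_harmonics = n_harmonics),
    onlshape_error = function(e) NA_real_)
  passed <- inside &&
    hull$concave_area_px <= concave_max_px2 &&
    hull$hull_ratio <= hull_ratio_max &&
    !is.na(rr) && rr >= restore_min
  structure(list(inside_hi = inside,
                 concave_area_px = hull$concave_area_px,
                 hull_ratio = hull$hull_ratio,
                 restore_ratio_min = rr,
                 passed = passed),
            class = "criteria_report")
}

#' Select the ONL-Base contour by bottom-up level search
#'
#' Scans candidate levels upward from the reference plane in steps of
#' `step_px` up to `max_level_frac` of the peak height and returns the
#' lowest level whose iso-contour passes all four admissibility criteria
#' -- the deepest admissible section of the layer. The selected level is
#' also reported in micrometres as the distance from the RPE line.
#'
#' @param hi a `height_image`.
#' @param ref a [reference_level()] for `hi` (computed if omitted).
#' @param step_px level-search step (default 1 axial pixel).
#' @param max_level_frac top of the search range as a fraction of the peak
#'   height (default 0.95).
#' @param ... criteria settings passed to [evaluate_criteria()].
#' @return An object of class `onlb_result`: `level_px`, `level_um`,
#'   `distance_rpe_um` (equal to `level_um`; heights are measured from the
#'   RPE line), `contour`, `criteria`, and `search` (per-level diagnostics
#'   data frame).
#' @export
select_onlb <- function(hi, ref = reference_level(hi), step_px = 1,
                        max_level_frac = 0.95, ...) {
  stopifnot(inherits(hi, "height_image"))
  top <- max_level_frac * max(hi$heights_px)
  start <- max(ref$level_px, step_px)
  if (start > top)
    stop_onlshape("reference level is above the search range",
                  "onlshape_selection_failure")
  levels <- seq(start, top, by = step_px)
  trace <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    lev <- levels[i]
    res <- tryCatch({
      ctr <- extract_level_contour(hi, lev)
      crit <- evaluate_criteria(hi, ctr, ...)
      list(contour = ctr, criteria = crit, error = NA_character_)
    }, onlshape_error = function(e) list(contour = NULL, criteria = NULL,
                                         error = conditionMessage(e)))
    if (!is.null(res$criteria)) {
      trace[[i]] <- data.frame(
        level_px = lev, inside_hi = res$criteria$inside_hi,
        concave_area_px = res$criteria$concave_area_px,
        hull_ratio = res$criteria$hull_ratio,
        restore_ratio_min = res$criteria$restore_ratio_min,
        passed = res$criteria$passed, error = NA_character_)
      if (res$criteria$passed) {
        return(structure(
          list(level_px = lev, level_um = lev * hi$axial_scale_um,
               distance_rpe_um = lev * hi$axial_scale_um,
               contour = res$contour, criteria = res$criteria,
               search = do.call(rbind, trace[seq_len(i)])),
          class = "onlb_result"))
      }
    } else {
      trace[[i]] <- data.frame(
        level_px = lev, inside_hi = NA, concave_area_px = NA_real_,
        hull_ratio = NA_real_, restore_ratio_min = NA_real_,
        passed = FALSE, error = res$error)
    }
  }
  stop_onlshape(
    sprintf("no level between %.1f and %.1f px passes the ONL-Base criteria",
            start, top),
    "onlshape_selection_failure", search = do.call(rbind, trace))
}

#' @export
print.onlb_result <- function(x, ...) {
  cat(sprintf("<onlb_result> level %.1f px (%.1f um from RPE), %d-vertex contour\n",
              x$level_px, x$level_um, nrow(x$contour$vertices)))
  cat(sprintf("  S = %.0f px^2, L = %.0f px, hull ratio %.3f, restore ratio %.3f\n",
              x$contour$area_S, x$contour$perimeter_L,
              x$criteria$hull_ratio, x$criteria$restore_ratio_min))
  invisible(x)
}
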