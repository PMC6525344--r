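#' ONL thickness grid from a surface stack
#'
#' Per-A-scan axial distance between the RPE line and the ONL/OPL boundary,
#' in axial pixels, as a B-scans x A-scans matrix.
#'
#' @param stack a [surface_stack()].
#' @return numeric matrix `rpe_depth - onl_depth`, all entries >= 0.
#' @export
thickness_grid <- function(stack) {
  stopifnot(inherits(stack, "surface_stack"))
  th <- stack$rpe_depth - stack$onl_depth
  if (any(th < 0))
    stop_onlshape("negative ONL thickness: segmentation surfaces cross",
                  "onlshape_crossing_error")
  th
}

#' Linear row interpolation of a B-scan grid
#'
#' Upsamples the sparse B-scan direction to `target_rows` rows. Input row
#' `i` (1-based) maps to output position `1 + (i-1)*(target_rows-1)/(n_in-1)`;
#' each output row is the linear blend of its two bracketing input rows, so
#' the first and last input rows are reproduced exactly and any grid whose
#' columns are affine in the row index is interpolated without error.
#'
#' @param grid numeric matrix with >= 2 rows.
#' @param target_rows output row count (default 512); must be >= `nrow(grid)`.
#' @return `target_rows x ncol(grid)` matrix.
#' @export
interpolate_rows <- function(grid, target_rows = 512L) {
  grid <- as.matrix(grid)
  n_in <- nrow(grid)
  if (n_in < 2)
    stop_onlshape("need at least 2 input rows to interpolate", "onlshape_parameter_error")
  if (target_rows < n_in)
    stop_onlshape("target_rows must be >= number of input rows", "onlshape_parameter_error")
  # weight matrix: each output row is a 2-point lerp of bracketing input rows
  s <- (seq_len(target_rows) - 1) * (n_in - 1) / (target_rows - 1) + 1
  j <- pmin(floor(s), n_in - 1)
  w <- s - j
  W <- matrix(0, target_rows, n_in)
  W[cbind(seq_len(target_rows), j)] <- 1 - w
  W[cbind(seq_len(target_rows), j + 1)] <- W[cbind(seq_len(target_rows), j + 1)] + w
  W %*% grid
}

#' Build the 512x512 ONL height image
#'
#' Composes [thickness_grid()] and [interpolate_rows()] (rows, then columns
#' if the A-scan count differs from `target_size`) and attaches the axial
#' micrometre scale. The height image ("HI") is the standard 512x512 map of
#' ONL-to-RPE distance; heights in micrometres are `heights_px * axial_scale_um`.
#'
#' @param stack a [surface_stack()].
#' @param axial_scale_um micrometres per axial pixel (default 3.87).
#' @param target_size output grid side (default 512).
#' @param lateral_extent_mm lateral field width represented (default 6.7).
#' @return An object of class `height_image` with fields `heights_px`
#'   (`target_size` square matrix), `axial_scale_um`, `lateral_extent_mm`,
#'   `laterality`, `subject_id`.
#' @export
build_height_image <- function(stack, axial_scale_um = 3.87,
                               target_size = 512L, lateral_extent_mm = 6.7) {
  th <- thickness_grid(stack)
  h <- interpolate_rows(th, target_size)
  if (ncol(h) != target_size)
    h <- t(interpolate_rows(t(h), target_size))
  structure(
    list(heights_px = h, axial_scale_um = axial_scale_um,
         lateral_extent_mm = lateral_extent_mm,
         laterality = stack$laterality, subject_id = stack$subject_id),
    class = "height_image")
}

#' Height image constructed directly from a pixel-height matrix
#'
#' Convenience constructor used by tests and simulations that already hold
#' a full-resolution height map.
#'
#' @inheritParams build_height_image
#' @param heights_px square numeric matrix of heights in axial pixels.
#' @param laterality,subject_id metadata carried along.
#' @export
height_image <- function(heights_px, axial_scale_um = 3.87,
                         lateral_extent_mm = 6.7, laterality = "OS",
                         subject_id = "anon") {
  heights_px <- as.matrix(heights_px)
  if (any(!is.finite(heights_px)) || any(heights_px < 0))
    stop_onlshape("heights must be finite and >= 0", "onlshape_range_error")
  structure(
    list(heights_px = heights_px, axial_scale_um = axial_scale_um,
         lateral_extent_mm = lateral_extent_mm,
         laterality = match.arg(laterality, c("OD", "OS")),
         subject_id = subject_id),
    class = "height_image")
}

#' @export
print.height_image <- function(x, ...) {
  cat(sprintf("<height_image> subject %s (%s): %dx%d px, axial scale %.3g um/px\n",
              x$subject_id, x$laterality, nrow(x$heights_px), ncol(x$heights_px),
              x$axial_scale_um))
  cat(sprintf("  height range: %.2f - %.2f px (%.1f - %.1f um)\n",
              min(x$heights_px), max(x$heights_px),
              min(x$heights_px) * x$axial_scale_um,
              max(x$heights_px) * x$axial_scale_um))
  invisible(x)
}

#' Micrometre view of a height image
#' @param hi a `height_image`.
#' @return matrix of heights in micrometres.
#' @export
heights_um <- function(hi) hi$heights_px * hi$axial_scale_um

#' Reference plane level of a height image
#'
#' The reference plane is the height level of maximum frequency of the
#' height histogram: heights are binned into bins of width `bin_width_px`
#' centred on integer multiples of the bin width, and the centre of the
#' highest-count bin is returned; ties break towards the lower bin.
#'
#' @param hi a `height_image`.
#' @param bin_width_px histogram bin width in axial pixels (default 1).
#' @param include_zero include zero-height pixels in the histogram
#'   (default `TRUE`).
#' @return An object of class `reference_level` with fields `level_px`,
#'   `level_um`, `bin_width_px`, `histogram` (data frame of bin centres and
#'   counts).
#' @export
reference_level <- function(hi, bin_width_px = 1, include_zero = TRUE) {
  stopifnot(inherits(hi, "height_image"))
  h <- as.vector(hi$heights_px)
  if (!include_zero) h <- h[h > 0]
  if (length(h) == 0 || all(h == 0)) {
    warning("height image is all zero; reference level set to 0")
    return(structure(list(level_px = 0, level_um = 0,
                          bin_width_px = bin_width_px,
                          histogram = data.frame(center = 0, count = length(h))),
                     class = "reference_level"))
  }
  k <- floor(h / bin_width_px + 0.5)           # bin index, centres at k*bw
  counts <- tabulate(k + 1L, nbins = max(k) + 1L)
  centers <- (seq_along(counts) - 1L) * bin_width_px
  best <- which.max(counts)                    # first max = lowest bin on ties
  structure(
    list(level_px = centers[best],
         level_um = centers[best] * hi$axial_scale_um,
         bin_width_px = bin_width_px,
         histogram = data.frame(center = centers, count = counts)),
    class = "reference_level")
}

#' Per-subject ONL height statistic
#'
#' The scalar "ONL height" reported per subject, in micrometres. The
#' default reading is the reference-plane level (the modal base thickness
#' of the layer); `mean` and `max` of the height map are selectable.
#'
#' @param hi a `height_image`.
#' @param ref a [reference_level()] for `hi`.
#' @param mode one of `"reference_level"`, `"mean"`, `"max"`.
#' @return ONL height in micrometres.
#' @export
onl_height_summary <- function(hi, ref = reference_level(hi),
                               mode = c("reference_level", "mean", "max")) {
  mode <- tryCatch(match.arg(mode), error = function(e)
    stop_onlshape("mode must be one of reference_level, mean, max",
                  "onlshape_parameter_error"))
  switch(mode,
         reference_level = ref$level_um,
         mean = mean(heights_um(hi)),
         max = max(heights_um(hi)))
}
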