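#' Construct a segmentation surface stack
#'
#' A surface stack holds the two segmented boundary surfaces of one eye as
#' depth-per-A-scan grids: the ONL/OPL boundary (`onl_depth`) and the RPE
#' line (`rpe_depth`), both in axial pixels measured from the top of the
#' OCT volume. Rows are B-scans (row 1 = superior-most), columns are
#' A-scans (column 1 = leftmost in the displayed image).
#'
#' @param onl_depth numeric matrix of ONL/OPL boundary depths (axial px).
#' @param rpe_depth numeric matrix of RPE line depths, same shape; must be
#'   deeper (larger depth) than `onl_depth` everywhere.
#' @param subject_id subject identifier string.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param axial_range_px axial extent of the volume in pixels (default 400).
#' @return An object of class `surface_stack`.
#' @export
surface_stack <- function(onl_depth, rpe_depth, subject_id, laterality,
                          axial_range_px = 400L) {
  onl_depth <- as.matrix(onl_depth)
  rpe_depth <- as.matrix(rpe_depth)
  if (!identical(dim(onl_depth), dim(rpe_depth)))
    stop_onlshape("onl_depth and rpe_depth must have identical shape",
                  "onlshape_format_error")
  if (!all(is.finite(onl_depth)) || !all(is.finite(rpe_depth)))
    stop_onlshape("depth grids contain non-finite values",
                  "onlshape_format_error")
  if (any(onl_depth < 0) || any(rpe_depth >= axial_range_px) ||
      any(onl_depth >= axial_range_px) || any(rpe_depth < 0))
    stop_onlshape(sprintf("depth values must lie in [0, %d)", axial_range_px),
                  "onlshape_range_error")
  laterality <- match.arg(laterality, c("OD", "OS"))
  bad <- which(rpe_depth < onl_depth, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_onlshape(
      sprintf("RPE line crosses above the ONL/OPL boundary at B-scan %d, A-scan %d (first of %d cells)",
              bad[1, 1], bad[1, 2], nrow(bad)),
      "onlshape_crossing_error", cell = bad[1, ])
  }
  structure(
    list(onl_depth = onl_depth, rpe_depth = rpe_depth,
         n_bscans = nrow(onl_depth), n_ascans = ncol(onl_depth),
         axial_range_px = as.integer(axial_range_px),
         laterality = laterality, subject_id = as.character(subject_id)),
    class = "surface_stack")
}

#' @export
print.surface_stack <- function(x, ...) {
  cat(sprintf("<surface_stack> subject %s (%s): %d B-scans x %d A-scans, axial range %d px\n",
              x$subject_id, x$laterality, x$n_bscans, x$n_ascans, x$axial_range_px))
  th <- range(x$rpe_depth - x$onl_depth)
  cat(sprintf("  ONL thickness range: %.2f - %.2f px\n", th[1], th[2]))
  invisible(x)
}

#' Write a surface stack to the self-describing text format
#'
#' The format is line-oriented and diffable: header lines
#' `#onlshape-surface v1`, `#subject`, `#laterality`, `#shape rows cols`,
#' `#axial_range`, followed by two labeled blocks `ONL:` and `RPE:` of
#' tab-delimited depth values at 3 decimal places. Output is byte-identical
#' for identical input.
#'
#' @param stack a [surface_stack()].
#' @param path output file path (conventionally `*.surf.txt`).
#' @return `path`, invisibly.
#' @export
write_surface_stack <- function(stack, path) {
  stopifnot(inherits(stack, "surface_stack"))
  fmt_block <- function(m) apply(m, 1, function(r) paste(sprintf("%.3f", r), collapse = "\t"))
  lines <- c(
    "#onlshape-surface v1",
    paste0("#subject ", stack$subject_id),
    paste0("#laterality ", stack$laterality),
    sprintf("#shape %d %d", stack$n_bscans, stack$n_ascans),
    sprintf("#axial_range %d", stack$axial_range_px),
    "ONL:", fmt_block(stack$onl_depth),
    "RPE:", fmt_block(stack$rpe_depth))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_onlshape(sprintf("cannot open '%s' for writing", path), "onlshape_io_error"))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a surface stack from the text format
#'
#' Accepts tab- or space-delimited number blocks. Validates shape, depth
#' range and the RPE-below-ONL ordering; a crossing is a hard error
#' reporting the first offending cell.
#'
#' @param path file written by [write_surface_stack()].
#' @return A validated [surface_stack()].
#' @export
read_surface_stack <- function(path) {
  if (!file.exists(path))
    stop_onlshape(sprintf("surface file not found: '%s'", path), "onlshape_io_error")
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    hit <- hdr[startsWith(hdr, paste0("#", key, " "))]
    if (length(hit) != 1)
      stop_onlshape(sprintf("malformed header: expected one '#%s' line", key),
                    "onlshape_format_error")
    sub(paste0("^#", key, " +"), "", hit)
  }
  shape <- as.integer(strsplit(get_field("shape"), "[ \t]+")[[1]])
  if (length(shape) != 2 || anyNA(shape))
    stop_onlshape("malformed '#shape rows cols' header", "onlshape_format_error")
  axr <- as.integer(get_field("axial_range"))
  i_onl <- which(lines == "ONL:"); i_rpe <- which(lines == "RPE:")
  if (length(i_onl) != 1 || length(i_rpe) != 1 || i_rpe <= i_onl)
    stop_onlshape("expected one 'ONL:' block followed by one 'RPE:' block",
                  "onlshape_format_error")
  parse_block <- function(block_lines, label) {
    block_lines <- block_lines[nzchar(trimws(block_lines))]
    if (length(block_lines) != shape[1])
      stop_onlshape(sprintf("%s block has %d rows, header declares %d",
                            label, length(block_lines), shape[1]),
                    "onlshape_format_error")
    vals <- scan(text = gsub(",", "\t", block_lines, fixed = TRUE),
                 quiet = TRUE)
    if (length(vals) != shape[1] * shape[2])
      stop_onlshape(sprintf("%s block has wrong number of values", label),
                    "onlshape_format_error")
    matrix(vals, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  }
  onl <- parse_block(lines[(i_onl + 1):(i_rpe - 1)], "ONL")
  rpe <- parse_block(lines[(i_rpe + 1):length(lines)], "RPE")
  surface_stack(onl, rpe, subject_id = get_field("subject"),
                laterality = get_field("laterality"), axial_range_px = axr)
}

#' Read a subject metadata table
#'
#' Expects columns `subject_id, group, laterality, mh, mv, logmar_va`;
#' comma- and tab-delimited dialects are both accepted. MCHART scores must
#' lie in the instrument's range (0 to 2 degrees of viewing angle; 0 means
#' no detectable distortion). Duplicate subject ids are rejected.
#'
#' @param path delimited text file with a header row.
#' @return A data frame with one row per subject.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path))
    stop_onlshape(sprintf("subject table not found: '%s'", path), "onlshape_io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "laterality", "mh", "mv", "logmar_va")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_onlshape(paste0("subject table missing column(s): ",
                         paste(missing, collapse = ", ")),
                  "onlshape_format_error")
  if (nrow(df) == 0) {
    warning("subject table is empty")
    return(df[required])
  }
  if (anyDuplicated(df$subject_id))
    stop_onlshape("duplicate subject_id in subject table", "onlshape_format_error")
  if (!all(df$group %in% c("ERM", "control")))
    stop_onlshape("group must be 'ERM' or 'control'", "onlshape_format_error")
  if (!all(df$laterality %in% c("OD", "OS")))
    stop_onlshape("laterality must be 'OD' or 'OS'", "onlshape_format_error")
  for (col in c("mh", "mv")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 2))
      stop_onlshape(sprintf("%s scores must lie in [0, 2]", col),
                    "onlshape_range_error")
  }
  df[required]
}

#' Write a subject metadata table as CSV
#'
#' @param subjects data frame as returned by [read_subject_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}
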