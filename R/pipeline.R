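#' Analysis run configuration
#'
#' Bundles every tunable constant of the pipeline with its study default:
#' axial scale 3.87 um per pixel, histogram bin width 1 px, admissibility
#' bounds (20000 px^2 concave area, hull ratio 1.2, restorability 0.95),
#' five elliptic Fourier terms evaluated at 100/50/25 boundary points,
#' 1-px level-search step, and a 10-degree axis window for the correlation
#' subset. The full configuration is serialized into every run report.
#'
#' @param axial_scale_um micrometres per axial pixel.
#' @param bin_width_px reference-plane histogram bin width.
#' @param concave_max_px2,hull_ratio_max,restore_min ONL-Base criteria bounds.
#' @param n_harmonics,point_counts elliptic Fourier settings.
#' @param step_px,max_level_frac level-search settings.
#' @param axis_window_deg axis-window half-width for [table2_correlations()].
#' @param var_equal use Student rather than Welch t in group comparisons.
#' @param mirror_od mirror right-eye angles into the left-eye frame.
#' @param onl_height_mode per-subject ONL height statistic mode.
#' @param seed seed recorded with the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(axial_scale_um = 3.87, bin_width_px = 1,
                       concave_max_px2 = 20000, hull_ratio_max = 1.2,
                       restore_min = 0.95, n_harmonics = 5L,
                       point_counts = c(100L, 50L, 25L), step_px = 1,
                       max_level_frac = 0.95, axis_window_deg = 10,
                       var_equal = FALSE, mirror_od = TRUE,
                       onl_height_mode = "reference_level", seed = 1L) {
  structure(list(axial_scale_um = axial_scale_um, bin_width_px = bin_width_px,
                 concave_max_px2 = concave_max_px2,
                 hull_ratio_max = hull_ratio_max, restore_min = restore_min,
                 n_harmonics = as.integer(n_harmonics),
                 point_counts = as.integer(point_counts),
                 step_px = step_px, max_level_frac = max_level_frac,
                 axis_window_deg = axis_window_deg, var_equal = var_equal,
                 mirror_od = mirror_od, onl_height_mode = onl_height_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Analyze one subject's surfaces
#'
#' Deterministic composition of the per-eye pipeline: height image ->
#' reference level -> ONL-Base selection -> moment-ellipse fit -> shape
#' parameters -> MH/MV. A subject whose level search fails (no admissible
#' contour, e.g. a deformation running off the imaged field) is returned
#' flagged `excluded` with the failure reason rather than dropped.
#'
#' @param stack a [surface_stack()].
#' @param meta one-row data frame (or list) with `subject_id`, `group`,
#'   `laterality`, `mh`, `mv`, `logmar_va`.
#' @param cfg a [run_config()].
#' @return one-row data frame of per-subject results.
#' @export
analyze_subject <- function(stack, meta, cfg = run_config()) {
  stopifnot(inherits(stack, "surface_stack"))
  hi <- build_height_image(stack, axial_scale_um = cfg$axial_scale_um)
  ref <- reference_level(hi, bin_width_px = cfg$bin_width_px)
  base <- data.frame(
    subject_id = stack$subject_id,
    group = meta$group, laterality = stack$laterality,
    mh = meta$mh, mv = meta$mv, logmar_va = meta$logmar_va,
    mh_mv = mh_mv_ratio(meta$mh, meta$mv),
    onl_height_um = onl_height_summary(hi, ref, cfg$onl_height_mode),
    reference_level_px = ref$level_px)
  onlb <- tryCatch(
    select_onlb(hi, ref, step_px = cfg$step_px,
                max_level_frac = cfg$max_level_frac,
                concave_max_px2 = cfg$concave_max_px2,
                hull_ratio_max = cfg$hull_ratio_max,
                restore_min = cfg$restore_min,
                n_harmonics = cfg$n_harmonics,
                point_counts = cfg$point_counts),
    onlshape_selection_failure = function(e) e)
  if (inherits(onlb, "condition")) {
    return(cbind(base, data.frame(
      level_px = NA_real_, level_um = NA_real_, axis_deg = NA_real_,
      theta_raw_deg = NA_real_, circularity = NA_real_,
      area_ratio = NA_real_, axis_ratio = NA_real_,
      area_S_px2 = NA_real_, perimeter_L_px = NA_real_,
      excluded = TRUE, exclusion_reason = conditionMessage(onlb))))
  }
  sp <- shape_params(onlb$contour, stack$laterality,
                     n_harmonics = cfg$n_harmonics, mirror_od = cfg$mirror_od)
  cbind(base, data.frame(
    level_px = onlb$level_px, level_um = onlb$level_um,
    axis_deg = sp$axis_deg, theta_raw_deg = sp$theta_raw_deg,
    circularity = sp$circularity, area_ratio = sp$area_ratio,
    axis_ratio = sp$axis_ratio,
    area_S_px2 = onlb$contour$area_S,
    perimeter_L_px = onlb$contour$perimeter_L,
    excluded = FALSE, exclusion_reason = ""))
}

#' Run the full cohort analysis over a directory of surfaces
#'
#' Reads `subjects.csv` and one `<subject_id>.surf.txt` per row, analyzes
#' every subject, and writes `results.csv`, `table1.csv`, `table2.csv`
#' and `run_report.json` (configuration, exclusions, package version) to
#' `output_dir`. Output is byte-identical for identical inputs and
#' configuration.
#'
#' @param input_dir directory with surface files and `subjects.csv`.
#' @param cfg a [run_config()].
#' @param output_dir where to write results (created if needed); `NULL`
#'   skips writing.
#' @return list with `results`, `table1`, `table2`, `excluded` (ids).
#' @export
run_cohort <- function(input_dir, cfg = run_config(), output_dir = NULL) {
  subj_path <- file.path(input_dir, "subjects.csv")
  if (!file.exists(subj_path))
    stop_onlshape(sprintf("missing subject table: '%s'", subj_path),
                  "onlshape_io_error")
  subjects <- read_subject_table(subj_path)
  if (nrow(subjects) == 0)
    stop_onlshape("no subjects to analyze", "onlshape_run_error")
  results <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    meta <- subjects[i, ]
    sf <- file.path(input_dir, paste0(meta$subject_id, ".surf.txt"))
    stack <- read_surface_stack(sf)
    analyze_subject(stack, meta, cfg)
  }))
  if (all(results$excluded))
    stop_onlshape("no analyzable subjects (all excluded)", "onlshape_run_error")
  tab1 <- table1_summary(results, var_equal = cfg$var_equal)
  tab2 <- table2_correlations(results, axis_window_deg = cfg$axis_window_deg)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_stable <- function(df, path) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) signif(x, 10))
      utils::write.table(df, path, sep = ",", row.names = FALSE,
                         quote = FALSE, eol = "\n")
    }
    write_csv_stable(results, file.path(output_dir, "results.csv"))
    write_csv_stable(tab1, file.path(output_dir, "table1.csv"))
    write_csv_stable(tab2, file.path(output_dir, "table2.csv"))
    report <- list(
      package = "onlshape",
      version = as.character(utils::packageVersion("onlshape")),
      config = unclass(cfg),
      n_subjects = nrow(results),
      n_excluded = sum(results$excluded),
      excluded = results$subject_id[results$excluded])
    jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(results = results, table1 = tab1, table2 = tab2,
       excluded = results$subject_id[results$excluded])
}
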