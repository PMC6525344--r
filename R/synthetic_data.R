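#' Parametric foveal bump model
#'
#' Synthetic ONL height field: a constant base layer plus an anisotropic
#' Gaussian foveal bump whose level sets are ellipses of axis ratio
#' `sigma_major_px / sigma_minor_px` at orientation `theta_true_deg`
#' (left-eye frame, counterclockwise positive). A multiplicative radial
#' ripple `1 + ripple_amp * cos(ripple_lobes * psi)` is applied to the
#' level-set radius, so every level set shares the same shape and the
#' ground-truth shape parameters are level-independent. Additive Gaussian
#' noise perturbs the rendered surfaces.
#'
#' @param base_height_px background ONL thickness (axial px).
#' @param peak_height_px foveal peak height above the base.
#' @param sigma_major_px,sigma_minor_px Gaussian widths along the major
#'   and minor axes (`sigma_major_px >= sigma_minor_px > 0`).
#' @param theta_true_deg major-axis orientation in the left-eye frame,
#'   degrees in (-90, 90].
#' @param ripple_amp fractional radial ripple amplitude in \[0, 0.5).
#' @param ripple_lobes integer lobe count >= 3.
#' @param noise_sd_px SD of additive surface noise (axial px).
#' @param laterality `"OD"` or `"OS"`; OD fields are rendered mirrored so
#'   the left-eye-frame truth stays `theta_true_deg`.
#' @param subject_id identifier carried into the surfaces.
#' @param seed RNG seed for the noise stream.
#' @return list of class `bump_model`.
#' @export
bump_model <- function(base_height_px = 14, peak_height_px = 55,
                       sigma_major_px = 60, sigma_minor_px = 42,
                       theta_true_deg = 0, ripple_amp = 0,
                       ripple_lobes = 12L, noise_sd_px = 0,
                       laterality = "OS", subject_id = "sim", seed = 1L) {
  if (peak_height_px <= 0 || sigma_minor_px <= 0 ||
      sigma_major_px < sigma_minor_px)
    stop_onlshape("need peak_height_px > 0 and sigma_major_px >= sigma_minor_px > 0",
                  "onlshape_parameter_error")
  if (ripple_amp < 0 || ripple_amp >= 0.5)
    stop_onlshape("ripple_amp must lie in [0, 0.5)", "onlshape_parameter_error")
  if (ripple_lobes < 3)
    stop_onlshape("ripple_lobes must be >= 3", "onlshape_parameter_error")
  structure(list(base_height_px = base_height_px,
                 peak_height_px = peak_height_px,
                 sigma_major_px = sigma_major_px,
                 sigma_minor_px = sigma_minor_px,
                 theta_true_deg = wrap_angle_deg(theta_true_deg),
                 ripple_amp = ripple_amp,
                 ripple_lobes = as.integer(ripple_lobes),
                 noise_sd_px = noise_sd_px,
                 laterality = match.arg(laterality, c("OD", "OS")),
                 subject_id = subject_id, seed = as.integer(seed)),
            class = "bump_model")
}

# height field at world coordinates (x right, y up), left-eye frame
bump_height_field <- function(model, x, y, center) {
  th <- model$theta_true_deg * pi / 180
  dx <- x - center[1]; dy <- y - center[2]
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  ru <- u / model$sigma_major_px
  rv <- v / model$sigma_minor_px
  rho <- sqrt(ru^2 + rv^2)
  g <- 1 + model$ripple_amp * cos(model$ripple_lobes * atan2(rv, ru))
  model$base_height_px + model$peak_height_px * exp(-0.5 * (rho / g)^2)
}

#' Analytic ground-truth contour of a bump model
#'
#' The noiseless level set of the bump at unit elliptical radius (its
#' shape is the same at every level), as a dense polygon in the left-eye
#' frame, from which the analytic shape-parameter truth is derived.
#'
#' @param model a `bump_model`.
#' @param n_points polygon density (default 720).
#' @return An `onl_contour`.
#' @export
truth_contour <- function(model, n_points = 720L) {
  psi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  g <- 1 + model$ripple_amp * cos(model$ripple_lobes * psi)
  u <- model$sigma_major_px * g * cos(psi)
  v <- model$sigma_minor_px * g * sin(psi)
  th <- model$theta_true_deg * pi / 180
  contour_polygon(cbind(cos(th) * u - sin(th) * v,
                        sin(th) * u + cos(th) * v))
}

# level-independent analytic shape truth for a model
model_truth <- function(model) {
  ctr <- truth_contour(model)
  fit <- fit_ellipse_moments(region_moments(ctr))
  data.frame(
    subject_id = model$subject_id,
    laterality = model$laterality,
    theta_true_deg = model$theta_true_deg,
    axis_ratio_true = model$sigma_major_px / model$sigma_minor_px,
    circularity_true = circularity(ctr),
    area_ratio_true = area_ratio(ctr$area_S, fit),
    base_height_px = model$base_height_px,
    peak_height_px = model$peak_height_px,
    sigma_major_px = model$sigma_major_px,
    sigma_minor_px = model$sigma_minor_px,
    ripple_amp = model$ripple_amp,
    ripple_lobes = model$ripple_lobes,
    noise_sd_px = model$noise_sd_px,
    seed = model$seed)
}

#' Render segmentation surfaces from a bump model
#'
#' Evaluates the bump field at the 49 B-scan positions (the continuous
#' field is sampled exactly where the scanner acquires, so row
#' interpolation in the analysis is the only resampling), renders a flat
#' RPE surface at `rpe_depth_px`, sets the ONL/OPL boundary at
#' `rpe_depth_px - height`, adds seeded Gaussian noise, and mirrors the
#' columns for right eyes.
#'
#' @param model a `bump_model`.
#' @param n_bscans,n_ascans acquisition grid (default 49 x 512).
#' @param grid_size full-resolution lateral grid side (default 512).
#' @param rpe_depth_px constant RPE depth (default 300).
#' @param axial_range_px volume depth (default 400).
#' @return list with `stack` (a [surface_stack()]) and `truth` (one-row
#'   data frame of ground-truth parameters).
#' @export
generate_surfaces <- function(model, n_bscans = 49L, n_ascans = 512L,
                              grid_size = 512L, rpe_depth_px = 300,
                              axial_range_px = 400L) {
  stopifnot(inherits(model, "bump_model"))
  center <- c((n_ascans + 1) / 2, (grid_size + 1) / 2)
  # B-scan i sits at full-resolution row 1 + (i-1)*(grid_size-1)/(n_bscans-1);
  # row 1 is superior, so world y = grid_size + 1 - row
  rows <- 1 + (seq_len(n_bscans) - 1) * (grid_size - 1) / (n_bscans - 1)
  ys <- grid_size + 1 - rows
  xs <- seq_len(n_ascans)
  if (model$laterality == "OD") xs <- n_ascans + 1 - xs   # horizontal mirror
  X <- matrix(xs, n_bscans, n_ascans, byrow = TRUE)
  Y <- matrix(ys, n_bscans, n_ascans)
  h <- bump_height_field(model, X, Y, center)
  h <- with_local_seed(model$seed, {
    if (model$noise_sd_px > 0)
      h + matrix(stats::rnorm(length(h), 0, model$noise_sd_px),
                 n_bscans, n_ascans)
    else h
  })
  h <- pmin(pmax(h, 0), rpe_depth_px - 1e-6)
  stack <- surface_stack(onl_depth = rpe_depth_px - h,
                         rpe_depth = matrix(rpe_depth_px, n_bscans, n_ascans),
                         subject_id = model$subject_id,
                         laterality = model$laterality,
                         axial_range_px = axial_range_px)
  list(stack = stack, truth = model_truth(model))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

default_group_params <- function(group) {
  if (group == "ERM")
    list(base_mean = 21.73, base_sd = 3.33,     # 84.1 +/- 12.9 um at 3.87 um/px
         peak_mean = 55, peak_sd = 8,
         sigma_minor_mean = 45, sigma_minor_sd = 6,
         axis_ratio_mean = 1.54, axis_ratio_sd = 0.37,
         theta_mean = -1.28, theta_sd = 29.1,
         ripple_amp_mean = 0.05, ripple_amp_sd = 0.02, ripple_amp_max = 0.09,
         ripple_lobes = 4:6,
         noise_sd = 1.0,
         logmar_mean = 0.24, logmar_sd = 0.16)
  else
    list(base_mean = 13.98, base_sd = 1.37,     # 54.1 +/- 5.3 um
         peak_mean = 48, peak_sd = 6,
         sigma_minor_mean = 42, sigma_minor_sd = 5,
         axis_ratio_mean = 1.51, axis_ratio_sd = 0.35,
         theta_mean = -6.25, theta_sd = 21.8,
         ripple_amp_mean = 0.03, ripple_amp_sd = 0.015, ripple_amp_max = 0.07,
         ripple_lobes = 4:6,
         noise_sd = 1.0,
         logmar_mean = -0.12, logmar_sd = 0.03)
}

#' Cohort simulation specification
#'
#' Group sizes default to the study design (39 ERM eyes, 21 fellow-eye
#' controls). Per-group bump-parameter distributions default to values
#' emulating the reported cohort (base thickness from the group ONL
#' heights, axis ratio and axis angle from the group means/SDs, mild
#' boundary ripple kept within the admissibility bounds). `mchart_link`
#' couples the simulated MCHART anisotropy MH/MV to ground-truth shape:
#' `log(MH/MV) = log_sd * (rho * z + sqrt(1-rho^2) * eps)` with `z` the
#' standardized ground-truth value of `target` across the ERM group, so
#' `rho` is the built-in latent correlation (negative by default: more
#' irregular, lower-area-ratio eyes report more horizontal distortion).
#'
#' @param n_erm,n_control group sizes.
#' @param erm,control named lists overriding entries of the per-group
#'   parameter distributions (see source of `default_group_params`).
#' @param mchart_link list with `rho`, `target` (ground-truth column),
#'   `log_sd`, `mv_log_mean`, `mv_log_sd`.
#' @param seed master seed; per-subject streams are derived from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_erm = 39L, n_control = 21L,
                        erm = list(), control = list(),
                        mchart_link = list(), seed = 1L) {
  if (n_erm < 1 || n_control < 0)
    stop_onlshape("need n_erm >= 1 and n_control >= 0", "onlshape_parameter_error")
  link <- utils::modifyList(
    list(rho = -0.47, target = "area_ratio_true", log_sd = 0.7,
         mv_log_mean = log(0.45), mv_log_sd = 0.55),
    mchart_link)
  structure(list(
    n_erm = as.integer(n_erm), n_control = as.integer(n_control),
    erm = utils::modifyList(default_group_params("ERM"), erm),
    control = utils::modifyList(default_group_params("control"), control),
    mchart_link = link, seed = as.integer(seed)),
    class = "cohort_spec")
}

# deterministic per-subject substream seed, kept below 2^31
derive_seed <- function(master, index) {
  ((master %% 1000003) * 2147483 + index * 7919) %% 2147483647
}

# MCHART chart quantization: 0.1-degree steps, floor of detection at 0.2
quantize_mchart <- function(x) {
  q <- round(pmin(pmax(x, 0), 2) * 10) / 10
  ifelse(q < 0.2, 0, q)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject bump models from the group distributions of `spec`
#' (deterministic per-subject substreams derived from the master seed),
#' simulates MCHART MH/MV scores linked to ground-truth deformation, and
#' optionally renders and writes the segmentation surfaces.
#'
#' @param spec a [cohort_spec()].
#' @param dir if non-NULL, write `<subject>.surf.txt` files,
#'   `subjects.csv` and `ground_truth.csv` there.
#' @param render_surfaces set `FALSE` to skip surface rendering and return
#'   only subject metadata and ground truth (fast path for statistical
#'   calibration studies).
#' @return list with `subjects` (metadata data frame), `truth`
#'   (ground-truth data frame), `models` (list of `bump_model`), and
#'   `stacks` (list of `surface_stack` or NULL).
#' @export
generate_cohort <- function(spec, dir = NULL, render_surfaces = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_erm + spec$n_control
  groups <- rep(c("ERM", "control"), c(spec$n_erm, spec$n_control))
  ids <- sprintf("s%03d", seq_len(n))
  models <- vector("list", n)
  logmar <- numeric(n)
  for (i in seq_len(n)) {
    gp <- if (groups[i] == "ERM") spec$erm else spec$control
    sseed <- derive_seed(spec$seed, i)
    drawn <- with_local_seed(sseed, {
      sig_min <- rtrunc_norm(1, gp$sigma_minor_mean, gp$sigma_minor_sd, 28, 58)
      ar <- rtrunc_norm(1, gp$axis_ratio_mean, gp$axis_ratio_sd, 1.0, 2.2)
      amp <- rtrunc_norm(1, gp$ripple_amp_mean, gp$ripple_amp_sd, 0, gp$ripple_amp_max)
      m <- bump_model(
        base_height_px = rtrunc_norm(1, gp$base_mean, gp$base_sd, 5, 40),
        peak_height_px = rtrunc_norm(1, gp$peak_mean, gp$peak_sd, 30, 90),
        sigma_major_px = sig_min * ar, sigma_minor_px = sig_min,
        theta_true_deg = wrap_angle_deg(stats::rnorm(1, gp$theta_mean, gp$theta_sd)),
        ripple_amp = amp,
        ripple_lobes = sample(gp$ripple_lobes, 1),
        noise_sd_px = gp$noise_sd,
        laterality = sample(c("OD", "OS"), 1),
        subject_id = ids[i],
        seed = derive_seed(sseed, 1))
      list(model = m, logmar = round(stats::rnorm(1, gp$logmar_mean, gp$logmar_sd), 2))
    })
    models[[i]] <- drawn$model
    logmar[i] <- drawn$logmar
  }
  truth <- do.call(rbind, lapply(models, model_truth))
  truth$group <- groups
  # MCHART scores: ERM eyes get MH/MV linked to ground-truth shape
  link <- spec$mchart_link
  mh <- mv <- numeric(n)
  erm_idx <- which(groups == "ERM")
  tv <- truth[[link$target]][erm_idx]
  z <- if (stats::sd(tv) > 0) (tv - mean(tv)) / stats::sd(tv) else tv * 0
  scores <- with_local_seed(derive_seed(spec$seed, 999983), {
    eps <- stats::rnorm(length(erm_idx))
    log_ratio <- link$log_sd * (link$rho * z + sqrt(1 - link$rho^2) * eps)
    mv_raw <- exp(stats::rnorm(length(erm_idx), link$mv_log_mean, link$mv_log_sd))
    cbind(mv_raw * exp(log_ratio), mv_raw)
  })
  mh[erm_idx] <- quantize_mchart(scores[, 1])
  mv[erm_idx] <- quantize_mchart(scores[, 2])
  subjects <- data.frame(subject_id = ids, group = groups,
                         laterality = vapply(models, `[[`, "", "laterality"),
                         mh = mh, mv = mv, logmar_va = logmar)
  stacks <- NULL
  if (render_surfaces) {
    sims <- lapply(models, generate_surfaces)
    stacks <- lapply(sims, `[[`, "stack")
    names(stacks) <- ids
  }
  if (!is.null(dir)) {
    if (is.null(stacks))
      stop_onlshape("cannot write a cohort generated without surfaces",
                    "onlshape_parameter_error")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_surface_stack(stacks[[i]], file.path(dir, paste0(ids[i], ".surf.txt")))
    write_subject_table(subjects, file.path(dir, "subjects.csv"))
    utils::write.table(truth, file.path(dir, "ground_truth.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE, eol = "\n")
  }
  list(subjects = subjects, truth = truth, models = models, stacks = stacks)
}
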