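#' Configuration for a synthetic delineation cohort
#'
#' Bundles the study design (patients, observers, imaging systems, organs),
#' the voxel grid, the linear model on the Dice scale that the generated
#' geometry realises, and the distributions for correction times and
#' confidence scores. All defaults emulate a two-arm multi-reader pelvic
#' study: 20 patients scanned on both a high-performance and a conventional
#' CBCT system, three observers correcting AI contours of five organs.
#'
#' The metric-scale model is `y = beta0 + beta1 * x + u_patient + v_observer +
#' eps`, with `x` coded 0 for the high-performance arm and 1 for the
#' conventional arm, so a negative `beta1_dsc` means the conventional arm has
#' lower Dice agreement.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_observers number of observers (>= 2).
#' @param imaging_systems two arm labels; the first is coded `x = 0`.
#' @param organs organ labels; defaults to the five pelvic organs.
#' @param grid_shape voxels per axis.
#' @param spacing_mm voxel size in mm (scalar or length 3).
#' @param beta0_dsc,beta1_dsc per-organ baseline Dice in the `x = 0` arm and
#'   imaging-system effect (conventional minus high-performance).
#' @param beta0_hd95,beta1_hd95 per-organ HD95 baseline and effect in mm,
#'   used by [generate_metric_table()]; cohort geometry is calibrated on the
#'   Dice scale and HD95 emerges from the same deformations.
#' @param sigma2_patient,sigma2_observer,sigma2_residual variance components
#'   on the Dice scale (>= 0).
#' @param deformation_scale multiplier mapping the target metric level to the
#'   geometric perturbation magnitude; 0 disables all deformation.
#' @param correction_time_model list with `organ_mean_s` and `organ_sd_s`,
#'   organs x arms matrices of lognormal mean/SD in seconds.
#' @param confidence_model organs x arms x 5 array of categorical
#'   probabilities over scores 1..5 (each slice sums to 1).
#' @param outlier_scenario list `enabled` flag + `patient` index: grossly
#'   degrade the conventional-arm bladder AI contour of one patient,
#'   emulating a failed acquisition on a heavy patient.
#' @param exclude_bowel_patient optional patient index whose bowel records
#'   are emitted as missing (limited field of view), exercising unbalanced
#'   analysis paths.
#' @param bootstrap_B bootstrap replicates used by [run_pipeline()].
#' @param seed integer seed making the whole cohort reproducible.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20L,
                          n_observers = 3L,
                          imaging_systems = c("high_performance", "conventional"),
                          organs = c("prostate", "seminal_vesicles", "bladder",
                                     "rectum", "bowel"),
                          grid_shape = c(96L, 96L, 96L),
                          spacing_mm = 2,
                          beta0_dsc = c(prostate = 0.86, seminal_vesicles = 0.71,
                                        bladder = 0.95, rectum = 0.89, bowel = 0.86),
                          beta1_dsc = c(prostate = 0.00, seminal_vesicles = 0.00,
                                        bladder = -0.03, rectum = 0.00, bowel = -0.03),
                          beta0_hd95 = c(prostate = 5.03, seminal_vesicles = 6.14,
                                         bladder = 4.53, rectum = 8.25, bowel = 11.33),
                          beta1_hd95 = c(prostate = 0.35, seminal_vesicles = 0.63,
                                         bladder = 1.95, rectum = 0.13, bowel = 0.68),
                          sigma2_patient = 3e-3,
                          sigma2_observer = 4e-4,
                          sigma2_residual = 2.5e-3,
                          deformation_scale = 1,
                          correction_time_model = NULL,
                          confidence_model = NULL,
                          outlier_scenario = list(enabled = FALSE, patient = 1L),
                          exclude_bowel_patient = NULL,
                          bootstrap_B = 10000L,
                          seed = 1L) {
  n_patients <- as.integer(n_patients); n_observers <- as.integer(n_observers)
  if (n_patients < 2L) stop("`n_patients` must be >= 2")
  if (n_observers < 2L) stop("`n_observers` must be >= 2")
  if (length(imaging_systems) != 2L || anyDuplicated(imaging_systems))
    stop("`imaging_systems` must be two distinct labels")
  if (length(organs) < 1L || anyDuplicated(organs)) stop("invalid `organs`")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("`grid_shape` must be 3 axis lengths >= 4")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be strictly positive and finite")
  for (nm in c("sigma2_patient", "sigma2_observer", "sigma2_residual")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single value >= 0")
  }
  if (deformation_scale < 0) stop("`deformation_scale` must be >= 0")
  norg <- length(organs)
  recycle <- function(v, nm) {
    if (length(v) == 1L) v <- rep(v, norg)
    if (length(v) != norg) stop("`", nm, "` must have one value per organ")
    stats::setNames(as.numeric(v), organs)
  }
  beta0_dsc <- recycle(beta0_dsc, "beta0_dsc")
  beta1_dsc <- recycle(beta1_dsc, "beta1_dsc")
  beta0_hd95 <- recycle(beta0_hd95, "beta0_hd95")
  beta1_hd95 <- recycle(beta1_hd95, "beta1_hd95")
  if (any(beta0_dsc <= 0 | beta0_dsc > 1)) stop("`beta0_dsc` must lie in (0, 1]")

  if (is.null(correction_time_model))
    correction_time_model <- default_time_model(organs, imaging_systems)
  validate_time_model(correction_time_model, organs, imaging_systems)
  if (is.null(confidence_model))
    confidence_model <- default_confidence_model(organs, imaging_systems)
  validate_confidence_model(confidence_model, organs, imaging_systems)

  if (!is.list(outlier_scenario) || is.null(outlier_scenario$enabled))
    stop("`outlier_scenario` must be a list with `enabled` and `patient`")
  outlier_scenario$enabled <- isTRUE(outlier_scenario$enabled)
  outlier_scenario$patient <- as.integer(outlier_scenario$patient %||% 1L)
  if (outlier_scenario$enabled &&
      (outlier_scenario$patient < 1L || outlier_scenario$patient > n_patients))
    stop("outlier patient index out of range")
  if (!is.null(exclude_bowel_patient)) {
    exclude_bowel_patient <- as.integer(exclude_bowel_patient)
    if (!"bowel" %in% organs) stop("`exclude_bowel_patient` set but no bowel organ")
    if (exclude_bowel_patient < 1L || exclude_bowel_patient > n_patients)
      stop("`exclude_bowel_patient` out of range")
  }
  structure(list(
    n_patients = n_patients, n_observers = n_observers,
    imaging_systems = imaging_systems, organs = organs,
    grid_shape = grid_shape, spacing_mm = spacing_mm,
    beta0_dsc = beta0_dsc, beta1_dsc = beta1_dsc,
    beta0_hd95 = beta0_hd95, beta1_hd95 = beta1_hd95,
    sigma2_patient = sigma2_patient, sigma2_observer = sigma2_observer,
    sigma2_residual = sigma2_residual,
    deformation_scale = deformation_scale,
    correction_time_model = correction_time_model,
    confidence_model = confidence_model,
    outlier_scenario = outlier_scenario,
    exclude_bowel_patient = exclude_bowel_patient,
    bootstrap_B = as.integer(bootstrap_B),
    seed = as.integer(seed)), class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Arm totals follow the reported workflow times (~11 min per 5-organ scan);
# the per-organ split is even, with SD scaled by 1/sqrt(n_organs) so organ
# times sum back to the arm-level mean/SD.
default_time_model <- function(organs, systems) {
  total_mean <- c(663, 672); total_sd <- c(197, 190)
  norg <- length(organs)
  m <- outer(rep(1 / norg, norg), total_mean)
  s <- outer(rep(1, norg), total_sd) / sqrt(norg)
  dimnames(m) <- dimnames(s) <- list(organs, systems)
  list(organ_mean_s = m, organ_sd_s = s)
}

validate_time_model <- function(tm, organs, systems) {
  for (nm in c("organ_mean_s", "organ_sd_s")) {
    x <- tm[[nm]]
    if (is.null(x) || !is.matrix(x) || !identical(dim(x), c(length(organs), length(systems))))
      stop("`correction_time_model$", nm, "` must be an organs x arms matrix")
    if (any(!is.finite(x)) || any(x < 0)) stop("correction times must be >= 0")
  }
  invisible(TRUE)
}

# Confidence scores 1..5 as 1 + Binomial(4, p): p = (mean - 1) / 4 reproduces
# arm-level mean scores with realistic spread (SD ~0.6 at mean 4.5, ~1.0 at 3.5).
default_confidence_model <- function(organs, systems) {
  means <- cbind(c(4.5, 4.3, 4.9, 4.8, 4.6), c(3.5, 3.5, 4.5, 4.3, 4.4))
  if (length(organs) != 5L) means <- matrix(4.2, length(organs), 2)
  arr <- array(NA_real_, c(length(organs), 2L, 5L),
               dimnames = list(organs, systems, paste0("s", 1:5)))
  for (i in seq_along(organs)) for (j in 1:2) {
    p <- (means[i, j] - 1) / 4
    arr[i, j, ] <- stats::dbinom(0:4, 4, p)
  }
  arr
}

validate_confidence_model <- function(cm, organs, systems) {
  if (!is.array(cm) || !identical(dim(cm), c(length(organs), length(systems), 5L)))
    stop("`confidence_model` must be an organs x arms x 5 probability array")
  if (any(cm < 0) || any(abs(apply(cm, c(1, 2), sum) - 1) > 1e-6))
    stop("confidence distributions must be non-negative and sum to 1")
  invisible(TRUE)
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Scalar and vector fields override the defaults of [cohort_config()];
#' unknown fields raise an error.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return a validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the jsonlite package")
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must define a mapping of fields")
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         "; known fields: ", paste(known, collapse = ", "))
  # matrix/array fields are stored flat (column-major); rebuild them
  organs <- vals$organs %||% eval(formals(cohort_config)$organs)
  systems <- vals$imaging_systems %||% eval(formals(cohort_config)$imaging_systems)
  if (!is.null(vals$correction_time_model)) {
    vals$correction_time_model <- lapply(vals$correction_time_model, function(m) {
      m <- matrix(unlist(m), nrow = length(organs))
      dimnames(m) <- list(organs, systems)
      m
    })
  }
  if (!is.null(vals$confidence_model))
    vals$confidence_model <- array(unlist(vals$confidence_model),
                                   c(length(organs), length(systems), 5L),
                                   dimnames = list(organs, systems, paste0("s", 1:5)))
  do.call(cohort_config, vals)
}

#' Write a cohort configuration to YAML
#' @param config a `cohort_config`.
#' @param path output filename.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  # flatten matrix/array fields (column-major); read_cohort_config rebuilds them
  x$correction_time_model <- lapply(x$correction_time_model, as.numeric)
  x$confidence_model <- as.numeric(x$confidence_model)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Organ geometry: superellipsoid truth shapes in a pelvis-like arrangement.
# Offsets are mm relative to the grid center; semi-axes in mm. `exy`/`ez` are
# the in-plane and axial superellipsoid exponents (2 = ellipsoid, larger =
# boxier / more cylindrical).
organ_geometry <- function(organ) {
  tab <- list(
    prostate          = list(offset = c(0, 0, -26), semi = c(22, 20, 19), exy = 2, ez = 2.5),
    seminal_vesicles  = list(offset = c(0, 20, -14), semi = c(26, 12, 10), exy = 2, ez = 2),
    bladder           = list(offset = c(0, -20, 9), semi = c(38, 34, 31), exy = 2.2, ez = 2.2),
    rectum            = list(offset = c(0, 34, -24), semi = c(15, 13, 44), exy = 2, ez = 6),
    bowel             = list(offset = c(0, 0, 40), semi = c(46, 40, 28), exy = 2, ez = 2)
  )
  g <- tab[[organ]]
  # unlisted organ labels fall back to a mid-size central ellipsoid
  if (is.null(g)) g <- list(offset = c(0, 0, 0), semi = c(25, 25, 25), exy = 2, ez = 2)
  g
}

superellipsoid_inside <- function(X, Y, Z, center, semi, exy, ez) {
  r2 <- abs((X - center[1]) / semi[1])^exy + abs((Y - center[2]) / semi[2])^exy
  r2^(ez / exy) + abs((Z - center[3]) / semi[3])^ez <= 1
}

# Smooth random displacement field: a sum of low-frequency vector sinusoids.
# RMS displacement magnitude equals `scale` (mm); the maximum possible
# magnitude is scale * sqrt(2 * n_modes).
draw_field_modes <- function(n_modes = 6L, wavelength_mm = c(45, 110)) {
  lapply(seq_len(n_modes), function(m) {
    k <- rnorm(3); k <- k / sqrt(sum(k^2))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    list(k = k, lambda = runif(1, wavelength_mm[1], wavelength_mm[2]),
         phi = runif(1, 0, 2 * pi), u = u)
  })
}

eval_field <- function(modes, scale, axes) {
  dims <- lengths(axes)
  dX <- dY <- dZ <- array(0, dims)
  if (scale <= 0) return(list(dX = dX, dY = dY, dZ = dZ))
  alpha <- scale * sqrt(2 / length(modes))
  for (m in modes) {
    w <- 2 * pi / m$lambda
    ph <- outer(outer(w * m$k[1] * axes[[1]], w * m$k[2] * axes[[2]], "+"),
                w * m$k[3] * axes[[3]], "+") + m$phi
    s <- sin(ph)
    dX <- dX + alpha * m$u[1] * s
    dY <- dY + alpha * m$u[2] * s
    dZ <- dZ + alpha * m$u[3] * s
  }
  list(dX = dX, dY = dY, dZ = dZ)
}

# Voxel-center coordinate arrays of a window (computed once per window and
# shared across the truth/AI/corrected builds).
window_coords <- function(axes) {
  n1 <- length(axes[[1]]); n2 <- length(axes[[2]]); n3 <- length(axes[[3]])
  list(X = array(axes[[1]], c(n1, n2, n3)),
       Y = array(rep(axes[[2]], each = n1), c(n1, n2, n3)),
       Z = array(rep(axes[[3]], each = n1 * n2), c(n1, n2, n3)),
       axes = axes)
}

# Build the (possibly warped) organ mask on a window of the full grid.
# The warped shape is {x : f(x + d(x)) <= 1}.
build_organ_mask <- function(coords, center, semi, exy, ez, modes = NULL, scale = 0) {
  if (is.null(coords$X)) coords <- window_coords(coords$axes %||% coords)
  if (is.null(modes) || scale <= 0)
    return(superellipsoid_inside(coords$X, coords$Y, coords$Z, center, semi, exy, ez))
  d <- eval_field(modes, scale, coords$axes)
  superellipsoid_inside(coords$X + d$dX, coords$Y + d$dY, coords$Z + d$dZ,
                        center, semi, exy, ez)
}

# Window of full-grid indices covering `center +/- half_extent_mm`, clamped to
# the grid. Returns index ranges and the world coordinates of voxel centers.
grid_window <- function(center, half_extent_mm, grid_shape, spacing_mm) {
  lo <- pmax(1L, floor((center - half_extent_mm) / spacing_mm) + 1L)
  hi <- pmin(grid_shape, ceiling((center + half_extent_mm) / spacing_mm) + 1L)
  axes <- lapply(1:3, function(a) (seq(lo[a], hi[a]) - 1) * spacing_mm[a])
  list(lo = lo, hi = hi, axes = axes,
       origin_mm = (lo - 1L) * spacing_mm)
}

# ---------------------------------------------------------------------------
# Displacement-magnitude -> Dice calibration. No closed form links a smooth
# random deformation to the Dice it induces, so the map is measured once per
# organ on a coarsened grid and inverted by monotone interpolation.
calibrate_displacement <- function(config,
                                   scales = c(0.5, 1, 2, 3, 4.5, 6.5, 9, 13),
                                   reps = 5L) {
  spacing <- pmax(config$spacing_mm, 4)  # coarse grid is enough for a mean map
  lapply(stats::setNames(config$organs, config$organs), function(org) {
    g <- organ_geometry(org)
    center <- g$semi + 3 * max(scales) / 2 + 3 * spacing  # local frame
    gs <- ceiling(2 * center / spacing) + 2L
    win <- grid_window(center, g$semi + 2.5 * max(scales) + 2 * spacing, gs, spacing)
    crd <- window_coords(win$axes)
    truth <- build_organ_mask(crd, center, g$semi, g$exy, g$ez)
    mean_dsc <- vapply(scales, function(s) {
      mean(vapply(seq_len(reps), function(r) {
        modes <- draw_field_modes()
        warped <- build_organ_mask(crd, center, g$semi, g$exy, g$ez, modes, s)
        2 * sum(truth & warped) / (sum(truth) + sum(warped))
      }, numeric(1)))
    }, numeric(1))
    # enforce strictly decreasing DSC in scale so the inversion is unique
    dsc <- c(1, cummin(pmin(mean_dsc, 1 - 1e-9)))
    dsc <- dsc - (seq_along(dsc) - 1) * 1e-9
    list(scale = c(0, scales), dsc = dsc)
  })
}

# invert the calibration: target Dice -> displacement scale (mm)
scale_for_dsc <- function(cal, target_dsc) {
  target_dsc <- pmin(pmax(target_dsc, min(cal$dsc)), 1)
  stats::approx(x = rev(cal$dsc), y = rev(cal$scale), xout = target_dsc,
                rule = 2)$y
}

# ---------------------------------------------------------------------------

#' Generate a full synthetic delineation cohort
#'
#' Builds, for every (patient, imaging system, organ, observer) combination:
#' a superellipsoid truth mask with patient-specific size/position jitter, an
#' AI contour obtained by warping the truth with a smooth random displacement
#' field, and an observer-corrected contour whose disagreement with the AI
#' contour realises the Dice-scale linear model `y = beta0 + beta1 x +
#' u_patient + v_observer + eps` (approximately, through the per-organ
#' displacement calibration), plus a correction time and a 1-5 confidence
#' score. Identical config (including seed) gives bit-identical output.
#'
#' @param config a [cohort_config()].
#' @return object of class `delineation_cohort`: list with `records` (one
#'   entry per delineation; see Details), `scans` (the patient x system scan
#'   units), `config`, and the displacement `calibration` used.
#' @details Each record is a list with fields `patient_id`, `observer_id`,
#'   `imaging_system`, `organ`, `truth_mask`, `ai_mask`, `corrected_mask`
#'   ([binary_mask()] objects sharing one grid window), `correction_time_s`,
#'   `confidence`, `missing`. Masks are carried on a per-organ bounding
#'   window of the full grid (with background border) to keep large cohorts
#'   in memory; `origin_mm` locates the window in world coordinates.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_rng(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  gs <- config$grid_shape; sp <- config$spacing_mm
  grid_center <- gs * sp / 2
  organs <- config$organs; systems <- config$imaging_systems
  np <- config$n_patients; no <- config$n_observers
  pat_ids <- sprintf("p%02d", seq_len(np))
  obs_ids <- sprintf("obs%d", seq_len(no))
  defscale <- config$deformation_scale

  cal <- if (defscale > 0) calibrate_displacement(config) else NULL

  # observer effects, per organ (consistent across patients)
  v <- matrix(rnorm(no * length(organs), 0, sqrt(config$sigma2_observer)),
              no, length(organs), dimnames = list(obs_ids, organs))

  tm <- config$correction_time_model
  records <- vector("list", np * 2L * length(organs) * no)
  ridx <- 0L
  for (ip in seq_len(np)) {
    u_i <- rnorm(length(organs), 0, sqrt(config$sigma2_patient))
    for (io in seq_along(organs)) {
      org <- organs[io]
      g <- organ_geometry(org)
      center <- grid_center + g$offset +
        pmin(pmax(rnorm(3, 0, 3), -8), 8)               # position jitter
      semi <- g$semi * pmin(pmax(exp(rnorm(3, 0, 0.07)), 0.8), 1.25)  # size jitter

      excluded <- !is.null(config$exclude_bowel_patient) && org == "bowel" &&
        ip == config$exclude_bowel_patient

      # draw all model targets first so the window can cover the deformations
      eps <- matrix(rnorm(2L * no, 0, sqrt(config$sigma2_residual)), 2L, no)
      ai_modes <- vector("list", 2L); corr_modes <- vector("list", 2L)
      s_ai <- numeric(2L); s_corr <- matrix(0, 2L, no)
      for (is in 1:2) {
        t_pa <- config$beta0_dsc[io] + config$beta1_dsc[io] * (is - 1L) + u_i[io]
        ai_modes[[is]] <- draw_field_modes()
        cm <- vector("list", no)
        for (jo in seq_len(no)) cm[[jo]] <- draw_field_modes()
        corr_modes[[is]] <- cm
        if (defscale > 0) {
          s_pa <- scale_for_dsc(cal[[org]], min(t_pa, 0.995))
          s_ai[is] <- 0.75 * s_pa * defscale
          y <- pmin(pmax(t_pa + v[, io] + eps[is, ], 0.30), 0.995)
          s_tot <- scale_for_dsc(cal[[org]], y) * defscale
          s_corr[is, ] <- sqrt(pmax(s_tot^2 - s_ai[is]^2, (0.15 * s_tot)^2))
        }
      }

      max_scale <- max(s_ai, s_corr)
      required <- semi + 2 * sp
      if (any(center - required < 0) || any(center + required > gs * sp))
        stop(sprintf(paste0("grid too small to contain organ '%s' at the ",
                            "requested size (needs +/- %.0f mm around its center)"),
                     org, max(required)))
      win <- grid_window(center, semi + 3 * max_scale + 3 * sp, gs, sp)
      crd <- if (excluded) NULL else window_coords(win$axes)

      truth_vox <- if (excluded) NULL else
        build_organ_mask(crd, center, semi, g$exy, g$ez)
      truth <- if (excluded) NULL else binary_mask(truth_vox, sp, win$origin_mm)

      for (is in 1:2) {
        ai_vox <- if (excluded) NULL else if (s_ai[is] > 0)
          build_organ_mask(crd, center, semi, g$exy, g$ez,
                           ai_modes[[is]], s_ai[is]) else truth_vox
        ai <- if (excluded) NULL else binary_mask(ai_vox, sp, win$origin_mm)
        for (jo in seq_len(no)) {
          corr_vox <- if (excluded) NULL else if (s_corr[is, jo] > 0)
            build_organ_mask(crd, center, semi, g$exy, g$ez,
                             corr_modes[[is]][[jo]], s_corr[is, jo]) else truth_vox
          mean_s <- tm$organ_mean_s[io, is]; sd_s <- tm$organ_sd_s[io, is]
          if (sd_s > 0 && mean_s > 0) {
            sdlog <- sqrt(log(1 + (sd_s / mean_s)^2))
            time_s <- rlnorm(1, log(mean_s) - sdlog^2 / 2, sdlog)
          } else time_s <- mean_s
          conf <- sample.int(5L, 1L, prob = config$confidence_model[io, is, ])
          ridx <- ridx + 1L
          records[[ridx]] <- list(
            patient_id = pat_ids[ip], observer_id = obs_ids[jo],
            imaging_system = systems[is], organ = org,
            truth_mask = if (excluded) NULL else truth,
            ai_mask = if (excluded) NULL else ai,
            corrected_mask = if (excluded) NULL else
              binary_mask(corr_vox, sp, win$origin_mm),
            correction_time_s = if (excluded) NA_real_ else time_s,
            confidence = if (excluded) NA_integer_ else conf,
            missing = excluded)
        }
      }
    }
  }
  cohort <- structure(list(
    records = records,
    scans = expand.grid(patient_id = pat_ids, imaging_system = systems,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    config = config, calibration = cal), class = "delineation_cohort")
  if (config$outlier_scenario$enabled)
    cohort <- apply_outlier_scenario(cohort, config$outlier_scenario$patient)
  cohort
}

#' @export
print.delineation_cohort <- function(x, ...) {
  cat(sprintf("<delineation_cohort> %d records (%d patients x %d systems x %d organs x %d observers), %d scan units\n",
              length(x$records), x$config$n_patients, 2L,
              length(x$config$organs), x$config$n_observers, nrow(x$scans)))
  invisible(x)
}

#' Metadata table of a cohort
#' @param cohort a `delineation_cohort`.
#' @return `data.frame` with one row per delineation record (ids, correction
#'   time, confidence, missing flag).
#' @export
cohort_metadata <- function(cohort) {
  records <- if (inherits(cohort, "delineation_cohort")) cohort$records else cohort
  out <- do.call(rbind, lapply(records, function(r)
    data.frame(patient_id = r$patient_id, observer_id = r$observer_id,
               imaging_system = r$imaging_system, organ = r$organ,
               correction_time_s = r$correction_time_s,
               confidence = r$confidence, missing = isTRUE(r$missing),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Degrade one patient's conventional-arm bladder AI contour
#'
#' Emulates a failed acquisition on a heavy patient: the AI bladder contour in
#' the conventional arm is replaced by a small, grossly displaced sphere, so
#' that its agreement with the corrected contour drops below Dice 0.2 with an
#' HD95 above 60 mm. The high-performance arm and all other organs/patients
#' are untouched.
#'
#' @param cohort a `delineation_cohort`.
#' @param patient_index patient number to degrade (1-based).
#' @return the modified cohort.
#' @export
apply_outlier_scenario <- function(cohort, patient_index) {
  stopifnot(inherits(cohort, "delineation_cohort"))
  config <- cohort$config
  if (patient_index < 1L || patient_index > config$n_patients)
    stop("patient index out of range")
  pid <- sprintf("p%02d", patient_index)
  if (!"bladder" %in% config$organs) stop("cohort has no bladder organ")
  conv <- config$imaging_systems[2]
  idx <- which(vapply(cohort$records, function(r)
    r$patient_id == pid && r$organ == "bladder" && r$imaging_system == conv &&
      !isTRUE(r$missing), logical(1)))
  if (!length(idx)) stop("no conventional-arm bladder records for patient ", pid)

  gs <- config$grid_shape; sp <- config$spacing_mm
  r0 <- cohort$records[[idx[1]]]
  # centroid of the truth bladder, in world mm
  w <- which(r0$truth_mask$voxels, arr.ind = TRUE)
  centroid <- r0$truth_mask$origin_mm +
    (colMeans(w) - 1) * r0$truth_mask$spacing_mm
  disp <- c(0, 40, -70)  # inferior-posterior gross displacement
  radius <- 12
  target <- centroid + disp
  if (any(target - radius - 2 * sp < 0) || any(target + radius + 2 * sp > gs * sp))
    stop("grid too small to realize the 60 mm outlier separation for the bladder")

  # enlarge the record window to cover both the organ and the displaced sphere
  lo_mm <- pmin(r0$truth_mask$origin_mm, target - radius - 2 * sp)
  hi_mm <- pmax(r0$truth_mask$origin_mm +
                  (dim(r0$truth_mask$voxels) - 1) * sp, target + radius + 2 * sp)
  lo <- pmax(1L, floor(lo_mm / sp) + 1L); hi <- pmin(gs, ceiling(hi_mm / sp) + 1L)
  axes <- lapply(1:3, function(a) (seq(lo[a], hi[a]) - 1) * sp[a])
  origin <- (lo - 1L) * sp
  newdim <- hi - lo + 1L

  embed <- function(mask) {
    out <- array(FALSE, newdim)
    off <- round((mask$origin_mm - origin) / sp)
    d <- dim(mask$voxels)
    out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <-
      mask$voxels
    binary_mask(out, sp, origin)
  }
  X <- outer(outer(axes[[1]], rep(1, length(axes[[2]]))), rep(1, length(axes[[3]])))
  Y <- outer(outer(rep(1, length(axes[[1]])), axes[[2]]), rep(1, length(axes[[3]])))
  Z <- outer(outer(rep(1, length(axes[[1]])), rep(1, length(axes[[2]]))), axes[[3]])
  sphere <- binary_mask((X - target[1])^2 + (Y - target[2])^2 +
                          (Z - target[3])^2 <= radius^2, sp, origin)
  if (!any(sphere$voxels)) stop("displaced bladder sphere has no voxels on this grid")
  for (i in idx) {
    r <- cohort$records[[i]]
    r$truth_mask <- embed(r$truth_mask)
    r$corrected_mask <- embed(r$corrected_mask)
    r$ai_mask <- sphere
    cohort$records[[i]] <- r
  }
  cohort
}

#' Simulate a balanced metric table directly from the linear model
#'
#' Bypasses all geometry: draws `y_ijk = beta0 + beta1 x_k + u_i + v_j +
#' eps_ijk` with independent zero-mean Gaussian patient, observer and residual
#' effects, on the complete balanced design (every patient x observer x arm
#' cell once). `x` is coded 0 for the first arm (high-performance), 1 for the
#' second (conventional).
#'
#' @param beta0,beta1 intercept and imaging-system effect on the metric scale.
#' @param sigma2_patient,sigma2_observer,sigma2_residual variance components
#'   (>= 0).
#' @param n_patients,n_observers design size.
#' @param imaging_systems two arm labels.
#' @param seed optional seed (caller's RNG state is preserved).
#' @return `data.frame` with `patient_id`, `observer_id`, `imaging_system`,
#'   `x`, `value`.
#' @export
generate_metric_table <- function(beta0, beta1, sigma2_patient,
                                  sigma2_observer, sigma2_residual,
                                  n_patients = 20L, n_observers = 3L,
                                  imaging_systems = c("high_performance",
                                                      "conventional"),
                                  seed = NULL) {
  if (any(c(sigma2_patient, sigma2_observer, sigma2_residual) < 0))
    stop("variance components must be >= 0")
  if (n_patients < 2L || n_observers < 2L)
    stop("need at least 2 patients and 2 observers")
  with_rng(seed, {
    d <- expand.grid(patient_id = sprintf("p%04d", seq_len(n_patients)),
                     observer_id = sprintf("obs%d", seq_len(n_observers)),
                     imaging_system = imaging_systems,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d$x <- as.numeric(d$imaging_system == imaging_systems[2])
    u <- rnorm(n_patients, 0, sqrt(sigma2_patient))
    v <- rnorm(n_observers, 0, sqrt(sigma2_observer))
    ip <- as.integer(factor(d$patient_id, levels = unique(d$patient_id)))
    jo <- as.integer(factor(d$observer_id, levels = unique(d$observer_id)))
    d$value <- beta0 + beta1 * d$x + u[ip] + v[jo] +
      rnorm(nrow(d), 0, sqrt(sigma2_residual))
    d
  })
}
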