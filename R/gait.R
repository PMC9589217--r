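# Synthetic single-stance gait trials: forward-kinematics marker trajectories
# under template joint-angle curves plus seeded Gaussian noise, and a
# double-hump ground reaction force with anterior-posterior and mediolateral
# components and a progressing center of pressure. Marker rate 100 Hz, force
# plate rate 1000 Hz.

#' Specify a synthetic stance-phase gait trial
#'
#' @param mass subject mass (kg), default 80.
#' @param height subject height (m), default 1.75.
#' @param duration stance duration (s), default 0.65.
#' @param noise_sd marker noise standard deviation (mm), default 0.
#' @param seed integer seed for the marker noise.
#' @param template path to the template waveform YAML (angles, GRF shape).
#' @param grf_scale multiplier applied to the GRF waveform (1 = template).
#' @return a validated `gait_trial_spec`.
#' @export
gait_trial_spec <- function(mass = 80, height = 1.75, duration = 0.65,
                            noise_sd = 0, seed = 1L,
                            template = kneegait_extdata("gait_template.yaml"),
                            grf_scale = 1) {
  check_positive(mass, "mass"); check_positive(height, "height")
  check_positive(duration, "duration"); check_nonneg(noise_sd, "noise_sd")
  check_nonneg(grf_scale, "grf_scale")
  tpl <- yaml::read_yaml(template)
  vmax <- max(unlist(tpl$grf$vertical_bw$v)) * grf_scale
  if (vmax <= 0 || vmax >= 3) {
    stop("field 'grf peak' must lie in (0, 3) body weight")
  }
  structure(list(mass = mass, height = height, duration = duration,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 template = tpl, grf_scale = grf_scale),
            class = "gait_trial_spec")
}

# Spline interpolator over % stance for one template channel.
.tpl_fun <- function(ch) {
  stats::splinefun(ch$t, ch$v, method = "natural")
}

#' Template generalized coordinates at given % stance
#'
#' Evaluates the template joint-angle/pelvis curves (the generating truth of
#' the synthetic trial) at the requested stance fractions.
#'
#' @param spec a `gait_trial_spec`.
#' @param pct numeric vector of % stance values in [0, 100].
#' @param model linkage model (for the standing pelvis height).
#' @return matrix (length(pct) x 11) of generalized coordinates, columns as
#'   `model$dof_names`; angles in rad, translations in mm.
#' @export
template_coordinates <- function(spec, pct, model) {
  a <- spec$template$angles
  deg <- pi / 180
  pelvis_h <- model$segments$thigh$length + model$segments$shank$length +
    0.065 * model$height * 1000   # standing pelvis-origin height above ground
  q <- cbind(
    pelvis_tx = .tpl_fun(a$pelvis_tx)(pct),
    pelvis_ty = pelvis_h + .tpl_fun(a$pelvis_ty)(pct),
    pelvis_tz = .tpl_fun(a$pelvis_tz)(pct),
    pelvis_rx = .tpl_fun(a$pelvis_rx)(pct) * deg,
    pelvis_ry = .tpl_fun(a$pelvis_ry)(pct) * deg,
    pelvis_rz = .tpl_fun(a$pelvis_rz)(pct) * deg,
    hip_flex = .tpl_fun(a$hip_flex)(pct) * deg,
    hip_add = .tpl_fun(a$hip_add)(pct) * deg,
    hip_rot = .tpl_fun(a$hip_rot)(pct) * deg,
    knee_flex = .tpl_fun(a$knee_flex)(pct) * deg,
    ankle_flex = .tpl_fun(a$ankle_flex)(pct) * deg)
  q
}

#' Generate a synthetic stance-phase gait trial
#'
#' Marker trajectories are produced by forward kinematics of the linkage under
#' the template coordinate curves plus seeded Gaussian noise; the ground
#' reaction force is the template double-hump waveform scaled by body weight,
#' with the center of pressure progressing heel to toe in the foot frame.
#'
#' @param spec a `gait_trial_spec`.
#' @param model a `linkage_model`; defaults to one scaled from the spec's
#'   subject mass and height.
#' @return a `gait_trial`: marker array (`frames x markers x 3`, mm, 100 Hz),
#'   GRF data frame (1000 Hz; forces N, COP mm, world frame), the generating
#'   template coordinates, and the spec.
#' @export
generate_gait_trial <- function(spec, model = default_linkage(spec$mass, spec$height)) {
  stopifnot(inherits(spec, "gait_trial_spec"))
  dt_m <- 0.01; dt_f <- 0.001
  t_m <- seq(0, spec$duration, by = dt_m)
  t_f <- seq(0, spec$duration, by = dt_f)
  pct_m <- 100 * t_m / spec$duration
  pct_f <- 100 * t_f / spec$duration

  q <- template_coordinates(spec, pct_m, model)
  nm <- length(model$markers)
  markers <- array(NA_real_, dim = c(length(t_m), nm, 3),
                   dimnames = list(NULL, names(model$markers), c("X", "Y", "Z")))
  for (i in seq_along(t_m)) {
    markers[i, , ] <- marker_positions(q[i, ], model)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    markers <- markers + array(stats::rnorm(length(markers), 0, spec$noise_sd),
                               dim = dim(markers))
  }

  g <- spec$template$grf
  bw <- spec$mass * GRAVITY
  sc <- spec$grf_scale
  fy <- pmax(.tpl_fun(g$vertical_bw)(pct_f), 0) * bw * sc
  fx <- .tpl_fun(g$anterior_bw)(pct_f) * bw * sc
  fz <- .tpl_fun(g$lateral_bw)(pct_f) * bw * sc
  # COP: foot-local path mapped through the (noise-free) foot pose at ground level
  cop <- matrix(NA_real_, length(t_f), 2)
  q_f <- template_coordinates(spec, pct_f, model)
  cop_loc_x <- .tpl_fun(g$cop_x_mm)(pct_f)
  cop_loc_z <- .tpl_fun(g$cop_z_mm)(pct_f)
  for (i in seq_along(t_f)) {
    fk <- forward_kinematics(q_f[i, ], model)
    p <- apply_transform(fk$foot, c(cop_loc_x[i], 0, cop_loc_z[i]))[1, ]
    cop[i, ] <- p[c(1, 3)]
  }
  grf <- data.frame(time = t_f, fx = fx, fy = fy, fz = fz,
                    copx = cop[, 1], copz = cop[, 2])

  structure(list(time = t_m, markers = markers, grf = grf,
                 template_q = q, spec = spec),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("Synthetic stance-phase gait trial\n")
  cat(sprintf("  %.0f ms stance, %d marker frames (100 Hz), %d GRF samples (1000 Hz)\n",
              1000 * x$spec$duration, length(x$time), nrow(x$grf)))
  cat(sprintf("  subject %.0f kg / %.2f m, marker noise SD %.2f mm (seed %d)\n",
              x$spec$mass, x$spec$height, x$spec$noise_sd, x$spec$seed))
  cat(sprintf("  vertical GRF peak %.2f BW\n",
              max(x$grf$fy) / (x$spec$mass * GRAVITY)))
  invisible(x)
}

#' Resample the ground reaction force to the marker rate
#'
#' Anti-alias low-pass filters the 1000 Hz force-plate channels (2nd-order
#' Butterworth, zero-phase) and decimates to the 100 Hz marker time base.
#'
#' @param trial a `gait_trial`.
#' @param cutoff_hz filter cutoff (Hz), default 30.
#' @return data frame at marker rate with the same columns as `trial$grf`.
#' @export
grf_at_marker_rate <- function(trial, cutoff_hz = 30) {
  grf <- trial$grf
  bf <- signal::butter(2, cutoff_hz / (0.5 / diff(grf$time[1:2])), type = "low")
  sm <- grf
  for (cl in c("fx", "fy", "fz", "copx", "copz")) {
    sm[[cl]] <- .lowpass(grf[[cl]], bf, pad = 200)
  }
  idx <- vapply(trial$time, function(t) which.min(abs(grf$time - t)), integer(1))
  out <- sm[idx, ]
  out$time <- trial$time
  rownames(out) <- NULL
  out
}

#' Write a gait trial to plain-text CSV files
#'
#' Writes `markers.csv` (wide: time then `NAME_X/Y/Z` in mm) and `grf.csv`
#' (time, forces in N, COP in mm).
#'
#' @param trial a `gait_trial`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nm <- dimnames(trial$markers)[[2]]
  wide <- data.frame(time = trial$time)
  for (j in seq_along(nm)) {
    for (k in 1:3) {
      wide[[paste0(nm[j], "_", c("X", "Y", "Z")[k])]] <- trial$markers[, j, k]
    }
  }
  f1 <- file.path(dir, "markers.csv"); f2 <- file.path(dir, "grf.csv")
  utils::write.csv(wide, f1, row.names = FALSE)
  utils::write.csv(trial$grf, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' Read a gait trial from CSV files written by [write_trial_csv()]
#'
#' @param dir directory containing `markers.csv` and `grf.csv`.
#' @param spec optional `gait_trial_spec` to attach (subject mass is needed
#'   for body-weight normalization downstream).
#' @return a `gait_trial` (without the generating template coordinates).
#' @export
read_trial_csv <- function(dir, spec = gait_trial_spec()) {
  wide <- utils::read.csv(file.path(dir, "markers.csv"))
  grf <- utils::read.csv(file.path(dir, "grf.csv"))
  cn <- setdiff(names(wide), "time")
  nm <- unique(sub("_[XYZ]$", "", cn))
  markers <- array(NA_real_, dim = c(nrow(wide), length(nm), 3),
                   dimnames = list(NULL, nm, c("X", "Y", "Z")))
  for (j in seq_along(nm)) {
    for (k in 1:3) {
      markers[, j, k] <- wide[[paste0(nm[j], "_", c("X", "Y", "Z")[k])]]
    }
  }
  structure(list(time = wide$time, markers = markers, grf = grf,
                 template_q = NULL, spec = spec), class = "gait_trial")
}
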