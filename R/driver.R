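# Orchestration: the concurrent loop (inverse kinematics -> inverse dynamics
# -> cubed-activation static optimization -> deformable contact solve, with
# knee secondary kinematics fed back into the musculoskeletal stage) at the
# 16 stance time points, the experiment matrix over meniscal variants, and
# file reporting.

#' Simulation configuration
#'
#' @param time_pct stance-phase evaluation grid (% stance); default the 16
#'   evenly distributed points 0, 6.67, ..., 100.
#' @param outer_max maximum concurrent-loop iterations per time point.
#' @param moment_tol convergence tolerance on the change in knee
#'   flexion-extension moment between outer iterations (N mm).
#' @param contact contact solver settings.
#' @param seed seed for the synthetic trial.
#' @param noise_sd marker noise SD (mm) for the synthetic trial.
#' @param geometry knee geometry spec.
#' @param variants named list of `tear_spec`s for [run_experiment_matrix()];
#'   default the 11-variant study set (intact + 9 tears + meniscectomy).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(time_pct = seq(0, 100, length.out = 16),
                              outer_max = 10, moment_tol = 500,
                              contact = contact_settings(),
                              seed = 1L, noise_sd = 0,
                              geometry = knee_geometry_spec(),
                              variants = NULL) {
  stopifnot(all(diff(time_pct) > 0), time_pct[1] >= 0,
            time_pct[length(time_pct)] <= 100, moment_tol > 0)
  if (is.null(variants)) {
    variants <- list(intact = NULL)
    for (loc in c("anterior_horn", "midbody", "posterior_horn")) {
      for (w in c(0.33, 0.50, 0.83)) {
        variants[[sprintf("%s_%02d", loc, round(100 * w))]] <- tear_spec(loc, w)
      }
    }
    variants$meniscectomy <- tear_spec(total_meniscectomy = TRUE)
  }
  structure(list(time_pct = time_pct, outer_max = outer_max,
                 moment_tol = moment_tol, contact = contact, seed = seed,
                 noise_sd = noise_sd, geometry = geometry,
                 variants = variants),
            class = "simulation_config")
}

# Musculoskeletal inputs shared by every variant of a matrix run.
.prepare_msk <- function(config, trial = NULL, linkage = NULL, muscles = NULL) {
  if (is.null(linkage)) linkage <- default_linkage()
  if (is.null(trial)) {
    trial <- generate_gait_trial(
      gait_trial_spec(noise_sd = config$noise_sd, seed = config$seed), linkage)
  }
  if (is.null(muscles)) muscles <- load_muscle_set(linkage)
  states <- inverse_kinematics(trial, linkage)
  list(trial = trial, linkage = linkage, muscles = muscles, states = states)
}

# Safe lookup in a named numeric vector (absent pair -> 0).
.force_of <- function(x, nm) {
  if (!is.null(x) && nm %in% names(x)) x[[nm]] else 0
}

# Applied tibiofemoral wrench (on the tibia, plateau frame, about the
# condylar axis point) at frame i: intersegmental load minus knee-crossing
# muscle forces.
.knee_wrench <- function(loads, i, fk, geom, forces, a_c) {
  F_w <- c(loads$F_knee_x[i], loads$F_knee_y[i], loads$F_knee_z[i])
  M_w <- c(loads$M_knee_x[i], loads$M_knee_y[i], loads$M_knee_z[i])
  for (mn in names(geom$knee_lines)) {
    kl <- geom$knee_lines[[mn]]
    fvec <- forces[[mn]] * kl$dir
    F_w <- F_w - fvec
    M_w <- M_w - cross3(kl$point - fk$knee, fvec)
  }
  Rt <- t(fk$shank$R)
  list(F = drop(Rt %*% F_w), M = drop(Rt %*% M_w))  # about knee centre = a_c
}

#' Run the concurrent stance analysis for one knee variant
#'
#' Per stance time point, iterates inverse dynamics (with the current knee
#' secondary kinematics), cubed-activation static optimization, and the
#' deformable contact solve until the knee flexion-extension moment changes
#' by less than `config$moment_tol` between iterations; each time point is
#' warm-started from the previous one. With `freeze_feedback = TRUE` the
#' secondary kinematics are never fed back (single-pass, non-concurrent
#' pipeline) for ablation comparisons.
#'
#' @param model a `knee_model` variant.
#' @param config a `simulation_config`.
#' @param msk shared musculoskeletal inputs from an internal preparation step
#'   (trial, linkage, muscle set, IK states); built on demand when NULL.
#' @param freeze_feedback disable the secondary-kinematics feedback.
#' @param warm optional previous `stance_solution` of another variant solved
#'   under the same inputs (e.g. the intact knee); used to warm-start each
#'   time point.
#' @param verbose print per-point progress.
#' @return a `stance_solution`: per-point data frame `summary`, lists of
#'   `activations`, `contacts`, `stress` (medial meniscus fields), the
#'   convergence history and the inputs used.
#' @export
run_stance <- function(model, config = simulation_config(), msk = NULL,
                       freeze_feedback = FALSE, warm = NULL, verbose = FALSE) {
  if (is.null(msk)) msk <- .prepare_msk(config)
  trial <- msk$trial; linkage <- msk$linkage; muscles <- msk$muscles
  states <- msk$states
  system <- contact_system(model, config$contact)
  a_c <- system$a_c
  bw <- trial$spec$mass * GRAVITY
  npt <- length(config$time_pct)
  idx <- vapply(config$time_pct, function(p) which.min(abs(states$pct - p)),
                integer(1))

  base_loads <- inverse_dynamics(states, trial, linkage)
  nf <- nrow(states)

  es <- rep(0, 5)
  state0 <- NULL
  contacts <- list(); acts <- list(); stress <- list()
  rows <- list(); histories <- list()
  for (t in seq_len(npt)) {
    i <- idx[t]
    qi <- as.numeric(states[i, linkage$dof_names])
    es_t <- if (!is.null(warm)) warm$es[t, ] else es
    st0 <- if (!is.null(warm)) warm$contacts[[t]]$u else state0
    loads_i <- base_loads
    outer <- 0L; dM <- Inf
    # a variant warm-started from another solution of the same inputs can
    # test the moment-stability criterion against that solution's moment
    M_prev <- if (!is.null(warm)) warm$summary$tau_knee_flex[t] else NA_real_
    res <- NULL; sol <- NULL
    mom_hist <- numeric(0)
    repeat {
      outer <- outer + 1L
      es_mat <- if (freeze_feedback) NULL else
        matrix(rep(es_t, each = nf), nf, 5)
      loads_i <- inverse_dynamics(states, trial, linkage, es = es_mat)
      geom <- compute_muscle_geometry(qi, linkage, muscles,
                                      es = if (freeze_feedback) rep(0, 5) else es_t)
      mom <- c(hip_flex = loads_i$tau_hip_flex[i],
               hip_add = loads_i$tau_hip_add[i],
               hip_rot = loads_i$tau_hip_rot[i],
               knee_flex = loads_i$tau_knee_flex[i],
               ankle_flex = loads_i$tau_ankle_flex[i])
      sol <- solve_static_optimization(mom, geom, muscles)
      fk <- forward_kinematics(qi, linkage,
                               es = if (freeze_feedback) rep(0, 5) else es_t)
      W <- .knee_wrench(loads_i, i, fk, geom, sol$forces, a_c)
      res <- solve_contact(model, flexion = qi[10], W_target = W,
                           system = system, settings = config$contact,
                           es0 = es_t, state0 = st0, bw = bw)
      mom_hist <- c(mom_hist, mom[["knee_flex"]])
      dM <- if (is.na(M_prev)) Inf else abs(mom[["knee_flex"]] - M_prev)
      M_prev <- mom[["knee_flex"]]
      es_new <- res$es
      d_es <- vnorm(es_new - es_t)
      es_t <- es_new; st0 <- res$u
      if (freeze_feedback) break
      if (dM < config$moment_tol || outer >= config$outer_max) break
    }
    es <- es_t; state0 <- res$u
    contacts[[t]] <- res; acts[[t]] <- sol
    sf <- if (!is.null(model$bodies$medial_meniscus)) {
      meniscus_stress(model, res, "medial_meniscus")
    } else NULL
    stress[t] <- list(sf)   # keep NULL entries (meniscectomy has no field)
    tip <- model$tear_tip$medial_meniscus
    tipstat <- if (!is.null(sf) && length(tip)) tag_tear_tip_stress(sf, tip)
      else list(max = NA_real_, mean = NA_real_)
    rows[[t]] <- data.frame(
      pct = config$time_pct[t], frame = i,
      knee_flex = qi[10],
      es_tx = es_t[1], es_ty = es_t[2], es_tz = es_t[3],
      es_rx = es_t[4], es_ry = es_t[5],
      tau_knee_flex = M_prev,
      outer_iterations = outer, converged = res$converged,
      moment_delta = dM,
      medial_meniscus_force = .force_of(res$forces, "femoral_cartilage-medial_meniscus"),
      medial_cartilage_force = .force_of(res$forces, "femoral_cartilage-medial_tibial_cartilage"),
      lateral_meniscus_force = .force_of(res$forces, "femoral_cartilage-lateral_meniscus"),
      lateral_cartilage_force = .force_of(res$forces, "femoral_cartilage-lateral_tibial_cartilage"),
      medial_ratio = if (is.null(res$medial_ratio)) NA_real_ else res$medial_ratio,
      peak_pressure_medial = max(.force_of(res$pressures, "femoral_cartilage-medial_meniscus"),
                                 .force_of(res$pressures, "femoral_cartilage-medial_tibial_cartilage")),
      pressure_medial_cartilage = .force_of(res$pressures, "femoral_cartilage-medial_tibial_cartilage"),
      tip_max_shear = tipstat$max, tip_mean_shear = tipstat$mean,
      objective = sol$objective, statopt_feasible = sol$feasible,
      max_activation = max(sol$activations))
    histories[[t]] <- mom_hist
    if (verbose) {
      cat(sprintf("  pct %5.1f: outer %d (dM %.1f N mm), contact %s, ratio %s\n",
                  config$time_pct[t], outer, dM,
                  res$converged, signif(res$medial_ratio, 3)))
    }
  }
  summary <- do.call(rbind, rows)
  summary$medial_meniscus_force_bw <- summary$medial_meniscus_force / bw
  summary$medial_cartilage_force_bw <- summary$medial_cartilage_force / bw
  structure(list(summary = summary, contacts = contacts,
                 activations = acts, stress = stress,
                 es = as.matrix(summary[, c("es_tx", "es_ty", "es_tz",
                                            "es_rx", "es_ry")]),
                 moment_histories = histories,
                 variant = model$variant, model = model,
                 config = config, bw = bw),
            class = "stance_solution")
}

#' @export
print.stance_solution <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Stance solution (%s): %d time points, %d converged\n",
              x$variant, nrow(s), sum(s$converged)))
  cat(sprintf("  outer iterations: %s; max |dM| at exit %.1f N mm\n",
              paste(range(s$outer_iterations), collapse = "-"),
              max(s$moment_delta[is.finite(s$moment_delta)])))
  cat(sprintf("  peak medial forces: meniscus %.2f BW, cartilage direct %.2f BW\n",
              max(s$medial_meniscus_force_bw), max(s$medial_cartilage_force_bw)))
  if (any(is.finite(s$medial_ratio))) {
    cat(sprintf("  medial meniscal load share: mean %.2f over loaded points\n",
                mean(s$medial_ratio[is.finite(s$medial_ratio)])))
  }
  invisible(x)
}

#' Grid indices of the two vertical-GRF peaks
#'
#' Maximum weight acceptance and push-off: the two local maxima of the
#' vertical ground reaction force, mapped to the nearest stance grid points.
#'
#' @param trial a `gait_trial`.
#' @param time_pct stance grid (% stance).
#' @return integer vector of length 2 (grid indices).
#' @export
grf_peak_points <- function(trial, time_pct = seq(0, 100, length.out = 16)) {
  fy <- trial$grf$fy
  pct <- 100 * trial$grf$time / max(trial$grf$time)
  half <- pct <= 50
  p1 <- pct[half][which.max(fy[half])]
  p2 <- pct[!half][which.max(fy[!half])]
  c(which.min(abs(time_pct - p1)), which.min(abs(time_pct - p2)))
}

#' Run the full experiment matrix
#'
#' Runs every variant of `config$variants` (default: intact, nine radial
#' tears, total meniscectomy) under identical marker and ground-reaction
#' inputs, and assembles aligned comparison series: tear-tip maximum shear
#' (with the matched-location intact baseline), medial cartilage force (BW),
#' meniscal load share, and peak pressures at the two GRF-peak time points,
#' plus percentage changes versus intact.
#'
#' @param config a `simulation_config`.
#' @param verbose print per-variant progress.
#' @return an `experiment_matrix` list: `solutions` (per variant),
#'   `comparison` (long data frame), `peaks` (grid indices of the GRF peaks),
#'   `percent_change` and `failed` (variants excluded, with errors).
#' @export
run_experiment_matrix <- function(config = simulation_config(),
                                  verbose = FALSE) {
  msk <- .prepare_msk(config)
  intact_model <- build_knee_geometry(config$geometry)
  peaks <- grf_peak_points(msk$trial, config$time_pct)

  solutions <- list(); failed <- list()
  intact_sol <- NULL
  for (vn in names(config$variants)) {
    model <- if (is.null(config$variants[[vn]])) intact_model
      else apply_radial_tear(intact_model, config$variants[[vn]])
    if (verbose) cat(sprintf("variant %s ...\n", vn))
    sol <- tryCatch(
      run_stance(model, config, msk = msk,
                 warm = if (vn != "intact") intact_sol else NULL,
                 verbose = FALSE),
      error = function(e) e)
    if (inherits(sol, "error")) {
      failed[[vn]] <- conditionMessage(sol)
      next
    }
    solutions[[vn]] <- sol
    if (vn == "intact") intact_sol <- sol
  }
  if (length(solutions) == 0) stop("every variant failed")

  comparison <- NULL
  for (vn in names(solutions)) {
    s <- solutions[[vn]]$summary
    cmp <- data.frame(variant = vn, pct = s$pct,
                      tip_max_shear = s$tip_max_shear,
                      medial_cartilage_force_bw = s$medial_cartilage_force_bw,
                      medial_meniscus_force_bw = s$medial_meniscus_force_bw,
                      medial_ratio = s$medial_ratio,
                      peak_pressure_medial = s$peak_pressure_medial,
                      pressure_medial_cartilage = s$pressure_medial_cartilage,
                      converged = s$converged)
    # matched-location intact tear-tip series for torn variants
    if (vn != "intact" && !is.null(config$variants[[vn]]) &&
        !config$variants[[vn]]$total_meniscectomy && !is.null(intact_sol)) {
      tipm <- matched_tip_elements(intact_model, config$variants[[vn]])
      cmp$intact_tip_max_shear <- vapply(intact_sol$stress, function(sf)
        tag_tear_tip_stress(sf, tipm)$max, numeric(1))
    } else {
      cmp$intact_tip_max_shear <- NA_real_
    }
    comparison <- rbind(comparison, cmp)
  }

  pc <- NULL
  if (!is.null(intact_sol)) {
    ref <- intact_sol$summary
    for (vn in setdiff(names(solutions), "intact")) {
      s <- solutions[[vn]]$summary
      loaded <- ref$medial_cartilage_force + ref$medial_meniscus_force > 1
      pc <- rbind(pc, data.frame(
        variant = vn,
        d_cartilage_force_pct = 100 *
          (max(s$medial_cartilage_force) - max(ref$medial_cartilage_force)) /
          max(max(ref$medial_cartilage_force), 1e-9),
        d_peak_pressure_wa_pct = 100 *
          (s$pressure_medial_cartilage[peaks[1]] -
             ref$pressure_medial_cartilage[peaks[1]]) /
          max(ref$pressure_medial_cartilage[peaks[1]], 1e-9),
        mean_ratio = mean(s$medial_ratio[is.finite(s$medial_ratio)])))
    }
  }
  structure(list(solutions = solutions, comparison = comparison,
                 peaks = peaks, percent_change = pc, failed = failed,
                 config = config, trial = msk$trial),
            class = "experiment_matrix")
}

#' @export
print.experiment_matrix <- function(x, ...) {
  cat(sprintf("Experiment matrix: %d variants (%d failed); GRF peaks at grid points %d and %d\n",
              length(x$solutions), length(x$failed), x$peaks[1], x$peaks[2]))
  if (!is.null(x$percent_change)) {
    cat("  peak medial cartilage force change vs intact (%):\n")
    for (r in seq_len(nrow(x$percent_change))) {
      cat(sprintf("    %-18s %+7.1f\n", x$percent_change$variant[r],
                  x$percent_change$d_cartilage_force_pct[r]))
    }
  }
  invisible(x)
}

# Deterministic fixed-format CSV writer (byte-identical across identical runs).
.write_csv_fixed <- function(df, path, digits = 10) {
  out <- df
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- formatC(out[[cl]], digits = digits,
                                                    format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write report files for a matrix (or single stance) run
#'
#' Writes per-variant summary CSVs, the aligned comparison CSV, VTK stress
#' fields at the two GRF-peak time points, and a plain-text run report
#' (configuration hash, package version, convergence and invariant-check
#' outcomes). Re-running on the same results produces identical files.
#'
#' @param result an `experiment_matrix` or `stance_solution`.
#' @param dir output directory.
#' @return invisibly, the report file path.
#' @export
report <- function(result, dir) {
  if (inherits(result, "stance_solution")) {
    result <- structure(list(solutions = stats::setNames(list(result),
                                                         result$variant),
                             comparison = NULL, peaks = c(1L, 1L),
                             percent_change = NULL, failed = list(),
                             config = result$config, trial = NULL),
                        class = "experiment_matrix")
  }
  if (length(result$solutions) == 0) stop("no completed runs to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (vn in names(result$solutions)) {
    .write_csv_fixed(result$solutions[[vn]]$summary,
                     file.path(dir, sprintf("summary_%s.csv", vn)))
  }
  if (!is.null(result$comparison)) {
    .write_csv_fixed(result$comparison, file.path(dir, "comparison.csv"))
  }
  if (!is.null(result$percent_change)) {
    .write_csv_fixed(result$percent_change, file.path(dir, "percent_change.csv"))
  }
  # VTK fields at the GRF-peak points for each variant with a medial meniscus
  for (vn in names(result$solutions)) {
    sol <- result$solutions[[vn]]
    for (pk in unique(result$peaks)) {
      sf <- sol$stress[[pk]]
      if (is.null(sf)) next
      write_vtk_model(sol$model,
                      file.path(dir, sprintf("stress_%s_p%02d.vtk", vn, pk)),
                      cell_fields = list(
                        max_shear = list(medial_meniscus = sf$max_shear),
                        sigma_cc = list(medial_meniscus = sf$sigma_cc)))
    }
  }
  cfg_txt <- paste(utils::capture.output(utils::str(result$config)), collapse = "\n")
  tf <- tempfile(); writeLines(cfg_txt, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  rep_path <- file.path(dir, "run_report.txt")
  lines <- c(
    "kneegait run report",
    sprintf("package version: %s", as.character(utils::packageVersion("kneegait"))),
    sprintf("config md5: %s", hash),
    sprintf("variants completed: %s", paste(names(result$solutions), collapse = ", ")),
    sprintf("variants failed: %s",
            if (length(result$failed)) paste(names(result$failed), collapse = ", ")
            else "none"),
    "convergence:")
  for (vn in names(result$solutions)) {
    s <- result$solutions[[vn]]$summary
    lines <- c(lines, sprintf("  %-18s %d/%d contact-converged, outer its %s",
                              vn, sum(s$converged), nrow(s),
                              paste(range(s$outer_iterations), collapse = "-")))
  }
  writeLines(lines, rep_path)
  invisible(rep_path)
}
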