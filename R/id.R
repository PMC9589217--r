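# Inverse dynamics: bottom-up Newton-Euler recursion (foot -> shank -> thigh)
# driven by the primary joint-angle series and the marker-rate ground reaction
# force. Segment kinematics are differentiated by central differences after
# zero-phase low-pass filtering (2nd-order Butterworth, default 6 Hz cutoff).

#' Inverse dynamics of a stance trial
#'
#' Computes net intersegmental joint forces and moments at the ankle, knee and
#' hip, plus the generalized joint torques about the primary DOF axes used by
#' the static optimization.
#'
#' @param states a `joint_state_series` from [inverse_kinematics()] (or a
#'   matrix/data frame with the 11 coordinate columns plus `time`).
#' @param trial the `gait_trial` providing the ground reaction force.
#' @param model a `linkage_model`.
#' @param cutoff_hz low-pass cutoff for coordinate smoothing (Hz); `NA`
#'   disables filtering.
#' @param es optional n x 5 matrix of knee secondary kinematics applied frame
#'   by frame (default zeros); shifts the knee center used for the knee moment.
#' @return a `joint_loads` data frame per frame: joint force and moment
#'   vectors (N, N mm, world frame, action of the proximal on the distal
#'   segment at the joint center) and generalized torques `tau_hip_flex`,
#'   `tau_hip_add`, `tau_hip_rot`, `tau_knee_flex`, `tau_ankle_flex` (N mm).
#' @export
inverse_dynamics <- function(states, trial, model, cutoff_hz = 6, es = NULL) {
  tm <- states$time
  if (is.unsorted(tm, strictly = TRUE)) stop("non-monotone time stamps")
  nf <- length(tm)
  dt <- diff(tm[1:2])
  qm <- as.matrix(states[, model$dof_names])
  if (!is.na(cutoff_hz) && nf > 12) {
    bf <- signal::butter(2, cutoff_hz * 2 * dt, type = "low")
    qm <- apply(qm, 2, .lowpass, bf = bf)
  }
  if (is.null(es)) es <- matrix(0, nf, 5)

  grf <- grf_at_marker_rate(trial)
  if (nrow(grf) != nf) stop("time-base mismatch between states and GRF")

  # world kinematics per frame
  fks <- lapply(seq_len(nf), function(i) forward_kinematics(qm[i, ], model, es[i, ]))
  segs <- c("foot", "shank", "thigh")
  com_w <- lapply(segs, function(s) {
    t(vapply(fks, function(fk) apply_transform(fk[[s]], model$segments[[s]]$com)[1, ],
             numeric(3))) / 1000   # m
  })
  names(com_w) <- segs
  Rws <- lapply(segs, function(s) lapply(fks, function(fk) fk[[s]]$R))
  names(Rws) <- segs

  acc <- lapply(com_w, function(p) .central_diff2(p, dt))
  angvel <- lapply(Rws, function(Rl) .angular_velocity(Rl, dt))
  angacc <- lapply(angvel, function(w) .central_diff1(w, dt))

  g_vec <- c(0, -GRAVITY, 0)
  out <- data.frame(time = tm, pct = 100 * tm / max(tm))
  force_cols <- list(); moment_cols <- list()
  tau <- matrix(0, nf, 5, dimnames = list(NULL, c(
    "tau_hip_flex", "tau_hip_add", "tau_hip_rot", "tau_knee_flex",
    "tau_ankle_flex")))
  F_jt <- array(0, c(nf, 3, 3), dimnames = list(NULL, c("ankle", "knee", "hip"), NULL))
  M_jt <- array(0, c(nf, 3, 3), dimnames = list(NULL, c("ankle", "knee", "hip"), NULL))

  for (i in seq_len(nf)) {
    fk <- fks[[i]]
    joints_m <- list(ankle = fk$ankle / 1000, knee = fk$knee / 1000,
                     hip = fk$hip / 1000)
    F_ext <- c(grf$fx[i], grf$fy[i], grf$fz[i])
    cop_m <- c(grf$copx[i], 0, grf$copz[i]) / 1000
    F_dist <- F_ext; r_dist <- cop_m; M_dist <- c(0, 0, 0)
    for (k in seq_along(segs)) {
      s <- segs[k]
      jname <- c("ankle", "knee", "hip")[k]
      m <- model$segments[[s]]$mass
      Iw <- Rws[[s]][[i]] %*% (model$segments[[s]]$inertia * 1e-6) %*% t(Rws[[s]][[i]])
      a <- acc[[s]][i, ]; w <- angvel[[s]][i, ]; al <- angacc[[s]][i, ]
      r_com <- com_w[[s]][i, ]
      r_j <- joints_m[[jname]]
      # force balance: F_joint + F_dist + m g = m a
      F_j <- m * a - m * g_vec - F_dist
      # moment balance about the COM
      M_j <- drop(Iw %*% al) + cross3(w, drop(Iw %*% w)) -
        M_dist - cross3(r_dist - r_com, F_dist) - cross3(r_j - r_com, F_j)
      F_jt[i, jname, ] <- F_j
      M_jt[i, jname, ] <- M_j * 1000   # N m -> N mm
      # pass the reaction up to the next segment
      F_dist <- -F_j; r_dist <- r_j; M_dist <- -M_j
    }
    # generalized torque projections onto the instantaneous DOF axes
    Rp <- fk$pelvis$R
    a_hf <- drop(Rp %*% c(0, 0, 1))
    a_ha <- drop(Rp %*% rot_z(qm[i, "hip_flex"]) %*% c(1, 0, 0))
    a_hr <- drop(Rp %*% rot_z(qm[i, "hip_flex"]) %*% rot_x(qm[i, "hip_add"]) %*% c(0, 1, 0))
    a_kf <- drop(fk$thigh$R %*% c(0, 0, -1))   # knee flexion about -Z of thigh
    a_af <- drop(fk$shank$R %*% c(0, 0, 1))
    tau[i, ] <- c(sum(M_jt[i, "hip", ] * a_hf), sum(M_jt[i, "hip", ] * a_ha),
                  sum(M_jt[i, "hip", ] * a_hr), sum(M_jt[i, "knee", ] * a_kf),
                  sum(M_jt[i, "ankle", ] * a_af))
  }

  for (j in c("ankle", "knee", "hip")) {
    for (k in 1:3) {
      out[[paste0("F_", j, "_", c("x", "y", "z")[k])]] <- F_jt[, j, k]
      out[[paste0("M_", j, "_", c("x", "y", "z")[k])]] <- M_jt[, j, k]
    }
  }
  out <- cbind(out, as.data.frame(tau))
  out$grf_fx <- grf$fx; out$grf_fy <- grf$fy; out$grf_fz <- grf$fz
  out$grf_copx <- grf$copx; out$grf_copz <- grf$copz
  class(out) <- c("joint_loads", "data.frame")
  out
}

# zero-phase Butterworth low-pass with odd-reflection end padding (avoids the
# large filtfilt edge transients on short stance records)
.lowpass <- function(x, bf, pad = 30) {
  n <- length(x)
  p <- min(pad, n - 1)
  head_pad <- 2 * x[1] - x[(p + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
  y[(p + 1):(p + n)]
}

# second derivative by central differences, one-sided at the ends
.central_diff2 <- function(p, dt) {
  n <- nrow(p)
  a <- matrix(0, n, ncol(p))
  if (n >= 3) {
    a[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - 2 * p[2:(n - 1), , drop = FALSE] +
                         p[1:(n - 2), , drop = FALSE]) / dt^2
    a[1, ] <- a[2, ]; a[n, ] <- a[n - 1, ]
  }
  a
}

.central_diff1 <- function(p, dt) {
  n <- nrow(p)
  v <- matrix(0, n, ncol(p))
  if (n >= 3) {
    v[2:(n - 1), ] <- (p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]) / (2 * dt)
    v[1, ] <- v[2, ]; v[n, ] <- v[n - 1, ]
  }
  v
}

# angular velocity from a rotation-matrix series: vee(Rdot R^T)
.angular_velocity <- function(Rl, dt) {
  n <- length(Rl)
  w <- matrix(0, n, 3)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      Rd <- (Rl[[i + 1]] - Rl[[i - 1]]) / (2 * dt)
      W <- Rd %*% t(Rl[[i]])
      w[i, ] <- c(W[3, 2] - W[2, 3], W[1, 3] - W[3, 1], W[2, 1] - W[1, 2]) / 2
    }
    w[1, ] <- w[2, ]; w[n, ] <- w[n - 1, ]
  }
  w
}
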