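# Inverse kinematics: per-frame weighted least-squares fit of the 11 primary
# generalized coordinates to marker positions (Levenberg-Marquardt
# Gauss-Newton). Secondary knee kinematics are not tracked from markers.

#' Inverse kinematics of a gait trial
#'
#' Per frame, minimizes the weighted sum of squared marker residuals over the
#' primary degrees of freedom (pelvis 6, hip 3, knee flexion, ankle flexion).
#' Frames with missing markers are gap-interpolated linearly up to `max_gap`
#' consecutive frames; longer gaps are an error.
#'
#' @param trial a `gait_trial`.
#' @param model a `linkage_model`.
#' @param weights optional per-marker weights (default 1).
#' @param max_gap maximum marker gap to interpolate (frames), default 5.
#' @param tol convergence tolerance on the coordinate update (rad / mm).
#' @return a `joint_state_series` data frame: time, % stance, the 11
#'   coordinates (rad, mm) and the per-frame RMS marker residual (mm).
#' @export
inverse_kinematics <- function(trial, model, weights = NULL, max_gap = 5,
                               tol = 1e-10) {
  mk <- trial$markers
  nf <- dim(mk)[1]; nm <- dim(mk)[2]
  if (is.null(weights)) weights <- rep(1, nm)
  mk <- .fill_marker_gaps(mk, max_gap)

  w <- rep(sqrt(weights), each = 1)
  qs <- matrix(NA_real_, nf, 11, dimnames = list(NULL, model$dof_names))
  rms <- numeric(nf)
  q <- .ik_initial_guess(mk[1, , ], model)
  for (i in seq_len(nf)) {
    target <- mk[i, , ]
    res_fun <- function(qq) {
      pos <- marker_positions(qq, model)
      as.numeric(t(pos - target)) * rep(sqrt(weights), each = 3)
    }
    fit <- .levenberg_marquardt(q, res_fun, tol = tol)
    if (!fit$ok) stop(sprintf("inverse kinematics: singular pose at frame %d", i))
    q <- fit$par
    qs[i, ] <- q
    rms[i] <- sqrt(mean(fit$residual^2))
  }
  out <- data.frame(time = trial$time, pct = 100 * trial$time / max(trial$time))
  out <- cbind(out, as.data.frame(qs))
  out$rms_residual <- rms
  class(out) <- c("joint_state_series", "data.frame")
  out
}

# Linear gap interpolation per marker channel; errors on gaps > max_gap or
# missing data at the trial boundaries beyond the limit.
.fill_marker_gaps <- function(mk, max_gap) {
  nf <- dim(mk)[1]
  for (j in seq_len(dim(mk)[2])) {
    miss <- apply(is.na(mk[, j, , drop = FALSE]), 1, any)
    if (!any(miss)) next
    runs <- rle(miss)
    if (max(runs$lengths[runs$values]) > max_gap) {
      stop(sprintf("marker '%s': gap longer than %d frames",
                   dimnames(mk)[[2]][j], max_gap))
    }
    if (miss[1] || miss[nf]) {
      stop(sprintf("marker '%s': missing at the trial boundary",
                   dimnames(mk)[[2]][j]))
    }
    for (k in 1:3) {
      mk[, j, k] <- stats::approx(which(!miss), mk[!miss, j, k],
                                  xout = seq_len(nf))$y
    }
  }
  mk
}

# Pelvis-centroid translation seed; angles from zero.
.ik_initial_guess <- function(frame1, model) {
  pelvis_idx <- which(vapply(model$markers, function(m) m$segment == "pelvis",
                             logical(1)))
  loc <- t(vapply(model$markers[pelvis_idx], function(m) m$local, numeric(3)))
  q <- rep(0, 11)
  q[1:3] <- colMeans(frame1[pelvis_idx, , drop = FALSE]) - colMeans(loc)
  q
}

# Damped Gauss-Newton with finite-difference Jacobian.
.levenberg_marquardt <- function(q0, res_fun, tol = 1e-10, max_iter = 100) {
  q <- q0
  r <- res_fun(q)
  lambda <- 1e-4
  for (it in seq_len(max_iter)) {
    J <- .fd_jacobian(res_fun, q, r)
    JtJ <- crossprod(J)
    g <- crossprod(J, r)
    repeat {
      H <- JtJ + lambda * diag(ncol(J))
      dq <- tryCatch(-solve(H, g), error = function(e) NULL)
      if (is.null(dq)) return(list(par = q, residual = r, ok = FALSE))
      r_new <- res_fun(q + as.numeric(dq))
      if (sum(r_new^2) <= sum(r^2) || lambda > 1e8) break
      lambda <- lambda * 10
    }
    if (lambda > 1e8 && sum(r_new^2) > sum(r^2)) break
    q <- q + as.numeric(dq)
    r <- r_new
    lambda <- max(lambda / 10, 1e-12)
    if (max(abs(dq)) < tol) break
  }
  list(par = q, residual = r, ok = TRUE)
}

.fd_jacobian <- function(fun, q, r0 = fun(q), h = 1e-7) {
  J <- matrix(0, length(r0), length(q))
  for (k in seq_along(q)) {
    qp <- q; qp[k] <- qp[k] + h
    qm <- q; qm[k] <- qm[k] - h
    J[, k] <- (fun(qp) - fun(qm)) / (2 * h)
  }
  J
}
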