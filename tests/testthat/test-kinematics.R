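# Inverse kinematics and inverse dynamics.

test_that("zero-noise trial round-trips the generating template angles", {
  tr <- fx_trial(); ml <- fx_linkage()
  st <- fx_states()
  err <- max(abs(as.matrix(st[, ml$dof_names]) - tr$template_q))
  expect_lt(err, 1e-6)        # rad (and mm for the pelvis translations)
  expect_lt(max(st$rms_residual), 1e-6)
})

test_that("IK is invariant to a rigid translation of the whole marker set", {
  tr <- fx_trial(); ml <- fx_linkage()
  tr5 <- tr
  keep <- 1:5
  tr5$time <- tr$time[keep]; tr5$markers <- tr$markers[keep, , ]
  st1 <- inverse_kinematics(tr5, ml)
  tr5b <- tr5
  for (k in 1:3) tr5b$markers[, , k] <- tr5$markers[, , k] + c(100, -50, 30)[k]
  st2 <- inverse_kinematics(tr5b, ml)
  ang <- setdiff(ml$dof_names, c("pelvis_tx", "pelvis_ty", "pelvis_tz"))
  expect_equal(as.matrix(st2[, ang]), as.matrix(st1[, ang]), tolerance = 1e-7)
  expect_equal(st2$pelvis_tx, st1$pelvis_tx + 100, tolerance = 1e-6)
})

test_that("marker gaps are interpolated up to the limit and rejected beyond", {
  tr <- fx_trial(); ml <- fx_linkage()
  trg <- tr
  keep <- 1:12
  trg$time <- tr$time[keep]; trg$markers <- tr$markers[keep, , ]
  trg$markers[5:7, 2, ] <- NA   # 3-frame gap
  st <- inverse_kinematics(trg, ml, max_gap = 5)
  expect_false(anyNA(st$knee_flex))
  trg$markers[3:11, 2, ] <- NA  # 9-frame gap
  expect_error(inverse_kinematics(trg, ml, max_gap = 5), "gap")
})

test_that("static upright stance with aligned loads produces zero joint moments", {
  ml <- fx_linkage()
  # align every segment COM with the vertical joint line so the supporting
  # force through the joint centres balances gravity without any moment
  ml0 <- ml
  for (s in names(ml0$segments)) ml0$segments[[s]]$com[c(1, 3)] <- 0
  nf <- 25
  q0 <- rep(0, 11); q0[1:3] <- c(0, 900, 0)
  states <- data.frame(time = seq(0, by = 0.01, length.out = nf))
  qm <- matrix(rep(q0, each = nf), nf, 11,
               dimnames = list(NULL, ml0$dof_names))
  states <- cbind(states, as.data.frame(qm))
  leg_mass <- sum(vapply(c("thigh", "shank", "foot"),
                         function(s) ml0$segments[[s]]$mass, numeric(1)))
  fk <- forward_kinematics(q0, ml0)
  supported <- leg_mass * GRAVITY   # GRF supports exactly the leg weight
  trial <- list(time = states$time,
                grf = data.frame(time = seq(0, by = 0.001,
                                            length.out = (nf - 1) * 10 + 1),
                                 fx = 0, fy = supported,
                                 fz = 0, copx = fk$ankle[1], copz = fk$ankle[3]),
                spec = gait_trial_spec())
  class(trial) <- "gait_trial"
  ld <- inverse_dynamics(states, trial, ml0, cutoff_hz = NA)
  mid <- 8:(nf - 7)
  for (j in c("ankle", "knee", "hip")) {
    for (k in c("x", "y", "z")) {
      expect_lt(max(abs(ld[[paste0("M_", j, "_", k)]][mid])), 1e-6)
    }
  }
})

test_that("planar two-link inverse dynamics matches the closed-form solution", {
  # prescribed sinusoidal hip angle, locked knee/ankle, no GRF: the knee
  # moment follows the rigid-body pendulum equation of the distal assembly
  ml <- fx_linkage()
  ml0 <- ml
  for (s in names(ml0$segments)) {
    ml0$segments[[s]]$com[c(1, 3)] <- 0   # COM on the segment line
  }
  nf <- 201; dt <- 0.01
  tvec <- seq(0, by = dt, length.out = nf)
  amp <- 0.3; om <- 2 * pi
  th <- amp * sin(om * tvec)
  states <- data.frame(time = tvec)
  qm <- matrix(0, nf, 11, dimnames = list(NULL, ml0$dof_names))
  qm[, "pelvis_ty"] <- 1000
  qm[, "hip_flex"] <- th
  states <- cbind(states, as.data.frame(qm))
  trial <- list(time = tvec,
                grf = data.frame(time = seq(0, max(tvec), by = 0.001),
                                 fx = 0, fy = 0, fz = 0, copx = 0, copz = 0),
                spec = gait_trial_spec())
  class(trial) <- "gait_trial"
  ld <- inverse_dynamics(states, trial, ml0, cutoff_hz = NA)

  # closed form for the shank+foot assembly swinging about the knee, itself
  # rotating with the thigh: both segments rotate rigidly with angle th about
  # the hip (knee locked), so about the knee:
  # M_k = (I_k + m d_k l_t) thdd + m g (d_k sin th + ...) -- derive directly
  m_s <- ml0$segments$shank$mass; m_f <- ml0$segments$foot$mass
  lt <- ml0$segments$thigh$length / 1000
  # distal-assembly COM relative to the knee (m) and inertia about its COM
  c_s <- -ml0$segments$shank$com[2] / 1000
  c_f <- (ml0$segments$shank$length - ml0$segments$foot$com[2]) / 1000
  d_k <- (m_s * c_s + m_f * c_f) / (m_s + m_f)
  m_d <- m_s + m_f
  I_d <- (ml0$segments$shank$inertia[3, 3] +
            ml0$segments$foot$inertia[3, 3]) * 1e-6 +
    m_s * (c_s - d_k)^2 + m_f * (c_f - d_k)^2
  thd <- amp * om * cos(om * tvec)
  thdd <- -amp * om^2 * sin(om * tvec)
  # COM of the distal assembly lies at radius r_k = l_t + d_k below the hip,
  # rotating with th: tangential acceleration (l_t + d_k) thdd, plus gravity
  g <- GRAVITY
  M_closed <- (I_d + m_d * d_k * (lt + d_k)) * thdd +
    m_d * g * d_k * sin(th)
  mid <- 30:(nf - 30)
  err <- max(abs(ld$M_knee_z[mid] / 1000 - M_closed[mid])) /
    max(abs(M_closed[mid]))
  expect_lt(err, 1e-3)
})

test_that("external-load contribution to the moments is linear in the GRF", {
  ml <- fx_linkage(); tr <- fx_trial(); st <- fx_states()
  ld1 <- inverse_dynamics(st, tr, ml)
  tr2 <- tr; tr2$grf[, c("fx", "fy", "fz")] <- 2 * tr$grf[, c("fx", "fy", "fz")]
  ld2 <- inverse_dynamics(st, tr2, ml)
  tr0 <- tr; tr0$grf[, c("fx", "fy", "fz")] <- 0
  ld0 <- inverse_dynamics(st, tr0, ml)
  mid <- 10:55
  expect_equal(ld2$M_knee_z[mid] - ld0$M_knee_z[mid],
               2 * (ld1$M_knee_z[mid] - ld0$M_knee_z[mid]), tolerance = 1e-8)
})

test_that("non-monotone time stamps are rejected", {
  st <- fx_states()
  st2 <- st; st2$time[3] <- st2$time[5]
  expect_error(inverse_dynamics(st2[c(1:3, 5, 4, 6:10), ], fx_trial(), fx_linkage()),
               "non-monotone")
})
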