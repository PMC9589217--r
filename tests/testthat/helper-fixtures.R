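# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fx_linkage <- function() {
  if (is.null(.fixtures$linkage)) .fixtures$linkage <- default_linkage()
  .fixtures$linkage
}

fx_muscles <- function() {
  if (is.null(.fixtures$muscles)) .fixtures$muscles <- load_muscle_set(fx_linkage())
  .fixtures$muscles
}

fx_trial <- function() {
  if (is.null(.fixtures$trial)) {
    .fixtures$trial <- generate_gait_trial(gait_trial_spec(noise_sd = 0),
                                           fx_linkage())
  }
  .fixtures$trial
}

fx_states <- function() {
  if (is.null(.fixtures$states)) {
    .fixtures$states <- inverse_kinematics(fx_trial(), fx_linkage())
  }
  .fixtures$states
}

fx_knee <- function() {
  if (is.null(.fixtures$knee)) .fixtures$knee <- build_knee_geometry()
  .fixtures$knee
}

# A unit cube hex body in canonical node ordering.
fx_cube <- function() {
  nd <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
              c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  list(nodes = nd, elems = matrix(1:8, 1, 8))
}

# Independent hand evaluation of the piecewise ligament law (the oracle kept
# deliberately separate from the implementation).
oracle_ligament <- function(l, l0, k1, k2, eps_l = 0.03) {
  eps <- (l - l0) / l0
  if (eps <= 0) return(0)
  if (eps <= 2 * eps_l) return(k1 * (l - l0)^2)
  k2 * (l - (1 + eps_l) * l0)
}

# Rigid sphere on a flat bonded elastic layer, in the thin-layer regime
# (contact radius >> layer thickness) where the elastic-foundation closed
# form F = pi E_conf R d^2 / t applies: build a knee spec whose "condyle" is
# a sphere and whose tibial cartilage is a thin flat layer, press to a
# prescribed depth and integrate the reaction.
.sphere_layer_setup <- function(R = 400, t_layer = 0.5, nx = 32) {
  spec <- knee_geometry_spec(
    condyle_radius_sagittal = R, condyle_radius_frontal = R,
    condyle_clearance = 1e-6, dish_depth = 1e-9,
    plateau_half_x = 24, plateau_half_z = 24, condyle_offset_z = 1e-6,
    cartilage_thickness = t_layer,
    femoral_cartilage_thickness = 1e-6,   # rigid indenter
    cart_nx = nx, cart_nz = nx, cart_nlayer = 2)
  st <- contact_settings(penalty_num = 1e4)
  model <- build_knee_geometry(spec)
  sys <- contact_system(model, st)
  sys$bodies$medial_tibial_cartilage$a_c <- sys$a_c
  list(spec = spec, model = model, st = st, sys = sys)
}

.sphere_layer_force <- function(setup, depth) {
  T_es <- kneegait:::.es_pose(
    c(0, -(depth + setup$spec$condyle_clearance), 0, 0, 0), setup$sys$a_c)
  bs <- kneegait:::.solve_body(setup$sys$bodies$medial_tibial_cartilage, T_es,
                               setup$spec, 0, setup$st)
  bs$cf$W_femur$F[2]   # upward force the layer exerts on the indenter
}
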