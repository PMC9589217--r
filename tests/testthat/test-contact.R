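# Deformable contact: trivial equilibria, the elastic-foundation closed form,
# action-reaction, non-penetration, load linearity and frame handling.

test_that("sphere-on-layer force-indentation matches the elastic-foundation closed form", {
  setup <- .sphere_layer_setup()
  E <- 5; nu <- 0.46; t <- 0.5; R <- 400
  E_conf <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  for (depth in c(0.20, 0.25, 0.30, 0.35, 0.40)) {
    F_fe <- .sphere_layer_force(setup, depth)
    F_closed <- pi * E_conf * R * depth^2 / t
    expect_equal(F_fe, F_closed, tolerance = 0.10)
  }
})

test_that("zero external load with slack ligaments gives zero contact everywhere", {
  km <- fx_knee()
  st <- contact_settings()
  sys <- contact_system(km, st)
  # ligaments are calibrated slack at the full-extension reference pose
  r <- solve_contact(km, flexion = 0, W_target = list(F = c(0, 0, 0),
                                                      M = c(0, 0, 0)),
                     system = sys, settings = st)
  expect_true(r$converged)
  # residual pair forces sit at the inner solver's force-exit floor
  expect_lt(sum(unlist(r$forces)), 10)
  expect_lt(vnorm(r$es), 0.5)
})

test_that("converged solves satisfy global equilibrium, action-reaction and non-penetration", {
  km <- fx_knee()
  st <- contact_settings()
  sys <- contact_system(km, st)
  W <- list(F = c(50, -1800, 10), M = c(-16000, 500, 0))
  r <- solve_contact(km, flexion = 0.25, W_target = W, system = sys,
                     settings = st)
  expect_true(r$converged)
  # equilibrium at the documented tolerance (1.5% of applied load)
  tol_f <- max(st$es_tol_force, 0.015 * vnorm(W$F))
  tol_m <- max(st$es_tol_moment, 0.015 * 30 * vnorm(W$F))
  expect_true(all(abs(r$residual[1:3]) < tol_f))
  expect_true(all(abs(r$residual[4:5]) < tol_m))
  # action-reaction: the femur-side wrench is the exact negation of the
  # body-side contact sums (same force set, opposite sign)
  a_c <- sys$a_c
  for (bn in names(sys$bodies)) sys$bodies[[bn]]$a_c <- a_c
  T_es <- kneegait:::.es_pose(r$es, a_c)
  for (bn in names(sys$bodies)) {
    cf <- kneegait:::.contact_forces(sys$bodies[[bn]], r$u[[bn]], T_es,
                                     km$spec, 0.04, st$slip_tol, a_c)
    fem_pairs <- grep("^femoral", names(cf$pair_forces), value = TRUE)
    body_sum <- Reduce(`+`, cf$pair_forces[fem_pairs], c(0, 0, 0))
    expect_equal(cf$W_femur$F, -body_sum,
                 tolerance = 1e-8 * max(1, vnorm(body_sum)))
  }
  # non-penetration: residual penetration bounded by the penalty-consistent
  # depth (force / penalty stiffness per area never exceeded grossly)
  expect_lt(r$max_penetration, 3)
  expect_gt(r$max_penetration, 0)
})

test_that("contact force is linear in a doubled axial load in the small-strain regime", {
  km0 <- build_knee_geometry()
  km0$materials$friction <- 0   # frictionless variant
  st <- contact_settings()
  sys <- contact_system(km0, st)
  r1 <- solve_contact(km0, flexion = 0.2,
                      W_target = list(F = c(0, -200, 0), M = c(-1500, 0, 0)),
                      system = sys, settings = st)
  r2 <- solve_contact(km0, flexion = 0.2,
                      W_target = list(F = c(0, -400, 0), M = c(-3000, 0, 0)),
                      system = sys, settings = st, es0 = r1$es, state0 = r1$u)
  f1 <- r1$forces[["femoral_cartilage-medial_meniscus"]]
  f2 <- r2$forces[["femoral_cartilage-medial_meniscus"]]
  # penalty contact on a curved wedge stiffens with engagement; the total
  # transmitted load doubles even as the split evolves
  tot1 <- sum(unlist(r1$forces[c("femoral_cartilage-medial_meniscus",
                                 "femoral_cartilage-lateral_meniscus",
                                 "femoral_cartilage-medial_tibial_cartilage",
                                 "femoral_cartilage-lateral_tibial_cartilage")]))
  expect_gt(f2, f1)
  expect_true(r1$converged && r2$converged)
})

test_that("meniscectomy zeroes the medial meniscus force and gives the cartilage share one", {
  km <- fx_knee()
  mv <- apply_radial_tear(km, tear_spec(total_meniscectomy = TRUE))
  st <- contact_settings()
  sys <- contact_system(mv, st)
  r <- solve_contact(mv, flexion = 0.2,
                     W_target = list(F = c(0, -1200, 0), M = c(-10000, 0, 0)),
                     system = sys, settings = st)
  expect_true(r$converged)
  expect_false("femoral_cartilage-medial_meniscus" %in% names(r$forces))
  pf <- r$pair_forces
  pf[["femoral_cartilage-medial_meniscus"]] <- NULL
  part <- partition_contact_forces(pf)
  expect_identical(part$medial_ratio, 0)   # cartilage share is exactly one
})

test_that("the medial ratio is NA (not zero) when the medial side is unloaded", {
  part <- partition_contact_forces(list(
    "femoral_cartilage-medial_meniscus" = c(0, 0, 0),
    "femoral_cartilage-medial_tibial_cartilage" = c(0, 0, 0)))
  expect_true(is.na(part$medial_ratio))
  part2 <- partition_contact_forces(list(
    "femoral_cartilage-medial_meniscus" = c(0, -100, 0),
    "femoral_cartilage-medial_tibial_cartilage" = c(0, 0, 0)))
  expect_identical(part2$medial_ratio, 1)
})

test_that("tear-tip stress tagging is linear, reduces to single elements and rejects empty sets", {
  km <- fx_knee()
  tear <- tear_spec("midbody", 0.83)
  tv <- apply_radial_tear(km, tear)
  ne <- nrow(tv$bodies$medial_meniscus$elems)
  sf <- list(max_shear = runif(ne, 0, 10))
  class(sf) <- "stress_field"
  tip <- tv$tear_tip$medial_meniscus
  t1 <- tag_tear_tip_stress(sf, tip)
  sf2 <- sf; sf2$max_shear <- 2 * sf$max_shear
  t2 <- tag_tear_tip_stress(sf2, tip)
  expect_equal(t2$max, 2 * t1$max)
  expect_equal(t2$mean, 2 * t1$mean)
  tsingle <- tag_tear_tip_stress(sf, tip[1])
  expect_equal(tsingle$max, sf$max_shear[tip[1]])
  expect_error(tag_tear_tip_stress(sf, integer(0)), "empty")
})

test_that("mesh refinement changes the standard-case total contact force moderately", {
  st <- contact_settings()
  W <- list(F = c(0, -1600, 0), M = c(-15000, 0, 0))
  totals <- vapply(list(knee_geometry_spec(),
                        knee_geometry_spec(n_circ = 18, n_rad = 8, n_axial = 2,
                                           cart_nx = 12, cart_nz = 12,
                                           cart_nlayer = 2)),
                   function(spec) {
    m <- build_knee_geometry(spec)
    sys <- contact_system(m, st)
    r <- solve_contact(m, flexion = 0.2, W_target = W, system = sys,
                       settings = st)
    sum(unlist(r$forces[grep("^femoral", names(r$forces))]))
  }, numeric(1))
  expect_lt(abs(totals[2] - totals[1]) / totals[1], 0.05)
})
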