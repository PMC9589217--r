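# Hexahedral elasticity: closed-form compliance, rigid-body modes, material
# rotation, stress recovery.

test_that("isotropic single cube reproduces uniaxial compliance to 1e-8", {
  body <- fx_cube()
  D <- material_matrix_isotropic(5, 0.46)
  K <- as.matrix(assemble_elasticity(body, D, bbar = TRUE))
  fixed <- c(3 * (1:4 - 1) + 3, 1, 2, 3 * (2 - 1) + 2)  # bottom z + pins
  free <- setdiff(1:24, fixed)
  f <- rep(0, 24); f[3 * (5:8 - 1) + 3] <- 0.25   # 1 MPa on the top face
  u <- rep(0, 24); u[free] <- solve(K[free, free], f[free])
  eps_z <- u[3 * (5 - 1) + 3]
  eps_x <- u[3 * (2 - 1) + 1] - u[1]
  expect_equal(eps_z, 1 / 5, tolerance = 1e-8)
  expect_equal(eps_x, -0.46 / 5, tolerance = 1e-8)
})

test_that("transversely isotropic cube matches its compliance matrix along each axis", {
  body <- fx_cube()
  Dt <- material_matrix_transiso()    # 140 / 20 MPa
  K <- as.matrix(assemble_elasticity(body, Dt, bbar = FALSE))
  pull_axis <- function(K, axis) {
    # pins: clamp the loaded direction on the back face, both transverse
    # directions at node 1, and one rotation-blocking component at a node
    # offset within the face
    faces <- list(x = list(fix = c(1, 4, 5, 8), load = c(2, 3, 6, 7), d = 1,
                           pin = c(4, 3)),
                  y = list(fix = c(1, 2, 5, 6), load = c(3, 4, 7, 8), d = 2,
                           pin = c(2, 3)),
                  z = list(fix = c(1, 2, 3, 4), load = c(5, 6, 7, 8), d = 3,
                           pin = c(2, 2)))
    fc <- faces[[axis]]
    fixed <- 3 * (fc$fix - 1) + fc$d
    others <- setdiff(1:3, fc$d)
    fixed <- c(fixed, 3 * (1 - 1) + others, 3 * (fc$pin[1] - 1) + fc$pin[2])
    free <- setdiff(1:24, fixed)
    f <- rep(0, 24); f[3 * (fc$load - 1) + fc$d] <- 0.25
    u <- rep(0, 24); u[free] <- solve(K[free, free], f[free])
    u[3 * (fc$load[1] - 1) + fc$d]
  }
  expect_equal(pull_axis(K, "x"), 1 / 140, tolerance = 1e-8)  # circumferential
  expect_equal(pull_axis(K, "y"), 1 / 20, tolerance = 1e-8)   # radial
  expect_equal(pull_axis(K, "z"), 1 / 20, tolerance = 1e-8)   # axial
})

test_that("rigid-body modes carry zero energy", {
  body <- fx_cube()
  for (D in list(material_matrix_isotropic(5, 0.46), material_matrix_transiso())) {
    K <- as.matrix(assemble_elasticity(body, D, bbar = TRUE))
    for (tr in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      u <- rep(tr, 8)
      expect_lt(max(abs(K %*% u)), 1e-10)
    }
    # infinitesimal rotation about z
    u <- as.numeric(t(cbind(-body$nodes[, 2], body$nodes[, 1], 0))) * 1e-3
    expect_lt(abs(drop(t(u) %*% K %*% u)), 1e-12)
  }
})

test_that("Bond rotation of the stiffness preserves strain energy", {
  set.seed(5)
  Dl <- material_matrix_transiso()
  R <- rot_z(0.4) %*% rot_x(-0.7)
  Kb <- bond_matrix(R)
  Dg <- Kb %*% Dl %*% t(Kb)
  for (i in 1:10) {
    # strain tensor rotated consistently must give the same energy density
    E <- matrix(rnorm(9), 3); E <- (E + t(E)) / 2
    to_voigt <- function(E) c(diag(E), 2 * E[1, 2], 2 * E[2, 3], 2 * E[1, 3])
    e_l <- to_voigt(t(R) %*% E %*% R)
    e_g <- to_voigt(E)
    expect_equal(drop(t(e_g) %*% Dg %*% e_g), drop(t(e_l) %*% Dl %*% e_l),
                 tolerance = 1e-9)
  }
})

test_that("hydrostatic stress has zero maximum shear; uniaxial gives sigma/2", {
  body <- fx_cube()
  D <- material_matrix_isotropic(5, 0.3)
  # hydrostatic: u = eps * x
  eps <- 1e-3
  u_h <- as.numeric(t(body$nodes)) * eps
  sf <- recover_stress(body, D, u_h)
  expect_lt(sf$max_shear[1], 1e-12)
  # uniaxial strain state along x with frames aligned to x
  u_x <- rep(0, 24); u_x[seq(1, 24, by = 3)] <- body$nodes[, 1] * eps
  frame <- list(cbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  sf2 <- recover_stress(body, D, u_x, frames = frame)
  S <- sf2$tensor[[1]]
  expect_equal(sf2$sigma_cc[1], S[1, 1], tolerance = 1e-12)
  expect_equal(sf2$max_shear[1], (S[1, 1] - S[2, 2]) / 2, tolerance = 1e-12)
})

test_that("principal stresses match an independent closed-form eigensolution", {
  set.seed(8)
  body <- fx_cube()
  D <- material_matrix_isotropic(5, 0.46)
  for (rep in 1:10) {
    u <- rnorm(24, sd = 1e-3)
    sf <- recover_stress(body, D, u, bbar = TRUE)
    S <- sf$tensor[[1]]
    # closed-form invariant-based principal values (trigonometric method)
    I1 <- sum(diag(S))
    Sd <- S - diag(I1 / 3, 3)
    J2 <- sum(Sd^2) / 2
    J3 <- det(Sd)
    if (J2 < 1e-20) next
    th <- acos(max(-1, min(1, 3 * sqrt(3) / 2 * J3 / J2^1.5))) / 3
    pr <- I1 / 3 + 2 * sqrt(J2 / 3) * cos(th + c(0, -2, 2) * pi / 3)
    expect_equal(sort(sf$principal[1, ], decreasing = TRUE),
                 sort(pr, decreasing = TRUE), tolerance = 1e-10)
  }
})

test_that("non-SPD material specifications are rejected at load time", {
  expect_error(material_matrix_isotropic(5, 0.6), "nu")
  expect_error(material_matrix_transiso(E_circ = 1, E_trans = 20,
                                        nu_out = 0.9),
               "positive definite")
})
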