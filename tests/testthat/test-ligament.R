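# Nonlinear ligament bundles, horn attachment springs and the transverse
# ligament.

test_that("ligament law matches independent evaluation on random draws and the canonical table", {
  set.seed(11)
  for (i in 1:1000) {
    k1 <- runif(1, 1, 50); k2 <- runif(1, 10, 150)
    l0 <- runif(1, 15, 60); l <- l0 * runif(1, 0.8, 1.3)
    expect_equal(ligament_force(l, l0, k1, k2),
                 oracle_ligament(l, l0, k1, k2), tolerance = 1e-10)
  }
  tab <- kneegait:::.ligament_table
  for (r in seq_len(nrow(tab))) {
    l0 <- 30
    for (l in c(28, 30, 30.9, 31.5, 31.8 + 1e-9, 33, 36)) {
      expect_equal(ligament_force(l, l0, tab$k1[r], tab$k2[r]),
                   oracle_ligament(l, l0, tab$k1[r], tab$k2[r]),
                   tolerance = 1e-10)
    }
  }
})

test_that("ligament force is zero at and below slack, continuous at zero strain", {
  expect_identical(ligament_force(30, 30, 22.48, 83.15), 0)
  expect_identical(ligament_force(25, 30, 22.48, 83.15), 0)
  eps <- 1e-9
  expect_lt(ligament_force(30 + eps, 30, 22.48, 83.15), 1e-10)
})

test_that("worked branch examples evaluate as derived by hand", {
  # toe branch: k1 (l - l0)^2 at 5% strain
  expect_equal(ligament_force(31.5, 30, 22.48, 83.15), 22.48 * 1.5^2,
               tolerance = 1e-12)
  # linear branch at 10% strain: k2 (l - 1.03 l0)
  expect_equal(ligament_force(33, 30, 22.48, 83.15), 83.15 * (33 - 1.03 * 30),
               tolerance = 1e-12)
})

test_that("the toe/linear transition jump is reported, not smoothed", {
  jump <- ligament_force_jump(30, 22.48, 83.15)
  lt <- 30 * 1.06
  below <- ligament_force(lt - 1e-7, 30, 22.48, 83.15)
  above <- ligament_force(lt + 1e-7, 30, 22.48, 83.15)
  expect_equal(above - below, jump, tolerance = 1e-4)
})

test_that("packaged ligament table loads, validates and calibrates slack", {
  p <- load_ligament_params()
  expect_equal(nrow(p), 23)   # bundle element counts of the canonical table
  p <- calibrate_slack_lengths(p)
  # zero reference strain: exactly slack at the reference pose
  w <- passive_wrench(p)
  expect_equal(w$force_tibia, c(0, 0, 0))
  expect_true(all(w$forces == 0))
})

test_that("a single taut ligament produces the r x f wrench and action-reaction holds", {
  p <- load_ligament_params()
  p <- p[1, , drop = FALSE]
  p$l0 <- 20  # force it taut at reference
  pose <- rigid_transform()
  w <- passive_wrench(p, pose)
  fem <- c(p$fx, p$fy, p$fz); tib <- c(p$tx, p$ty, p$tz)
  len <- sqrt(sum((fem - tib)^2))
  fmag <- oracle_ligament(len, 20, p$k1, p$k2)
  fvec <- fmag * (fem - tib) / len
  expect_equal(w$force_tibia, fvec, tolerance = 1e-10)
  expect_equal(w$moment_tibia,
               c(tib[2] * fvec[3] - tib[3] * fvec[2],
                 tib[3] * fvec[1] - tib[1] * fvec[3],
                 tib[1] * fvec[2] - tib[2] * fvec[1]), tolerance = 1e-10)
  expect_equal(w$force_femur, -w$force_tibia)
  expect_equal(w$moment_femur, -w$moment_tibia)
})

test_that("horn springs reproduce axial rod stiffness and documented scalings", {
  # single spring: k = E a / l
  sp <- build_horn_springs(matrix(c(0, 5, 0), 1), matrix(c(0, 0, 0), 1),
                           E = 100, area = 10)
  expect_equal(sp$k, 100 * 10 / 5, tolerance = 1e-12)
  # n equal parallel springs: total stiffness E a / l regardless of n
  for (n in c(2, 5, 9)) {
    hn <- cbind(0, rep(5, n), seq_len(n))
    tn <- cbind(0, rep(0, n), seq_len(n))
    sp <- build_horn_springs(hn, tn, E = 100, area = 10)
    expect_equal(sum(sp$k), 100 * 10 / 5, tolerance = 1e-12)
  }
  # doubling length halves the per-spring stiffness
  s1 <- build_horn_springs(matrix(c(0, 4, 0), 1), matrix(c(0, 0, 0), 1), 50, 8)
  s2 <- build_horn_springs(matrix(c(0, 8, 0), 1), matrix(c(0, 0, 0), 1), 50, 8)
  expect_equal(s2$k, s1$k / 2, tolerance = 1e-12)
  expect_error(build_horn_springs(matrix(0, 1, 3), matrix(0, 1, 3), 100, 10),
               "zero-length")
})

test_that("assembled horn springs match a uniform rod in a single-axis pull", {
  # pull every horn node the same small distance along the rod axis: the
  # resultant force equals (E a / l) * u within 1%
  n <- 7; l <- 6; E <- 600; area <- 55
  hn <- cbind(seq(0, 3, length.out = n), rep(l, n), 0)
  tn <- cbind(seq(0, 3, length.out = n), rep(0, n), 0)
  sp <- build_horn_springs(hn, tn, E = E, area = area)
  u <- 0.01
  f <- sum(sp$k * u)   # springs aligned with the pull
  expect_equal(f, E * area / l * u, tolerance = 0.01)
})

test_that("transverse ligament splits total stiffness over parallel springs", {
  m <- matrix(rnorm(9), 3); l <- m + 2
  tr <- build_transverse_ligament(m, l, k_total = 12.5)
  expect_equal(sum(tr$k), 12.5, tolerance = 1e-12)
})
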