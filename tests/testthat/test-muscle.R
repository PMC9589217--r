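# Hill-type muscle units: force-length curves, path wrapping, moment arms.

test_that("hill force matches direct curve evaluation on a random grid", {
  set.seed(3)
  mus <- list(fmax = 1234)
  for (i in 1:50) {
    a <- runif(1); l <- runif(1, 0.6, 1.6)
    expect_identical(hill_force(mus, a, l),
                     1234 * (a * active_force_length(l) + passive_force_length(l)))
  }
})

test_that("slack passive element produces zero force at zero activation", {
  mus <- list(fmax = 500)
  expect_identical(hill_force(mus, 0, 1), 0)
  expect_identical(hill_force(mus, 0, 0.8), 0)
  expect_equal(hill_force(mus, 1, 1),
               500 * (active_force_length(1) + passive_force_length(1)))
  expect_identical(active_force_length(1), 1)
})

test_that("force is monotone non-decreasing in activation", {
  mus <- list(fmax = 800)
  for (l in c(0.7, 1, 1.3)) {
    f <- vapply(seq(0, 1, by = 0.1), function(a) hill_force(mus, a, l),
                numeric(1))
    expect_true(all(diff(f) >= 0))
  }
})

# in-memory single-muscle set spanning the knee at lever distance d
.toy_muscle <- function(d = 40, wrap = NULL, wrap_pair = NULL) {
  ms <- list(name = "toy", fmax = 1000, lopt = 100, lts = 0, ref_lnorm = 1,
             paths = list(list(
               list(segment = "thigh", local = c(d, -300, 0)),
               list(segment = "shank", local = c(d, -50, 0)))),
             wraps = list(wrap), n = 1L)
  if (!is.null(wrap)) ms$wraps[[1]]$pair <- wrap_pair
  class(ms) <- "muscle_set"
  ms
}

test_that("a straight two-point muscle crossing a hinge has moment arm equal to its lever", {
  ml <- fx_linkage()
  ms <- .toy_muscle(d = 40)
  g <- compute_muscle_geometry(rep(0, 11), ml, ms)
  # both points at x = 40 on either side of the knee hinge: scalar arm = 40 mm
  expect_equal(abs(g$moment_arms[1, "knee_flex"]), 40, tolerance = 1e-3)
})

test_that("cylinder-wrapped planar path length matches the tangent-arc closed form", {
  # points and cylinder in one plane perpendicular to the axis
  a <- c(-30, 10, 0); b <- c(30, 15, 0)
  center <- c(0, 30, 0); axis <- c(0, 0, 1); R <- 18
  len <- kneegait:::.segment_length_wrapped(a, b, center, axis, R, "toy")
  # independent closed form: tangent lengths + arc between tangent points
  va <- a - center; vb <- b - center
  da <- sqrt(sum(va^2)); db <- sqrt(sum(vb^2))
  phi <- acos(sum(va * vb) / (da * db))
  arc <- phi - acos(R / da) - acos(R / db)
  L <- sqrt(da^2 - R^2) + R * arc + sqrt(db^2 - R^2)
  expect_equal(len, L, tolerance = 1e-9)
  # no wrap when the chord clears the cylinder
  len2 <- kneegait:::.segment_length_wrapped(a, b, c(0, 60, 0), axis, R, "toy")
  expect_equal(len2, sqrt(sum((b - a)^2)), tolerance = 1e-12)
  expect_error(kneegait:::.segment_length_wrapped(c(0, 25, 0), b, center, axis,
                                                  R, "toy"),
               "inside")
})

test_that("tendon-excursion moment arms agree with an independent length derivative", {
  ml <- fx_linkage(); ms <- fx_muscles()
  set.seed(13)
  for (rep in 1:10) {
    q <- rep(0, 11)
    q[7] <- runif(1, -0.2, 0.5); q[8] <- runif(1, -0.15, 0.15)
    q[9] <- runif(1, -0.15, 0.15); q[10] <- runif(1, 0, 0.6)
    q[11] <- runif(1, -0.3, 0.3)
    g <- compute_muscle_geometry(q, ml, ms)
    # independent central difference at a different step size
    h <- 2e-5
    for (dname in c("knee_flex", "ankle_flex")) {
      di <- c(knee_flex = 10L, ankle_flex = 11L)[[dname]]
      qp <- q; qp[di] <- qp[di] + h
      qm <- q; qm[di] <- qm[di] - h
      arm <- -(kneegait:::.muscle_path_lengths(qp, ml, ms) -
                 kneegait:::.muscle_path_lengths(qm, ml, ms)) / (2 * h)
      expect_equal(unname(g$moment_arms[, dname]), unname(arm),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("secondary-kinematics update is stateless and identity at zero", {
  ml <- fx_linkage(); ms <- fx_muscles()
  q <- rep(0, 11); q[7] <- 0.3; q[10] <- 0.4
  g0 <- compute_muscle_geometry(q, ml, ms)
  g_id <- update_geometry_with_secondary(q, ml, ms, es = rep(0, 5))
  expect_identical(g_id$length, g0$length)
  expect_identical(g_id$moment_arms, g0$moment_arms)
  es <- c(5, -1, 2, 0.02, -0.01)
  g1 <- update_geometry_with_secondary(q, ml, ms, es = es)
  g_back <- update_geometry_with_secondary(q, ml, ms, es = rep(0, 5))
  expect_equal(g_back$length, g0$length, tolerance = 1e-12)
})

test_that("anterior tibial translation lengthens the hamstrings within a geometric bound", {
  ml <- fx_linkage(); ms <- fx_muscles()
  q <- rep(0, 11); q[10] <- 0.3
  g0 <- compute_muscle_geometry(q, ml, ms)
  g1 <- update_geometry_with_secondary(q, ml, ms, es = c(5, 0, 0, 0, 0))
  hams <- c("semimembranosus", "semitendinosus", "biceps_femoris_long")
  for (h in hams) {
    dl <- g1$length[[h]] - g0$length[[h]]
    expect_gt(dl, 0)
    expect_lt(dl, 5)   # cannot exceed the translation itself
  }
})

test_that("packaged muscle set satisfies its structural invariants", {
  ms <- fx_muscles()
  expect_equal(ms$n, 20L)
  expect_equal(sum(grepl("^gluteus_maximus", ms$name)), 3L)
  expect_true(all(ms$fmax > 0) && all(ms$lopt > 0) && all(ms$lts >= 0))
  segs <- vapply(ms$paths, function(p)
    length(unique(vapply(p, `[[`, character(1), "segment"))), integer(1))
  expect_true(all(segs >= 2 | vapply(ms$paths, length, integer(1)) >= 2))
})
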