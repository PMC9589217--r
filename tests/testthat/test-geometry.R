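# Parametric knee geometry, mesh audit, radial tears and material frames.

test_that("default model has the full body set and the study's contact pairs", {
  km <- fx_knee()
  expect_s3_class(km, "knee_model")
  # three rigid bones
  for (b in c("femur", "tibia", "patella")) expect_false(is.null(km$bodies[[b]]))
  # five cartilage bodies
  carts <- c("femoral_cartilage_medial", "femoral_cartilage_lateral",
             "patellar_cartilage", "medial_tibial_cartilage",
             "lateral_tibial_cartilage")
  for (b in carts) expect_false(is.null(km$bodies[[b]]))
  # two menisci
  expect_false(is.null(km$bodies$medial_meniscus))
  expect_false(is.null(km$bodies$lateral_meniscus))
  expect_setequal(km$contact_pairs, c(
    "femoral_cartilage-medial_meniscus",
    "femoral_cartilage-lateral_meniscus",
    "femoral_cartilage-medial_tibial_cartilage",
    "femoral_cartilage-lateral_tibial_cartilage",
    "femoral_cartilage-patellar_cartilage",
    "medial_meniscus-medial_tibial_cartilage",
    "lateral_meniscus-lateral_tibial_cartilage"))
  expect_true(audit_mesh(km)$ok)
})

test_that("minimal circumferential count still yields positive Jacobians", {
  spec <- knee_geometry_spec(n_circ = 2, n_rad = 2, n_axial = 1)
  km <- build_knee_geometry(spec)
  expect_true(audit_mesh(km)$ok)
})

test_that("doubling all length fields scales node coordinates exactly by two", {
  s1 <- knee_geometry_spec()
  lens <- c("condyle_radius_sagittal", "condyle_radius_frontal",
            "condyle_offset_z", "condyle_clearance", "plateau_half_x",
            "plateau_half_z", "dish_depth", "cartilage_thickness",
            "femoral_cartilage_thickness", "meniscus_r_inner",
            "meniscus_r_outer", "meniscus_h_inner", "meniscus_h_outer",
            "horn_anchor_offset")
  args <- unclass(s1)
  for (f in lens) args[[f]] <- 2 * args[[f]]
  s2 <- do.call(knee_geometry_spec, args)
  k1 <- build_knee_geometry(s1); k2 <- build_knee_geometry(s2)
  for (b in c("medial_meniscus", "lateral_meniscus", "medial_tibial_cartilage")) {
    expect_equal(k2$bodies[[b]]$nodes, 2 * k1$bodies[[b]]$nodes,
                 tolerance = 1e-12)
    expect_identical(k2$bodies[[b]]$elems, k1$bodies[[b]]$elems)
  }
})

test_that("mesh audit passes over a randomized spec sweep", {
  set.seed(7)
  for (rep in 1:8) {
    spec <- knee_geometry_spec(
      condyle_radius_sagittal = runif(1, 28, 42),
      condyle_radius_frontal = runif(1, 18, 30),
      meniscus_r_inner = runif(1, 8, 12),
      meniscus_r_outer = runif(1, 17, 24),
      meniscus_h_inner = runif(1, 0.6, 2),
      meniscus_h_outer = runif(1, 5, 9),
      n_circ = sample(8:16, 1), n_rad = sample(3:7, 1),
      n_axial = sample(1:2, 1))
    km <- build_knee_geometry(spec)
    aud <- audit_mesh(km)
    expect_true(aud$ok)
    expect_gt(aud$min_jacobian, 0)
  }
})

test_that("spec validation names the offending field", {
  expect_error(knee_geometry_spec(cartilage_thickness = -1),
               "cartilage_thickness")
  expect_error(knee_geometry_spec(meniscus_r_inner = 25, meniscus_r_outer = 20),
               "meniscus_r_inner")
  expect_error(knee_geometry_spec(sector_anterior_deg = 50), "partition")
})

test_that("radial tears remove the documented element band and stay connected", {
  km <- fx_knee()
  n0 <- nrow(km$bodies$medial_meniscus$elems)
  nr <- km$spec$n_rad
  for (loc in c("anterior_horn", "midbody", "posterior_horn")) {
    for (w in c(0.33, 0.50, 0.83)) {
      tv <- apply_radial_tear(km, tear_spec(loc, w))
      removed <- n0 - nrow(tv$bodies$medial_meniscus$elems)
      expect_equal(removed, round(w * nr) * km$spec$n_axial)
      expect_equal(mesh_components(tv$bodies$medial_meniscus$elems), 1)
      expect_gt(length(tv$tear_tip$medial_meniscus), 0)
      # horn attachments preserved
      expect_equal(names(tv$horn_springs), names(km$horn_springs))
    }
  }
})

test_that("tear removal is monotone in width and idempotent in count", {
  km <- fx_knee()
  counts <- vapply(c(0.2, 0.33, 0.5, 0.83), function(w)
    nrow(apply_radial_tear(km, tear_spec("midbody", w))$bodies$medial_meniscus$elems),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  t1 <- apply_radial_tear(km, tear_spec("midbody", 0.5))
  t2 <- apply_radial_tear(km, tear_spec("midbody", 0.5))
  expect_identical(t1$bodies$medial_meniscus$elems,
                   t2$bodies$medial_meniscus$elems)
})

test_that("a vanishing removal band leaves the geometry unchanged", {
  km <- fx_knee()
  tv <- apply_radial_tear(km, tear_spec("midbody", 1e-6))
  expect_identical(tv$bodies$medial_meniscus$elems,
                   km$bodies$medial_meniscus$elems)
})

test_that("total meniscectomy removes the body, its pairs and couplings", {
  km <- fx_knee()
  mv <- apply_radial_tear(km, tear_spec(total_meniscectomy = TRUE))
  expect_null(mv$bodies$medial_meniscus)
  expect_false(any(grepl("medial_meniscus", mv$contact_pairs)))
  expect_null(mv$transverse_springs)
  expect_false(any(grepl("^medial_meniscus", names(mv$horn_springs))))
})

test_that("matched-location intact tip elements correspond to the torn tip", {
  km <- fx_knee()
  tear <- tear_spec("midbody", 0.83)
  tv <- apply_radial_tear(km, tear)
  tipm <- matched_tip_elements(km, tear)
  # same spatial centroids
  torn_cen <- colMeans(tv$bodies$medial_meniscus$nodes[
    tv$bodies$medial_meniscus$elems[tv$tear_tip$medial_meniscus[1], ], ])
  intact_cen <- colMeans(km$bodies$medial_meniscus$nodes[
    km$bodies$medial_meniscus$elems[tipm[1], ], ])
  expect_equal(torn_cen, intact_cen, tolerance = 1e-12)
})

test_that("material frames are orthonormal and tangent to the centroid ring", {
  km <- fx_knee()
  for (f in km$frames$medial_meniscus) {
    expect_lt(max(abs(crossprod(f) - diag(3))), 1e-12)
    expect_gt(det(f), 0)
  }
  # element nearest the most anterior point of the annulus: circumferential
  # direction within 1 degree of the mediolateral axis
  men <- km$bodies$medial_meniscus
  cen <- t(vapply(seq_len(nrow(men$elems)), function(e)
    colMeans(men$nodes[men$elems[e, ], ]), numeric(3)))
  ant <- which.max(cen[, 1])
  circ <- km$frames$medial_meniscus[[ant]][, 1]
  ang <- acos(min(1, abs(sum(circ * c(0, 0, 1))))) * 180 / pi
  # the most anterior element centre sits within half an element of the true
  # anterior pole; allow the sector half-width on top of the 1-degree check
  expect_lt(ang, 1 + 0.5 * km$spec$extent_deg / km$spec$n_circ)
})

test_that("frames rotate with the mesh (equivariance about the axial axis)", {
  km <- fx_knee()
  R <- rot_y(0.7)
  km2 <- km
  men <- km2$bodies$medial_meniscus
  men$nodes <- men$nodes %*% t(R)
  men$centre <- drop(R %*% men$centre)
  km2$bodies$medial_meniscus <- men
  km2 <- assign_material_frames(km2)
  for (e in seq_along(km$frames$medial_meniscus)) {
    expect_equal(km2$frames$medial_meniscus[[e]],
                 R %*% km$frames$medial_meniscus[[e]],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("mesh writers emit readable VTK and Abaqus subsets", {
  km <- fx_knee()
  d <- withr::local_tempdir()
  fv <- file.path(d, "m.vtk"); fi <- file.path(d, "m.inp")
  write_vtk_model(km, fv)
  write_inp_model(km, fi)
  v <- readLines(fv)
  expect_identical(v[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^CELLS ", v)))
  n_nodes <- sum(vapply(km$bodies, function(b)
    if (is.null(b)) 0L else nrow(b$nodes), integer(1)))
  expect_identical(v[5], sprintf("POINTS %d double", n_nodes))
  inp <- readLines(fi)
  expect_true(any(grepl("^\\*ELEMENT, TYPE=C3D8", inp)))
  expect_true(any(grepl("^\\*ELEMENT, TYPE=S3", inp)))
})
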