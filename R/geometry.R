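# Parametric knee geometry: a desk-scale, fully synthetic stand-in for
# segmented subject geometry. Rigid bone surfaces (bi-radius condyle caps,
# dished tibial plateau, patellar cap) as triangulated shells; elastic bodies
# (tibial cartilage layers, C-shaped wedge-profile menisci) as 8-node
# hexahedral meshes. Tibia frame throughout: X anterior, Y superior, Z lateral
# (right knee; medial = -Z); plateau rim plane at y = 0, knee center at the
# origin.

#' Specify parametric knee geometry
#'
#' All lengths in mm, angles in degrees. The meniscus is a C-shaped swept
#' wedge: an annulus sector of `extent_deg` centred on each tibial
#' compartment, opening towards the intercondylar notch, partitioned into
#' anterior horn / midbody / posterior horn sectors.
#'
#' @param condyle_radius_sagittal,condyle_radius_frontal condyle cap radii of
#'   curvature (mm).
#' @param condyle_offset_z distance of each condyle (and compartment) centre
#'   from the midline (mm).
#' @param condyle_clearance unloaded gap between the femoral cartilage apex
#'   and the plateau rim plane (mm).
#' @param plateau_half_x,plateau_half_z half-extents of each compartment's
#'   cartilage footprint (mm).
#' @param dish_depth depth of the tibial cartilage dish at the compartment
#'   centre (mm).
#' @param cartilage_thickness tibial cartilage thickness (mm).
#' @param femoral_cartilage_thickness bone-mounted femoral cartilage layer
#'   thickness (mm); enters the contact compliance.
#' @param meniscus_r_inner,meniscus_r_outer inner/outer radii of the meniscus
#'   annulus (mm).
#' @param meniscus_h_inner,meniscus_h_outer wedge heights at the inner and
#'   outer rim (mm).
#' @param extent_deg angular extent of the C (deg).
#' @param sector_anterior_deg,sector_midbody_deg,sector_posterior_deg sector
#'   extents (deg); must sum to `extent_deg`.
#' @param n_circ,n_rad,n_axial meniscus element counts (circumferential,
#'   radial, axial).
#' @param cart_nx,cart_nz,cart_nlayer tibial cartilage element counts.
#' @param horn_anchor_offset arc-length continuation from each horn face to
#'   its tibial anchor nodes (mm).
#' @param horn_E Young's modulus of the horn attachments (MPa).
#' @param transverse_stiffness total anterior transverse ligament stiffness
#'   (N/mm).
#' @return a validated `knee_geometry_spec`.
#' @export
knee_geometry_spec <- function(condyle_radius_sagittal = 35,
                               condyle_radius_frontal = 24,
                               condyle_offset_z = 22,
                               condyle_clearance = 0.2,
                               plateau_half_x = 28,
                               plateau_half_z = 21,
                               dish_depth = 0.3,
                               cartilage_thickness = 2,
                               femoral_cartilage_thickness = 2.2,
                               meniscus_r_inner = 10,
                               meniscus_r_outer = 21,
                               meniscus_h_inner = 0.8,
                               meniscus_h_outer = 7,
                               extent_deg = 300,
                               sector_anterior_deg = 90,
                               sector_midbody_deg = 120,
                               sector_posterior_deg = 90,
                               n_circ = 12, n_rad = 6, n_axial = 1,
                               cart_nx = 8, cart_nz = 8, cart_nlayer = 1,
                               horn_anchor_offset = 8,
                               horn_E = 600,
                               transverse_stiffness = 12.5) {
  spec <- as.list(environment())
  lens <- c("condyle_radius_sagittal", "condyle_radius_frontal",
            "condyle_offset_z", "plateau_half_x", "plateau_half_z",
            "dish_depth", "cartilage_thickness", "femoral_cartilage_thickness",
            "meniscus_r_inner", "meniscus_r_outer", "meniscus_h_inner",
            "meniscus_h_outer", "horn_anchor_offset")
  for (f in lens) check_positive(spec[[f]], f)
  check_nonneg(spec$condyle_clearance, "condyle_clearance")
  check_positive(spec$horn_E, "horn_E")
  check_positive(spec$transverse_stiffness, "transverse_stiffness")
  if (spec$meniscus_r_inner >= spec$meniscus_r_outer) {
    stop("field 'meniscus_r_inner' must be smaller than 'meniscus_r_outer'")
  }
  if (abs(spec$sector_anterior_deg + spec$sector_midbody_deg +
            spec$sector_posterior_deg - spec$extent_deg) > 1e-9) {
    stop("sector extents must partition the annulus: anterior + midbody + posterior = extent_deg")
  }
  for (f in c("n_circ", "n_rad", "n_axial", "cart_nx", "cart_nz", "cart_nlayer")) {
    if (spec[[f]] < 2 && f %in% c("n_circ", "n_rad")) {
      stop(sprintf("field '%s' must be >= 2", f))
    }
    if (spec[[f]] < 1) stop(sprintf("field '%s' must be >= 1", f))
  }
  class(spec) <- "knee_geometry_spec"
  spec
}

# hex8 node ordering: bottom ring counter-clockwise (viewed from +normal),
# then top ring. Structured-grid node index helper.
.grid_idx <- function(i, j, k, ni, nj) {
  (k * (nj + 1) + j) * (ni + 1) + i + 1L
}

# Structured hex block connectivity for an (ni x nj x nk)-element grid.
.hex_block_elems <- function(ni, nj, nk) {
  el <- matrix(0L, ni * nj * nk, 8)
  e <- 0L
  for (k in 0:(nk - 1)) for (j in 0:(nj - 1)) for (i in 0:(ni - 1)) {
    e <- e + 1L
    el[e, ] <- c(.grid_idx(i, j, k, ni, nj), .grid_idx(i + 1, j, k, ni, nj),
                 .grid_idx(i + 1, j + 1, k, ni, nj), .grid_idx(i, j + 1, k, ni, nj),
                 .grid_idx(i, j, k + 1, ni, nj), .grid_idx(i + 1, j, k + 1, ni, nj),
                 .grid_idx(i + 1, j + 1, k + 1, ni, nj), .grid_idx(i, j + 1, k + 1, ni, nj))
  }
  el
}

# One meniscus in "medial convention" (compartment centre at -z, opening
# towards +z); returns nodes, elems, per-element (i, j, k) indices and angle,
# horn face node ids and arc tangents at the two ends.
.build_meniscus <- function(spec) {
  nc <- spec$n_circ; nr <- spec$n_rad; na <- spec$n_axial
  cz <- -spec$condyle_offset_z
  th0 <- 60 * pi / 180                         # anterior horn end
  dth <- -spec$extent_deg * pi / 180           # swept clockwise through medial
  r <- seq(spec$meniscus_r_inner, spec$meniscus_r_outer, length.out = nr + 1)
  h <- spec$meniscus_h_inner +
    (spec$meniscus_h_outer - spec$meniscus_h_inner) *
    (r - spec$meniscus_r_inner) / (spec$meniscus_r_outer - spec$meniscus_r_inner)
  nodes <- matrix(0, (nc + 1) * (nr + 1) * (na + 1), 3)
  for (k in 0:na) for (j in 0:nr) for (i in 0:nc) {
    th <- th0 + dth * i / nc
    y <- h[j + 1] * k / na
    nodes[.grid_idx(i, j, k, nc, nr), ] <-
      c(r[j + 1] * cos(th), y, cz + r[j + 1] * sin(th))
  }
  elems <- .hex_block_elems(nc, nr, na)
  # element (circumferential, radial, axial) indices, 1-based
  ijk <- cbind(rep(rep(1:nc, nr), na), rep(rep(1:nr, each = nc), na),
               rep(1:na, each = nc * nr))
  arc_frac <- (ijk[, 1] - 0.5) / nc           # 0 anterior end -> 1 posterior
  fa <- spec$sector_anterior_deg / spec$extent_deg
  fm <- (spec$sector_anterior_deg + spec$sector_midbody_deg) / spec$extent_deg
  sector <- ifelse(arc_frac < fa, "anterior_horn",
                   ifelse(arc_frac < fm, "midbody", "posterior_horn"))
  horn_faces <- list(
    anterior = unique(as.integer(outer(0:nr, 0:na, function(j, k)
      .grid_idx(0L, j, k, nc, nr)))),
    posterior = unique(as.integer(outer(0:nr, 0:na, function(j, k)
      .grid_idx(nc, j, k, nc, nr)))))
  horn_tangents <- list(
    anterior = c(-sin(th0), 0, cos(th0)) * sign(-dth),   # arc continuation
    posterior = c(-sin(th0 + dth), 0, cos(th0 + dth)) * sign(dth))
  .fix_orientation(list(nodes = nodes, elems = elems, ijk = ijk,
       sector = sector, angle = th0 + dth * (ijk[, 1] - 0.5) / nc,
       centre = c(0, 0, cz), horn_faces = horn_faces,
       horn_tangents = horn_tangents))
}

# Flip hex ordering body-wide if the (structured, uniformly oriented) block
# came out left-handed.
.fix_orientation <- function(body) {
  if (ncol(body$elems) != 8) return(body)
  j <- hex_min_jacobians(body$nodes, body$elems[1, , drop = FALSE])
  if (j <= 0) {
    body$elems <- body$elems[, c(4, 3, 2, 1, 8, 7, 6, 5), drop = FALSE]
  }
  body
}

# Mirror a body in z (medial <-> lateral), restoring element orientation.
.mirror_z <- function(body) {
  body$nodes[, 3] <- -body$nodes[, 3]
  if (ncol(body$elems) == 8) {
    body$elems <- body$elems[, c(4, 3, 2, 1, 8, 7, 6, 5), drop = FALSE]
  } else {
    body$elems <- body$elems[, c(1, 3, 2), drop = FALSE]
  }
  if (!is.null(body$centre)) body$centre[3] <- -body$centre[3]
  body
}

# Tibial cartilage block for one compartment (medial convention, centre -z):
# dished top surface, uniform thickness, base bonded to the tibia.
.build_tibial_cartilage <- function(spec) {
  nx <- spec$cart_nx; nz <- spec$cart_nz; nl <- spec$cart_nlayer
  cz <- -spec$condyle_offset_z
  xs <- seq(-spec$plateau_half_x, spec$plateau_half_x, length.out = nx + 1)
  zs <- seq(cz - spec$plateau_half_z, cz + spec$plateau_half_z, length.out = nz + 1)
  top <- function(x, z) {
    s <- (x / spec$plateau_half_x)^2 + ((z - cz) / spec$plateau_half_z)^2
    -spec$dish_depth * pmax(0, 1 - s)
  }
  nodes <- matrix(0, (nx + 1) * (nz + 1) * (nl + 1), 3)
  for (k in 0:nl) for (j in 0:nz) for (i in 0:nx) {
    yt <- top(xs[i + 1], zs[j + 1])
    y <- yt - spec$cartilage_thickness * (1 - k / nl)
    nodes[.grid_idx(i, j, k, nx, nz), ] <- c(xs[i + 1], y, zs[j + 1])
  }
  elems <- .hex_block_elems(nx, nz, nl)
  base_nodes <- as.integer(outer(0:nx, 0:nz, function(i, j)
    .grid_idx(i, j, 0L, nx, nz)))
  top_nodes <- as.integer(outer(0:nx, 0:nz, function(i, j)
    .grid_idx(i, j, nl, nx, nz)))
  .fix_orientation(list(nodes = nodes, elems = elems, centre = c(0, 0, cz),
       base_nodes = base_nodes, top_nodes = top_nodes))
}

# Triangulated height-function patch (rigid shell).
.tri_patch <- function(xs, zs, yfun, offset = c(0, 0, 0)) {
  ni <- length(xs) - 1; nj <- length(zs) - 1
  nodes <- matrix(0, (ni + 1) * (nj + 1), 3)
  for (j in 0:nj) for (i in 0:ni) {
    nodes[j * (ni + 1) + i + 1, ] <-
      c(xs[i + 1], yfun(xs[i + 1], zs[j + 1]), zs[j + 1]) + offset
  }
  tris <- matrix(0L, 2 * ni * nj, 3)
  t <- 0L
  for (j in 0:(nj - 1)) for (i in 0:(ni - 1)) {
    n1 <- j * (ni + 1) + i + 1L; n2 <- n1 + 1L
    n3 <- n1 + ni + 1L; n4 <- n3 + 1L
    t <- t + 1L; tris[t, ] <- c(n1, n2, n4)
    t <- t + 1L; tris[t, ] <- c(n1, n4, n3)
  }
  list(nodes = nodes, elems = tris)
}

# Femoral condyle lower-surface height function in the femur frame (outer
# cartilage surface; bi-radius cap). Valid near the cap bottom.
condyle_surface_y <- function(x, z, spec, side = c("medial", "lateral")) {
  side <- match.arg(side)
  cz <- if (side == "medial") -spec$condyle_offset_z else spec$condyle_offset_z
  spec$condyle_clearance + .cap_term(x, spec$condyle_radius_sagittal) +
    .cap_term(z - cz, spec$condyle_radius_frontal)
}

# circular-cap sagittal/frontal profile, C1-continued linearly beyond 0.85 R
.cap_term <- function(d, R) {
  cl <- 0.85 * R
  ad <- abs(d)
  inside <- ad <= cl
  y <- numeric(length(d))
  y[inside] <- R - sqrt(R^2 - d[inside]^2)
  slope <- cl / sqrt(R^2 - cl^2)
  y[!inside] <- (R - sqrt(R^2 - cl^2)) + slope * (ad[!inside] - cl)
  y
}

#' @keywords internal
.cap_grad <- function(d, R) {
  cl <- 0.85 * R
  ad <- abs(d)
  g <- numeric(length(d))
  inside <- ad <= cl
  g[inside] <- d[inside] / sqrt(R^2 - d[inside]^2)
  g[!inside] <- sign(d[!inside]) * cl / sqrt(R^2 - cl^2)
  g
}

#' Build the parametric knee model
#'
#' Constructs the rigid bone shells, the five bone-mounted/elastic cartilage
#' bodies, the two menisci with horn attachment and transverse-ligament
#' springs, per-element meniscus material frames, and the contact pair list.
#' Deterministic for a fixed spec.
#'
#' @param spec a `knee_geometry_spec`.
#' @return a `knee_model` list: `bodies` (named meshes), `sector`/`ijk` maps
#'   for the menisci, `frames` (per-element triads), `horn_springs`,
#'   `transverse_springs`, `contact_pairs`, `materials`, `variant`, `spec`.
#' @export
build_knee_geometry <- function(spec = knee_geometry_spec()) {
  stopifnot(inherits(spec, "knee_geometry_spec"))
  med_men <- .build_meniscus(spec)
  lat_men <- .mirror_z(.build_meniscus(spec))
  med_cart <- .build_tibial_cartilage(spec)
  lat_cart <- .mirror_z(.build_tibial_cartilage(spec))
  # lateral mirror also flips the (base/top) node sets ordering only, ids valid
  lat_cart$base_nodes <- med_cart$base_nodes
  lat_cart$top_nodes <- med_cart$top_nodes

  # rigid shells
  Rs <- spec$condyle_radius_sagittal
  xs <- seq(-0.7 * Rs, 0.7 * Rs, length.out = 11)
  femur <- list(med = NULL, lat = NULL)
  zc <- spec$condyle_offset_z
  zr <- spec$condyle_radius_frontal * 0.7
  fem_med <- .tri_patch(xs, seq(-zc - zr, -zc + zr, length.out = 9),
                        function(x, z) condyle_surface_y(x, z, spec, "medial"))
  fem_lat <- .tri_patch(xs, seq(zc - zr, zc + zr, length.out = 9),
                        function(x, z) condyle_surface_y(x, z, spec, "lateral"))
  femur <- list(nodes = rbind(fem_med$nodes, fem_lat$nodes),
                elems = rbind(fem_med$elems, fem_lat$elems + nrow(fem_med$nodes)))
  tib_z <- seq(-zc - spec$plateau_half_z - 5, zc + spec$plateau_half_z + 5,
               length.out = 13)
  tibia <- .tri_patch(seq(-spec$plateau_half_x - 5, spec$plateau_half_x + 5,
                          length.out = 11), tib_z,
                      function(x, z) -spec$cartilage_thickness - spec$dish_depth)
  patella <- .tri_patch(seq(-12, 12, length.out = 5), seq(-14, 14, length.out = 5),
                        function(x, z) sqrt(max(0, 20^2 - x^2 - z^2)) / 4,
                        offset = c(Rs + 12, 10, 0))

  # bone-mounted femoral/patellar cartilage slabs (thin hex layers riding the
  # rigid surfaces; not part of the deformable solve, their compliance enters
  # the contact foundation)
  fc <- function(side) {
    czs <- if (side == "medial") -zc else zc
    nxf <- 8; nzf <- 8
    xs2 <- seq(-0.6 * Rs, 0.6 * Rs, length.out = nxf + 1)
    zs2 <- seq(czs - 0.6 * spec$condyle_radius_frontal,
               czs + 0.6 * spec$condyle_radius_frontal, length.out = nzf + 1)
    nodes <- matrix(0, (nxf + 1) * (nzf + 1) * 2, 3)
    for (k in 0:1) for (j in 0:nzf) for (i in 0:nxf) {
      y <- condyle_surface_y(xs2[i + 1], zs2[j + 1], spec, side) +
        spec$femoral_cartilage_thickness * k
      nodes[.grid_idx(i, j, k, nxf, nzf), ] <- c(xs2[i + 1], y, zs2[j + 1])
    }
    .fix_orientation(list(nodes = nodes, elems = .hex_block_elems(nxf, nzf, 1)))
  }
  pat_cart <- list(nodes = {
    nn <- matrix(0, 25 * 2, 3)
    xs3 <- seq(-10, 10, length.out = 5); zs3 <- seq(-10, 10, length.out = 5)
    for (k in 0:1) for (j in 0:4) for (i in 0:4) {
      nn[.grid_idx(i, j, k, 4L, 4L), ] <-
        c(Rs + 10 - 2 * k, xs3[i + 1] / 4 + 5, zs3[j + 1] / 2)
    }
    nn
  }, elems = .hex_block_elems(4, 4, 1))
  pat_cart <- .fix_orientation(pat_cart)

  bodies <- list(
    femur = femur, tibia = tibia, patella = patella,
    femoral_cartilage_medial = fc("medial"),
    femoral_cartilage_lateral = fc("lateral"),
    patellar_cartilage = pat_cart,
    medial_tibial_cartilage = med_cart,
    lateral_tibial_cartilage = lat_cart,
    medial_meniscus = med_men,
    lateral_meniscus = lat_men)

  contact_pairs <- c(
    "femoral_cartilage-medial_meniscus",
    "femoral_cartilage-lateral_meniscus",
    "femoral_cartilage-medial_tibial_cartilage",
    "femoral_cartilage-lateral_tibial_cartilage",
    "femoral_cartilage-patellar_cartilage",
    "medial_meniscus-medial_tibial_cartilage",
    "lateral_meniscus-lateral_tibial_cartilage")

  model <- structure(list(
    bodies = bodies, spec = spec, variant = "intact",
    contact_pairs = contact_pairs,
    tear_tip = list(medial_meniscus = integer(0)),
    materials = list(cartilage = list(E = 5, nu = 0.46),
                     meniscus = list(E_circ = 140, E_trans = 20,
                                     nu_in = 0.2, nu_out = 0.3,
                                     G_out = 10),
                     friction = 0.04)
  ), class = "knee_model")
  model <- .attach_passive_meshes(model)
  model <- assign_material_frames(model)
  audit <- audit_mesh(model)
  if (!audit$ok) stop(audit$message)
  model
}

# Horn attachment springs (Eq. of the axial-rod reading) and the anterior
# transverse ligament for the current meniscus meshes.
.attach_passive_meshes <- function(model) {
  spec <- model$spec
  area <- (spec$meniscus_h_inner + spec$meniscus_h_outer) / 2 *
    (spec$meniscus_r_outer - spec$meniscus_r_inner)
  springs <- list()
  for (side in c("medial_meniscus", "lateral_meniscus")) {
    men <- model$bodies[[side]]
    if (is.null(men)) next
    for (horn in c("anterior", "posterior")) {
      ids <- men$horn_faces[[horn]]
      hn <- men$nodes[ids, , drop = FALSE]
      tangent <- men$horn_tangents[[horn]]
      if (side == "lateral_meniscus") tangent[3] <- -tangent[3]
      anchors <- sweep(hn, 2, spec$horn_anchor_offset * tangent, `+`)
      anchors[, 2] <- 0   # anchored on the tibial plateau plane
      sp <- build_horn_springs(hn, anchors, E = spec$horn_E, area = area,
                               horn_id = paste(side, horn, sep = "_"))
      sp$node_id <- ids
      sp$body <- side
      springs[[paste(side, horn, sep = "_")]] <- sp
    }
  }
  model$horn_springs <- springs
  if (!is.null(model$bodies$medial_meniscus) &&
      !is.null(model$bodies$lateral_meniscus)) {
    mid <- model$bodies$medial_meniscus$horn_faces$anterior
    lid <- model$bodies$lateral_meniscus$horn_faces$anterior
    n <- min(length(mid), length(lid))
    tr <- build_transverse_ligament(
      model$bodies$medial_meniscus$nodes[mid[1:n], , drop = FALSE],
      model$bodies$lateral_meniscus$nodes[lid[1:n], , drop = FALSE],
      k_total = spec$transverse_stiffness)
    tr$medial_id <- mid[1:n]; tr$lateral_id <- lid[1:n]
    model$transverse_springs <- tr
  } else {
    model$transverse_springs <- NULL
  }
  model
}

#' Assign per-element material frames to the menisci
#'
#' Each meniscus element carries an orthonormal triad (circumferential,
#' radial, axial): the circumferential vector is the tangent of the annulus
#' centroid ring at the element centroid, the axial vector is the global
#' superior direction projected orthogonal to it, and the radial vector
#' completes the right-handed triad.
#'
#' @param model a `knee_model`.
#' @return the model with `frames[[body]]` set (list of 3x3 matrices, columns
#'   circumferential/radial/axial).
#' @export
assign_material_frames <- function(model) {
  model$frames <- model$frames %||% list()
  for (side in c("medial_meniscus", "lateral_meniscus")) {
    men <- model$bodies[[side]]
    if (is.null(men)) next
    frames <- vector("list", nrow(men$elems))
    for (e in seq_len(nrow(men$elems))) {
      cen <- colMeans(men$nodes[men$elems[e, ], , drop = FALSE])
      d <- cen - men$centre
      radial_xz <- c(d[1], 0, d[3])
      if (vnorm(radial_xz) < 1e-9) stop("degenerate meniscus element: zero-length tangent")
      # tangent of the centroid ring: perpendicular to the radial direction in
      # the plateau plane
      circ <- vhat(c(-radial_xz[3], 0, radial_xz[1]))
      axial <- c(0, 1, 0) - sum(c(0, 1, 0) * circ) * circ
      axial <- vhat(axial)
      rad <- cross3(axial, circ)  # completes right-handed (circ, rad, axial)
      frames[[e]] <- cbind(circ = circ, radial = rad, axial = axial)
    }
    model$frames[[side]] <- frames
  }
  model
}

#' Mesh audit: Jacobians, orientation and structural checks
#'
#' Verifies that every hexahedron has a positive Jacobian determinant at all
#' 2x2x2 Gauss points (which also enforces consistent orientation), and that
#' each meniscus is a single face-connected component.
#'
#' @param model a `knee_model`.
#' @return list with `ok` (logical), `message`, and `min_jacobian`.
#' @export
audit_mesh <- function(model) {
  minj <- Inf
  for (nm in names(model$bodies)) {
    b <- model$bodies[[nm]]
    if (is.null(b) || ncol(b$elems) != 8) next
    jd <- hex_min_jacobians(b$nodes, b$elems)
    if (any(jd <= 0)) {
      return(list(ok = FALSE, min_jacobian = min(jd),
                  message = sprintf("inverted element in body '%s' (element %d)",
                                    nm, which.min(jd))))
    }
    minj <- min(minj, min(jd))
  }
  for (nm in c("medial_meniscus", "lateral_meniscus")) {
    b <- model$bodies[[nm]]
    if (is.null(b)) next
    ncomp <- mesh_components(b$elems)
    if (ncomp != 1) {
      return(list(ok = FALSE, min_jacobian = minj,
                  message = sprintf("body '%s' has %d connected components", nm, ncomp)))
    }
  }
  list(ok = TRUE, min_jacobian = minj, message = "mesh audit passed")
}

#' Minimum Jacobian determinant per hexahedral element
#'
#' Trilinear 8-node elements evaluated at the 2x2x2 Gauss points.
#'
#' @param nodes n x 3 node coordinates.
#' @param elems m x 8 connectivity (1-based).
#' @return numeric vector of per-element minimum determinants (mm^3).
#' @export
hex_min_jacobians <- function(nodes, elems) {
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  out <- numeric(nrow(elems))
  for (e in seq_len(nrow(elems))) {
    X <- nodes[elems[e, ], , drop = FALSE]
    dets <- apply(pts, 1, function(p) det(crossprod(.hex_dshape(p), X)))
    out[e] <- min(dets)
  }
  out
}

# shape-function derivatives of the trilinear hex at (xi, eta, zeta): 8 x 3
.hex_dshape <- function(p) {
  xi <- p[1]; eta <- p[2]; ze <- p[3]
  s <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1, -1, 1, -1,
                -1, -1,  1,  1, -1,  1,  1, 1,  1, -1, 1,  1),
              8, 3, byrow = TRUE)
  d <- matrix(0, 8, 3)
  for (a in 1:8) {
    d[a, 1] <- s[a, 1] * (1 + s[a, 2] * eta) * (1 + s[a, 3] * ze) / 8
    d[a, 2] <- s[a, 2] * (1 + s[a, 1] * xi) * (1 + s[a, 3] * ze) / 8
    d[a, 3] <- s[a, 3] * (1 + s[a, 1] * xi) * (1 + s[a, 2] * eta) / 8
  }
  d
}

#' Number of face-connected components of a hex mesh
#'
#' Two elements are adjacent when they share a full quadrilateral face.
#'
#' @param elems m x 8 connectivity.
#' @return integer component count.
#' @export
mesh_components <- function(elems) {
  if (nrow(elems) == 0) return(0L)
  faces <- list(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  keys <- character(0); owner <- integer(0)
  edges <- matrix(0L, 0, 2)
  fk <- new.env(hash = TRUE)
  for (e in seq_len(nrow(elems))) {
    for (f in faces) {
      key <- paste(sort(elems[e, f]), collapse = "-")
      prev <- fk[[key]]
      if (is.null(prev)) fk[[key]] <- e
      else edges <- rbind(edges, c(prev, e))
    }
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(elems) - igraph::vcount(g)))
  igraph::components(g)$no
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("Parametric knee model (variant: %s)\n", x$variant))
  for (nm in names(x$bodies)) {
    b <- x$bodies[[nm]]
    if (is.null(b)) next
    kind <- if (ncol(b$elems) == 8) "hex8" else "tri"
    cat(sprintf("  %-28s %5d nodes %5d %s elements\n", nm, nrow(b$nodes),
                nrow(b$elems), kind))
  }
  cat(sprintf("  %d contact pairs; %d horn spring sets; tear-tip elements: %d\n",
              length(x$contact_pairs), length(x$horn_springs),
              length(x$tear_tip$medial_meniscus)))
  invisible(x)
}
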