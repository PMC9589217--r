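# Right lower-limb linkage: pelvis, thigh, shank, foot (plus a massless
# patella handled through the extensor mechanism). Segment frames are aligned
# with the global frame at the upright reference pose; each segment's origin
# is its proximal joint center. Joint structure: hip 3-DOF spherical,
# tibiofemoral 6-DOF (flexion primary + 5 secondary), patellofemoral 6-DOF
# (resolved by a simplified extensor-mechanism equilibrium), ankle 1-DOF hinge.

#' Build the default right-lower-limb linkage model
#'
#' Segment lengths, masses, centers of mass and radii of gyration are scaled
#' from subject mass and height with standard anthropometric fractions read
#' from the packaged `anthropometry.yaml`; marker placements are segment-local
#' (mm).
#'
#' @param mass subject mass (kg), default 80.
#' @param height subject height (m), default 1.75.
#' @param anthropometry path to the anthropometric fraction YAML.
#' @return a `linkage_model` list: per-segment length (mm), mass (kg), COM
#'   (segment-local mm), inertia tensor (kg mm^2, at COM), joint offsets and
#'   the marker placement map.
#' @export
default_linkage <- function(mass = 80, height = 1.75,
                            anthropometry = kneegait_extdata("anthropometry.yaml")) {
  check_positive(mass, "mass"); check_positive(height, "height")
  an <- yaml::read_yaml(anthropometry)
  H <- height * 1000  # mm

  seg <- function(name) {
    a <- an$segments[[name]]
    len <- a$length_fraction * H
    m <- a$mass_fraction * mass
    com <- c(0, -a$com_fraction * len, 0) + 1000 * unlist(a$com_offset_m %||% list(0,0,0))
    rg <- unlist(a$gyration_fractions) * len      # mm, about COM axes
    I <- diag(m * rg^2)                            # kg mm^2
    if (any(diag(I) <= 0)) stop(sprintf("segment '%s': inertia must be positive", name))
    list(name = name, length = len, mass = m, com = com, inertia = I)
  }
  segments <- list(pelvis = seg("pelvis"), thigh = seg("thigh"),
                   shank = seg("shank"), foot = seg("foot"))

  markers <- lapply(an$markers, function(mk) {
    list(segment = mk$segment, local = as.numeric(unlist(mk$local)))
  })

  structure(list(
    mass = mass, height = height,
    segments = segments,
    hip_offset = c(0, 0, an$hip_offset_z_fraction * H),  # pelvis-local, right hip
    markers = markers,
    dof_names = c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                  "pelvis_rx", "pelvis_ry", "pelvis_rz",
                  "hip_flex", "hip_add", "hip_rot", "knee_flex", "ankle_flex")
  ), class = "linkage_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.linkage_model <- function(x, ...) {
  cat("Right lower-limb linkage model\n")
  cat(sprintf("  subject: %.1f kg, %.2f m\n", x$mass, x$height))
  for (s in x$segments) {
    cat(sprintf("  %-7s length %6.1f mm, mass %5.2f kg\n", s$name, s$length, s$mass))
  }
  cat(sprintf("  %d markers, DOFs: %s\n", length(x$markers),
              paste(x$dof_names, collapse = ", ")))
  invisible(x)
}

#' Forward kinematics of the linkage
#'
#' Maps the 11 primary generalized coordinates to world poses of the pelvis,
#' thigh, shank and foot. Coordinates: pelvis translation (mm) and rotation
#' (rad, Z-X-Y flexion/obliquity/rotation), hip flexion/adduction/internal
#' rotation (rad), knee flexion (rad, flexion positive), ankle dorsiflexion
#' (rad, dorsiflexion positive). An optional knee secondary-kinematics offset
#' `es` (tx, ty, tz in mm; rx varus-valgus, ry internal-external in rad,
#' applied tibia-relative-to-femur at the knee center) repositions the shank
#' and everything distal.
#'
#' @param q numeric vector of length 11 (see `model$dof_names`).
#' @param model a `linkage_model`.
#' @param es optional length-5 secondary-kinematics offset (default zeros).
#' @return list of rigid transforms (world <- segment) per segment, plus world
#'   positions of the hip, knee and ankle centers.
#' @export
forward_kinematics <- function(q, model, es = c(0, 0, 0, 0, 0)) {
  stopifnot(length(q) == 11, length(es) == 5)
  pelvis <- rigid_transform(
    rot_z(q[4]) %*% rot_x(q[5]) %*% rot_y(q[6]), q[1:3])
  hip_w <- apply_transform(pelvis, model$hip_offset)[1, ]
  thigh <- rigid_transform(
    pelvis$R %*% rot_z(q[7]) %*% rot_x(q[8]) %*% rot_y(q[9]), hip_w)
  knee_local <- c(0, -model$segments$thigh$length, 0)
  knee_w <- apply_transform(thigh, knee_local)[1, ]
  # knee flexion positive rotates the shank posteriorly (about -Z)
  R_knee <- rot_z(-q[10])
  # secondary kinematics: tibia relative to femur at the knee center
  R_es <- rot_x(es[4]) %*% rot_y(es[5])
  shank <- rigid_transform(thigh$R %*% R_knee %*% R_es,
                           knee_w + drop(thigh$R %*% R_knee %*% es[1:3]))
  ankle_local <- c(0, -model$segments$shank$length, 0)
  ankle_w <- apply_transform(shank, ankle_local)[1, ]
  foot <- rigid_transform(shank$R %*% rot_z(q[11]), ankle_w)
  list(pelvis = pelvis, thigh = thigh, shank = shank, foot = foot,
       hip = hip_w, knee = knee_w, ankle = ankle_w)
}

#' World marker positions for a pose
#'
#' @inheritParams forward_kinematics
#' @return matrix (n_markers x 3, mm) with marker names as rownames.
#' @export
marker_positions <- function(q, model, es = c(0, 0, 0, 0, 0)) {
  fk <- forward_kinematics(q, model, es)
  out <- t(vapply(model$markers, function(mk) {
    apply_transform(fk[[mk$segment]], mk$local)[1, ]
  }, numeric(3)))
  rownames(out) <- names(model$markers)
  out
}
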