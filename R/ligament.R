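# Passive structures of the tibiofemoral joint: nonlinear ligament bundles,
# meniscal horn attachment springs and the anterior transverse ligament.

# Canonical ligament stiffness table (N mm^-2 for the quadratic toe region k1,
# N mm^-1 for the linear region k2). The packaged YAML is validated against
# these values at load time.
.ligament_table <- data.frame(
  ligament = c("ACL", "ACL", "PCL", "PCL", "MCL", "MCL", "MCL",
               "PMC", "LCL", "ALS", "OPL"),
  bundle   = c("anterior", "posterior", "anterior", "posterior",
               "anterior", "oblique", "deep", "main", "main", "main", "main"),
  count    = c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 3L, 3L, 3L, 3L),
  k1       = c(22.48, 26.27, 31.26, 19.29, 10.00, 5.00, 5.00,
               12.00, 10.00, 5.00, 3.00),
  k2       = c(83.15, 83.15, 125.00, 60.00, 91.25, 27.86, 21.07,
               52.59, 72.22, 19.00, 21.42),
  stringsAsFactors = FALSE
)

#' Tension-only nonlinear ligament bundle force
#'
#' Piecewise force-strain law for a one-dimensional ligament bundle: zero in
#' compression, quadratic in elongation through the toe region
#' (strain up to `2 * eps_l`), linear beyond it. With strain
#' `eps = (l - l0) / l0`:
#' \itemize{
#'   \item `f = 0` for `eps <= 0`
#'   \item `f = k1 * (l - l0)^2` for `0 < eps <= 2 * eps_l`
#'   \item `f = k2 * (l - (1 + eps_l) * l0)` for `eps > 2 * eps_l`
#' }
#'
#' @param l current bundle length (mm); may be a vector.
#' @param l0 slack length (mm).
#' @param k1 toe-region stiffness (N mm^-2).
#' @param k2 linear-region stiffness (N mm^-1).
#' @param eps_l reference strain constant separating the regions (default 0.03).
#' @return tensile force (N), same length as `l`.
#' @export
ligament_force <- function(l, l0, k1, k2, eps_l = 0.03) {
  check_positive(l0, "l0"); check_positive(k1, "k1"); check_positive(k2, "k2")
  stopifnot(all(l > 0))
  eps <- (l - l0) / l0
  f <- numeric(length(l))
  toe <- eps > 0 & eps <= 2 * eps_l
  lin <- eps > 2 * eps_l
  f[toe] <- k1 * (l[toe] - l0)^2
  f[lin] <- k2 * (l[lin] - (1 + eps_l) * l0)
  f
}

#' Force discontinuity of the ligament law at the toe/linear transition
#'
#' The two branches need not match at `eps = 2 * eps_l` for arbitrary
#' stiffness constants; the jump is reported, never smoothed away.
#'
#' @inheritParams ligament_force
#' @return signed jump (N): linear-branch limit minus toe-branch limit.
#' @export
ligament_force_jump <- function(l0, k1, k2, eps_l = 0.03) {
  lt <- (1 + 2 * eps_l) * l0
  k2 * (lt - (1 + eps_l) * l0) - k1 * (lt - l0)^2
}

#' Load and validate the packaged ligament parameter set
#'
#' Reads the ligament YAML (stiffness constants plus femoral/tibial attachment
#' coordinates per bundle element) and validates every `k1`/`k2` against the
#' canonical stiffness table compiled into the package.
#'
#' @param path YAML file; defaults to the packaged parameter set.
#' @return data frame with one row per bundle spring element: `ligament`,
#'   `bundle`, `element`, `k1`, `k2`, `eps_l`, `ref_strain`, femoral attachment
#'   `fx, fy, fz` and tibial attachment `tx, ty, tz` (mm, tibia frame at the
#'   full-extension reference pose).
#' @export
load_ligament_params <- function(path = kneegait_extdata("ligaments.yaml")) {
  raw <- yaml::read_yaml(path)
  rows <- list()
  for (lig in raw$ligaments) {
    key <- paste(lig$ligament, lig$bundle)
    ref <- .ligament_table[paste(.ligament_table$ligament,
                                 .ligament_table$bundle) == key, ]
    if (nrow(ref) != 1) {
      stop(sprintf("unknown ligament bundle '%s' in %s", key, path))
    }
    if (abs(lig$k1 - ref$k1) > 1e-9 || abs(lig$k2 - ref$k2) > 1e-9) {
      stop(sprintf("stiffness for '%s' in %s does not match the canonical table",
                   key, path))
    }
    if (length(lig$elements) != ref$count) {
      stop(sprintf("'%s' must have %d bundle elements", key, ref$count))
    }
    for (i in seq_along(lig$elements)) {
      el <- lig$elements[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        ligament = lig$ligament, bundle = lig$bundle, element = i,
        k1 = lig$k1, k2 = lig$k2,
        eps_l = if (is.null(lig$eps_l)) 0.03 else lig$eps_l,
        ref_strain = if (is.null(el$ref_strain)) 0 else el$ref_strain,
        fx = el$femur[1], fy = el$femur[2], fz = el$femur[3],
        tx = el$tibia[1], ty = el$tibia[2], tz = el$tibia[3],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibrate ligament slack lengths at a reference pose
#'
#' Slack lengths are not observable from geometry alone; each bundle is
#' assigned the slack length that produces its configured reference strain at
#' the full-extension reference pose (`femur_pose`). A reference strain of 0
#' makes the bundle exactly slack there.
#'
#' @param params data frame from [load_ligament_params()].
#' @param femur_pose rigid transform of the femur relative to the tibia at the
#'   reference pose (default identity).
#' @return `params` with an added `l0` column (mm).
#' @export
calibrate_slack_lengths <- function(params, femur_pose = rigid_transform()) {
  fem <- apply_transform(femur_pose, as.matrix(params[, c("fx", "fy", "fz")]))
  tib <- as.matrix(params[, c("tx", "ty", "tz")])
  len <- sqrt(rowSums((fem - tib)^2))
  params$l0 <- len / (1 + params$ref_strain)
  params
}

#' Build meniscal horn attachment springs
#'
#' Each meniscal horn is anchored to the tibia by `n_h` linear springs joining
#' horn-face nodes to tibial attachment nodes. Per spring,
#' `k_hp = E * a_h / (n_h * l_hp)` with `l_hp` the node-pair distance, so the
#' parallel assembly reproduces the axial stiffness `E * a_h / l` of a uniform
#' rod of the horn's face area.
#'
#' @param horn_nodes n x 3 matrix of horn-face node coordinates (mm).
#' @param tibia_nodes n x 3 matrix of paired tibial attachment nodes (mm).
#' @param E Young's modulus of the horn attachment (MPa).
#' @param area horn face area (mm^2).
#' @param horn_id identifier carried through to the output.
#' @return data frame with one spring per row: node index, paired coordinates,
#'   rest length `l` (mm) and stiffness `k` (N mm^-1).
#' @export
build_horn_springs <- function(horn_nodes, tibia_nodes, E, area,
                               horn_id = "horn") {
  check_positive(E, "E"); check_positive(area, "area")
  horn_nodes <- as.matrix(horn_nodes); tibia_nodes <- as.matrix(tibia_nodes)
  stopifnot(ncol(horn_nodes) == 3, all(dim(horn_nodes) == dim(tibia_nodes)))
  n <- nrow(horn_nodes)
  if (n < 1) stop("a horn attachment needs at least one spring")
  l <- sqrt(rowSums((horn_nodes - tibia_nodes)^2))
  if (any(l < 1e-9)) stop("zero-length horn attachment spring")
  data.frame(horn = horn_id, node = seq_len(n),
             hx = horn_nodes[, 1], hy = horn_nodes[, 2], hz = horn_nodes[, 3],
             tx = tibia_nodes[, 1], ty = tibia_nodes[, 2], tz = tibia_nodes[, 3],
             l = l, k = E * area / (n * l), stringsAsFactors = FALSE)
}

#' Build transverse ligament springs between the meniscal anterior horns
#'
#' The anterior transverse ligament joining the anterior margins of the two
#' menisci is modeled as `n` parallel linear springs whose total stiffness is
#' `k_total` (default 12.5 N/mm).
#'
#' @param medial_nodes,lateral_nodes n x 3 matrices of paired endpoint nodes.
#' @param k_total total spring-set stiffness (N mm^-1).
#' @return data frame of springs with per-spring stiffness `k_total / n`.
#' @export
build_transverse_ligament <- function(medial_nodes, lateral_nodes,
                                      k_total = 12.5) {
  check_positive(k_total, "k_total")
  medial_nodes <- as.matrix(medial_nodes); lateral_nodes <- as.matrix(lateral_nodes)
  stopifnot(all(dim(medial_nodes) == dim(lateral_nodes)))
  n <- nrow(medial_nodes)
  data.frame(node = seq_len(n),
             mx = medial_nodes[, 1], my = medial_nodes[, 2], mz = medial_nodes[, 3],
             lx = lateral_nodes[, 1], ly = lateral_nodes[, 2], lz = lateral_nodes[, 3],
             k = k_total / n, stringsAsFactors = FALSE)
}

#' Aggregate ligament forces into a wrench on the tibia (and femur)
#'
#' Evaluates every calibrated bundle at the given femur pose and sums the
#' tension-only forces into a resultant force and moment about `about` on the
#' tibia; the femur wrench is equal and opposite.
#'
#' @param params calibrated ligament data frame (with `l0`).
#' @param femur_pose rigid transform of the femur relative to the tibia.
#' @param about point (mm) about which moments are taken (default knee center
#'   at the origin).
#' @return list with `force_tibia`, `moment_tibia`, `force_femur`,
#'   `moment_femur` (N, N mm) and the per-bundle `forces` vector (N).
#' @export
passive_wrench <- function(params, femur_pose = rigid_transform(),
                           about = c(0, 0, 0)) {
  fem <- apply_transform(femur_pose, as.matrix(params[, c("fx", "fy", "fz")]))
  tib <- as.matrix(params[, c("tx", "ty", "tz")])
  d <- fem - tib
  len <- sqrt(rowSums(d^2))
  f <- vapply(seq_len(nrow(params)), function(i) {
    ligament_force(len[i], params$l0[i], params$k1[i], params$k2[i],
                   params$eps_l[i])
  }, numeric(1))
  ft <- c(0, 0, 0); mt <- c(0, 0, 0)
  for (i in seq_len(nrow(params))) {
    if (f[i] <= 0) next
    u <- unname(d[i, ] / len[i])    # pulls the tibial insertion toward the femur
    fi <- f[i] * u
    ft <- ft + fi
    mt <- mt + cross3(unname(tib[i, ]) - about, fi)
  }
  # two-point tension elements: the femur-side wrench about the same point is
  # the exact negation (the line of action joins the two attachments)
  list(force_tibia = ft, moment_tibia = mt,
       force_femur = -ft, moment_femur = -mt,
       forces = f, lengths = len)
}
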