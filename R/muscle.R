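# Hill-type muscle units with path wrapping and tendon-excursion moment arms.
# Rigid tendon, no force-velocity term: forces are resolved per time point by
# static optimization, so only the force-length properties matter.

#' Normalized active force-length curve
#'
#' Gaussian active curve centered at optimal fiber length (width 0.45).
#'
#' @param lnorm normalized fiber length (dimensionless).
#' @return normalized active force scale in [0, 1].
#' @export
active_force_length <- function(lnorm) {
  exp(-((lnorm - 1) / 0.45)^2)
}

#' Normalized passive force-length curve
#'
#' Exponential passive curve, zero at and below optimal length, reaching 1 at
#' a passive strain of `e0` (default 0.6).
#'
#' @param lnorm normalized fiber length.
#' @param kpe exponential shape factor (default 4).
#' @param e0 passive strain at which the normalized force reaches 1.
#' @return normalized passive force (>= 0).
#' @export
passive_force_length <- function(lnorm, kpe = 4, e0 = 0.6) {
  ifelse(lnorm <= 1, 0,
         (exp(kpe * (lnorm - 1) / e0) - 1) / (exp(kpe) - 1))
}

#' Hill-type muscle force (rigid tendon, no velocity term)
#'
#' `force = fmax * (a * f_active(lnorm) + f_passive(lnorm))`; monotone
#' non-decreasing in activation.
#'
#' @param muscle one row of a muscle set (list with `fmax`).
#' @param activation activation in [0, 1].
#' @param lnorm normalized fiber length (> 0).
#' @return force (N).
#' @export
hill_force <- function(muscle, activation, lnorm) {
  stopifnot(all(activation >= 0 & activation <= 1), all(lnorm > 0))
  muscle$fmax * (activation * active_force_length(lnorm) +
                   passive_force_length(lnorm))
}

#' Normalized fiber length under the rigid-tendon assumption
#'
#' `(path length - tendon slack length) / optimal fiber length`, floored at
#' 0.01 (a fiber cannot invert; paths shorter than the tendon slack length
#' leave the fiber maximally shortened).
#'
#' @param muscles a `muscle_set`.
#' @param length muscle-tendon path lengths (mm), one per muscle.
#' @return normalized fiber lengths (dimensionless).
#' @export
normalized_fiber_length <- function(muscles, length) {
  pmax((length - muscles$lts) / muscles$lopt, 0.01)
}

#' Load the packaged 20-muscle parameter set
#'
#' Reads the muscle YAML and calibrates tendon slack lengths flagged `auto` so
#' fibers sit at optimal length in the upright reference pose of `model`.
#'
#' @param model a `linkage_model` (for the reference-pose calibration).
#' @param path muscle YAML file.
#' @return a `muscle_set` list: `name`, `fmax` (N), `lopt` (mm), `lts` (mm),
#'   `paths` (per-muscle path point list), `wraps` (per-muscle wrap spec or
#'   NULL), `n`.
#' @export
load_muscle_set <- function(model,
                            path = kneegait_extdata("muscles_20.yaml")) {
  raw <- yaml::read_yaml(path)$muscles
  n <- length(raw)
  name <- vapply(raw, `[[`, character(1), "name")
  fmax <- vapply(raw, `[[`, numeric(1), "fmax")
  lopt <- vapply(raw, `[[`, numeric(1), "lopt")
  if (any(fmax <= 0) || any(lopt <= 0)) stop("muscle force parameters must be > 0")
  paths <- lapply(raw, function(m) {
    lapply(m$path, function(p) list(segment = p$segment,
                                    local = as.numeric(unlist(p$local))))
  })
  segcount <- vapply(paths, function(pp)
    length(unique(vapply(pp, `[[`, character(1), "segment"))), integer(1))
  if (any(lengths(paths) < 2) || any(segcount < 2)) {
    stop("every muscle needs >= 2 path points spanning >= 2 segments")
  }
  wraps <- lapply(raw, function(m) {
    if (is.null(m$wrap)) return(NULL)
    list(segment = m$wrap$segment,
         center = as.numeric(unlist(m$wrap$center)),
         axis = vhat(as.numeric(unlist(m$wrap$axis))),
         radius = m$wrap$radius,
         pair = m$wrap_pair)
  })
  ref_lnorm <- vapply(raw, function(m) {
    if (is.null(m$ref_lnorm)) 1 else as.numeric(m$ref_lnorm)
  }, numeric(1))
  ms <- list(name = name, fmax = fmax, lopt = lopt, lts = rep(0, n),
             ref_lnorm = ref_lnorm, paths = paths, wraps = wraps, n = n)
  ms <- .index_paths(ms)
  class(ms) <- "muscle_set"
  # tendon slack calibration: fibers sit at ref_lnorm * lopt in the upright
  # reference pose
  ref_len <- .muscle_path_lengths(rep(0, 11), model, ms)
  lts_raw <- vapply(raw, function(m) {
    if (identical(m$lts, "auto")) NA_real_ else as.numeric(m$lts)
  }, numeric(1))
  ms$lts <- ifelse(is.na(lts_raw), ref_len - ref_lnorm * lopt, lts_raw)
  if (any(ms$lts < 0)) stop("calibrated tendon slack length is negative")
  ms
}

#' @export
print.muscle_set <- function(x, ...) {
  cat(sprintf("Muscle set: %d Hill-type units (rigid tendon)\n", x$n))
  cat(sprintf("  total Fmax %.0f N; %d with wrapping surfaces\n",
              sum(x$fmax), sum(!vapply(x$wraps, is.null, logical(1)))))
  invisible(x)
}

# Precompute flat point/pair indexing for vectorized path-length evaluation.
.index_paths <- function(ms) {
  seg <- character(0); loc <- NULL
  pair_a <- integer(0); pair_b <- integer(0); pair_m <- integer(0)
  pair_wrap <- integer(0)   # 0 = straight, else index into wrap list
  off <- 0L
  for (m in seq_len(ms$n)) {
    pp <- ms$paths[[m]]
    k <- length(pp)
    seg <- c(seg, vapply(pp, `[[`, character(1), "segment"))
    loc <- rbind(loc, t(vapply(pp, `[[`, numeric(3), "local")))
    wr <- ms$wraps[[m]]
    for (j in seq_len(k - 1)) {
      pair_a <- c(pair_a, off + j); pair_b <- c(pair_b, off + j + 1L)
      pair_m <- c(pair_m, m)
      pair_wrap <- c(pair_wrap, if (!is.null(wr) && wr$pair == j) m else 0L)
    }
    off <- off + k
  }
  ms$flat <- list(seg = seg, loc = loc, pair_a = pair_a, pair_b = pair_b,
                  pair_m = pair_m, pair_wrap = pair_wrap,
                  by_seg = split(seq_along(seg), seg))
  ms
}

# Length of one possibly-wrapped path segment between world points a and b
# against a cylinder (world-frame center point on the axis, unit axis, radius).
.segment_length_wrapped <- function(a, b, center, axis, radius, muscle = "") {
  pa <- a - center; pb <- b - center
  za <- sum(pa * axis); zb <- sum(pb * axis)
  va <- pa - za * axis; vb <- pb - zb * axis
  da <- vnorm(va); db <- vnorm(vb)
  if (da < radius || db < radius) {
    stop(sprintf("muscle '%s': path point inside its wrapping cylinder", muscle))
  }
  # 2D minimum distance from the axis to the chord in the transverse plane
  d2 <- vb - va
  tt <- if (sum(d2 * d2) < 1e-14) 0 else
    max(0, min(1, -sum(va * d2) / sum(d2 * d2)))
  dmin <- vnorm(va + tt * d2)
  if (dmin >= radius) return(vnorm(b - a))
  phi <- acos(max(-1, min(1, sum(va * vb) / (da * db))))
  theta <- phi - acos(radius / da) - acos(radius / db)
  if (theta < 0) return(vnorm(b - a))
  l2d <- sqrt(da^2 - radius^2) + radius * theta + sqrt(db^2 - radius^2)
  sqrt(l2d^2 + (zb - za)^2)
}

# Path lengths of every muscle at pose q (optionally with knee secondary
# kinematics es); vectorized over all path points grouped by host segment,
# with the few wrapped pairs handled individually.
.muscle_path_lengths <- function(q, model, muscles, es = c(0, 0, 0, 0, 0)) {
  fk <- forward_kinematics(q, model, es)
  fl <- muscles$flat
  if (is.null(fl)) {
    muscles <- .index_paths(muscles)
    fl <- muscles$flat
  }
  W <- matrix(0, nrow(fl$loc), 3)
  for (sn in names(fl$by_seg)) {
    idx <- fl$by_seg[[sn]]
    W[idx, ] <- apply_transform(fk[[sn]], fl$loc[idx, , drop = FALSE])
  }
  d <- W[fl$pair_b, , drop = FALSE] - W[fl$pair_a, , drop = FALSE]
  seg_len <- sqrt(rowSums(d^2))
  wrapped <- which(fl$pair_wrap > 0L)
  for (w in wrapped) {
    m <- fl$pair_wrap[w]
    wr <- muscles$wraps[[m]]
    cw <- apply_transform(fk[[wr$segment]], wr$center)[1, ]
    aw <- drop(fk[[wr$segment]]$R %*% wr$axis)
    seg_len[w] <- .segment_length_wrapped(W[fl$pair_a[w], ], W[fl$pair_b[w], ],
                                          cw, aw, wr$radius, muscles$name[m])
  }
  as.numeric(tapply(seg_len, fl$pair_m, sum)[as.character(seq_len(muscles$n))])
}

#' Muscle geometry (lengths and moment arms) at a pose
#'
#' Path lengths through via points with cylinder wrapping
#' (tangent-arc-tangent construction when a straight segment penetrates its
#' cylinder), and per-DOF moment arms by the tendon-excursion method:
#' `r = -dL/dq`, central difference.
#'
#' @param q length-11 generalized coordinate vector.
#' @param model a `linkage_model`.
#' @param muscles a `muscle_set`.
#' @param es knee secondary kinematics (tx, ty, tz mm; varus-valgus,
#'   internal-external rad), default zeros.
#' @param h finite-difference step (rad), default 1e-5.
#' @return a `muscle_geometry` list: `length` (mm), `moment_arms`
#'   (n x 5, mm, columns hip_flex/hip_add/hip_rot/knee_flex/ankle_flex) and
#'   `knee_lines` (per knee-crossing muscle: application point on the
#'   tibia-side body and pull direction toward the femur side, world frame).
#' @export
compute_muscle_geometry <- function(q, model, muscles, es = c(0, 0, 0, 0, 0),
                                    h = 1e-5) {
  dof_idx <- c(hip_flex = 7L, hip_add = 8L, hip_rot = 9L, knee_flex = 10L,
               ankle_flex = 11L)
  len <- .muscle_path_lengths(q, model, muscles, es)
  if (any(len <= 0)) stop("non-positive muscle path length")
  arms <- matrix(0, muscles$n, length(dof_idx),
                 dimnames = list(muscles$name, names(dof_idx)))
  for (d in seq_along(dof_idx)) {
    qp <- q; qp[dof_idx[d]] <- qp[dof_idx[d]] + h
    qm <- q; qm[dof_idx[d]] <- qm[dof_idx[d]] - h
    lp <- .muscle_path_lengths(qp, model, muscles, es)
    lm <- .muscle_path_lengths(qm, model, muscles, es)
    arms[, d] <- -(lp - lm) / (2 * h)
  }

  # lines of action of knee-crossing path segments (for the contact solve):
  # force applied on the tibia-side body at its attachment, pulling toward the
  # femur-side point
  fk <- forward_kinematics(q, model, es)
  tibia_side <- c("shank", "foot")
  knee_lines <- list()
  for (m in seq_len(muscles$n)) {
    pp <- muscles$paths[[m]]
    segs <- vapply(pp, `[[`, character(1), "segment")
    for (k in seq_len(length(pp) - 1)) {
      crosses <- (segs[k] %in% c("pelvis", "thigh")) &&
        (segs[k + 1] %in% tibia_side)
      if (!crosses) next
      a <- apply_transform(fk[[segs[k]]], pp[[k]]$local)[1, ]
      b <- apply_transform(fk[[segs[k + 1]]], pp[[k + 1]]$local)[1, ]
      knee_lines[[muscles$name[m]]] <- list(point = b, dir = vhat(a - b))
    }
  }
  structure(list(length = stats::setNames(len, muscles$name),
                 moment_arms = arms, knee_lines = knee_lines,
                 q = q, es = es),
            class = "muscle_geometry")
}

#' Recompute muscle geometry with updated knee secondary kinematics
#'
#' Pure function of its inputs: repositions the tibia (and everything distal)
#' by the secondary kinematics `es` and re-derives all muscle lengths and
#' moment arms. With `es = 0` the result equals the primary-only geometry.
#'
#' @inheritParams compute_muscle_geometry
#' @return a `muscle_geometry` (see [compute_muscle_geometry()]).
#' @export
update_geometry_with_secondary <- function(q, model, muscles, es) {
  compute_muscle_geometry(q, model, muscles, es = es)
}
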