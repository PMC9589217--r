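# Quasi-static deformable knee contact. Deformable bodies (two menisci as one
# coupled system with horn and transverse-ligament springs; the two tibial
# cartilage layers with bonded bases) contact bone-mounted rigid surfaces by
# a node-to-surface penalty with regularized Coulomb friction. The femoral
# condyle surface is the parametric bi-radius cap (flexion-invariant, so the
# femur pose in the contact solve is the 5-DOF secondary-kinematics offset);
# bone-mounted cartilage compliance enters as an elastic foundation in series
# with the numerical penalty. The five knee secondary DOFs are driven to
# quasi-static equilibrium of the contact + ligament wrench against the
# applied tibiofemoral load.

#' Contact solver settings
#'
#' @param penalty_num numerical penalty stiffness per unit area (N/mm^3)
#'   placed in series with the cartilage foundation stiffness.
#' @param slip_tol friction regularization slip tolerance (mm).
#' @param newton_tol inner (elastic) Newton displacement tolerance (mm).
#' @param newton_max inner Newton iteration cap.
#' @param es_tol_force,es_tol_moment secondary-kinematics equilibrium
#'   tolerances (N, N mm).
#' @param es_max outer Newton iteration cap.
#' @return settings list.
#' @export
contact_settings <- function(penalty_num = 50, slip_tol = 0.2,
                             newton_tol = 3e-4, newton_max = 40,
                             es_tol_force = 5, es_tol_moment = 250,
                             es_max = 100) {
  as.list(environment())
}

# Tributary node areas of a structured quad sheet given its faces (n x 4).
.node_areas <- function(nodes, faces) {
  A <- numeric(nrow(nodes))
  for (f in seq_len(nrow(faces))) {
    q <- nodes[faces[f, ], , drop = FALSE]
    a <- 0.5 * vnorm(cross3(q[3, ] - q[1, ], q[4, ] - q[2, ]))
    A[faces[f, ]] <- A[faces[f, ]] + a / 4
  }
  A
}

# Quad faces of the k = const sheet of a structured block.
.sheet_faces <- function(ni, nj, k) {
  fs <- matrix(0L, ni * nj, 4)
  f <- 0L
  for (j in 0:(nj - 1)) for (i in 0:(ni - 1)) {
    f <- f + 1L
    fs[f, ] <- c(.grid_idx(i, j, k, ni, nj), .grid_idx(i + 1, j, k, ni, nj),
                 .grid_idx(i + 1, j + 1, k, ni, nj), .grid_idx(i, j + 1, k, ni, nj))
  }
  fs
}

#' Precompute the contact system for a knee model variant
#'
#' Assembles and caches everything reused across contact solves: body
#' stiffness matrices (with grounded horn/foundation springs), contact node
#' sets with tributary areas, effective penalty stiffnesses and calibrated
#' ligaments.
#'
#' @param model a `knee_model`.
#' @param settings from [contact_settings()].
#' @param ligaments calibrated ligament table; default loads and calibrates
#'   the packaged set at the full-extension reference pose.
#' @return a `contact_system` list.
#' @export
contact_system <- function(model, settings = contact_settings(),
                           ligaments = NULL) {
  spec <- model$spec
  mats <- model$materials
  E_conf <- mats$cartilage$E * (1 - mats$cartilage$nu) /
    ((1 + mats$cartilage$nu) * (1 - 2 * mats$cartilage$nu))
  k_found_fem <- 1 / (spec$femoral_cartilage_thickness / E_conf +
                        1 / settings$penalty_num)
  k_found_tib <- 1 / (spec$cartilage_thickness / E_conf +
                        1 / settings$penalty_num)
  a_c <- c(0, spec$condyle_clearance + spec$condyle_radius_sagittal, 0)

  sys <- list(model = model, settings = settings, a_c = a_c,
              mu = mats$friction, bodies = list())

  # --- menisci system (both menisci, coupled) ---
  men_sides <- intersect(c("medial_meniscus", "lateral_meniscus"),
                         names(model$bodies))
  men_sides <- men_sides[!vapply(men_sides, function(s)
    is.null(model$bodies[[s]]), logical(1))]
  if (length(men_sides)) {
    offs <- c(0L); nodes <- NULL; Ks <- list()
    top <- list(); bottom <- list()
    for (s in men_sides) {
      b <- model$bodies[[s]]
      Ks[[s]] <- assemble_elasticity(b, .meniscus_D_elems(model, s), bbar = FALSE)
      offs <- c(offs, offs[length(offs)] + nrow(b$nodes))
      nodes <- rbind(nodes, b$nodes)
    }
    names(offs) <- c(men_sides, "end")
    K <- Matrix::bdiag(Ks)
    # horn springs (to ground) and transverse ligament (coupling)
    trips <- list(i = integer(0), j = integer(0), x = numeric(0))
    add_spring <- function(trips, d1, d2, k, dir) {
      # spring along unit dir between dof sets (d2 = NULL -> grounded)
      Kl <- k * outer(dir, dir)
      for (p in 1:3) for (q in 1:3) {
        trips$i <- c(trips$i, d1[p]); trips$j <- c(trips$j, d1[q])
        trips$x <- c(trips$x, Kl[p, q])
        if (!is.null(d2)) {
          trips$i <- c(trips$i, d2[p], d1[p], d2[p])
          trips$j <- c(trips$j, d2[q], d2[q], d1[q])
          trips$x <- c(trips$x, Kl[p, q], -Kl[p, q], -Kl[p, q])
        }
      }
      trips
    }
    for (hn in names(model$horn_springs)) {
      sp <- model$horn_springs[[hn]]
      off <- offs[[sp$body[1]]]
      for (r in seq_len(nrow(sp))) {
        dir <- vhat(c(sp$hx[r] - sp$tx[r], sp$hy[r] - sp$ty[r],
                      sp$hz[r] - sp$tz[r]))
        d1 <- 3 * (off + sp$node_id[r] - 1) + 1:3
        trips <- add_spring(trips, d1, NULL, sp$k[r], dir)
      }
    }
    tr <- model$transverse_springs
    if (!is.null(tr) && all(c("medial_meniscus", "lateral_meniscus") %in% men_sides)) {
      for (r in seq_len(nrow(tr))) {
        dir <- vhat(c(tr$mx[r] - tr$lx[r], tr$my[r] - tr$ly[r],
                      tr$mz[r] - tr$lz[r]))
        d1 <- 3 * (offs[["medial_meniscus"]] + tr$medial_id[r] - 1) + 1:3
        d2 <- 3 * (offs[["lateral_meniscus"]] + tr$lateral_id[r] - 1) + 1:3
        trips <- add_spring(trips, d1, d2, tr$k[r], dir)
      }
    }
    if (length(trips$i)) {
      K <- K + Matrix::sparseMatrix(i = trips$i, j = trips$j, x = trips$x,
                                    dims = dim(K))
    }
    # contact node sets: top sheet vs femur, bottom sheet vs plateau
    for (s in men_sides) {
      b <- model$bodies[[s]]
      nc <- spec$n_circ; nr <- spec$n_rad; na <- spec$n_axial
      fs_top <- .sheet_faces(nc, nr, na)
      fs_bot <- .sheet_faces(nc, nr, 0L)
      # keep only faces whose elements survived tearing
      keep_cols <- unique(b$ijk[, 1] + (b$ijk[, 2] - 1) * nc)
      all_cols <- rep(1:nc, nr) + (rep(1:nr, each = nc) - 1) * nc
      fs_top <- fs_top[all_cols %in% keep_cols, , drop = FALSE]
      fs_bot <- fs_bot[all_cols %in% keep_cols, , drop = FALSE]
      A_top <- .node_areas(b$nodes, fs_top)
      A_bot <- .node_areas(b$nodes, fs_bot)
      side <- if (s == "medial_meniscus") "medial" else "lateral"
      tn <- which(A_top > 0); bn <- which(A_bot > 0)
      top[[s]] <- list(ids = tn + offs[[s]], X = b$nodes[tn, , drop = FALSE],
                       area = A_top[tn], k = k_found_fem, side = side)
      bottom[[s]] <- list(ids = bn + offs[[s]], X = b$nodes[bn, , drop = FALSE],
                          area = A_bot[bn], k = k_found_tib, side = side)
    }
    sys$bodies$menisci <- .prep_body(list(
      K = K, nodes = nodes, offs = offs, free = seq_len(nrow(K)),
      femur_contacts = top, plane_contacts = bottom, sides = men_sides))
  }

  # --- tibial cartilage systems ---
  for (s in c("medial_tibial_cartilage", "lateral_tibial_cartilage")) {
    b <- model$bodies[[s]]
    Dc <- material_matrix_isotropic(mats$cartilage$E, mats$cartilage$nu)
    K <- assemble_elasticity(b, Dc, bbar = TRUE)
    fixed <- as.integer(t(outer(b$base_nodes, 1:3, function(n, k) 3 * (n - 1) + k)))
    free <- setdiff(seq_len(nrow(K)), fixed)
    fs_top <- .sheet_faces(spec$cart_nx, spec$cart_nz, spec$cart_nlayer)
    A_top <- .node_areas(b$nodes, fs_top)
    tn <- which(A_top > 0)
    side <- if (s == "medial_tibial_cartilage") "medial" else "lateral"
    sys$bodies[[s]] <- .prep_body(list(
      K = K, nodes = b$nodes, free = free,
      femur_contacts = stats::setNames(list(list(ids = tn, X = b$nodes[tn, , drop = FALSE],
                                     area = A_top[tn],
                                     k = 1 / (spec$femoral_cartilage_thickness / E_conf +
                                                1 / settings$penalty_num),
                                     side = side)), s),
      plane_contacts = list(), sides = s))
  }

  if (is.null(ligaments)) {
    ligaments <- calibrate_slack_lengths(load_ligament_params(),
                                         femur_pose = rigid_transform())
  }
  sys$ligaments <- ligaments
  sys$jcache <- new.env(parent = emptyenv())
  sys
}

# Femur pose (tibia/plateau frame) for secondary kinematics es about the
# condylar axis point a_c; flexion is handled separately (surface-invariant,
# ligaments get flexion explicitly).
.es_pose <- function(es, a_c) {
  R <- rot_x(es[4]) %*% rot_y(es[5])
  rigid_transform(R, a_c + es[1:3] - drop(R %*% a_c))
}

# Full femur pose including flexion (for ligament attachments).
.femur_pose <- function(flexion, es, a_c) {
  Rf <- rot_z(flexion)
  Tf <- rigid_transform(Rf, a_c - drop(Rf %*% a_c))
  compose_transform(.es_pose(es, a_c), Tf)
}

# Gradient of the condyle height function (C1-continued cap).
.condyle_grad <- function(x, z, spec, side) {
  cz <- if (side == "medial") -spec$condyle_offset_z else spec$condyle_offset_z
  cbind(.cap_grad(x, spec$condyle_radius_sagittal),
        .cap_grad(z - cz, spec$condyle_radius_frontal))
}

# Smoothed penalty: quadratic transition over pen in [0, eps] makes the
# force and stiffness continuous at grazing contact (suppresses active-set
# chatter for nodes resting exactly on a surface).
.pen_force <- function(pen, eps = 0.02) {
  ifelse(pen < eps, pen^2 / (2 * eps), pen - eps / 2)
}
.pen_slope <- function(pen, eps = 0.02) {
  pmin(pen, eps) / eps
}

# Contact forces (and Jacobian triplets) for one body system at displacement u
# under femur pose T_es. Vectorized over contact nodes. Returns the nodal
# force vector, femur-side reaction wrench about a_c, per-pair force sums and
# the penalty-stiffness triplets for the consistent Jacobian.
.contact_forces <- function(bsys, u, T_es, spec, mu, slip_tol, a_c,
                            u_fric = u) {
  n <- length(u)
  f <- numeric(n)
  Ji <- integer(0); Jj <- integer(0); Jx <- numeric(0)
  W_femur_F <- c(0, 0, 0); W_femur_M <- c(0, 0, 0)
  pair_forces <- list()
  max_pen <- 0
  inv <- invert_transform(T_es)
  for (cn in names(bsys$femur_contacts)) {
    cc <- bsys$femur_contacts[[cn]]
    dof <- cc$dof
    xdef <- cc$X + cbind(u[dof[, 1]], u[dof[, 2]], u[dof[, 3]])
    xf <- apply_transform(inv, xdef)
    ys <- condyle_surface_y(xf[, 1], xf[, 3], spec, cc$side)
    pen <- xf[, 2] - ys
    act <- which(pen > 0)
    Fsum <- c(0, 0, 0)
    if (length(act)) {
      gr <- .condyle_grad(xf[act, 1], xf[act, 3], spec, cc$side)
      gnorm <- sqrt(1 + gr[, 1]^2 + gr[, 2]^2)
      # normals in the femur frame, rotated to global
      Nf <- cbind(-gr[, 1], 1, -gr[, 2]) / gnorm
      Ng <- Nf %*% t(T_es$R)
      kA <- cc$k * cc$area[act]
      fn <- kA * .pen_force(pen[act])
      Fv <- -fn * Ng
      if (mu > 0) {
        Ut <- cbind(u_fric[dof[act, 1]], u_fric[dof[act, 2]], u_fric[dof[act, 3]])
        Ut <- Ut - rowSums(Ut * Ng) * Ng
        utn <- sqrt(rowSums(Ut^2))
        sel <- utn > 1e-12
        if (any(sel)) {
          Fv[sel, ] <- Fv[sel, ] - (mu * fn[sel] * tanh(utn[sel] / slip_tol) /
                                      utn[sel]) * Ut[sel, , drop = FALSE]
        }
      }
      da <- dof[act, , drop = FALSE]
      idx <- as.integer(t(da))
      f[idx] <- f[idx] + as.numeric(t(Fv))
      kslope <- kA * gnorm * .pen_slope(pen[act])
      # 3x3 penalty blocks kslope * n n^T per active node
      nr_ <- length(act)
      Ji <- c(Ji, rep(idx, each = 3))
      Jj <- c(Jj, as.integer(t(da[, rep(1:3, 3), drop = FALSE])))
      NN <- array(0, c(nr_, 3, 3))
      for (p in 1:3) for (q in 1:3) NN[, p, q] <- kslope * Ng[, p] * Ng[, q]
      Jx <- c(Jx, as.numeric(aperm(NN, c(3, 2, 1))))
      W_femur_F <- W_femur_F - colSums(Fv)
      rel <- sweep(xdef[act, , drop = FALSE], 2, a_c)
      W_femur_M <- W_femur_M - c(
        sum(rel[, 2] * Fv[, 3] - rel[, 3] * Fv[, 2]),
        sum(rel[, 3] * Fv[, 1] - rel[, 1] * Fv[, 3]),
        sum(rel[, 1] * Fv[, 2] - rel[, 2] * Fv[, 1]))
      Fsum <- colSums(Fv)
      max_pen <- max(max_pen, pen[act])
    }
    pair_forces[[paste0("femoral_cartilage-", cn)]] <- Fsum
  }
  for (cn in names(bsys$plane_contacts)) {
    cc <- bsys$plane_contacts[[cn]]
    dof <- cc$dof
    pen <- -(cc$X[, 2] + u[dof[, 2]])
    act <- which(pen > 0)
    Fsum <- c(0, 0, 0)
    if (length(act)) {
      kA <- cc$k * cc$area[act]
      fn <- kA * .pen_force(pen[act])
      Fv <- cbind(0, fn, 0)
      if (mu > 0) {
        Ut <- cbind(u_fric[dof[act, 1]], 0, u_fric[dof[act, 3]])
        utn <- sqrt(rowSums(Ut^2))
        sel <- utn > 1e-12
        if (any(sel)) {
          Fv[sel, ] <- Fv[sel, ] - (mu * fn[sel] * tanh(utn[sel] / slip_tol) /
                                      utn[sel]) * Ut[sel, , drop = FALSE]
        }
      }
      da <- dof[act, , drop = FALSE]
      idx <- as.integer(t(da))
      f[idx] <- f[idx] + as.numeric(t(Fv))
      Ji <- c(Ji, da[, 2]); Jj <- c(Jj, da[, 2])
      Jx <- c(Jx, kA * .pen_slope(pen[act]))
      Fsum <- colSums(Fv)
      max_pen <- max(max_pen, pen[act])
    }
    pair_forces[[paste0(cn, "-", cc$side, "_tibial_cartilage")]] <- Fsum
  }
  list(f = f, Ji = Ji, Jj = Jj, Jx = Jx,
       W_femur = list(F = W_femur_F, M = W_femur_M),
       pair_forces = pair_forces, max_pen = max_pen)
}

# Analytic sensitivity of one body's femur-side contact wrench to the five
# secondary DOFs, via the adjoint of the converged inner solve: with contact
# stiffness C and surface-velocity map V_a per active node,
# J du = B des  (B from surface motion), then
# dW/des = sum_a P_a (du_a/des - V_a), P_a = c_a n n'.
# Friction (frozen) and surface-curvature terms are neglected: this is a
# Newton approximation, safeguarded by the outer line search.
.body_wrench_jacobian <- function(bsys, u, T_es, spec, a_c, mu = 0,
                                  slip_tol = 0.2) {
  inv <- invert_transform(T_es)
  n_dof <- nrow(bsys$K)
  free <- bsys$free
  act_list <- list()
  Ji <- integer(0); Jj <- integer(0); Jx <- numeric(0)
  for (cn in names(bsys$femur_contacts)) {
    cc <- bsys$femur_contacts[[cn]]
    dof <- cc$dof
    xdef <- cc$X + cbind(u[dof[, 1]], u[dof[, 2]], u[dof[, 3]])
    xf <- apply_transform(inv, xdef)
    pen <- xf[, 2] - condyle_surface_y(xf[, 1], xf[, 3], spec, cc$side)
    act <- which(pen > 0)
    if (!length(act)) next
    gr <- .condyle_grad(xf[act, 1], xf[act, 3], spec, cc$side)
    for (ii in seq_along(act)) {
      a <- act[ii]
      gnorm <- sqrt(1 + gr[ii, 1]^2 + gr[ii, 2]^2)
      n_up <- drop(T_es$R %*% (c(-gr[ii, 1], 1, -gr[ii, 2]) / gnorm))
      c_a <- cc$k * cc$area[a] * gnorm * .pen_slope(pen[a])
      r_a <- xdef[a, ] - a_c
      V_a <- cbind(diag(3), cross3(c(1, 0, 0), r_a), cross3(c(0, 1, 0), r_a))
      # friction direction (frozen-state regularized Coulomb), for the
      # d(friction)/d(normal force) sensitivity
      tvec <- c(0, 0, 0)
      if (mu > 0) {
        ut <- u[dof[a, ]]
        ut <- ut - sum(ut * n_up) * n_up
        utn <- vnorm(ut)
        if (utn > 1e-12) tvec <- -mu * tanh(utn / slip_tol) * ut / utn
      }
      act_list[[length(act_list) + 1L]] <- list(
        dof = dof[a, ], c = c_a, n = n_up, x = xdef[a, ], V = V_a, t = tvec)
      Kc <- c_a * outer(n_up, n_up)
      Ji <- c(Ji, rep(dof[a, ], each = 3)); Jj <- c(Jj, rep(dof[a, ], times = 3))
      Jx <- c(Jx, as.numeric(Kc))
    }
  }
  for (cn in names(bsys$plane_contacts)) {
    cc <- bsys$plane_contacts[[cn]]
    dof2 <- 3 * (cc$ids - 1) + 2
    pen <- -(cc$X[, 2] + u[dof2])
    act <- which(pen > 0)
    if (!length(act)) next
    Ji <- c(Ji, dof2[act]); Jj <- c(Jj, dof2[act])
    Jx <- c(Jx, cc$k * cc$area[act] * .pen_slope(pen[act]))
  }
  dW <- matrix(0, 6, 5)
  if (!length(act_list)) return(dW)
  Jff <- bsys$Kff
  if (length(Ji)) {
    fi <- bsys$map[Ji]; fj <- bsys$map[Jj]
    keep <- fi > 0 & fj > 0
    Jff <- Jff + Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = fi[keep], j = fj[keep], x = Jx[keep],
      dims = c(length(free), length(free))))
  }
  B <- matrix(0, length(free), 5)
  for (al in act_list) {
    fidx <- bsys$map[al$dof]
    nv <- drop(crossprod(al$n, al$V))          # 1 x 5
    ok <- fidx > 0
    B[fidx[ok], ] <- B[fidx[ok], , drop = FALSE] +
      al$c * outer(al$n[ok], nv)
  }
  ch <- tryCatch(Matrix::update(bsys$cache$chol, Jff +
                   Matrix::Diagonal(length(free), 1e-8), mult = 0),
                 error = function(e) NULL)
  X <- if (is.null(ch)) as.matrix(Matrix::solve(Jff, B))
       else as.matrix(Matrix::solve(ch, B))
  for (al in act_list) {
    fidx <- bsys$map[al$dof]
    Xa <- matrix(0, 3, 5)
    ok <- fidx > 0
    Xa[ok, ] <- X[fidx[ok], , drop = FALSE]
    dfn <- al$c * drop(crossprod(al$n, Xa - al$V))              # 1 x 5
    dR <- outer(al$n, dfn) + outer(al$t, dfn)   # normal + friction coupling
    dW[1:3, ] <- dW[1:3, ] + dR
    rx <- skew(al$x - a_c)
    dW[4:6, ] <- dW[4:6, ] + rx %*% dR
  }
  dW
}

# Precompute the free-DOF system and a reusable symbolic Cholesky analysis.
.prep_body <- function(bsys) {
  for (cn in names(bsys$femur_contacts)) {
    ids <- bsys$femur_contacts[[cn]]$ids
    bsys$femur_contacts[[cn]]$dof <- cbind(3 * (ids - 1) + 1, 3 * (ids - 1) + 2,
                                           3 * (ids - 1) + 3)
  }
  for (cn in names(bsys$plane_contacts)) {
    ids <- bsys$plane_contacts[[cn]]$ids
    bsys$plane_contacts[[cn]]$dof <- cbind(3 * (ids - 1) + 1, 3 * (ids - 1) + 2,
                                           3 * (ids - 1) + 3)
  }
  free <- bsys$free
  bsys$Kff <- Matrix::forceSymmetric(bsys$K[free, free, drop = FALSE])
  bsys$map <- integer(nrow(bsys$K))       # full dof -> free index (0 = fixed)
  bsys$map[free] <- seq_along(free)
  bsys$cache <- new.env(parent = emptyenv())
  bsys$cache$chol <- Matrix::Cholesky(bsys$Kff +
    Matrix::Diagonal(length(free), 1e-8), LDL = FALSE, perm = TRUE)
  bsys
}

# Inner solve of one body system under femur pose T_es. Two deterministic
# passes: the frictionless normal-penalty problem first (smooth; full Newton
# with residual backtracking), then a re-solve with the regularized Coulomb
# friction forces frozen from the frictionless field. The result is a pure
# function of the pose (warm starts only accelerate), which keeps the outer
# secondary-kinematics residual smooth. Numeric-only Cholesky
# refactorization on the cached symbolic analysis (contact terms only touch
# nodal diagonal blocks already in the stiffness pattern).
.solve_body <- function(bsys, T_es, spec, mu, st, u0 = NULL, probe = FALSE) {
  n <- nrow(bsys$K)
  u <- if (is.null(u0)) numeric(n) else u0
  free <- bsys$free
  it_tot <- 0L
  cf <- NULL
  u_fric <- NULL    # NULL = frictionless pass
  passes <- if (probe) 2L else 1:2   # probe: friction frozen at the base state
  for (pass in passes) {
    mu_eff <- if (pass == 1) 0 else mu
    if (pass == 2) {
      if (mu <= 0 && !probe) break
      u_fric <- if (probe) u0 else u
    }
    cf <- .contact_forces(bsys, u, T_es, spec, mu_eff, st$slip_tol, bsys$a_c,
                          u_fric = if (is.null(u_fric)) u else u_fric)
    for (it in seq_len(st$newton_max)) {
      it_tot <- it_tot + 1L
      r <- drop(bsys$K %*% u) - cf$f
      rf <- r[free]
      r_exit <- max(0.1, 2e-4 * sqrt(sum(cf$f^2)))  # N; force-level exit
      if (sqrt(sum(rf^2)) < r_exit) break
      Jff <- bsys$Kff
      if (length(cf$Ji)) {
        fi <- bsys$map[cf$Ji]; fj <- bsys$map[cf$Jj]
        keep <- fi > 0 & fj > 0
        Jff <- Jff + Matrix::forceSymmetric(Matrix::sparseMatrix(
          i = fi[keep], j = fj[keep], x = cf$Jx[keep],
          dims = c(length(free), length(free))))
      }
      ch <- tryCatch(Matrix::update(bsys$cache$chol, Jff +
                       Matrix::Diagonal(length(free), 1e-8), mult = 0),
                     error = function(e) NULL)
      duf <- if (is.null(ch)) {
        as.numeric(Matrix::solve(Jff, -rf))
      } else as.numeric(Matrix::solve(ch, -rf))
      du <- numeric(n); du[free] <- duf
      step <- 1
      for (bt in 1:4) {
        u_new <- u + step * du
        cf_new <- .contact_forces(bsys, u_new, T_es, spec, mu_eff, st$slip_tol,
                                  bsys$a_c,
                                  u_fric = if (is.null(u_fric)) u_new else u_fric)
        r_new <- (drop(bsys$K %*% u_new) - cf_new$f)[free]
        if (sqrt(sum(r_new^2)) <= sqrt(sum(rf^2)) * (1 - 1e-4 * step) ||
            max(abs(du)) * step < st$newton_tol) break
        step <- step / 2
      }
      u <- u + step * du
      cf <- cf_new
      if (max(abs(du)) * step < st$newton_tol) break
      if (sqrt(sum(r_new^2)) < r_exit) break
    }
  }
  list(u = u, cf = cf, iterations = it_tot)
}

#' Solve the tibiofemoral contact problem at one time point
#'
#' Finds the knee secondary kinematics `es` (anterior/superior/lateral
#' femoral translation in mm, varus-valgus and internal-external rotation in
#' rad, about the condylar axis point) at which the contact plus ligament
#' wrench on the tibia balances the applied tibiofemoral load `W_target` in
#' the five secondary components; the flexion component is balanced by the
#' muscles upstream. Deterministic for fixed inputs.
#'
#' @param model a `knee_model`.
#' @param flexion knee flexion angle (rad) for the ligament geometry.
#' @param W_target list with `F` (N) and `M` (N mm about the condylar axis
#'   point): the wrench the joint structures must exert on the tibia.
#' @param system cached [contact_system()]; rebuilt when NULL.
#' @param settings solver settings.
#' @param es0 warm-start secondary kinematics (length 5).
#' @param state0 optional warm-start displacement fields from a previous
#'   solve.
#' @param error_on_fail error (rather than flag) on non-convergence.
#' @return a `contact_result`: converged `es`, partitioned contact forces (N
#'   and body weight via `bw` if given), medial load-share ratio, peak
#'   pressures, displacement fields, residual history and diagnostics.
#' @param bw body weight (N) used to express forces in BW; NA skips.
#' @export
solve_contact <- function(model, flexion, W_target, system = NULL,
                          settings = contact_settings(), es0 = rep(0, 5),
                          state0 = NULL, bw = NA, error_on_fail = FALSE,
                          verbose = FALSE) {
  if (is.null(system)) system <- contact_system(model, settings)
  st <- settings
  spec <- model$spec
  a_c <- system$a_c
  for (bn in names(system$bodies)) system$bodies[[bn]]$a_c <- a_c

  lig <- system$ligaments
  mu <- system$mu
  ustate <- state0
  # warm displacement fields only transfer between systems with matching
  # DOF layouts (e.g. intact -> torn, where tears delete elements but keep
  # the node set; not intact -> meniscectomy)
  if (!is.null(ustate)) {
    for (bn in names(system$bodies)) {
      if (!is.null(ustate[[bn]]) &&
          length(ustate[[bn]]) != nrow(system$bodies[[bn]]$K)) {
        ustate[[bn]] <- NULL
      }
    }
    ustate <- ustate[names(ustate) %in% names(system$bodies)]
    if (length(ustate) == 0) ustate <- NULL
  }

  eval_R <- function(es, keep = FALSE, fast = FALSE) {
    T_es <- .es_pose(es, a_c)
    st_use <- st
    if (fast) st_use$newton_max <- 2L   # short probe for FD Jacobians
    Wt_F <- c(0, 0, 0); Wt_M <- c(0, 0, 0)
    sols <- list(); pair_forces <- list(); max_pen <- 0
    for (bn in names(system$bodies)) {
      bs <- .solve_body(system$bodies[[bn]], T_es, spec, mu, st_use,
                        u0 = ustate[[bn]], probe = fast)
      sols[[bn]] <- bs
      if (!fast) ustate[[bn]] <<- bs$u  # warm start for later evaluations
      # wrench ON the tibia side = -(reaction on femur); plane contacts are
      # internal to the tibia side and cancel there
      Wt_F <- Wt_F - bs$cf$W_femur$F
      Wt_M <- Wt_M - bs$cf$W_femur$M
      for (pn in names(bs$cf$pair_forces)) {
        pair_forces[[pn]] <- bs$cf$pair_forces[[pn]]
      }
      max_pen <- max(max_pen, bs$cf$max_pen)
    }
    pw <- passive_wrench(lig, .femur_pose(flexion, es, a_c), about = a_c)
    Wt_F <- Wt_F + pw$force_tibia
    Wt_M <- Wt_M + pw$moment_tibia
    R <- c(Wt_F - W_target$F, (Wt_M - W_target$M)[1:2])
    if (keep) {
      list(R = R, sols = sols, pair_forces = pair_forces, max_pen = max_pen,
           lig = pw)
    } else R
  }

  # equilibrium tolerances: absolute floor, relative (1.5%) under high load
  tol_f <- max(st$es_tol_force, 1.5e-2 * vnorm(W_target$F))
  tol_m <- max(st$es_tol_moment,
               1.5e-2 * max(vnorm(W_target$M[1:2]), 30 * vnorm(W_target$F)))
  scale <- c(rep(tol_f, 3), rep(tol_m, 2))
  es <- es0
  # gross initial penetration backoff along the compression axis
  for (k in 1:20) {
    T_es <- .es_pose(es, a_c)
    pen_probe <- 0
    for (bn in names(system$bodies)) {
      cf0 <- .contact_forces(system$bodies[[bn]], numeric(nrow(system$bodies[[bn]]$K)),
                             T_es, spec, mu, st$slip_tol, a_c)
      pen_probe <- max(pen_probe, cf0$max_pen)
    }
    if (pen_probe < 4) break   # only truly gross initial overlap
    es[2] <- es[2] + (pen_probe - 2)
  }

  # Outer solve: Newton on the 5 secondary DOFs with analytic (adjoint)
  # Jacobians, under adaptive load incrementation: the applied wrench is
  # ramped with a step that grows on easy converged increments and bisects
  # on failures -- the standard continuation scheme for stiff contact.
  W_full <- W_target
  hist <- numeric(0)
  it <- 0L

  analytic_jacobian <- function(es) {
    T_cur <- .es_pose(es, a_c)
    dWc <- matrix(0, 6, 5)
    for (bn in names(system$bodies)) {
      dWc <- dWc + .body_wrench_jacobian(system$bodies[[bn]],
                                         ustate[[bn]], T_cur, spec, a_c,
                                         mu = mu, slip_tol = st$slip_tol)
    }
    Jlig <- matrix(0, 5, 5)
    hl <- c(1e-3, 1e-3, 1e-3, 1e-5, 1e-5)
    pw0 <- passive_wrench(lig, .femur_pose(flexion, es, a_c), about = a_c)
    w0 <- c(pw0$force_tibia, pw0$moment_tibia[1:2])
    for (d in 1:5) {
      ep <- es; ep[d] <- ep[d] + hl[d]
      pw1 <- passive_wrench(lig, .femur_pose(flexion, ep, a_c), about = a_c)
      Jlig[, d] <- (c(pw1$force_tibia, pw1$moment_tibia[1:2]) - w0) / hl[d]
    }
    -rbind(dWc[1:3, ], dWc[4:5, ]) + Jlig
  }

  # Newton sub-solve at one load level; returns convergence flag
  newton_at <- function(max_its) {
    stalls <- 0L
    conv <- all(abs(R[1:3]) < tol_f) && all(abs(R[4:5]) < tol_m)
    sub_it <- 0L
    while (!conv && sub_it < max_its && it < st$es_max) {
      it <<- it + 1L; sub_it <- sub_it + 1L
      J <- analytic_jacobian(es)
      des <- tryCatch(solve(J + diag(5) * 1e-8, -R),
                      error = function(e) .pinv_solve(J, -R))
      lim <- c(1.5, 1.5, 1.5, 0.06, 0.06)   # trust region per DOF
      des <- des * min(1, min(lim / pmax(abs(des), 1e-12)))
      step <- 1
      repeat {
        es_new <- es + step * des
        R_new <- eval_R(es_new)
        if (vnorm(R_new / scale) < vnorm(R / scale) || step < 0.1) break
        step <- step / 2
      }
      if (vnorm(R_new / scale) < 1.02 * vnorm(R / scale)) {
        # accept including near-flat moves: the residual carries solver noise
        # and flat traversal escapes plateaus
        if (vnorm(R_new / scale) < vnorm(R / scale)) stalls <- 0L
        else stalls <- stalls + 1L
        es <<- es_new; R <<- R_new
      } else {
        stalls <- stalls + 1L
      }
      if (stalls >= 4L) break
      if (verbose) {
        cat(sprintf("  outer %2d lam %.2f |R| %9.3g step %.3f es [%s]\n", it,
                    lam, vnorm(R / scale), step,
                    paste(signif(es, 3), collapse = " ")))
      }
      hist <<- c(hist, vnorm(R / scale))
      conv <- all(abs(R[1:3]) < tol_f) && all(abs(R[4:5]) < tol_m)
    }
    conv
  }

  warm <- !(is.null(state0) && max(abs(es0)) < 1e-9)
  converged <- FALSE
  lam <- 1
  if (warm) {
    # warm start: single full-load Newton attempt
    W_target <- W_full
    R <- eval_R(es)
    hist <- c(hist, vnorm(R / scale))
    converged <- newton_at(max_its = 25L)
  }
  if (!converged) {
    # cold (or failed-warm) start: ramp the load with adaptive increments
    es <- rep(0, 5); ustate <- list()
    lam_done <- 0; dlam <- 0.34
    snap_es <- es; snap_u <- ustate
    while (lam_done < 1 && it < st$es_max) {
      lam <- min(1, lam_done + dlam)
      W_target <- list(F = lam * W_full$F, M = lam * W_full$M)
      R <- eval_R(es)
      hist <- c(hist, vnorm(R / scale))
      ok <- newton_at(max_its = 18L)
      if (ok) {
        lam_done <- lam
        snap_es <- es; snap_u <- ustate
        dlam <- min(1, dlam * 1.6)
        if (lam_done >= 1) converged <- TRUE
      } else {
        es <- snap_es; ustate <- snap_u
        dlam <- dlam / 2
        if (dlam < 0.04) break
      }
    }
  }
  if (!converged) {   # report the final residual at full load
    W_target <- list(F = W_full$F, M = W_full$M)
    R <- eval_R(es)
  }

  W_target <- W_full
  fin <- eval_R(es, keep = TRUE)
  if (!converged && error_on_fail) {
    stop(sprintf("contact solve did not converge: residual %s",
                 paste(signif(R, 3), collapse = " ")))
  }
  ustate <- lapply(fin$sols, `[[`, "u")

  res <- partition_contact_forces(fin$pair_forces, bw = bw)
  pressures <- .contact_pressures(system, ustate, .es_pose(es, a_c), spec)
  structure(list(
    es = es, converged = converged, iterations = it,
    residual = R, residual_history = hist, max_penetration = fin$max_pen,
    pair_forces = fin$pair_forces, forces = res$forces_N,
    forces_bw = res$forces_bw, medial_ratio = res$medial_ratio,
    pressures = pressures, u = ustate,
    ligament_forces = fin$lig$forces,
    W_tibia = list(F = R[1:3] + W_target$F,
                   M = c(R[4:5] + W_target$M[1:2], NA))
  ), class = "contact_result")
}

# Peak contact pressure per femoral pair (N/mm^2) from the converged fields.
.contact_pressures <- function(system, ustate, T_es, spec) {
  out <- list()
  inv <- invert_transform(T_es)
  for (bn in names(system$bodies)) {
    u <- ustate[[bn]]
    bsys <- system$bodies[[bn]]
    for (cn in names(bsys$femur_contacts)) {
      cc <- bsys$femur_contacts[[cn]]
      dof <- cbind(3 * (cc$ids - 1) + 1, 3 * (cc$ids - 1) + 2, 3 * (cc$ids - 1) + 3)
      xdef <- cc$X + cbind(u[dof[, 1]], u[dof[, 2]], u[dof[, 3]])
      xf <- apply_transform(inv, xdef)
      pen <- pmax(xf[, 2] - condyle_surface_y(xf[, 1], xf[, 3], spec, cc$side), 0)
      out[[paste0("femoral_cartilage-", cn)]] <- max(cc$k * pen)
    }
  }
  out
}

#' Partition contact forces and the medial load-share ratio
#'
#' Sums the converged contact tractions per contact pair and forms the medial
#' ratio `|F(femur -> medial meniscus)| / (|F(-> medial meniscus)| +
#' |F(-> medial tibial cartilage direct)|)`. With zero total medial force the
#' ratio is undefined and reported as NA.
#'
#' @param pair_forces named list of per-pair force vectors (N) as stored in a
#'   `contact_result`.
#' @param bw body weight (N) for BW normalization; NA skips.
#' @return list with `forces_N` (per-pair magnitudes), `forces_bw`,
#'   `medial_ratio`.
#' @export
partition_contact_forces <- function(pair_forces, bw = NA) {
  mag <- vapply(pair_forces, vnorm, numeric(1))
  pick <- function(nm) if (nm %in% names(mag)) mag[[nm]] else 0
  f_men <- pick("femoral_cartilage-medial_meniscus")
  f_cart <- pick("femoral_cartilage-medial_tibial_cartilage")
  tot <- f_men + f_cart
  ratio <- if (tot > 1e-9) f_men / tot else NA_real_
  list(forces_N = mag,
       forces_bw = if (is.na(bw)) NULL else mag / bw,
       medial_ratio = ratio)
}

#' @export
print.contact_result <- function(x, ...) {
  cat("Knee contact solve",
      if (x$converged) sprintf("(converged in %d steps)\n", x$iterations)
      else "(NOT converged)\n")
  cat(sprintf("  es: t = [%.2f %.2f %.2f] mm, vv/ie = [%.3f %.3f] deg\n",
              x$es[1], x$es[2], x$es[3], x$es[4] * 180 / pi, x$es[5] * 180 / pi))
  for (pn in names(x$forces)) {
    cat(sprintf("  %-48s %8.1f N\n", pn, x$forces[[pn]]))
  }
  cat(sprintf("  medial meniscus load share: %s; max penetration %.3f mm\n",
              ifelse(is.na(x$medial_ratio), "NA", sprintf("%.3f", x$medial_ratio)),
              x$max_penetration))
  invisible(x)
}

#' Meniscus stress field from a converged contact solve
#'
#' @param model the `knee_model`.
#' @param result a `contact_result`.
#' @param side meniscus body name.
#' @return a `stress_field` for the requested meniscus (see
#'   [recover_stress()]).
#' @export
meniscus_stress <- function(model, result, side = "medial_meniscus") {
  b <- model$bodies[[side]]
  if (is.null(b)) stop(sprintf("body '%s' absent from this variant", side))
  sys_off <- 0L
  sides <- intersect(c("medial_meniscus", "lateral_meniscus"), names(model$bodies))
  sides <- sides[!vapply(sides, function(s) is.null(model$bodies[[s]]), logical(1))]
  for (s in sides) {
    if (s == side) break
    sys_off <- sys_off + nrow(model$bodies[[s]]$nodes)
  }
  u_all <- result$u$menisci
  dofs <- 3 * sys_off + seq_len(3 * nrow(b$nodes))
  recover_stress(b, .meniscus_D_elems(model, side), u_all[dofs],
                 frames = model$frames[[side]])
}

#' Tear-tip stress summary
#'
#' Maximum (and mean) of the element maximum-shear stress over the tagged
#' tear-tip element set; for an intact model pass the matched-location set
#' from [matched_tip_elements()].
#'
#' @param stress a `stress_field` of the medial meniscus.
#' @param tip_elements integer element ids (the tagged set).
#' @return list with `max` and `mean` (MPa).
#' @export
tag_tear_tip_stress <- function(stress, tip_elements) {
  if (length(tip_elements) == 0) stop("empty tear-tip element set")
  v <- stress$max_shear[tip_elements]
  list(max = max(v), mean = mean(v))
}
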