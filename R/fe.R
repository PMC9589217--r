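# Linear elastic 8-node hexahedral elements: isotropic cartilage with
# mean-dilatation (B-bar) treatment of near-incompressibility, transversely
# isotropic menisci with per-element local frames. Voigt order
# (xx, yy, zz, xy, yz, zx) with engineering shear strains.

#' Isotropic elasticity matrix
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 6x6 stiffness matrix (MPa), Voigt order (xx, yy, zz, xy, yz, zx).
#' @export
material_matrix_isotropic <- function(E, nu) {
  check_positive(E, "E")
  if (nu <= -1 || nu >= 0.5) stop("field 'nu' must lie in (-1, 0.5)")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Transversely isotropic elasticity matrix (local frame)
#'
#' Local axes: 1 = circumferential (stiff), 2 = radial, 3 = axial; the 2-3
#' plane is the isotropy plane. Built from the compliance matrix and checked
#' for symmetric positive definiteness.
#'
#' @param E_circ circumferential modulus (MPa), default 140.
#' @param E_trans radial/axial modulus (MPa), default 20.
#' @param nu_in in-plane (radial-axial) Poisson's ratio, default 0.2.
#' @param nu_out out-of-plane Poisson's ratio (circumferential-transverse),
#'   default 0.3.
#' @param G_out out-of-plane shear modulus (MPa), default 10; the in-plane
#'   shear modulus is `E_trans / (2 (1 + nu_in))`.
#' @return 6x6 local stiffness matrix (MPa).
#' @export
material_matrix_transiso <- function(E_circ = 140, E_trans = 20,
                                     nu_in = 0.2, nu_out = 0.3, G_out = 10) {
  check_positive(E_circ, "E_circ"); check_positive(E_trans, "E_trans")
  check_positive(G_out, "G_out")
  G_in <- E_trans / (2 * (1 + nu_in))
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / E_circ
  S[2, 2] <- S[3, 3] <- 1 / E_trans
  S[1, 2] <- S[2, 1] <- S[1, 3] <- S[3, 1] <- -nu_out / E_circ
  S[2, 3] <- S[3, 2] <- -nu_in / E_trans
  S[4, 4] <- 1 / G_out   # 1-2 shear
  S[5, 5] <- 1 / G_in    # 2-3 shear (isotropy plane)
  S[6, 6] <- 1 / G_out   # 1-3 shear
  D <- solve(S)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("transversely isotropic stiffness is not positive definite")
  (D + t(D)) / 2
}

#' Bond stress-rotation matrix for Voigt notation
#'
#' Maps local Voigt stress to global: `sigma_g = K %*% sigma_l` for a rotation
#' `R` whose columns are the local axes in global coordinates; the stiffness
#' transforms as `D_g = K D_l t(K)` (engineering shear convention).
#'
#' @param R 3x3 rotation (columns = local axes in global frame).
#' @return 6x6 Bond matrix.
#' @export
bond_matrix <- function(R) {
  K <- matrix(0, 6, 6)
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  for (i in 1:3) {
    K[i, 1:3] <- R[i, ]^2
    for (q in 1:3) {
      p <- pairs[[q]]
      K[i, 3 + q] <- 2 * R[i, p[1]] * R[i, p[2]]
    }
  }
  for (r in 1:3) {
    ij <- pairs[[r]]
    K[3 + r, 1:3] <- R[ij[1], ] * R[ij[2], ]
    for (q in 1:3) {
      p <- pairs[[q]]
      K[3 + r, 3 + q] <- R[ij[1], p[1]] * R[ij[2], p[2]] +
        R[ij[1], p[2]] * R[ij[2], p[1]]
    }
  }
  K
}

# B matrix (6 x 24) from global shape derivatives dN (8 x 3).
.hex_B <- function(dN) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dN[a, 1]
    B[2, c0 + 2] <- dN[a, 2]
    B[3, c0 + 3] <- dN[a, 3]
    B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
    B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
    B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
  }
  B
}

#' Element stiffness of an 8-node hexahedron
#'
#' Full 2x2x2 Gauss integration; with `bbar = TRUE` the volumetric part of
#' the strain-displacement operator is replaced by its element mean
#' (mean-dilatation selective treatment for near-incompressible isotropic
#' materials).
#'
#' @param X 8 x 3 node coordinates (mm).
#' @param D 6x6 material stiffness (MPa), already in the global frame.
#' @param bbar logical; mean-dilatation volumetric treatment.
#' @return 24 x 24 element stiffness (N/mm).
#' @export
hex_stiffness <- function(X, D, bbar = FALSE) {
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  Bs <- vector("list", 8); dets <- numeric(8)
  for (g in 1:8) {
    dsh <- .hex_dshape(pts[g, ])
    J <- crossprod(dsh, X)
    detJ <- det(J)
    if (detJ <= 0) stop(sprintf("inverted element (det J = %.3g)", detJ))
    # J[i, j] = dx_j / dxi_i, so dN/dx = dsh %*% t(J^-1)
    dN <- dsh %*% t(solve(J))
    Bs[[g]] <- .hex_B(dN)
    dets[g] <- detJ
  }
  if (bbar) {
    vol_rows <- function(B) (B[1, ] + B[2, ] + B[3, ]) / 3
    bbar_row <- Reduce(`+`, Map(function(B, w) vol_rows(B) * w, Bs, dets)) / sum(dets)
    one <- c(1, 1, 1, 0, 0, 0)
    Bs <- lapply(Bs, function(B) B + outer(one, bbar_row - vol_rows(B)))
  }
  Ke <- matrix(0, 24, 24)
  for (g in 1:8) Ke <- Ke + crossprod(Bs[[g]], D %*% Bs[[g]]) * dets[g]
  (Ke + t(Ke)) / 2
}

#' Assemble the sparse stiffness of an elastic body
#'
#' @param body mesh list with `nodes` (n x 3) and `elems` (m x 8).
#' @param D_elems either a single 6x6 matrix (used for all elements) or a
#'   list of per-element 6x6 matrices (e.g. rotated transversely isotropic).
#' @param bbar mean-dilatation flag, passed to [hex_stiffness()].
#' @return sparse symmetric stiffness (3n x 3n, `Matrix::dgCMatrix`).
#' @export
assemble_elasticity <- function(body, D_elems, bbar = FALSE) {
  ne <- nrow(body$elems)
  single <- is.matrix(D_elems)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  idx_cache <- vector("list", ne)
  trip_i <- vector("list", ne); trip_j <- vector("list", ne); trip_x <- vector("list", ne)
  for (e in seq_len(ne)) {
    X <- body$nodes[body$elems[e, ], , drop = FALSE]
    D <- if (single) D_elems else D_elems[[e]]
    Ke <- hex_stiffness(X, D, bbar = bbar)
    dofs <- as.integer(t(outer(body$elems[e, ], 1:3, function(n, k) 3 * (n - 1) + k)))
    trip_i[[e]] <- rep(dofs, each = 24)
    trip_j[[e]] <- rep(dofs, times = 24)
    trip_x[[e]] <- as.numeric(Ke)
  }
  n <- 3 * nrow(body$nodes)
  Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                       x = unlist(trip_x), dims = c(n, n), symmetric = FALSE)
}

#' Recover element stresses from a displacement field
#'
#' Strain evaluated with the element-centre strain-displacement operator
#' (volume-averaged volumetric part, matching the stiffness integration);
#' stress from the same material matrices used in assembly. Derived scalars:
#' maximum shear `(sigma_1 - sigma_3) / 2` from the principal stresses and,
#' where local frames are given, the circumferential normal stress
#' `sigma_cc = c' S c` (tension positive).
#'
#' @param body mesh list (`nodes`, `elems`).
#' @param D_elems material matrices as in [assemble_elasticity()].
#' @param u displacement vector (3n).
#' @param frames optional per-element 3x3 triads (column 1 = circumferential).
#' @param bbar mean-dilatation flag used at assembly.
#' @return a `stress_field`: list with `tensor` (list of 3x3), `max_shear`,
#'   `sigma_cc` (NA without frames), `principal` (m x 3).
#' @export
recover_stress <- function(body, D_elems, u, frames = NULL, bbar = FALSE) {
  ne <- nrow(body$elems)
  single <- is.matrix(D_elems)
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  tensors <- vector("list", ne)
  max_shear <- numeric(ne); sigma_cc <- rep(NA_real_, ne)
  principal <- matrix(0, ne, 3)
  for (e in seq_len(ne)) {
    X <- body$nodes[body$elems[e, ], , drop = FALSE]
    dofs <- as.integer(t(outer(body$elems[e, ], 1:3, function(n, k) 3 * (n - 1) + k)))
    ue <- u[dofs]
    # volume-averaged B (consistent with the element-centre state)
    Bsum <- matrix(0, 6, 24); vsum <- 0
    for (g in 1:8) {
      dsh <- .hex_dshape(pts[g, ])
      J <- crossprod(dsh, X)
      detJ <- det(J)
      Bsum <- Bsum + .hex_B(dsh %*% t(solve(J))) * detJ
      vsum <- vsum + detJ
    }
    eps <- drop((Bsum / vsum) %*% ue)
    D <- if (single) D_elems else D_elems[[e]]
    sig <- drop(D %*% eps)
    S <- matrix(c(sig[1], sig[4], sig[6],
                  sig[4], sig[2], sig[5],
                  sig[6], sig[5], sig[3]), 3, 3)
    tensors[[e]] <- S
    pr <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    principal[e, ] <- pr
    max_shear[e] <- (pr[1] - pr[3]) / 2
    if (!is.null(frames)) {
      cvec <- frames[[e]][, 1]
      sigma_cc[e] <- drop(crossprod(cvec, S %*% cvec))
    }
  }
  structure(list(tensor = tensors, max_shear = max_shear,
                 sigma_cc = sigma_cc, principal = principal),
            class = "stress_field")
}

# Per-element global material matrices for a meniscus body.
.meniscus_D_elems <- function(model, side) {
  mat <- model$materials$meniscus
  Dl <- material_matrix_transiso(mat$E_circ, mat$E_trans, mat$nu_in,
                                 mat$nu_out, mat$G_out)
  lapply(model$frames[[side]], function(Q) {
    K <- bond_matrix(Q)
    K %*% Dl %*% t(K)
  })
}
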