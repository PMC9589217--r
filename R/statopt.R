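# Static optimization of muscle activations: minimize the sum of cubed
# activations subject to joint-moment equilibrium and activation bounds [0, 1].
# Primal-dual interior-point Newton on the cubic program, followed by an
# active-set KKT polish so bound-degenerate optima (e.g. all-zero activations
# at zero required moment) are recovered exactly.

#' Solve the cubed-activation program
#'
#' Minimizes `sum(s^3)` over activations `s` subject to the linear equality
#' constraints `A s = b` (joint-moment equilibrium, with muscle forces affine
#' in activation folded into `A` and `b`) and bounds `0 <= s <= 1`.
#'
#' @param A p x m constraint matrix (N mm per unit activation).
#' @param b length-p required moment vector (N mm).
#' @param s0 cold-start activation (default 0.1 for every muscle).
#' @param tol primal/dual convergence tolerance.
#' @param max_iter interior-point iteration cap.
#' @param feas_tol absolute equality-feasibility tolerance (units of `b`).
#' @return list with `s` (activations), `objective`, `lambda` (equality
#'   multipliers), `kkt_residual`, `moment_residual` (`A s - b`), `feasible`
#'   (logical), `iterations`.
#' @export
solve_activation_program <- function(A, b, s0 = NULL, tol = 1e-10,
                                     max_iter = 500, feas_tol = NULL) {
  A <- as.matrix(A)
  m <- ncol(A); p <- nrow(A)
  b <- as.numeric(b)
  stopifnot(length(b) == p, m >= 1)
  scale_b <- max(1, max(abs(A)), max(abs(b)))

  s <- if (is.null(s0)) rep(0.1, m) else pmin(pmax(s0, 1e-3), 1 - 1e-3)
  y <- rep(0, p)
  zl <- rep(1, m); zh <- rep(1, m)

  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- 3 * s^2
    rd <- g + drop(crossprod(A, y)) - zl + zh
    rp <- drop(A %*% s) - b
    gap <- (sum(s * zl) + sum((1 - s) * zh)) / (2 * m)
    if (max(abs(rd)) < 1e-8 * scale_b && max(abs(rp)) < 1e-8 * scale_b &&
        gap < tol) break
    # complementarity converged but equality still violated: infeasible exit
    if (gap < tol && it > 20) break
    # stronger centering while primal-infeasible keeps iterates off the bounds
    sigma <- if (max(abs(rp)) > 1e-6 * scale_b) 0.5 else 0.1
    mu <- sigma * gap
    rl <- s * zl - mu
    rh <- (1 - s) * zh - mu

    D <- zl / s + zh / (1 - s)
    M <- 6 * s + D                     # diagonal of the condensed system
    rhs1 <- -rd - rl / s + rh / (1 - s)
    AMi <- sweep(A, 2, M, `/`)          # A %*% diag(1/M)
    S <- AMi %*% t(A)
    reg <- 1e-10 * max(mean(diag(S)), 1)  # guards rank collapse as columns
    dy <- tryCatch(solve(S + reg * diag(p), AMi %*% rhs1 + rp),  # deactivate
                   error = function(e) qr.solve(S + 1e-6 * max(diag(S)) * diag(p),
                                                AMi %*% rhs1 + rp))
    ds <- (rhs1 - drop(crossprod(A, dy))) / M
    dzl <- -(rl + zl * ds) / s
    dzh <- (-rh + zh * ds) / (1 - s)

    # separate primal/dual fraction-to-boundary steps
    ap <- 1; ad <- 1
    neg <- ds < 0; if (any(neg)) ap <- min(ap, min(-s[neg] / ds[neg]))
    pos <- ds > 0; if (any(pos)) ap <- min(ap, min((1 - s[pos]) / ds[pos]))
    neg <- dzl < 0; if (any(neg)) ad <- min(ad, min(-zl[neg] / dzl[neg]))
    neg <- dzh < 0; if (any(neg)) ad <- min(ad, min(-zh[neg] / dzh[neg]))
    ap <- min(0.995 * ap, 1); ad <- min(0.995 * ad, 1)
    s <- pmin(pmax(s + ap * ds, 1e-13), 1 - 1e-13)
    y <- y + ad * drop(dy)
    zl <- pmax(zl + ad * dzl, 1e-13)
    zh <- pmax(zh + ad * dzh, 1e-13)
    if (!all(is.finite(c(s, y, zl, zh)))) break
  }

  rp <- drop(A %*% s) - b
  if (is.null(feas_tol)) feas_tol <- 1e-6 * scale_b
  feasible <- max(abs(rp)) <= feas_tol
  if (feasible) {
    pol <- .polish_active_set(A, b, s, y)
    s <- pol$s; y <- pol$y
  } else {
    # capacity exceeded: report the bounded least-squares moment fit instead
    ls <- stats::optim(pmin(pmax(s, 0), 1),
                       fn = function(x) sum((drop(A %*% x) - b)^2),
                       gr = function(x) 2 * drop(crossprod(A, drop(A %*% x) - b)),
                       method = "L-BFGS-B", lower = 0, upper = 1,
                       control = list(maxit = 500, factr = 1e3))
    s <- ls$par
  }

  g <- 3 * s^2
  rd_free <- g + drop(crossprod(A, y))
  kkt <- .kkt_residual(A, b, s, y)
  list(s = s, objective = sum(s^3), lambda = y,
       kkt_residual = kkt, moment_residual = drop(A %*% s) - b,
       feasible = feasible, iterations = it)
}

# Active-set Newton polish: clamp near-bound activations exactly, re-solve the
# equality-constrained cubic program on the free set, verify multiplier signs.
.polish_active_set <- function(A, b, s, y, tol_act = 1e-7, max_pass = 10) {
  m <- length(s)
  at_lo <- s < tol_act
  at_hi <- s > 1 - tol_act
  for (pass in seq_len(max_pass)) {
    free <- !(at_lo | at_hi)
    sf <- s; sf[at_lo] <- 0; sf[at_hi] <- 1
    if (any(free)) {
      Af <- A[, free, drop = FALSE]
      bf <- b - drop(A[, at_hi, drop = FALSE] %*% rep(1, sum(at_hi)))
      x <- pmin(pmax(sf[free], 1e-6), 1)
      for (k in 1:50) {
        g <- 3 * x^2
        H <- pmax(6 * x, 1e-9)
        r1 <- g + drop(crossprod(Af, y))
        r2 <- drop(Af %*% x) - bf
        AHi <- sweep(Af, 2, H, `/`)
        S <- AHi %*% t(Af)
        dy <- .pinv_solve(S, -AHi %*% r1 + r2)
        dx <- -(r1 + drop(crossprod(Af, dy))) / H
        # keep iterates inside (0, 1); variables that hit a bound are clamped
        # on the next pass
        alpha <- 1
        hit_lo <- dx < 0 & x + dx < 0
        hit_hi <- dx > 0 & x + dx > 1
        if (any(hit_lo)) alpha <- min(alpha, min(-x[hit_lo] / dx[hit_lo]))
        if (any(hit_hi)) alpha <- min(alpha, min((1 - x[hit_hi]) / dx[hit_hi]))
        x <- x + alpha * dx
        y <- y + drop(dy)
        if (max(abs(dx)) < 1e-14 && max(abs(r2)) < 1e-12) break
      }
      sf[free] <- x
    } else {
      # all activations clamped; multipliers from least squares on r1 = 0
      y <- .pinv_solve(t(A), -3 * sf^2)
    }
    s <- sf
    # multiplier sign check on clamped variables
    red <- 3 * s^2 + drop(crossprod(A, y))
    bad_lo <- at_lo & red < -1e-9     # wants to increase from 0: release
    bad_hi <- at_hi & red > 1e-9      # wants to decrease from 1: release
    newly_lo <- !at_lo & s < tol_act
    newly_hi <- !at_hi & s > 1 - tol_act
    if (!any(bad_lo | bad_hi | newly_lo | newly_hi)) break
    at_lo <- (at_lo & !bad_lo) | newly_lo
    at_hi <- (at_hi & !bad_hi) | newly_hi
  }
  list(s = s, y = y)
}

# Moore-Penrose solve (rank-deficient safe).
.pinv_solve <- function(M, v) {
  sv <- svd(M)
  keep <- sv$d > max(sv$d[1], 1e-300) * 1e-12
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], v)) / sv$d[keep]))
}

# Max-norm KKT residual of the bound-constrained cubic program.
.kkt_residual <- function(A, b, s, y) {
  red <- 3 * s^2 + drop(crossprod(A, y))
  # stationarity projected onto bounds: interior -> |red|; at 0 -> max(-red,0);
  # at 1 -> max(red, 0)
  r <- abs(red)
  r[s <= 1e-9] <- pmax(-red[s <= 1e-9], 0)
  r[s >= 1 - 1e-9] <- pmax(red[s >= 1 - 1e-9], 0)
  max(c(r, abs(drop(A %*% s) - b)))
}

#' Static optimization of muscle forces at one time point
#'
#' Builds the joint-moment equilibrium constraints from the current muscle
#' geometry (tendon-excursion moment arms) and Hill forces affine in
#' activation, then solves the cubed-activation program. Equilibrium is
#' enforced on the hip (3 components), knee flexion-extension and ankle
#' dorsiflexion-plantarflexion moments; the remaining knee components are
#' balanced by the contact/ligament solve.
#'
#' @param moments named numeric vector of required net muscle moments (N mm)
#'   for the constrained DOFs (names from `geom$moment_arms` columns).
#' @param geom muscle geometry from [compute_muscle_geometry()]: lengths and
#'   per-DOF moment arms.
#' @param muscles muscle set from [load_muscle_set()].
#' @param ... passed to [solve_activation_program()].
#' @return an `activation_solution`: activations, forces (N), objective,
#'   residuals and solver diagnostics.
#' @export
solve_static_optimization <- function(moments, geom, muscles, ...) {
  dofs <- names(moments)
  stopifnot(all(dofs %in% colnames(geom$moment_arms)))
  lnorm <- normalized_fiber_length(muscles, geom$length)
  alpha <- muscles$fmax * active_force_length(lnorm)   # dF/ds
  beta <- muscles$fmax * passive_force_length(lnorm)   # activation-independent
  R <- t(geom$moment_arms[, dofs, drop = FALSE])       # p x m, mm
  A <- sweep(R, 2, alpha, `*`)
  b <- as.numeric(moments) - drop(R %*% beta)
  sol <- solve_activation_program(A, b, ...)
  forces <- alpha * sol$s + beta
  structure(list(activations = stats::setNames(sol$s, muscles$name),
                 forces = stats::setNames(forces, muscles$name),
                 objective = sol$objective,
                 moment_residual = stats::setNames(sol$moment_residual, dofs),
                 kkt_residual = sol$kkt_residual,
                 feasible = sol$feasible,
                 iterations = sol$iterations),
            class = "activation_solution")
}

#' @export
print.activation_solution <- function(x, ...) {
  cat("Static optimization solution\n")
  cat(sprintf("  objective sum(s^3): %.6g  (feasible: %s, %d IP iterations)\n",
              x$objective, x$feasible, x$iterations))
  cat(sprintf("  max |moment residual|: %.3g N mm, KKT residual: %.3g\n",
              max(abs(x$moment_residual)), x$kkt_residual))
  act <- x$activations[x$activations > 1e-4]
  if (length(act)) {
    cat("  active muscles:\n")
    for (n in names(sort(act, decreasing = TRUE))) {
      cat(sprintf("    %-28s %.3f\n", n, x$activations[[n]]))
    }
  } else cat("  (all activations ~ 0)\n")
  invisible(x)
}
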