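#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx optim rnorm runif sd setNames spline splinefun
#' @importFrom utils read.csv write.csv packageVersion
NULL

# Global coordinate convention used everywhere in the package (right leg):
# right-handed, X anterior, Y superior, Z lateral. Lengths in mm, forces in N,
# stresses in MPa, angles in rad unless a function says otherwise.

#' Elementary rotation matrices
#'
#' Right-handed rotations about the global axes of the package convention
#' (X anterior, Y superior, Z lateral).
#'
#' @param a rotation angle (rad).
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Rigid transform as rotation + translation
#'
#' @param R 3x3 rotation matrix.
#' @param t translation vector (length 3).
#' @return list with elements `R` and `t`; applies as `x -> R x + t`.
#' @keywords internal
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  list(R = R, t = as.numeric(t))
}

#' Compose two rigid transforms (`a` after `b`: x -> a(b(x)))
#' @keywords internal
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Apply a rigid transform to an n x 3 matrix of points (rows)
#' @keywords internal
apply_transform <- function(tr, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(tr$R), 2, tr$t, `+`)
}

#' Invert a rigid transform
#' @keywords internal
invert_transform <- function(tr) {
  Rt <- t(tr$R)
  rigid_transform(Rt, -as.numeric(Rt %*% tr$t))
}

#' Skew-symmetric cross-product matrix
#' @keywords internal
skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Cross product of two 3-vectors
#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean norm
#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a vector, erroring on (near-)zero length
#' @keywords internal
vhat <- function(v, tol = 1e-12) {
  n <- vnorm(v)
  if (n < tol) stop("cannot normalize a zero-length vector")
  v / n
}

#' Validate a scalar numeric field, erroring with the field name
#' @keywords internal
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("field '%s' must be a single positive finite number", name))
  }
  invisible(x)
}

#' @keywords internal
check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    stop(sprintf("field '%s' must be a single non-negative finite number", name))
  }
  invisible(x)
}

#' Gravitational acceleration (m s^-2) used for body-weight normalization
#' @keywords internal
GRAVITY <- 9.81

#' Path to a packaged configuration/fixture file
#'
#' @param name file name under the package's `extdata` directory.
#' @return absolute path to the file.
#' @export
kneegait_extdata <- function(name) {
  p <- system.file("extdata", name, package = "kneegait")
  if (!nzchar(p)) stop(sprintf("packaged data file '%s' not found", name))
  p
}
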