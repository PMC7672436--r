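# Low-level vector/rotation helpers shared across modules.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / n
}

#' Wrap angles into (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis
#' @param axis Length-3 axis (need not be unit).
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- .unit(axis)
  th <- .deg2rad(angle_deg)
  c1 <- cos(th); s1 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

.rot_z <- function(angle_deg) rotation_about(c(0, 0, 1), angle_deg)

.is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

# Kabsch: proper rotation R and translation t minimizing ||ref %*% t(R) + t - obs||.
# Returns list(rotation, translation, rmsd).
.kabsch <- function(ref, obs) {
  stopifnot(nrow(ref) == nrow(obs), nrow(ref) >= 3)
  mr <- colMeans(ref); mo <- colMeans(obs)
  A <- sweep(ref, 2, mr); B <- sweep(obs, 2, mo)
  sv <- svd(crossprod(A, B))  # t(A) %*% B
  d <- sign(det(sv$v %*% t(sv$u)))
  if (sum(svd(B)$d > 1e-6) < 2) stop("degenerate (collinear) coordinates: cannot fit a frame")
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- mo - as.vector(R %*% mr)
  fit <- sweep(A %*% t(R), 2, mo, "+")
  rmsd <- sqrt(mean(rowSums((fit - obs)^2)))
  list(rotation = R, translation = t, rmsd = rmsd)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from the second toward the third point, a
#' clockwise rotation of the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Length-3 coordinate vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (.vnorm(b2) < 1e-9) stop("undefined dihedral: coincident central points")
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  if (.vnorm(n1) < 1e-9 || .vnorm(n2) < 1e-9) {
    stop("undefined dihedral: collinear points")
  }
  m1 <- pracma_cross(n1, b2 / .vnorm(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  wrap_angle(.rad2deg(atan2(y, x)))
}

# cross product (no external dependency)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle subtended at a vertex
#' @param a,vertex,b Length-3 points; angle a-vertex-b.
#' @return Degrees in [0, 180].
#' @export
angle3 <- function(a, vertex, b) {
  v1 <- a - vertex; v2 <- b - vertex
  if (.vnorm(v1) < 1e-9 || .vnorm(v2) < 1e-9) stop("undefined angle: coincident points")
  .rad2deg(acos(max(-1, min(1, sum(.unit(v1) * .unit(v2))))))
}

# Signed angle from a to b about axis n (all 3-vectors), degrees.
.signed_angle_about <- function(a, b, n) {
  nn <- .unit(n)
  a <- a - sum(a * nn) * nn
  b <- b - sum(b * nn) * nn
  .rad2deg(atan2(sum(pracma_cross(a, b) * nn), sum(a * b)))
}
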