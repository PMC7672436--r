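# Independent oracles used across the suite.  These deliberately avoid the
# package's own geometry routines.

rand_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# four-point dihedral via projection onto the plane normal to the central
# bond (independent formulation from the package's atan2-of-cross version)
dihedral_oracle <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  v1 <- (p1 - p2) - sum((p1 - p2) * b) * b
  v2 <- (p4 - p3) - sum((p4 - p3) * b) * b
  cosphi <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  sgn <- sign(sum(cross3(v1, v2) * b))
  ang <- acos(max(-1, min(1, cosphi))) * 180 / pi
  # package/IUPAC convention: positive when far bond rotates clockwise
  -sgn * ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Kabsch via the quaternion eigenvalue method (Horn 1987) -- independent of
# the package's SVD route.  Returns rotation taking ref onto obs (after
# centering) and the superposition RMSD.
kabsch_oracle <- function(ref, obs) {
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(obs, 2, colMeans(obs))
  M <- crossprod(A, B)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz), 4, 4)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)), 3, 3,
    byrow = TRUE)
  fit <- A %*% t(R)
  list(rotation = R, rmsd = sqrt(mean(rowSums((fit - B)^2))))
}

# potential differences of a gradient field by composite-trapezoid line
# integration along grid paths (first along x at fixed first row, then
# along y), for curl-free fields on a regular grid
line_integral_oracle <- function(xs, ys, gx, gy) {
  nx <- length(xs); ny <- length(ys)
  dx <- diff(xs)[1]; dy <- diff(ys)[1]
  V <- matrix(0, nx, ny)
  for (i in 2:nx) V[i, 1] <- V[i - 1, 1] + dx * (gx[i - 1, 1] + gx[i, 1]) / 2
  for (j in 2:ny) V[, j] <- V[, j - 1] + dy * (gy[, j - 1] + gy[, j]) / 2
  V
}

# shared tolerance for exact algebra
TOL6 <- 1e-6

random_pair_params <- function() {
  base_pair_params(shear = runif(1, -3, 3), stretch = runif(1, -3, 3),
                   stagger = runif(1, -3, 3), buckle = runif(1, -60, 60),
                   propeller = runif(1, -60, 60), opening = runif(1, -60, 60))
}

params_vec <- function(p) unlist(p[c("shear", "stretch", "stagger",
                                     "buckle", "propeller", "opening")])

# analytic fe_surface on a grid (zero stderr) from a model surface
surface_on_grid <- function(msurf, spec, stderr = 0) {
  ctr <- pairscape:::.all_centers(spec)
  v <- if (spec$dims == 2) msurf$V(ctr[, 1], ctr[, 2]) else msurf$V(ctr[, 1])
  s <- structure(list(spec = spec, value = v - min(v),
                      stderr = rep(stderr, length(v)),
                      mask = rep(FALSE, length(v))),
                 class = "fe_surface")
  s
}
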