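# Internal geometry helpers. Coordinates are N x 3 matrices in Angstrom,
# frames right-handed.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

.com <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  colMeans(xyz)
}

# Angle between two vectors in degrees, in [0, 180].
.angle_deg <- function(a, b) {
  ct <- sum(.unit(a) * .unit(b))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees.
.rotation_about_axis <- function(axis, angle_deg) {
  u <- .unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Apply a rotation matrix to an N x 3 coordinate matrix.
.rotate_coords <- function(xyz, R) {
  xyz %*% t(R)
}

# Coordinates of atoms data.frame as an N x 3 matrix.
.coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# Express coordinates in a pore frame: origin at frame$origin, z along
# frame$axis. The two in-plane basis vectors are an arbitrary (but
# deterministic) orthonormal completion; only z and the radial distance
# sqrt(x^2 + y^2) are frame-invariant quantities, which is all downstream
# code uses.
.to_frame <- function(xyz, frame) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  ez <- .unit(frame$axis)
  ref <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- .unit(ref - sum(ref * ez) * ez)
  ey <- c(
    ez[2] * ex[3] - ez[3] * ex[2],
    ez[3] * ex[1] - ez[1] * ex[3],
    ez[1] * ex[2] - ez[2] * ex[1]
  )
  centred <- sweep(xyz, 2, frame$origin)
  cbind(centred %*% ex, centred %*% ey, centred %*% ez)
}

# Pairwise Euclidean distances between rows of two coordinate matrices.
.cross_dist <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}
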