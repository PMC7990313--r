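## Internal vector geometry: everything operates on plain numeric vectors
## of length 3 or N x 3 matrices, lengths in nm unless stated otherwise.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Angle at B in degrees for points A-B-C
vec_angle <- function(a, b, c) {
  u <- unitv(a - b); v <- unitv(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Signed dihedral A-B-C-D in degrees, IUPAC convention
dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## NeRF chain extension: place atom D bonded to C with |CD| = r,
## angle(B,C,D) = theta (deg) and dihedral(A,B,C,D) = phi (deg).
place_atom <- function(a, b, c, r, theta, phi) {
  th <- theta * pi / 180
  ph <- phi * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## Rotation matrix about unit axis by angle (radians), Rodrigues form
rotation_matrix <- function(axis, angle) {
  u <- unitv(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Minimum distance between two sets of points (rows); plain but vectorised
min_pair_dist <- function(xa, xb) {
  ## cross squared-distance matrix via the usual expansion
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(max(0, min(d2)))
}

## Full pairwise distance matrix between row sets
cross_dist <- function(xa, xb) {
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Round half away from zero (printed tables use half-up, not banker's)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
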