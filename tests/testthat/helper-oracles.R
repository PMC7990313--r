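## Independent oracles used across the suite. These are deliberately naive
## second implementations (scalar loops, closed forms) kept separate from
## the package code paths they check.

## Exhaustive O(N^2) geometric hydrogen-bond scan with its own vector math.
## Donors: N/O/S with a hydrogen position; acceptors: N/O. Same criterion as
## the package (d <= d_max, H-D-A angle <= angle_max, same-chain residue
## separation >= 2) but computed scalar-by-scalar.
bf_hbond_count <- function(system, xyz = NULL, d_max = 0.35,
                           angle_max = 30) {
  xyz <- if (is.null(xyz)) system$xyz else xyz
  a <- system$atoms
  h <- ecdyn:::construct_amide_h(system, xyz)
  count <- 0L
  for (i in seq_len(nrow(a))) {
    if (!(a$element[i] %in% c("N", "O", "S"))) next
    if (is.na(h[i, 1])) next
    for (j in seq_len(nrow(a))) {
      if (i == j || !(a$element[j] %in% c("N", "O"))) next
      if (a$chain[i] == a$chain[j] && abs(a$resid[i] - a$resid[j]) < 2) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > d_max || d < 1e-6) next
      v1 <- h[i, ] - xyz[i, ]
      v2 <- xyz[j, ] - xyz[i, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (ang <= angle_max) count <- count + 1L
    }
  }
  count
}

## Closed-form accessible area of two identical fused spheres of expanded
## radius R at centre distance D (< 2R): each loses a cap of height
## h = R - D/2.
two_sphere_area <- function(R, D) {
  h <- R - D / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

## Cyclic Jacobi eigensolver: an eigen() independent route for small
## symmetric matrices.
jacobi_eigen <- function(m, tol = 1e-12, max_sweeps = 100) {
  a <- as.matrix(m)
  n <- nrow(a)
  v <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- sqrt(sum(a[upper.tri(a)]^2))
    if (off < tol) break
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        if (abs(a[p, q]) < tol / n) next
        theta <- 0.5 * atan2(2 * a[p, q], a[q, q] - a[p, p])
        c_ <- cos(theta); s_ <- sin(theta)
        rot <- diag(n); rot[p, p] <- c_; rot[q, q] <- c_
        rot[p, q] <- s_; rot[q, p] <- -s_
        a <- t(rot) %*% a %*% rot
        v <- v %*% rot
      }
    }
  }
  ord <- order(diag(a), decreasing = TRUE)
  list(values = diag(a)[ord], vectors = v[, ord, drop = FALSE])
}

## Brute-force rigid superposition: exhaustive Euler-angle grid (with local
## refinement) minimising RMSD of mobile onto ref after centroid matching.
bf_superpose_rmsd <- function(mobile, ref, coarse = 15) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  m0 <- sweep(mobile, 2, cm); r0 <- sweep(ref, 2, cr)
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz2 <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rz2
  }
  eval_r <- function(ang) {
    r <- rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((m0 %*% t(r) - r0)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = coarse)
  gridb <- seq(0, pi, length.out = ceiling(coarse / 2))
  best <- c(0, 0, 0); best_v <- eval_r(best)
  for (a in grid) for (b in gridb) for (c in grid) {
    v <- eval_r(c(a, b, c))
    if (v < best_v) { best <- c(a, b, c); best_v <- v }
  }
  stats::optim(best, eval_r, method = "Nelder-Mead",
               control = list(reltol = 1e-12))$value
}

## Rand index between two partitions given as membership vectors
rand_index <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")[upper.tri(diag(n))]
  same_y <- outer(y, y, "==")[upper.tri(diag(n))]
  mean(same_x == same_y)
}

## Tiny fixture: a single free atom system of one element
atom_system <- function(elements, xyz) {
  suppressWarnings(ecdyn::md_system(
    tibble::tibble(name = elements, element = elements,
                   resid = seq_along(elements), resname = "ALA",
                   chain = "A"),
    xyz))
}

build_quiet <- function(...) suppressWarnings(ecdyn::build_peptide(...))
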