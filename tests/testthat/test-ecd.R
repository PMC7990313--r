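## Small stationary synthetic system reused across ECD tests: two chain
## groups driven by disjoint coherent modes over per-atom noise.
ecd_fixture <- function(n_frames = 2000, noise = 0.002, seed = 3) {
  sys <- suppressWarnings(build_mixture(n_abeta = 4, n_scp = 0, box = 9,
                                        seed = 11))
  g1 <- select_atoms(sys, chains = c("A", "B"))
  g2 <- select_atoms(sys, chains = c("C", "D"))
  modes <- list(
    latent_mode(g1, 0.1, 10, c(1, 0, 0)),
    latent_mode(g1, 0.1, 10, c(0, 1, 1)),
    latent_mode(g2, 0.1, 10, c(0, 0, 1)),
    latent_mode(g2, 0.1, 10, c(1, 1, 0)))
  sim <- simulate_trajectory(sys, modes = modes, schedule = NULL,
                             noise_sd = noise, n_frames = n_frames, dt = 2,
                             seed = seed)
  list(sys = sys, sim = sim,
       ca = select_atoms(sys, names = "CA"),
       group1 = c("A", "B"))
}

test_that("segmentation counts and truncation follow the window", {
  sys <- build_quiet("AGAGA")
  tr <- md_trajectory(sys, matrix(0, 110, 3 * nrow(sys$atoms)), dt = 200)
  ## 20 ns window at 0.2 ns segments -> 100 segments
  segs <- ecd_segments(tr, seg_len = 200, window = "first:20ns")
  expect_equal(length(segs), 100)
  ## window of exactly one segment
  tr2 <- md_trajectory(sys, matrix(0, 10, 3 * nrow(sys$atoms)), dt = 20)
  expect_equal(length(ecd_segments(tr2, seg_len = 200)), 1)
  ## 1.5 segments -> 1, remainder dropped
  tr3 <- md_trajectory(sys, matrix(0, 15, 3 * nrow(sys$atoms)), dt = 20)
  segs3 <- ecd_segments(tr3, seg_len = 200)
  expect_equal(length(segs3), 1)
  expect_equal(segs3[[1]], 1:10)
  ## window shorter than a segment errors
  expect_error(ecd_segments(tr2, seg_len = 500), "shorter")
})

test_that("covariance is zero for identical frames and kills rigid motion when aligned", {
  sys <- build_quiet("AGAGA")
  x <- as.numeric(t(sys$xyz))
  tr <- md_trajectory(sys, rbind(x, x, x), dt = 1)
  cv <- ecd_covariance(tr, align = FALSE)
  expect_lt(max(abs(cv)), 1e-20)
  ## pure translation, aligned away
  tr2 <- md_trajectory(sys, rbind(x, x + 0.5, x + 1.0), dt = 1)
  cv2 <- ecd_covariance(tr2, align = TRUE)
  expect_lt(max(abs(cv2)), 1e-10)
  expect_error(ecd_covariance(tr, frames = 1), "at least 2")
})

test_that("covariance eigenpairs match explicit accumulation and a Jacobi oracle", {
  set.seed(21)
  n_atoms <- 3; n_frames <- 100
  coords <- matrix(rnorm(n_frames * 3 * n_atoms, sd = 0.1), n_frames)
  cv <- ecd_covariance(coords, align = FALSE)
  ## explicit accumulation
  mu <- colMeans(coords)
  acc <- matrix(0, 9, 9)
  for (t in seq_len(n_frames)) {
    d <- coords[t, ] - mu
    acc <- acc + outer(d, d)
  }
  acc <- acc / n_frames
  expect_equal(unname(cv), acc, tolerance = 1e-12, ignore_attr = TRUE)
  em <- essential_modes(cv, d = 9)
  expect_equal(em$values, eigen(acc, symmetric = TRUE)$values,
               tolerance = 1e-10)
  ## independent Jacobi eigensolver on a random PSD 12x12
  m <- crossprod(matrix(rnorm(144), 12))
  jac <- jacobi_eigen(m)
  em2 <- suppressMessages(essential_modes(m, d = 12))
  expect_equal(em2$values, jac$values, tolerance = 1e-9)
  for (k in 1:12) {
    expect_equal(abs(sum(em2$vectors[, k] * jac$vectors[, k])), 1,
                 tolerance = 1e-6)
  }
})

test_that("trace is conserved and eigenvectors are orthonormal", {
  fx <- ecd_fixture(n_frames = 400)
  segs <- ecd_segments(fx$sim$traj, seg_len = 200)
  for (s in segs[1:2]) {
    cv <- ecd_covariance(fx$sim$traj, frames = s, selection = fx$ca)
    em <- suppressMessages(essential_modes(cv, d = 10))
    ## trace equals total per-coordinate variance of the aligned block
    expect_equal(em$trace, sum(diag(cv)), tolerance = 1e-12)
    gram <- crossprod(em$vectors)
    expect_lt(max(abs(gram - diag(10))), 1e-8)
    expect_true(all(diff(em$values) <= 1e-12))
  }
})

test_that("closed-form eigenstructure: rank-1 and isotropic covariances", {
  u <- ecdyn:::unitv(rnorm(12))
  c1 <- 0.04 * outer(u, u)
  e1 <- suppressMessages(essential_modes(c1, d = 5))
  expect_equal(e1$values[1] / e1$trace, 1, tolerance = 1e-12)
  expect_lt(max(e1$values[-1]), 1e-14)
  ## isotropic sigma^2 I on 4 atoms: all eigenvalues sigma^2, f_10 = 10/12
  iso <- suppressMessages(essential_modes(diag(0.01, 12), d = 10))
  expect_equal(iso$values, rep(0.01, 10))
  expect_equal(iso$fraction, 10 / 12, tolerance = 1e-12)
  expect_error(essential_modes(diag(3), d = 5), "exceeds")
})

test_that("atom images follow the definition", {
  ## two atoms moving identically in every mode have identical images;
  ## an atom with zero components is at the origin
  vec <- matrix(0, 9, 2)
  vec[1, 1] <- 1 / sqrt(2); vec[4, 1] <- 1 / sqrt(2)
  vec[2, 2] <- 1 / sqrt(2); vec[5, 2] <- 1 / sqrt(2)
  em <- structure(list(values = c(0.02, 0.01), vectors = vec, trace = 0.04,
                       fraction = 0.75, d = 2), class = "essential_modes")
  img <- atom_images(em)
  expect_equal(img[1, ], img[2, ], tolerance = 1e-12)
  expect_equal(img[3, ], rep(0, 6))
  ## explicit formula for atom 1, mode 1 component
  expect_equal(img[1, 1], sqrt(0.02) * (1 / sqrt(2)) / sqrt(0.03),
               tolerance = 1e-12)
})

test_that("disjoint-mode groups separate cleanly in image space", {
  fx <- ecd_fixture(n_frames = 1000, noise = 0.001)
  segs <- ecd_segments(fx$sim$traj, seg_len = 200)
  sel <- fx$ca
  in_g1 <- fx$sys$atoms$chain[sel] %in% fx$group1
  m <- ecdyn:::essential_modes_traj(fx$sim$traj$coords, segs[[1]], sel,
                                    d = 10, align = FALSE)
  img <- atom_images(m)
  d_all <- as.matrix(dist(img))
  intra <- max(d_all[in_g1, in_g1], d_all[!in_g1, !in_g1])
  inter <- min(d_all[in_g1, !in_g1])
  expect_gt(inter, 3 * intra)
})

test_that("pair correlation is symmetric, zero-diagonal, block-structured", {
  fx <- ecd_fixture(n_frames = 1000)
  rho <- ecd_pair_correlation(fx$sim$traj, selection = fx$ca, seg_len = 200)
  expect_equal(unname(unclass(rho)), t(unclass(rho)), ignore_attr = TRUE)
  expect_true(all(diag(rho) == 0))
  in_g1 <- fx$sys$atoms$chain[fx$ca] %in% fx$group1
  within <- mean(rho[in_g1, in_g1][upper.tri(rho[in_g1, in_g1])])
  between <- mean(rho[in_g1, !in_g1])
  expect_lt(within, between)
})

test_that("identical motion gives exactly coincident images (rho = 0)", {
  sys <- build_quiet(backbone_spec(strrep("A", 8), motif = "strand"))
  all_at <- seq_len(nrow(sys$atoms))
  modes <- list(latent_mode(all_at, 0.1, 10, c(1, 0, 0)),
                latent_mode(all_at, 0.05, 20, c(0, 1, 0)))
  sim <- simulate_trajectory(sys, modes = modes, noise_sd = 0,
                             n_frames = 400, dt = 2, seed = 8)
  rho <- ecd_pair_correlation(sim$traj, selection = all_at, seg_len = 200,
                              align = FALSE)
  expect_lt(max(rho), 1e-8)
})

test_that("flexibility is zero for identical motion and spots the noisy atom", {
  sys <- build_quiet(backbone_spec(strrep("A", 10), motif = "strand"))
  all_at <- seq_len(nrow(sys$atoms))
  modes <- list(latent_mode(all_at, 0.1, 10, c(1, 0, 0)))
  sim0 <- simulate_trajectory(sys, modes = modes, noise_sd = 0,
                              n_frames = 400, dt = 2, seed = 5)
  fl0 <- ecd_flexibility(sim0$traj, selection = all_at, seg_len = 200)
  expect_lt(max(fl0$flexibility), 1e-8)
  ## one atom with extra independent noise has the strictly largest f
  ns <- rep(0.002, nrow(sys$atoms)); ns[7] <- 0.02
  sim1 <- simulate_trajectory(sys, modes = modes, noise_sd = ns,
                              n_frames = 400, dt = 2, seed = 6)
  fl1 <- ecd_flexibility(sim1$traj, selection = all_at, seg_len = 200)
  expect_equal(which.max(fl1$flexibility), 7)
  expect_gt(sort(fl1$flexibility, decreasing = TRUE)[1],
            sort(fl1$flexibility, decreasing = TRUE)[2] * 2)
})

test_that("domain clustering splits exactly at a threshold in the gap", {
  fx <- ecd_fixture(n_frames = 1000)
  ## recovery protocol: no rigid motion in the generator, so no alignment
  rho <- ecd_pair_correlation(fx$sim$traj, selection = fx$ca, seg_len = 200,
                              align = FALSE)
  in_g1 <- fx$sys$atoms$chain[fx$ca] %in% fx$group1
  within <- max(rho[in_g1, in_g1], rho[!in_g1, !in_g1])
  between <- min(rho[in_g1, !in_g1])
  expect_gt(between, within)
  thr <- (within + between) / 2
  dom <- ecd_domains(fx$sim$traj, selection = fx$ca, threshold = thr,
                     min_size = 10, seg_len = 200, align = FALSE)
  expect_equal(length(unique(dom$domain)), 2)
  expect_equal(rand_index(dom$domain, as.integer(in_g1)), 1.0)
  ## rank 1 is the largest (here equal sizes; both present)
  expect_setequal(unique(dom$domain), c(1L, 2L))
  ## threshold below every pairwise distance: all atoms off-domain
  tiny <- ecd_domains(fx$sim$traj, selection = fx$ca, threshold = 1e-9,
                      min_size = 10, seg_len = 200, align = FALSE)
  expect_true(all(is.na(tiny$domain)))
  expect_error(ecd_domains(fx$sim$traj, threshold = 0), "positive")
})

test_that("descriptors are invariant to rigid rotation of the input frames", {
  fx <- ecd_fixture(n_frames = 400)
  tr <- fx$sim$traj
  r <- ecdyn:::rotation_matrix(c(1, 2, 0.5), 1.2)
  rot <- tr
  for (t in seq_len(n_frames(tr))) {
    fr <- frame_xyz(tr, t) %*% t(r)
    rot$coords[t, ] <- as.numeric(t(fr))
  }
  rho1 <- ecd_pair_correlation(tr, selection = fx$ca, seg_len = 200)
  rho2 <- ecd_pair_correlation(rot, selection = fx$ca, seg_len = 200)
  expect_equal(unclass(rho1), unclass(rho2), tolerance = 1e-6,
               ignore_attr = TRUE)
  fl1 <- ecd_flexibility(tr, selection = fx$ca, seg_len = 200)
  fl2 <- ecd_flexibility(rot, selection = fx$ca, seg_len = 200)
  expect_equal(fl1$flexibility, fl2$flexibility, tolerance = 1e-6)
})

test_that("window-averaged descriptors are stable under 2x longer segments", {
  fx <- ecd_fixture(n_frames = 2000)
  rho1 <- ecd_pair_correlation(fx$sim$traj, selection = fx$ca, seg_len = 200)
  rho2 <- ecd_pair_correlation(fx$sim$traj, selection = fx$ca, seg_len = 400)
  off1 <- mean(rho1[upper.tri(rho1)])
  off2 <- mean(rho2[upper.tri(rho2)])
  expect_lt(abs(off1 - off2) / off1, 0.10)
  fl1 <- ecd_flexibility(fx$sim$traj, selection = fx$ca, seg_len = 200)
  fl2 <- ecd_flexibility(fx$sim$traj, selection = fx$ca, seg_len = 400)
  expect_lt(abs(mean(fl1$flexibility) - mean(fl2$flexibility)) /
              mean(fl1$flexibility), 0.10)
})
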