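two_chain_system <- function(gap_nm) {
  a <- build_quiet(backbone_spec("VVVV", motif = "strand"), chain = "A")
  b <- build_quiet(backbone_spec("VVVV", motif = "strand"), chain = "B")
  ## translate B along x until the minimum inter-chain distance equals
  ## gap_nm (few fixed-point corrections since the gap is not linear in the
  ## shift)
  shift <- 50
  for (k in 1:6) {
    b2 <- ecdyn:::transform_system(b, translation = c(shift, 0, 0))
    d <- ecdyn:::min_pair_dist(a$xyz, b2$xyz)
    shift <- shift - (d - gap_nm)
  }
  ecdyn:::combine_systems(
    list(a, ecdyn:::transform_system(b, translation = c(shift, 0, 0))))
}

test_that("contact edges appear exactly at the cutoff", {
  expect_false(contact_graph(two_chain_system(5))["A", "B"])
  expect_true(contact_graph(two_chain_system(0.35))["A", "B"])
  g <- contact_graph(two_chain_system(0.35))
  expect_true(isSymmetric(g))
  expect_false(any(diag(g)))
})

test_that("cutoff sweep on a trimer matches the exhaustive distance table", {
  set.seed(3)
  chains <- lapply(c("A", "B", "C"), function(l) {
    s <- build_quiet(backbone_spec("VVVV", motif = "strand"), chain = l)
    ecdyn:::transform_system(s, translation = runif(3, 0, 2))
  })
  sys <- ecdyn:::combine_systems(chains)
  dists <- matrix(0, 3, 3)
  for (i in 1:2) for (j in (i + 1):3) {
    dists[i, j] <- dists[j, i] <-
      ecdyn:::min_pair_dist(chains[[i]]$xyz, chains[[j]]$xyz)
  }
  for (cutoff in c(0.2, 0.45, 1, 3)) {
    g <- contact_graph(sys, cutoff = cutoff)
    expect_equal(unname(g), dists <= cutoff & row(dists) != col(dists))
  }
})

test_that("raising the cutoff never splits a component", {
  sys <- suppressWarnings(build_mixture(n_abeta = 3, n_scp = 2, box = 6.5,
                                        min_gap = 0.3, seed = 14))
  cuts <- c(0.4, 0.6, 0.9, 1.5)
  parts <- lapply(cuts, function(ct) {
    aggregate_components(contact_graph(sys, cutoff = ct), sys)$partition
  })
  for (k in seq_along(cuts)[-1]) {
    ## every pair together at the smaller cutoff stays together
    prev <- parts[[k - 1]]; cur <- parts[[k]]
    for (i in seq_along(prev)) for (j in seq_along(prev)) {
      if (prev[i] == prev[j]) expect_true(unname(cur[i] == cur[j]))
    }
  }
})

test_that("composition strings are canonical and singletons are free", {
  sys <- suppressWarnings(build_mixture(n_abeta = 8, n_scp = 8, box = 7.5,
                                        seed = 1))
  empty <- matrix(FALSE, 16, 16, dimnames = list(LETTERS[1:16],
                                                 LETTERS[1:16]))
  st <- aggregate_components(empty, sys)
  expect_equal(nrow(st$components), 0)
  expect_equal(length(st$free), 16)
  ## constructed components {A,B,C,I,J} and {D,E}
  g <- empty
  for (p in list(c("A", "B"), c("B", "C"), c("C", "I"), c("I", "J"),
                 c("D", "E"))) {
    g[p[1], p[2]] <- g[p[2], p[1]] <- TRUE
  }
  st2 <- aggregate_components(g, sys)
  expect_equal(st2$components$composition,
               c("3Aβ42+2SST14", "2Aβ42"))
  ## relabelling within species leaves compositions unchanged
  g2 <- empty
  for (p in list(c("F", "G"), c("G", "H"), c("H", "K"), c("K", "L"),
                 c("A", "B"))) {
    g2[p[1], p[2]] <- g2[p[2], p[1]] <- TRUE
  }
  st3 <- aggregate_components(g2, sys)
  expect_equal(st3$components$composition, st2$components$composition)
})

test_that("scheduled merges are recovered as the final composition", {
  sys <- suppressWarnings(build_mixture(n_abeta = 2, n_scp = 2, box = 8.5,
                                        seed = 5))
  sched <- aggregation_schedule(tibble::tibble(
    time = c(20, 60), chain_a = c("A", "A"), chain_b = c("B", "I")),
    step_sd = 0.003, rot_sd = 0.2)
  sim <- simulate_trajectory(sys, schedule = sched, noise_sd = 0.005,
                             n_frames = 600, dt = 1, seed = 17)
  expect_equal(nrow(sim$truth$merges), 2)
  g <- contact_graph(sim$traj$system, frame_xyz(sim$traj, 600))
  st <- aggregate_components(g, sim$traj$system)
  truth <- truth_partition(sim$truth)
  truth_sizes <- sort(lengths(truth), decreasing = TRUE)
  expect_equal(st$components$size[1], truth_sizes[1])
  expect_equal(st$components$composition[1], "2Aβ42+1SST14")
  expect_equal(st$free, "J")
})

test_that("persistence filtering keeps majority edges and drops flickers", {
  sys <- two_chain_system(0.35)
  near <- as.numeric(t(sys$xyz))
  farxyz <- sys$xyz
  bidx <- which(sys$atoms$chain == "B")
  farxyz[bidx, 1] <- farxyz[bidx, 1] + 5
  far <- as.numeric(t(farxyz))
  ## 70% contact occupancy -> dimer
  tr <- md_trajectory(sys, rbind(near, near, near, near, near, near, near,
                                 far, far, far), dt = 1)
  tl <- aggregate_timeline(tr, window_frames = 10, persistence = 0.5)
  expect_equal(tl$composition, "2X")
  ## 40% -> dropped
  tr2 <- md_trajectory(sys, rbind(near, near, near, near, far, far, far,
                                  far, far, far), dt = 1)
  tl2 <- aggregate_timeline(tr2, window_frames = 10, persistence = 0.5)
  expect_equal(tl2$composition, "")
  expect_equal(tl2$free, "A,B")
  ## 60% kept at persistence 0.5
  tr3 <- md_trajectory(sys, tr$coords[c(1:6, 8:10, 8), ], dt = 1)
  tl3 <- aggregate_timeline(tr3, window_frames = 10, persistence = 0.5)
  expect_equal(tl3$composition, "2X")
})

test_that("terminus exposure flips exactly at the relative threshold", {
  chain <- build_quiet(backbone_spec("VVVVVV", motif = "strand"), chain = "A")
  free <- terminus_exposure(chain, "A", "C", n_points = 480)
  expect_equal(free$status, "surface")
  expect_gt(free$rel_sasa, 0.25)
  ## enclose the C-terminal residue in a cage of carbon atoms
  last <- which(chain$atoms$resid == max(chain$atoms$resid))
  centre <- colMeans(chain$xyz[last, , drop = FALSE])
  cage_pts <- ecdyn:::sphere_points(80) * 0.55 +
    rep(centre, each = 80)
  cage <- atom_system(rep("C", 80), cage_pts)
  cage$atoms$chain <- "B"
  cage$chains$label <- "B"
  caged <- suppressWarnings(ecdyn:::combine_systems(list(chain, cage)))
  buried <- terminus_exposure(caged, "A", "C", n_points = 480)
  expect_equal(buried$status, "buried")
  expect_lt(buried$rel_sasa, free$rel_sasa)
  ## classification flips exactly at the computed relative SASA
  eps <- 1e-9
  expect_equal(terminus_exposure(chain, "A", "C", n_points = 480,
                                 rel_threshold = free$rel_sasa - eps)$status,
               "surface")
  expect_equal(terminus_exposure(chain, "A", "C", n_points = 480,
                                 rel_threshold = free$rel_sasa + eps)$status,
               "buried")
})

test_that("contact classification types pi-pi, hydrogen bonds and hydrophobic pairs", {
  ## two phenylalanines with ring centroids 0.4 nm apart
  f1 <- build_quiet(backbone_spec("FF", motif = "strand"), chain = "A")
  cen <- function(sys, ch) {
    ring <- which(sys$atoms$chain == ch & sys$atoms$resid == 1 &
                    sys$atoms$name %in% c("CG", "CZ"))
    colMeans(sys$xyz[ring, , drop = FALSE])
  }
  f2 <- build_quiet(backbone_spec("FF", motif = "strand"), chain = "B")
  shift <- cen(f1, "A") - cen(f2, "B") + c(0.4, 0, 0)
  f2 <- ecdyn:::transform_system(f2, translation = shift)
  sys <- ecdyn:::combine_systems(list(f1, f2))
  cc <- classify_contacts(sys)
  pair <- cc[cc$resid_a == 1 & cc$resid_b == 1, ]
  expect_true(any(pair$aromatic_pipi))
  ## Leu-Val side-chain contact at 0.40 nm is hydrophobic; verify the
  ## distance against an exhaustive atom-pair scan
  l1 <- build_quiet(backbone_spec("LL", motif = "strand"), chain = "A")
  v1 <- build_quiet(backbone_spec("VV", motif = "strand"), chain = "B")
  sc <- function(sys, ch) which(sys$atoms$chain == ch &
                                  sys$atoms$name == "CB" &
                                  sys$atoms$resid == 1)
  delta <- l1$xyz[sc(l1, "A"), ] - v1$xyz[sc(v1, "B"), ] + c(0.40, 0, 0)
  v1 <- ecdyn:::transform_system(v1, translation = delta)
  sys2 <- ecdyn:::combine_systems(list(l1, v1))
  cc2 <- classify_contacts(sys2)
  pair2 <- cc2[cc2$resid_a == 1 & cc2$resid_b == 1, ]
  expect_true(any(pair2$hydrophobic))
  bf <- Inf
  ia <- which(sys2$atoms$chain == "A" & sys2$atoms$resid == 1 &
                sys2$atoms$name %in% c("CB", "CG", "CZ"))
  ib <- which(sys2$atoms$chain == "B" & sys2$atoms$resid == 1 &
                sys2$atoms$name %in% c("CB", "CG", "CZ"))
  for (i in ia) for (j in ib) {
    bf <- min(bf, sqrt(sum((sys2$xyz[i, ] - sys2$xyz[j, ])^2)))
  }
  expect_equal(bf, 0.40, tolerance = 1e-6)
  ## hydrogen-bonded contact pairs carry the hydrogen_bond flag
  sheet <- suppressWarnings(build_sheet("VVVVVV", "antiparallel"))
  ccs <- classify_contacts(sheet)
  hb <- find_hbonds(sheet)
  hb_inter <- hb[!hb$intra, ]
  expect_gt(nrow(hb_inter), 0)
  for (k in seq_len(nrow(hb_inter))) {
    hit <- ccs[(ccs$resid_a == hb_inter$donor_resid[k] &
                  ccs$resid_b == hb_inter$acceptor_resid[k]) |
               (ccs$resid_a == hb_inter$acceptor_resid[k] &
                  ccs$resid_b == hb_inter$donor_resid[k]), ]
    expect_true(any(hit$hydrogen_bond))
  }
})
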