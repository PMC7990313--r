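#' Latent collective mode for the synthetic generator
#'
#' A mode is a fixed unit displacement shape over a participating atom set
#' whose amplitude follows a stationary Ornstein-Uhlenbeck process with
#' stationary standard deviation `sigma` (nm) and correlation time `tau`
#' (ps). The default shape is a coherent translation of the participating
#' atoms along `direction`, i.e. every participant moves identically -- the
#' cleanest realisation of "correlated motion" that the ECD descriptors are
#' meant to detect.
#'
#' @param atoms Integer indices of participating atoms.
#' @param sigma Stationary amplitude SD in nm.
#' @param tau Correlation time in ps.
#' @param direction Length-3 direction of the coherent translation shape
#'   (normalised internally). Ignored when `shape` is given.
#' @param shape Optional explicit N_part x 3 matrix of per-atom displacement
#'   directions (normalised to a unit 3N-vector over participants).
#' @return A `latent_mode` list.
#' @export
latent_mode <- function(atoms, sigma, tau, direction = c(1, 0, 0),
                        shape = NULL) {
  stopifnot(sigma > 0, tau > 0, length(atoms) >= 1)
  if (is.null(shape)) {
    shape <- matrix(unitv(direction), length(atoms), 3, byrow = TRUE)
  }
  shape <- as.matrix(shape)
  stopifnot(nrow(shape) == length(atoms), ncol(shape) == 3)
  shape <- shape / sqrt(sum(shape^2))  # unit 3N-vector over participants
  structure(list(atoms = as.integer(atoms), sigma = sigma, tau = tau,
                 shape = shape), class = "latent_mode")
}

#' Scripted aggregation schedule
#'
#' @param events Data frame with columns `time` (ps, increasing) and
#'   `chain_a`, `chain_b`: at `time` the groups containing the two chains
#'   start drifting together; they are recorded as merged from the first
#'   frame their heavy atoms come within `contact_dist`.
#' @param step_sd Per-frame rigid random-walk translation SD per axis (nm).
#' @param rot_sd Per-frame rigid rotation step SD (degrees).
#' @param drift_rate Closing speed of a pending merge (nm/ps).
#' @param contact_dist Inter-group minimum atom distance (nm) at which a
#'   pending merge completes.
#' @return An `aggregation_schedule` list.
#' @export
aggregation_schedule <- function(events = NULL, step_sd = 0.01, rot_sd = 0.5,
                                 drift_rate = 0.02, contact_dist = 0.35) {
  if (!is.null(events)) {
    events <- tibble::as_tibble(events)
    stopifnot(all(c("time", "chain_a", "chain_b") %in% names(events)))
    if (is.unsorted(events$time)) abort("schedule event times must increase")
  }
  structure(list(events = events, step_sd = step_sd, rot_sd = rot_sd,
                 drift_rate = drift_rate, contact_dist = contact_dist),
            class = "aggregation_schedule")
}

#' Generate a synthetic trajectory with known ground truth
#'
#' Frame coordinates are built as rigid per-group motion applied to
#' (reference + sum of latent-mode displacements + isotropic per-atom
#' noise). The OU amplitude update is exact:
#' `a(t+dt) = a(t) exp(-dt/tau) + N(0, sigma^2 (1 - exp(-2 dt/tau)))`.
#' Chains move as independent rigid groups until a schedule event joins
#' them; joined groups drift into contact and then move as one. Contacts are
#' sticky: any two groups whose atoms come within the schedule's
#' `contact_dist` are merged and recorded, whether the approach was
#' scheduled or a chance encounter, so the recorded partition always is the
#' actual contact state of the trajectory.
#'
#' @param system Reference [md_system].
#' @param modes List of [latent_mode()] objects.
#' @param schedule An [aggregation_schedule()], or `NULL` for no rigid
#'   motion at all (chains held in place, internal motion only).
#' @param noise_sd Per-atom isotropic noise SD in nm (scalar or length-N).
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame spacing in ps.
#' @param seed Master seed; sub-streams for amplitudes, noise and rigid
#'   motion are derived at fixed offsets.
#' @return A list with `traj` (an [md_trajectory]) and `truth`, a list with
#'   `partition` (T x n_chains integer matrix of group ids), `amplitudes`
#'   (T x K matrix), `noise_sd` (length-N vector), `merges` (tibble of
#'   completed merges with first-contact frames) and `seed`.
#' @export
simulate_trajectory <- function(system, modes = list(), schedule = NULL,
                                noise_sd = 0, n_frames = 100, dt = 1,
                                seed = 1) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  n <- n_atoms(system)
  for (m in modes) {
    if (any(m$atoms < 1 | m$atoms > n)) {
      abort("latent mode participant set lies outside the system")
    }
  }
  noise_sd <- rep_len(noise_sd, n)
  chains <- system$chains$label
  chain_of <- match(system$atoms$chain, chains)
  k <- length(modes)

  ## stream 1: OU amplitudes, exact stationary update
  set.seed(seed + 1L)
  amp <- matrix(0, n_frames, max(k, 1))
  if (k > 0) {
    for (j in seq_len(k)) {
      s <- modes[[j]]$sigma
      rho <- exp(-dt / modes[[j]]$tau)
      innov_sd <- s * sqrt(1 - rho^2)
      a <- numeric(n_frames)
      a[1] <- rnorm(1, 0, s)
      for (t in 2:n_frames) a[t] <- a[t - 1] * rho + rnorm(1, 0, innov_sd)
      amp[, j] <- a
    }
  }
  ## stream 2: per-atom noise (lazy per frame to keep memory flat)
  noise_seed <- seed + 2L

  ## rigid-motion state: per chain pose (R, t); groups via union-find
  set.seed(seed + 3L)
  pose_r <- rep(list(diag(3)), length(chains))
  pose_t <- rep(list(c(0, 0, 0)), length(chains))
  parent <- seq_along(chains)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  group_ids <- function() vapply(seq_along(chains), find, integer(1))

  events <- if (!is.null(schedule)) schedule$events else NULL
  pending <- list()  # list of c(root_a, root_b) awaiting contact
  merges <- list()

  atom_rows <- split(seq_len(n), chain_of)
  x0 <- system$xyz
  times <- (seq_len(n_frames) - 1) * dt
  coords <- matrix(0, n_frames, 3 * n)
  partition <- matrix(0L, n_frames, length(chains),
                      dimnames = list(NULL, chains))

  for (t in seq_len(n_frames)) {
    ## internal coordinates: reference + modes + noise
    xint <- x0
    if (k > 0) {
      for (j in seq_len(k)) {
        xint[modes[[j]]$atoms, ] <- xint[modes[[j]]$atoms, ] +
          amp[t, j] * modes[[j]]$shape
      }
    }
    if (any(noise_sd > 0)) {
      set.seed(noise_seed + t)
      xint <- xint + matrix(rnorm(3 * n), n, 3) * noise_sd
    }
    ## activate scheduled events whose time has come
    if (!is.null(events) && nrow(events) > 0) {
      due <- events$time <= times[t]
      for (e in which(due)) {
        ra <- find(match(events$chain_a[e], chains))
        rb <- find(match(events$chain_b[e], chains))
        if (ra != rb) pending[[length(pending) + 1]] <- c(ra, rb)
      }
      events <- events[!due, , drop = FALSE]
    }
    ## apply current poses
    gid <- group_ids()
    xt <- xint
    for (c in seq_along(chains)) {
      idx <- atom_rows[[c]]
      xt[idx, ] <- xint[idx, , drop = FALSE] %*% t(pose_r[[c]]) +
        rep(pose_t[[c]], each = length(idx))
    }
    ## rigid update per group (skipped entirely with no schedule)
    if (!is.null(schedule)) {
      ## any two groups touching aggregate for good: contacts are sticky, so
      ## the recorded partition always reflects the actual contact state
      repeat {
        gid <- group_ids()
        merged_any <- FALSE
        for (ga in unique(gid)) {
          for (gb in unique(gid)) {
            if (gb <= ga) next
            ia <- unlist(atom_rows[which(gid == ga)])
            ib <- unlist(atom_rows[which(gid == gb)])
            if (min_pair_dist(xt[ia, , drop = FALSE],
                              xt[ib, , drop = FALSE]) <=
                  schedule$contact_dist) {
              parent[ga] <- gb
              merges[[length(merges) + 1]] <- tibble::tibble(
                frame = t, time = times[t],
                chains = paste(sort(chains[gid %in% c(ga, gb)]),
                               collapse = "+"))
              merged_any <- TRUE
            }
          }
          if (merged_any) break
        }
        if (!merged_any) break
      }
      gid <- group_ids()
      drift <- matrix(0, length(chains), 3)
      if (length(pending) > 0) {
        keep <- logical(length(pending))
        for (p in seq_along(pending)) {
          ra <- find(pending[[p]][1]); rb <- find(pending[[p]][2])
          if (ra == rb) next  # already in contact; drop from pending
          v <- unitv(colMeans(xt[unlist(atom_rows[which(gid == rb)]), ,
                                 drop = FALSE]) -
                       colMeans(xt[unlist(atom_rows[which(gid == ra)]), ,
                                   drop = FALSE]))
          step <- schedule$drift_rate * dt / 2
          drift[gid == ra, ] <- drift[gid == ra, ] +
            rep(step * v, each = sum(gid == ra))
          drift[gid == rb, ] <- drift[gid == rb, ] -
            rep(step * v, each = sum(gid == rb))
          keep[p] <- TRUE
        }
        pending <- pending[keep]
      }
      gid <- group_ids()
      for (g in unique(gid)) {
        members <- which(gid == g)
        idx <- unlist(atom_rows[members])
        mu <- colMeans(xt[idx, , drop = FALSE])
        dr <- rotation_matrix(rnorm(3), rnorm(1, 0, schedule$rot_sd * pi / 180))
        dtr <- rnorm(3, 0, schedule$step_sd) + drift[members[1], ]
        for (c in members) {
          pose_r[[c]] <- dr %*% pose_r[[c]]
          pose_t[[c]] <- as.numeric(dr %*% pose_t[[c]]) +
            (mu - as.numeric(dr %*% mu)) + dtr
          i2 <- atom_rows[[c]]
          xt[i2, ] <- sweep(xt[i2, , drop = FALSE], 2, mu) %*% t(dr) +
            rep(mu + dtr, each = length(i2))
        }
      }
    }
    partition[t, ] <- group_ids()
    coords[t, ] <- as.numeric(t(xt))
  }
  truth <- list(
    partition = partition,
    amplitudes = amp[, seq_len(k), drop = FALSE],
    noise_sd = noise_sd,
    merges = if (length(merges)) dplyr::bind_rows(merges)
             else tibble::tibble(frame = integer(), time = numeric(),
                                 chains = character()),
    seed = seed
  )
  list(traj = md_trajectory(system, coords, dt = dt), truth = truth)
}

#' Ground-truth chain partition at a frame
#'
#' @param truth The `truth` element returned by [simulate_trajectory()].
#' @param frame Frame index.
#' @return List of character vectors of chain labels, one per group, ordered
#'   by first chain.
#' @export
truth_partition <- function(truth, frame = nrow(truth$partition)) {
  g <- truth$partition[frame, ]
  unname(split(names(g), g))[order(vapply(
    unname(split(names(g), g)), function(x) x[1], character(1)))]
}
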