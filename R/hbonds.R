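## Amide hydrogen positions constructed on demand: H sits 0.1 nm from N,
## anti-parallel to the preceding residue's C=O (the standard backbone
## placement). First residue of each chain and prolines get no H (NA rows).
## Structures carrying explicit H atoms keep them; this helper only fills
## backbone amides that lack one.
construct_amide_h <- function(system, xyz = NULL) {
  xyz <- xyz %||% system$xyz
  a <- system$atoms
  h <- matrix(NA_real_, nrow(a), 3)
  ## rows indexed by the N atom they belong to
  for (lab in system$chains$label) {
    sel <- which(a$chain == lab)
    resids <- sort(unique(a$resid[sel]))
    idx_of <- function(r, nm) sel[a$resid[sel] == r & a$name[sel] == nm][1]
    for (r in resids[-1]) {
      ni <- idx_of(r, "N")
      if (is.na(ni) || a$resname[ni] == "PRO") next
      cp <- idx_of(r - 1, "C"); op <- idx_of(r - 1, "O")
      if (is.na(cp) || is.na(op)) next
      h[ni, ] <- xyz[ni, ] + 0.1 * unitv(xyz[cp, ] - xyz[op, ])
    }
  }
  h
}

## Species-pair class of a donor/acceptor chain pair: AB_AB, AB_SCP, SCP_SCP
## or NA when either chain is species OTHER.
hb_class <- function(sp_a, sp_b) {
  ga <- species_group(sp_a); gb <- species_group(sp_b)
  ifelse(is.na(ga) | is.na(gb), NA_character_,
         ifelse(ga == "AB" & gb == "AB", "AB_AB",
                ifelse(ga == "SCP" & gb == "SCP", "SCP_SCP", "AB_SCP")))
}

#' Geometric hydrogen-bond detection in one frame
#'
#' A bond is recorded when the donor--acceptor heavy-atom distance is at most
#' `d_max` and the hydrogen--donor--acceptor angle is at most `angle_max`
#' (the convention of the GROMACS analysis ecosystem; both cutoffs are
#' arguments because no single printed standard exists). Donors are N/O/S
#' atoms carrying a hydrogen -- explicit H atoms are used where present,
#' backbone amide H are constructed geometrically otherwise. Acceptors are
#' N and O atoms. Pairs closer than `min_seq_sep` residues along the same
#' chain are excluded.
#'
#' @param system An [md_system] (its coordinates, or `xyz` if given).
#' @param xyz Optional N x 3 coordinate override (a trajectory frame).
#' @param d_max Donor-acceptor distance cutoff in nm.
#' @param angle_max H-donor-acceptor angle cutoff in degrees.
#' @param min_seq_sep Minimum same-chain residue separation.
#' @return Tibble with one row per bond: atom indices `donor`, `hydrogen`
#'   (`NA` for constructed H), `acceptor`, chains, residues, species-pair
#'   `class` (`AB_AB`/`AB_SCP`/`SCP_SCP`), logical `intra`, `distance` (nm)
#'   and `angle` (deg).
#' @export
find_hbonds <- function(system, xyz = NULL, d_max = 0.35, angle_max = 30,
                        min_seq_sep = 2) {
  xyz <- xyz %||% system$xyz
  a <- system$atoms
  expl_h <- which(a$element == "H")
  don_idx <- which(a$element %in% c("N", "O", "S"))
  ## attach explicit hydrogens to their nearest bonded heavy atom
  hpos <- construct_amide_h(system, xyz)
  hsrc <- rep(NA_integer_, nrow(a))
  if (length(expl_h) > 0 && length(don_idx) > 0) {
    dm <- cross_dist(xyz[expl_h, , drop = FALSE],
                     xyz[don_idx, , drop = FALSE])
    for (k in seq_along(expl_h)) {
      j <- which.min(dm[k, ])
      if (dm[k, j] <= 0.12) {
        hv <- don_idx[j]
        hpos[hv, ] <- xyz[expl_h[k], ]
        hsrc[hv] <- expl_h[k]
      }
    }
  }
  donors <- which(!is.na(hpos[, 1]))
  acceptors <- which(a$element %in% c("N", "O"))
  if (length(donors) == 0 || length(acceptors) == 0) return(empty_hbonds())
  dm <- cross_dist(xyz[donors, , drop = FALSE],
                   xyz[acceptors, , drop = FALSE])
  cand <- which(dm <= d_max & dm > 1e-6, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_hbonds())
  di <- donors[cand[, 1]]; ai <- acceptors[cand[, 2]]
  same_chain <- a$chain[di] == a$chain[ai]
  keep <- !(same_chain & abs(a$resid[di] - a$resid[ai]) < min_seq_sep)
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0) return(empty_hbonds())
  ang <- vapply(seq_along(di), function(k) {
    vec_angle(hpos[di[k], ], xyz[di[k], ], xyz[ai[k], ])
  }, numeric(1))
  ok <- ang <= angle_max
  di <- di[ok]; ai <- ai[ok]; ang <- ang[ok]
  if (length(di) == 0) return(empty_hbonds())
  sp <- species_of(system)
  cls <- hb_class(sp[a$chain[di]], sp[a$chain[ai]])
  tibble::tibble(
    donor = di, hydrogen = hsrc[di], acceptor = ai,
    donor_chain = a$chain[di], acceptor_chain = a$chain[ai],
    donor_resid = a$resid[di], acceptor_resid = a$resid[ai],
    class = cls, intra = a$chain[di] == a$chain[ai],
    distance = sqrt(rowSums((xyz[di, , drop = FALSE] -
                               xyz[ai, , drop = FALSE])^2)),
    angle = ang
  )
}

empty_hbonds <- function() {
  tibble::tibble(
    donor = integer(), hydrogen = integer(), acceptor = integer(),
    donor_chain = character(), acceptor_chain = character(),
    donor_resid = integer(), acceptor_resid = integer(),
    class = character(), intra = logical(), distance = numeric(),
    angle = numeric()
  )
}

HB_CLASSES <- c("AB_AB", "AB_SCP", "SCP_SCP")

#' Hydrogen-bond census over a trajectory
#'
#' Counts bonds per frame by species-pair class (amyloid-beta with itself,
#' across species, cyclic peptides with themselves), with intra/inter chain
#' splits. Bonds involving `OTHER` chains enter `total` but no class.
#'
#' @param traj An [md_trajectory].
#' @param include_intra Count intra-chain bonds in the class columns
#'   (default `TRUE`; set `FALSE` to census inter-chain bonds only).
#' @inheritParams find_hbonds
#' @return A tibble of class `hbond_series`: `time` (ps), one column per
#'   class, `intra`, `inter`, `total` (sum of the three classes) and
#'   `all_bonds` (every detected bond, including `OTHER`-species chains).
#' @export
hbond_census <- function(traj, include_intra = TRUE, d_max = 0.35,
                         angle_max = 30) {
  times <- frame_times(traj)
  rows <- lapply(seq_len(n_frames(traj)), function(t) {
    hb <- find_hbonds(traj$system, frame_xyz(traj, t), d_max = d_max,
                      angle_max = angle_max)
    if (!include_intra) hb_cls <- hb[!hb$intra, ] else hb_cls <- hb
    counts <- table(factor(hb_cls$class, levels = HB_CLASSES))
    tibble::tibble(
      time = times[t],
      AB_AB = as.integer(counts["AB_AB"]),
      AB_SCP = as.integer(counts["AB_SCP"]),
      SCP_SCP = as.integer(counts["SCP_SCP"]),
      intra = sum(hb$intra), inter = sum(!hb$intra),
      total = as.integer(sum(counts)),
      all_bonds = nrow(hb)  # includes OTHER-species chains
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hbond_series", class(out))
  out
}

#' Window means of a hydrogen-bond census
#'
#' @param series An `hbond_series` from [hbond_census()].
#' @param window Window spec (see [resolve_window()]), e.g. `"last:20ns"`.
#' @return One-row tibble of per-class means and the total mean, reported to
#'   one decimal.
#' @export
hbond_window_means <- function(series, window = "all") {
  idx <- resolve_window(window, series$time)
  w <- series[idx, ]
  tibble::as_tibble(lapply(
    w[c(HB_CLASSES, "intra", "inter", "total", "all_bonds")],
    function(x) round_half_up(mean(x), 1)))
}

#' Extrema of a smoothed series
#'
#' Local maxima and minima of a moving-average smoothed series; the smoothing
#' window is in frames (0 or 1 = no smoothing). Plateau ties break to the
#' earliest time.
#'
#' @param x Numeric series, or an `hbond_series` (then `column` selects the
#'   series and times are attached).
#' @param smooth_window Moving-average width in frames.
#' @param column Column to use when `x` is a census tibble.
#' @return Tibble with `index`, `time` (when available), `type`
#'   (`"max"`/`"min"`) and the smoothed `value`.
#' @export
find_extrema <- function(x, smooth_window = 1, column = "AB_SCP") {
  times <- NULL
  if (is.data.frame(x)) {
    times <- x$time
    x <- x[[column]]
  }
  n <- length(x)
  if (n <= smooth_window) abort("series must be longer than smooth_window")
  s <- if (smooth_window > 1) {
    stats::filter(x, rep(1 / smooth_window, smooth_window), sides = 2)
  } else {
    x
  }
  s <- as.numeric(s)
  valid <- which(!is.na(s))
  lo <- min(valid); hi <- max(valid)
  ## an extremum must dominate its whole smoothing-scale neighbourhood, not
  ## just its immediate neighbours -- residual ripple around a smoothed
  ## extremum otherwise spawns spurious alternating extrema
  w <- max(1L, as.integer(smooth_window))
  res <- list()
  for (i in valid[valid > lo & valid < hi]) {
    nb <- s[max(lo, i - w):min(hi, i + w)]
    if (max(nb) == min(nb)) next  # locally constant
    first_at <- function(v) max(lo, i - w) - 1 + which(nb == v)[1]
    if (s[i] == max(nb) && first_at(max(nb)) == i) {
      res[[length(res) + 1]] <- tibble::tibble(index = i, type = "max",
                                               value = s[i])
    } else if (s[i] == min(nb) && first_at(min(nb)) == i) {
      res[[length(res) + 1]] <- tibble::tibble(index = i, type = "min",
                                               value = s[i])
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res)
         else tibble::tibble(index = integer(), type = character(),
                             value = numeric())
  if (!is.null(times)) out$time <- times[out$index]
  out
}
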