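## Backbone atom index table: one row per residue with N/CA/C/O atom indices
## (NA where missing) in chain order.
backbone_table <- function(system) {
  a <- system$atoms
  key <- paste(a$chain, a$resid)
  res <- tibble::tibble(chain = a$chain, resid = a$resid,
                        resname = a$resname)[!duplicated(key), ]
  pick <- function(nm) {
    idx <- rep(NA_integer_, nrow(res))
    hit <- a$name == nm
    m <- match(paste(res$chain, res$resid), key[hit])
    idx[!is.na(m)] <- which(hit)[m[!is.na(m)]]
    idx
  }
  res$N <- pick("N"); res$CA <- pick("CA"); res$C <- pick("C")
  res$O <- pick("O")
  res
}

## Kabsch-Sander hydrogen-bond energy between all residue pairs:
## E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol with the
## C=O of the acceptor residue and N-H of the donor residue; a bond is
## assigned iff E < -0.5 kcal/mol. Returns bond[i, j] = TRUE when the CO of
## residue i accepts the NH of residue j.
ks_hbond_matrix <- function(system, xyz = NULL) {
  xyz <- xyz %||% system$xyz
  bt <- backbone_table(system)
  nres <- nrow(bt)
  hpos <- construct_amide_h(system, xyz)
  hn <- matrix(NA_real_, nres, 3)
  ok_h <- !is.na(bt$N)
  hn[ok_h, ] <- hpos[bt$N[ok_h], ]
  has_d <- !is.na(hn[, 1]) & !is.na(bt$N)
  has_a <- !is.na(bt$C) & !is.na(bt$O)
  bond <- matrix(FALSE, nres, nres)
  energy <- matrix(0, nres, nres)
  if (any(has_a) && any(has_d)) {
    ai <- which(has_a); dj <- which(has_d)
    to_a <- function(m) m * 10  # nm -> Angstrom for the 332 factor
    r_on <- cross_dist(to_a(xyz[bt$O[ai], , drop = FALSE]),
                       to_a(xyz[bt$N[dj], , drop = FALSE]))
    r_ch <- cross_dist(to_a(xyz[bt$C[ai], , drop = FALSE]),
                       to_a(hn[dj, , drop = FALSE]))
    r_oh <- cross_dist(to_a(xyz[bt$O[ai], , drop = FALSE]),
                       to_a(hn[dj, , drop = FALSE]))
    r_cn <- cross_dist(to_a(xyz[bt$C[ai], , drop = FALSE]),
                       to_a(xyz[bt$N[dj], , drop = FALSE]))
    e <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    ## same-residue and direct peptide-bond neighbours can never H-bond
    same <- outer(bt$chain[ai], bt$chain[dj], "==") &
      abs(outer(bt$resid[ai], bt$resid[dj], "-")) < 2
    e[same] <- 0
    energy[ai, dj] <- e
    bond[ai, dj] <- e < -0.5
  }
  list(bond = bond, energy = energy, residues = bt)
}

SS_LEVELS <- c("H", "G", "I", "E", "B", "T", "S", "C")

#' Secondary-structure assignment for one frame
#'
#' Kabsch-Sander rules on backbone N/CA/C/O (amide H constructed
#' geometrically): n-turns from CO(i)->NH(i+n) bonds give 3/4/5-helices
#' (G/H/I), parallel/antiparallel bridge patterns give strands (E) and
#' isolated bridges (B), turns (T) and bends (S) fill in, everything else is
#' coil (C). Residues missing a backbone atom are forced to C with a
#' warning.
#'
#' @param system An [md_system].
#' @param xyz Optional coordinate override (a trajectory frame).
#' @return Tibble with `chain`, `resid`, `resname`, `ss` (one of
#'   H/G/I/E/B/T/S/C); attribute `"bridges"` holds a tibble of bridge pairs
#'   with their `sense` (`"parallel"`/`"antiparallel"`).
#' @export
assign_ss <- function(system, xyz = NULL) {
  ks <- ks_hbond_matrix(system, xyz)
  bt <- ks$residues
  hb <- ks$bond
  nres <- nrow(bt)
  miss <- is.na(bt$N) | is.na(bt$CA) | is.na(bt$C) | is.na(bt$O)
  if (any(miss)) {
    warn(sprintf("%d residue(s) missing backbone atoms; forced to coil",
                 sum(miss)))
  }
  same_chain <- function(i, j) bt$chain[i] == bt$chain[j]
  consec <- function(i, n) {
    j <- i + n
    j <= nres && same_chain(i, j) && bt$resid[j] - bt$resid[i] == n
  }
  turn <- list()
  for (n in 3:5) {
    tn <- logical(nres)
    for (i in seq_len(nres)) if (consec(i, n) && hb[i, i + n]) tn[i] <- TRUE
    turn[[as.character(n)]] <- tn
  }
  ## bridges
  br_i <- integer(); br_j <- integer(); br_sense <- character()
  inner <- function(i) i > 1 && i < nres && same_chain(i - 1, i + 1) &&
    bt$resid[i + 1] - bt$resid[i - 1] == 2
  for (i in seq_len(nres)) {
    if (!inner(i)) next
    for (j in seq_len(nres)) {
      if (!inner(j) || j <= i) next
      if (same_chain(i, j) && abs(bt$resid[i] - bt$resid[j]) < 3) next
      par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
      anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
      if (par || anti) {
        br_i <- c(br_i, i); br_j <- c(br_j, j)
        br_sense <- c(br_sense, if (anti) "antiparallel" else "parallel")
      }
    }
  }
  bridges <- tibble::tibble(i = br_i, j = br_j, sense = br_sense)
  ## a bridge extends to a ladder (E) when an adjacent residue pair also
  ## bridges with the same sense; isolated bridges are B
  in_ladder <- rep(FALSE, nrow(bridges))
  if (nrow(bridges) > 1) {
    for (k in seq_len(nrow(bridges))) {
      i <- bridges$i[k]; j <- bridges$j[k]; sn <- bridges$sense[k]
      jn <- if (sn == "parallel") c(j + 1, j - 1) else c(j - 1, j + 1)
      in_ladder[k] <- any(
        (bridges$i == i + 1 & bridges$j == jn[1] & bridges$sense == sn) |
        (bridges$i == i - 1 & bridges$j == jn[2] & bridges$sense == sn))
    }
  }
  ss <- rep("C", nres)
  ## bends: CA-trace direction change > 70 degrees
  for (i in seq_len(nres)) {
    if (i <= 2 || i >= nres - 1) next
    if (!consec(i - 2, 2) || !consec(i, 2)) next
    if (any(is.na(bt$CA[c(i - 2, i, i + 2)]))) next
    x <- (xyz %||% system$xyz)
    ang <- vec_angle(x[bt$CA[i - 2], ], x[bt$CA[i], ], x[bt$CA[i + 2], ])
    if (180 - ang > 70) ss[i] <- "S"
  }
  ## turns
  for (n in 3:5) {
    for (i in which(turn[[as.character(n)]])) {
      span <- (i + 1):(i + n - 1)
      ss[span][ss[span] %in% c("C", "S")] <- "T"
    }
  }
  ## 5-helix (I), then 3-helix (G): overwritten by E/B/H later via priority
  for (i in seq_len(nres)) {
    if (i > 1 && turn[["5"]][i - 1] && turn[["5"]][i]) ss[i:(i + 4)] <- "I"
  }
  for (i in seq_len(nres)) {
    if (i > 1 && turn[["3"]][i - 1] && turn[["3"]][i]) ss[i:(i + 2)] <- "G"
  }
  ## bridges / ladders
  bres <- unique(c(bridges$i[!in_ladder], bridges$j[!in_ladder]))
  ss[bres] <- "B"
  eres <- unique(c(bridges$i[in_ladder], bridges$j[in_ladder]))
  ss[eres] <- "E"
  ## 4-helix has top priority
  for (i in seq_len(nres)) {
    if (i > 1 && turn[["4"]][i - 1] && turn[["4"]][i]) ss[i:(i + 3)] <- "H"
  }
  ss[miss] <- "C"
  out <- tibble::tibble(chain = bt$chain, resid = bt$resid,
                        resname = bt$resname, ss = ss)
  attr(out, "bridges") <- bridges
  out
}

SS_CATEGORIES <- list(
  sheet = "E", bridge = "B", helix = c("H", "G", "I"), turn = "T",
  coil = c("C", "S")
)

#' Secondary-structure content over a trajectory
#'
#' Per-frame percentages of residues in the aggregated categories beta-sheet
#' (E), beta-bridge (B), helix (H/G/I), turn (T) and coil (C plus bend S),
#' computed by default over amyloid-beta residues only.
#'
#' @param traj An [md_trajectory].
#' @param chains `"AB"` (amyloid-beta chains only, the default), `"all"`, or
#'   a character vector of chain labels.
#' @return Tibble of class `ss_series`: `time` plus one percentage column per
#'   category (summing to 100 per frame).
#' @export
ss_content <- function(traj, chains = "AB") {
  labels <- content_chains(traj$system, chains)
  times <- frame_times(traj)
  rows <- lapply(seq_len(n_frames(traj)), function(t) {
    ssa <- assign_ss(traj$system, frame_xyz(traj, t))
    ssa <- ssa[ssa$chain %in% labels, ]
    pct <- vapply(SS_CATEGORIES, function(cl) {
      100 * sum(ssa$ss %in% cl) / nrow(ssa)
    }, numeric(1))
    tibble::as_tibble(c(list(time = times[t]), as.list(pct)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ss_series", class(out))
  out
}

content_chains <- function(system, chains) {
  if (identical(chains, "AB")) {
    labels <- system$chains$label[system$chains$species %in% AB_SPECIES]
    if (length(labels) == 0) abort("system has no amyloid-beta chains")
  } else if (identical(chains, "all")) {
    labels <- system$chains$label
  } else {
    labels <- chains
  }
  labels
}

#' Stable beta-sheet content of a window
#'
#' The headline "stable beta-sheet percentage": the window mean of the
#' per-frame percentage of residues assigned E. With
#' `definition = "persistence"` a residue instead counts once when it is E
#' in at least `persistence` of window frames.
#'
#' @param traj An [md_trajectory].
#' @param window Window spec (see [resolve_window()]), default `"last:20ns"`.
#' @param chains See [ss_content()].
#' @param category One of `"sheet"`, `"bridge"`, `"helix"`, `"turn"`,
#'   `"coil"`.
#' @param definition `"mean"` (time average, default) or `"persistence"`.
#' @param persistence Occupancy fraction for the persistence definition.
#' @return A single percentage.
#' @export
beta_content <- function(traj, window = "last:20ns", chains = "AB",
                         category = "sheet", definition = c("mean",
                                                            "persistence"),
                         persistence = 0.5) {
  definition <- match.arg(definition)
  labels <- content_chains(traj$system, chains)
  idx <- resolve_window(window, frame_times(traj))
  classes <- SS_CATEGORIES[[category]]
  per_frame <- lapply(idx, function(t) {
    ssa <- assign_ss(traj$system, frame_xyz(traj, t))
    ssa$ss[ssa$chain %in% labels] %in% classes
  })
  mat <- do.call(rbind, per_frame)
  if (definition == "mean") {
    mean(100 * rowMeans(mat))
  } else {
    100 * mean(colMeans(mat) >= persistence)
  }
}
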