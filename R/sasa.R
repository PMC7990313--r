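## Bondi van der Waals radii in nm; overridable in compute_sasa()
BONDI_RADII <- c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120)

## Deterministic near-uniform sphere points: golden-spiral lattice
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over atom spheres: each atom's accessible area is
#' `4 pi (r + probe)^2` times the fraction of a deterministic sphere-point
#' lattice not buried inside any neighbour's expanded sphere.
#'
#' @param system An [md_system].
#' @param xyz Optional coordinate override (a trajectory frame).
#' @param radii Named vector of van der Waals radii per element in nm
#'   (default Bondi). Unknown elements error.
#' @param probe Probe radius in nm (water: 0.14).
#' @param n_points Sphere lattice points per atom (>= 12).
#' @param selection Atom indices to compute over (others still occlude).
#' @return Tibble of class `sasa_profile`: one row per selected atom with
#'   `atom`, `chain`, `resid`, `name`, `element` and `area` (nm^2).
#' @export
compute_sasa <- function(system, xyz = NULL, radii = BONDI_RADII,
                         probe = 0.14, n_points = 960, selection = NULL) {
  stopifnot(n_points >= 12)
  xyz <- xyz %||% system$xyz
  a <- system$atoms
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown)) {
    abort(sprintf("no radius for element(s): %s (pass `radii` overrides)",
                  paste(unknown, collapse = ", ")))
  }
  r <- unname(radii[a$element]) + probe
  n <- nrow(a)
  selection <- selection %||% seq_len(n)
  pts <- sphere_points(n_points)
  d <- cross_dist(xyz, xyz)
  area <- numeric(length(selection))
  for (k in seq_along(selection)) {
    i <- selection[k]
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    if (length(nb) == 0) {
      area[k] <- 4 * pi * r[i]^2
      next
    }
    surf <- pts * r[i] + rep(xyz[i, ], each = n_points)
    d2 <- outer(rowSums(surf^2), rowSums(xyz[nb, , drop = FALSE]^2), "+") -
      2 * tcrossprod(surf, xyz[nb, , drop = FALSE])
    free <- rowSums(d2 < rep(r[nb]^2, each = n_points)) == 0
    area[k] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  out <- tibble::tibble(
    atom = selection, chain = a$chain[selection], resid = a$resid[selection],
    resname = a$resname[selection], name = a$name[selection],
    element = a$element[selection], area = area
  )
  class(out) <- c("sasa_profile", class(out))
  out
}

## Default hydrophobic residue set for the residue-based split policy
HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                          "PRO", "GLY", "CYS")

#' Hydrophobic/hydrophilic decomposition of a SASA profile
#'
#' Element policy: C and S atoms are hydrophobic, N and O hydrophilic,
#' H follows nothing here (reduced representation carries no stored H).
#' Residue policy: every atom of a residue in `hydrophobic_residues` is
#' hydrophobic.
#'
#' @param profile A `sasa_profile` from [compute_sasa()].
#' @param policy `"element"` (default) or `"residue"`.
#' @param hydrophobic_residues Residue set for the residue policy.
#' @return One-row tibble with `hydrophobic`, `hydrophilic` and `total`
#'   (nm^2); hydrophobic + hydrophilic equals total.
#' @export
split_sasa <- function(profile, policy = c("element", "residue"),
                       hydrophobic_residues = HYDROPHOBIC_RESIDUES) {
  policy <- match.arg(policy)
  if (policy == "element") {
    phobic <- profile$element %in% c("C", "S")
  } else {
    if (is.null(profile$resname)) {
      abort("residue split policy needs a `resname` column on the profile")
    }
    phobic <- toupper(profile$resname) %in% hydrophobic_residues
  }
  tibble::tibble(
    hydrophobic = sum(profile$area[phobic]),
    hydrophilic = sum(profile$area[!phobic]),
    total = sum(profile$area)
  )
}

#' Per-group SASA time series with window summaries
#'
#' Computes total (and split) SASA per frame for chain groups, then first/last
#' window means, SDs and the integer percent decrease
#' `round(100 (first - last) / first)` -- the quantity aggregation studies
#' tabulate to show hydrophobic burial.
#'
#' @param traj An [md_trajectory].
#' @param groups Named list of chain-label vectors; default one group per
#'   species present.
#' @param first,last Window specs for the two summary windows.
#' @param policy Split policy, see [split_sasa()].
#' @inheritParams compute_sasa
#' @return List with `series` (tibble of class `sasa_series`: time, group,
#'   hydrophobic, hydrophilic, total) and `summary` (tibble per group and
#'   split with first/last mean, sd and `decrease_pct`).
#' @export
sasa_timeseries <- function(traj, groups = NULL, first = "first:5ns",
                            last = "last:5ns", policy = "element",
                            probe = 0.14, n_points = 960) {
  sys <- traj$system
  if (is.null(groups)) {
    groups <- split(sys$chains$label, sys$chains$species)
  }
  times <- frame_times(traj)
  rows <- list()
  for (t in seq_len(n_frames(traj))) {
    prof <- compute_sasa(sys, frame_xyz(traj, t), probe = probe,
                         n_points = n_points)
    for (g in names(groups)) {
      sub <- prof[prof$chain %in% groups[[g]], ]
      sp <- split_sasa(sub, policy = policy)
      rows[[length(rows) + 1]] <- tibble::tibble(
        time = times[t], group = g, hydrophobic = sp$hydrophobic,
        hydrophilic = sp$hydrophilic, total = sp$total)
    }
  }
  series <- dplyr::bind_rows(rows)
  class(series) <- c("sasa_series", class(series))
  idx_f <- resolve_window(first, times)
  idx_l <- resolve_window(last, times)
  if (length(idx_f) >= length(times) || length(idx_l) >= length(times)) {
    abort("summary window spans the whole trajectory; shorten it")
  }
  summary <- dplyr::bind_rows(lapply(names(groups), function(g) {
    sg <- series[series$group == g, ]
    dplyr::bind_rows(lapply(c("hydrophobic", "hydrophilic", "total"),
                            function(split) {
      x <- sg[[split]]
      xf <- x[sg$time %in% times[idx_f]]
      xl <- x[sg$time %in% times[idx_l]]
      tibble::tibble(
        group = g, split = split,
        first_mean = mean(xf), first_sd = sd(xf),
        last_mean = mean(xl), last_sd = sd(xl),
        decrease_pct = percent_decrease(mean(xf), mean(xl))
      )
    }))
  }))
  list(series = series, summary = summary)
}
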