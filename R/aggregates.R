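#' Chain-level contact graph for one frame
#'
#' Symmetric boolean adjacency over chains: an edge joins two chains when
#' their minimum heavy-atom distance is at most `cutoff`.
#'
#' @param system An [md_system].
#' @param xyz Optional coordinate override (a trajectory frame).
#' @param cutoff Heavy-atom minimum-distance cutoff in nm.
#' @return Logical chain x chain matrix with chain labels as dimnames.
#' @export
contact_graph <- function(system, xyz = NULL, cutoff = 0.45) {
  xyz <- xyz %||% system$xyz
  labels <- system$chains$label
  if (length(labels) < 2) abort("contact graph needs at least 2 chains")
  heavy <- system$atoms$element != "H"
  idx <- lapply(labels, function(l) which(system$atoms$chain == l & heavy))
  m <- matrix(FALSE, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (i in seq_along(labels)[-length(labels)]) {
    for (j in (i + 1):length(labels)) {
      d <- min_pair_dist(xyz[idx[[i]], , drop = FALSE],
                         xyz[idx[[j]], , drop = FALSE])
      m[i, j] <- m[j, i] <- d <= cutoff
    }
  }
  m
}

## Canonical composition string, amyloid-beta species first, e.g.
## "3Aβ42+2SST14"
composition_string <- function(chain_labels, species_map) {
  sp <- species_map[chain_labels]
  order_sp <- c("ABETA42", "ABETA40", "SST14", "AVP", "OTHER")
  counts <- table(factor(sp, levels = order_sp))
  counts <- counts[counts > 0]
  paste(sprintf("%d%s", as.integer(counts), SPECIES_DISPLAY[names(counts)]),
        collapse = "+")
}

#' Connected aggregates of a contact graph
#'
#' @param graph Logical chain adjacency matrix (from [contact_graph()]).
#' @param system The [md_system] the graph belongs to (provides species).
#' @return List of class `aggregate_state`: `components` (tibble with
#'   `component`, `size`, `chains`, `composition`), `free` (chains in no
#'   multi-chain component) and `partition` (named integer vector).
#' @export
aggregate_components <- function(graph, system) {
  if (!isSymmetric(unname(graph))) abort("contact graph must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(graph, mode = "undirected")
  comp <- igraph::components(g)
  sp <- species_of(system)
  labels <- rownames(graph)
  membership <- comp$membership
  comps <- split(labels, membership)
  sizes <- lengths(comps)
  ord <- order(-sizes, vapply(comps, function(x) sort(x)[1], character(1)))
  comps <- comps[ord]
  out <- tibble::tibble(
    component = seq_along(comps),
    size = unname(lengths(comps)),
    chains = unname(vapply(comps, function(x) paste(sort(x), collapse = ""),
                           character(1))),
    composition = unname(vapply(comps, composition_string, character(1),
                                species_map = sp))
  )
  free <- sort(unlist(comps[out$size == 1], use.names = FALSE))
  structure(list(components = out[out$size > 1, ], free = free,
                 partition = setNames(match(membership, unique(membership)),
                                      labels)),
            class = "aggregate_state")
}

#' @export
print.aggregate_state <- function(x, ...) {
  if (nrow(x$components) == 0) {
    cat("<aggregate_state> no multi-chain aggregates\n")
  } else {
    cat("<aggregate_state>",
        paste(x$components$composition, collapse = ";"), "\n")
  }
  if (length(x$free)) cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregation timeline over windows with persistence filtering
#'
#' Splits the trajectory into consecutive windows; within each window an edge
#' is kept only when present in at least `persistence` of its frames (making
#' the status robust to transient detachment/adsorption of single chains),
#' then connected components are computed on the filtered graph.
#'
#' @param traj An [md_trajectory].
#' @param cutoff Contact cutoff in nm.
#' @param window_frames Frames per window (>= 2).
#' @param persistence Minimum within-window edge occupancy fraction.
#' @return Tibble with one row per window: `window`, `from`/`to` (ps),
#'   `composition` (";"-joined component strings) and `free`; attribute
#'   `"states"` holds the full `aggregate_state` objects.
#' @export
aggregate_timeline <- function(traj, cutoff = 0.45, window_frames = 10,
                               persistence = 0.5) {
  if (window_frames < 2) abort("windows need at least 2 frames")
  times <- frame_times(traj)
  starts <- seq(1, n_frames(traj) - window_frames + 1, by = window_frames)
  states <- list()
  rows <- lapply(seq_along(starts), function(w) {
    idx <- starts[w]:(starts[w] + window_frames - 1)
    acc <- NULL
    for (t in idx) {
      g <- contact_graph(traj$system, frame_xyz(traj, t), cutoff = cutoff)
      acc <- if (is.null(acc)) g + 0 else acc + g
    }
    keep <- (acc / length(idx)) >= persistence
    st <- aggregate_components(keep, traj$system)
    states[[w]] <<- st
    tibble::tibble(
      window = w, from = times[idx[1]], to = times[idx[length(idx)]],
      composition = paste(st$components$composition, collapse = ";"),
      free = paste(st$free, collapse = ",")
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "states") <- states
  out
}

## Reference SASA per residue type: area of the mid residue of an extended
## Gly-X-Gly tripeptide in the same reduced representation, cached per
## session so relative exposure is self-consistent with compute_sasa().
ref_sasa_env <- new.env(parent = emptyenv())

reference_residue_sasa <- function(resname, probe = 0.14, n_points = 960) {
  key <- sprintf("%s_%g_%d", resname, probe, n_points)
  if (!is.null(ref_sasa_env[[key]])) return(ref_sasa_env[[key]])
  one <- THREE_TO_ONE[resname]
  if (is.na(one)) abort(sprintf("no reference SASA for residue '%s'", resname))
  tri <- build_peptide(backbone_spec(paste0("G", one, "G"), motif = "strand"))
  prof <- compute_sasa(tri, probe = probe, n_points = n_points,
                       selection = which(tri$atoms$resid == 2))
  val <- sum(prof$area)
  ref_sasa_env[[key]] <- val
  val
}

#' Terminus exposure classification
#'
#' A chain terminus is "surface" when the terminal residue's SASA, relative
#' to the reference maximum for that residue type (an isolated extended
#' Gly-X-Gly computed in the same representation), reaches `rel_threshold`;
#' otherwise "buried".
#'
#' @param system An [md_system].
#' @param chain Chain label.
#' @param which `"N"` or `"C"` terminus.
#' @param xyz Optional coordinate override.
#' @param rel_threshold Relative-SASA threshold.
#' @param n_points Sphere points for the SASA evaluation.
#' @return A list with `status` (`"surface"`/`"buried"`), `rel_sasa`,
#'   `sasa` and `reference`.
#' @export
terminus_exposure <- function(system, chain, which = c("C", "N"), xyz = NULL,
                              rel_threshold = 0.25, n_points = 960) {
  which <- match.arg(which)
  a <- system$atoms
  in_chain <- which(a$chain == chain)
  if (length(in_chain) == 0) abort(sprintf("no chain '%s'", chain))
  resid <- if (which == "N") min(a$resid[in_chain]) else max(a$resid[in_chain])
  sel <- in_chain[a$resid[in_chain] == resid]
  prof <- compute_sasa(system, xyz = xyz, selection = sel,
                       n_points = n_points)
  ref <- reference_residue_sasa(a$resname[sel[1]], n_points = n_points)
  rel <- sum(prof$area) / ref
  list(status = if (rel >= rel_threshold) "surface" else "buried",
       rel_sasa = rel, sasa = sum(prof$area), reference = ref)
}

## Side-chain heavy atoms in the reduced representation
SIDECHAIN_NAMES <- c("CB", "CG", "CZ")

#' Classify residue-residue contacts in a frame
#'
#' For residue pairs within `consider` nm (minimum heavy-atom distance), the
#' contact is typed: `hydrophobic` when two side-chain heavy atoms of
#' hydrophobic residues are within `hydrophobic_cutoff`; `hydrogen_bond`
#' when the hydrogen-bond module records a bond between the two residues;
#' `aromatic_pipi` when both residues are aromatic (F/Y/W/H) and their ring
#' centroids (midpoint of the CG/CZ ring stubs) are within `pipi_cutoff`.
#' Ring orientation is not tested -- a stub-based simplification.
#'
#' @param system An [md_system].
#' @param xyz Optional coordinate override.
#' @param pairs Optional tibble of candidate pairs (`chain_a`, `resid_a`,
#'   `chain_b`, `resid_b`); default all inter-chain residue pairs within
#'   `consider`.
#' @param consider Candidate-pair distance bound in nm.
#' @param hydrophobic_cutoff,pipi_cutoff Type cutoffs in nm.
#' @return Tibble of contacts with `distance` (nm) and logical type columns
#'   `hydrophobic`, `hydrogen_bond`, `aromatic_pipi`.
#' @export
classify_contacts <- function(system, xyz = NULL, pairs = NULL,
                              consider = 0.6, hydrophobic_cutoff = 0.45,
                              pipi_cutoff = 0.55) {
  xyz <- xyz %||% system$xyz
  a <- system$atoms
  heavy <- a$element != "H"
  key <- paste(a$chain, a$resid)
  res <- unique(key)
  res_atoms <- split(which(heavy), key[heavy])[res]
  rc <- do.call(rbind, strsplit(res, " "))
  if (is.null(pairs)) {
    cand <- list()
    for (i in seq_along(res)) {
      for (j in seq_along(res)) {
        if (j <= i || rc[i, 1] == rc[j, 1]) next
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  } else {
    cand <- lapply(seq_len(nrow(pairs)), function(k) {
      c(match(paste(pairs$chain_a[k], pairs$resid_a[k]), res),
        match(paste(pairs$chain_b[k], pairs$resid_b[k]), res))
    })
  }
  hb <- find_hbonds(system, xyz)
  hb_keys <- character(0)
  if (nrow(hb) > 0) {
    hb_keys <- c(paste(hb$donor_chain, hb$donor_resid, hb$acceptor_chain,
                       hb$acceptor_resid),
                 paste(hb$acceptor_chain, hb$acceptor_resid, hb$donor_chain,
                       hb$donor_resid))
  }
  rows <- list()
  for (p in cand) {
    i <- p[1]; j <- p[2]
    xi <- xyz[res_atoms[[i]], , drop = FALSE]
    xj <- xyz[res_atoms[[j]], , drop = FALSE]
    d <- min_pair_dist(xi, xj)
    if (d > consider) next
    ni <- a$resname[res_atoms[[i]][1]]; nj <- a$resname[res_atoms[[j]][1]]
    ## hydrophobic: side-chain heavy atoms of hydrophobic residues in contact
    phobic <- FALSE
    if (ni %in% HYDROPHOBIC_RESIDUES && nj %in% HYDROPHOBIC_RESIDUES) {
      si <- res_atoms[[i]][a$name[res_atoms[[i]]] %in% SIDECHAIN_NAMES]
      sj <- res_atoms[[j]][a$name[res_atoms[[j]]] %in% SIDECHAIN_NAMES]
      if (length(si) && length(sj)) {
        phobic <- min_pair_dist(xyz[si, , drop = FALSE],
                                xyz[sj, , drop = FALSE]) <= hydrophobic_cutoff
      }
    }
    hbond <- paste(rc[i, 1], rc[i, 2], rc[j, 1], rc[j, 2]) %in% hb_keys
    ## pi-pi via ring stub centroids
    pipi <- FALSE
    arom <- c("PHE", "TYR", "TRP", "HIS")
    if (ni %in% arom && nj %in% arom) {
      cen <- function(idx) {
        ring <- idx[a$name[idx] %in% c("CG", "CZ")]
        if (length(ring) < 2) return(NULL)
        colMeans(xyz[ring, , drop = FALSE])
      }
      ci <- cen(res_atoms[[i]]); cj <- cen(res_atoms[[j]])
      if (!is.null(ci) && !is.null(cj)) pipi <- vnorm(ci - cj) <= pipi_cutoff
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain_a = rc[i, 1], resid_a = as.integer(rc[i, 2]), resname_a = ni,
      chain_b = rc[j, 1], resid_b = as.integer(rc[j, 2]), resname_b = nj,
      distance = d, hydrophobic = phobic, hydrogen_bond = hbond,
      aromatic_pipi = pipi)
  }
  if (length(rows)) dplyr::bind_rows(rows)
  else tibble::tibble(chain_a = character(), resid_a = integer(),
                      resname_a = character(), chain_b = character(),
                      resid_b = integer(), resname_b = character(),
                      distance = numeric(), hydrophobic = logical(),
                      hydrogen_bond = logical(), aromatic_pipi = logical())
}
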