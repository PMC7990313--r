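## Ideal backbone geometry (Engh-Huber-style standard values), in Angstrom
## and degrees; converted to nm at the end of the build.
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.6, ang_c_n_ca = 121.9,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, omega = 180
)

## Named (phi, psi) motifs; coil is drawn per residue from the uniform
## ranges phi in [-150, -60], psi in [-60, 150] (broad coil basin).
MOTIF_PHIPSI <- list(
  helix  = c(-57, -47),
  strand = c(-139, 135),
  turn   = c(75, -15)
)

#' Backbone specification for the peptide builder
#'
#' @param sequence One-letter amino-acid string.
#' @param motif A single motif name (`"helix"`, `"strand"`, `"coil"`,
#'   `"turn"`) or a character vector of length `nchar(sequence)` assigning a
#'   motif per residue. Ignored when `phi`/`psi` are given.
#' @param phi,psi Optional numeric vectors of per-residue backbone dihedrals
#'   in degrees (`phi[1]` and the last `psi` only affect terminal-atom
#'   placement).
#' @param cyclic Logical: treat the chain as disulfide-closed. The builder
#'   then bends the chain at its midpoint hinge to bring the restraint pair
#'   of residues (first/last Cys-like positions) close; the restraint only
#'   shapes the built geometry.
#' @return A `backbone_spec` list.
#' @export
backbone_spec <- function(sequence, motif = "coil", phi = NULL, psi = NULL,
                          cyclic = FALSE) {
  n <- nchar(sequence)
  if (n < 2) abort("sequence must have at least 2 residues")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(ONE_TO_THREE))
  if (length(bad)) {
    abort(sprintf("unknown residue letter(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(phi) || is.null(psi)) {
    motif <- if (length(motif) == 1) rep(motif, n) else motif
    stopifnot(length(motif) == n)
    pp <- t(vapply(motif, function(m) {
      if (m == "coil") c(runif(1, -150, -60), runif(1, -60, 150))
      else MOTIF_PHIPSI[[m]] %||% abort(sprintf("unknown motif '%s'", m))
    }, numeric(2)))
    phi <- pp[, 1]; psi <- pp[, 2]
  }
  stopifnot(length(phi) == n, length(psi) == n)
  structure(list(sequence = sequence, phi = phi, psi = psi, cyclic = cyclic),
            class = "backbone_spec")
}

AROMATIC <- c("F", "Y", "W", "H")

#' Build a peptide with ideal backbone geometry
#'
#' Extends the chain residue by residue (NeRF internal-coordinate
#' construction) with standard bond lengths (N-CA 1.458, CA-C 1.525, C-N
#' 1.329, C=O 1.231 Angstrom) and the spec's per-residue phi/psi. Each
#' residue gets N, CA, C, O atoms, a CB for non-glycine, and for aromatic
#' residues (F/Y/W/H) two ring stub atoms CG/CZ whose midpoint stands in for
#' the ring centroid in pi-stacking tests.
#'
#' @param spec A [backbone_spec()] (a plain sequence string is accepted and
#'   built as coil).
#' @param chain Chain label for the built peptide.
#' @return An [md_system] with coordinates in nm.
#' @export
build_peptide <- function(spec, chain = "A") {
  if (is.character(spec)) spec <- backbone_spec(spec)
  aa <- strsplit(spec$sequence, "")[[1]]
  n <- length(aa)
  g <- BB_GEOM
  bb <- vector("list", n)  # per residue: list(N, CA, C)
  bb[[1]] <- local({
    N <- c(0, 0, 0)
    CA <- c(g$n_ca, 0, 0)
    th <- g$ang_n_ca_c * pi / 180
    C <- CA + g$ca_c * c(-cos(th), sin(th), 0)
    list(N = N, CA = CA, C = C)
  })
  for (i in seq_len(n)[-1]) {
    p <- bb[[i - 1]]
    N <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, spec$psi[i - 1])
    CA <- place_atom(p$CA, p$C, N, g$n_ca, g$ang_c_n_ca, g$omega)
    C <- place_atom(p$C, N, CA, g$ca_c, g$ang_n_ca_c, spec$phi[i])
    bb[[i]] <- list(N = N, CA = CA, C = C)
  }
  rows <- list()
  coords <- list()
  add <- function(name, elem, i, xyz) {
    rows[[length(rows) + 1]] <<- list(
      name = name, element = elem, resid = i,
      resname = ONE_TO_THREE[[aa[i]]], chain = chain)
    coords[[length(coords) + 1]] <<- xyz
  }
  for (i in seq_len(n)) {
    b <- bb[[i]]
    add("N", "N", i, b$N)
    add("CA", "C", i, b$CA)
    add("C", "C", i, b$C)
    ## carbonyl O anti to the next amide N (dihedral N-CA-C-O = psi + 180)
    add("O", "O", i, place_atom(b$N, b$CA, b$C, g$c_o, g$ang_ca_c_o,
                                spec$psi[i] + 180))
    if (aa[i] != "G") {
      cb <- place_atom(b$C, b$N, b$CA, g$ca_cb, g$ang_n_ca_cb, 122.5)
      add("CB", "C", i, cb)
      if (aa[i] %in% AROMATIC) {
        cg <- place_atom(b$N, b$CA, cb, 1.52, 114, -60)
        add("CG", "C", i, cg)
        add("CZ", "C", i, place_atom(b$CA, cb, cg, 2.8, 170, 0))
      }
    }
  }
  atoms <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  xyz <- do.call(rbind, coords) / 10  # Angstrom -> nm
  sys <- md_system(atoms, xyz)
  if (isTRUE(spec$cyclic)) sys <- close_cycle(sys, aa)
  sys
}

## Crude disulfide-closure shaping: single hinge rotation at the midpoint
## residue, angle chosen to minimise the distance between the restraint pair
## (first and last Cys, falling back to termini). Chain stays topologically
## linear; only the built geometry is bent.
close_cycle <- function(sys, aa) {
  cys <- which(aa == "C")
  pair <- if (length(cys) >= 2) c(cys[1], cys[length(cys)])
          else c(1, length(aa))
  mid <- ceiling(length(aa) / 2)
  ca_idx <- select_atoms(sys, names = "CA")
  hinge <- sys$xyz[ca_idx[mid], ]
  axis_ref <- sys$xyz[ca_idx[mid] - 1, ] - hinge
  tail_idx <- which(sys$atoms$resid > mid)
  p1 <- sys$xyz[ca_idx[pair[1]], ]
  obj <- function(ang) {
    r <- rotation_matrix(axis_ref, ang)
    p2 <- as.numeric(r %*% (sys$xyz[ca_idx[pair[2]], ] - hinge)) + hinge
    vnorm(p2 - p1)
  }
  best <- stats::optimize(obj, c(-pi, pi))$minimum
  r <- rotation_matrix(axis_ref, best)
  sys$xyz[tail_idx, ] <- t(r %*% (t(sys$xyz[tail_idx, , drop = FALSE]) -
                                    hinge)) + rep(hinge, each = length(tail_idx))
  sys
}

## Rigid placement of a whole system: x -> x R^T + t
transform_system <- function(sys, rotation = diag(3), translation = c(0, 0, 0)) {
  sys$xyz <- sys$xyz %*% t(rotation) +
    matrix(translation, nrow(sys$xyz), 3, byrow = TRUE)
  sys
}

## Concatenate systems (chain labels must be distinct)
combine_systems <- function(systems, box = NULL) {
  atoms <- dplyr::bind_rows(lapply(systems, function(s) s$atoms))
  if (anyDuplicated(unlist(lapply(systems, function(s) s$chains$label)))) {
    abort("combine_systems: duplicated chain labels")
  }
  xyz <- do.call(rbind, lapply(systems, function(s) s$xyz))
  chains <- dplyr::bind_rows(lapply(systems, function(s) s$chains))
  md_system(atoms, xyz, chains = chains, box = box)
}

#' Build an ideal two-strand beta sheet
#'
#' Convenience fixture: two extended strands paired antiparallel or parallel
#' at hydrogen-bonding distance. Used to exercise inter-strand ladder
#' detection with a geometry whose hydrogen-bond register is known by
#' construction.
#'
#' @param sequence One-letter sequence of each strand.
#' @param sense `"antiparallel"` or `"parallel"`.
#' @param chains Labels for the two chains.
#' @param separation Inter-strand backbone separation in nm.
#' @return An [md_system] of two chains.
#' @export
build_sheet <- function(sequence = "VVVVVV", sense = "antiparallel",
                        chains = c("A", "B"), separation = 0.48) {
  s1 <- build_peptide(backbone_spec(sequence, motif = "strand"),
                      chain = chains[1])
  s2 <- build_peptide(backbone_spec(sequence, motif = "strand"),
                      chain = chains[2])
  ca1 <- s1$xyz[select_atoms(s1, names = "CA"), , drop = FALSE]
  axis <- unitv(ca1[nrow(ca1), ] - ca1[1, ])
  ## strand plane normal: perpendicular to the strand axis, in the plane of
  ## the CA trace spread
  dev <- sweep(ca1, 2, colMeans(ca1))
  sv <- svd(dev)
  side <- unitv(vcross(axis, sv$v[, 2]))
  if (sense == "antiparallel") {
    rot <- rotation_matrix(side, pi)
  } else {
    rot <- diag(3)
  }
  s2 <- transform_system(s2, rotation = rot)
  ## slide strand 2 along its own axis and across, minimising a crude
  ## HB-geometry penalty via grid search over axial offset
  ca2 <- function(sys) sys$xyz[select_atoms(sys, names = "CA"), , drop = FALSE]
  base_shift <- colMeans(ca1) - colMeans(ca2(s2))
  ## grid over axial offset and inter-strand separation, scoring both the
  ## Kabsch-Sander ladder bonds and the geometric N-H...O criterion so the
  ## pairing satisfies either detector
  best <- NULL; best_score <- Inf
  for (sep in separation + seq(-0.06, 0.06, by = 0.02)) {
    for (o in seq(-0.4, 0.4, by = 0.02)) {
      shift <- base_shift + sep * side + o * axis
      sheet <- combine_systems(list(s1, transform_system(s2,
                                                         translation = shift)))
      ks <- sum(ks_hbond_matrix(sheet)$bond)
      geo <- sum(!find_hbonds(sheet)$intra)
      score <- -(2 * ks + geo)
      if (score < best_score) { best_score <- score; best <- shift }
    }
  }
  combine_systems(list(s1, transform_system(s2, translation = best)))
}
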