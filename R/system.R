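#' Molecular system container
#'
#' An `md_system` bundles a static topology (chains, residues, atoms) with one
#' coordinate set. It is the object every analysis in the package consumes.
#' Coordinates are stored in nanometres; unit conversion happens only in the
#' file readers/writers (PDB is in Angstrom).
#'
#' @param atoms A data frame with one row per atom and columns `name` (PDB
#'   atom name, e.g. `"CA"`), `element` (`"C"`, `"N"`, ...), `resid`
#'   (1-based residue number within its chain), `resname` (three-letter
#'   residue code) and `chain` (single-letter chain label).
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in nm.
#' @param chains Optional data frame with columns `label`, `species`,
#'   `sequence`; inferred from `atoms` when omitted (species by exact
#'   sequence match against the built-in Abeta42/Abeta40/SST14/AVP
#'   sequences, anything else `OTHER`).
#' @param box Optional numeric length-3 vector of box edge lengths in nm.
#'
#' @return An object of class `md_system` with elements `atoms` (tibble),
#'   `chains` (tibble), `xyz` (N x 3 matrix, nm) and `box`.
#' @export
md_system <- function(atoms, xyz, chains = NULL, box = NULL) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("name", "element", "resid", "resname", "chain")
  if (!all(need %in% names(atoms))) {
    abort(paste0("atoms must have columns: ", paste(need, collapse = ", ")))
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3) {
    abort(sprintf("xyz must be %d x 3 (one row per atom)", nrow(atoms)))
  }
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (is.null(chains)) chains <- infer_chains(atoms)
  chains <- tibble::as_tibble(chains)
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(
    list(atoms = atoms, chains = chains, xyz = xyz, box = box),
    class = "md_system"
  )
}

THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
ONE_TO_THREE <- setNames(names(THREE_TO_ONE), unname(THREE_TO_ONE))

## One-letter sequence of a chain from its atom table (first atom per residue)
chain_sequence <- function(atoms_chain) {
  res <- atoms_chain[!duplicated(atoms_chain$resid), , drop = FALSE]
  res <- res[order(res$resid), , drop = FALSE]
  letters1 <- THREE_TO_ONE[res$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

## Species by exact sequence match; unknown sequences become OTHER
infer_species <- function(sequence) {
  hit <- names(SPECIES_SEQ)[match(sequence, SPECIES_SEQ)]
  if (is.na(hit)) "OTHER" else hit
}

infer_chains <- function(atoms) {
  labels <- unique(atoms$chain)
  seqs <- vapply(labels, function(l) {
    chain_sequence(atoms[atoms$chain == l, , drop = FALSE])
  }, character(1))
  species <- vapply(seqs, infer_species, character(1))
  if (any(species == "OTHER")) {
    warn(sprintf(
      "chain(s) %s match no known species sequence; classified OTHER",
      paste(labels[species == "OTHER"], collapse = ", ")
    ))
  }
  tibble::tibble(label = labels, species = unname(species),
                 sequence = unname(seqs))
}

#' @export
print.md_system <- function(x, ...) {
  cat(sprintf("<md_system> %d atoms, %d chains\n", nrow(x$atoms),
              nrow(x$chains)))
  sp <- table(x$chains$species)
  cat("  chains:", paste(sprintf("%d %s", sp, names(sp)), collapse = ", "),
      "\n")
  if (!is.null(x$box)) {
    cat(sprintf("  box: %.2f x %.2f x %.2f nm\n", x$box[1], x$box[2],
                x$box[3]))
  }
  invisible(x)
}

n_atoms <- function(system) nrow(system$atoms)

#' Select atoms of a system
#'
#' Builds an ordered, unique, ascending index vector into the system's atom
#' table, filtering by chain label, residue range and/or atom-name set.
#'
#' @param system An [md_system].
#' @param chains Character vector of chain labels, or `NULL` for all.
#' @param residues Integer vector of residue numbers (1-based within each
#'   chain), or `NULL` for all.
#' @param names Character vector of atom names (e.g. `"CA"`), or `NULL`.
#' @param elements Character vector of elements, or `NULL`. Use
#'   `heavy_atoms()` for everything but hydrogen.
#'
#' @return Sorted integer vector of 1-based atom indices with attribute
#'   `"expr"` recording the selection provenance.
#' @export
select_atoms <- function(system, chains = NULL, residues = NULL,
                         names = NULL, elements = NULL) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains))   keep <- keep & a$chain %in% chains
  if (!is.null(residues)) keep <- keep & a$resid %in% residues
  if (!is.null(names))    keep <- keep & a$name %in% names
  if (!is.null(elements)) keep <- keep & a$element %in% elements
  idx <- which(keep)
  attr(idx, "expr") <- paste(
    c(if (!is.null(chains)) paste0("chain ", paste(chains, collapse = "")),
      if (!is.null(residues)) "resid subset",
      if (!is.null(names)) paste0("name ", paste(names, collapse = "/")),
      if (!is.null(elements)) paste0("elem ", paste(elements, collapse = "/"))),
    collapse = " & ")
  idx
}

#' @rdname select_atoms
#' @export
heavy_atoms <- function(system, chains = NULL) {
  select_atoms(system, chains = chains,
               elements = setdiff(unique(system$atoms$element), "H"))
}

## Chain label -> species lookup
species_of <- function(system) {
  setNames(system$chains$species, system$chains$label)
}

## Chain species group: "AB" (amyloid-beta), "SCP" (small cyclic peptide),
## or NA for OTHER
species_group <- function(species) {
  ifelse(species %in% AB_SPECIES, "AB",
         ifelse(species %in% SCP_SPECIES, "SCP", NA_character_))
}

## Make chains whole under periodic boundaries: shift each atom by box
## multiples to the periodic image nearest its chain's first atom. Analyses
## assume compact chains; a chain split across a boundary would corrupt
## every distance-based census.
make_whole <- function(system) {
  if (is.null(system$box)) return(system)
  xyz <- system$xyz
  for (lab in system$chains$label) {
    idx <- which(system$atoms$chain == lab)
    ref <- xyz[idx[1], ]
    for (k in 1:3) {
      d <- xyz[idx, k] - ref[k]
      xyz[idx, k] <- xyz[idx, k] - system$box[k] * round(d / system$box[k])
    }
  }
  system$xyz <- xyz
  system
}
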