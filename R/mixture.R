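#' Build a randomly packed peptide mixture
#'
#' Emulates the study design: amyloid-beta chains (labels A, B, ...) and
#' small cyclic peptides (labels I, J, ...) placed at random positions and
#' orientations in a cubic box so that every inter-chain surface gap exceeds
#' `min_gap`. The default box edge (7.5 nm) realises ~4 mM for 8 chains of
#' each species; 4 mM fixes the box only approximately, so the edge is an
#' explicit argument.
#'
#' @param n_abeta Number of amyloid-beta chains.
#' @param abeta_species `"ABETA42"` or `"ABETA40"`.
#' @param n_scp Number of small cyclic peptide chains.
#' @param scp_species `"SST14"` or `"AVP"`.
#' @param box Cubic box edge length in nm.
#' @param min_gap Minimum inter-chain heavy-atom surface distance in nm.
#' @param seed Integer seed; the same seed reproduces the same coordinates.
#' @param max_tries Placement attempts per chain before giving up.
#' @return An [md_system] with `box` set.
#' @export
build_mixture <- function(n_abeta = 8, abeta_species = "ABETA42",
                          n_scp = 8, scp_species = "SST14",
                          box = 7.5, min_gap = 0.4, seed = 1,
                          max_tries = 200) {
  stopifnot(abeta_species %in% AB_SPECIES, scp_species %in% SCP_SPECIES)
  set.seed(seed)
  specs <- c(
    rep(abeta_species, n_abeta),
    rep(scp_species, n_scp)
  )
  labels <- c(LETTERS[seq_len(n_abeta)],
              LETTERS[8 + seq_len(n_scp)])
  if (n_abeta > 8 || n_scp > 18) abort("label scheme supports at most 8 + 18 chains")
  placed <- list()
  for (k in seq_along(specs)) {
    template <- build_peptide(
      backbone_spec(unname(SPECIES_SEQ[specs[k]]),
                    motif = "coil",
                    cyclic = specs[k] %in% SCP_SPECIES),
      chain = labels[k]
    )
    template$xyz <- sweep(template$xyz, 2, colMeans(template$xyz))
    ok <- FALSE
    achieved <- Inf
    for (try in seq_len(max_tries)) {
      rot <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
      pos <- runif(3, 0, box)
      cand <- transform_system(template, rotation = rot, translation = pos)
      ## keep the whole chain inside the box (packing stays image-free)
      rng <- apply(cand$xyz, 2, range)
      shift <- pmax(0, -rng[1, ]) - pmax(0, rng[2, ] - box)
      cand <- transform_system(cand, translation = shift)
      gap <- if (length(placed) == 0) Inf else min(vapply(
        placed, function(p) min_pair_dist(p$xyz, cand$xyz), numeric(1)))
      achieved <- min(achieved, gap)
      if (gap > min_gap) {
        placed[[length(placed) + 1]] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place chain %d/%d at gap > %.2f nm (best achieved %.2f nm); enlarge the box",
        k, length(specs), min_gap, achieved))
    }
  }
  if (length(placed) == 1) {
    ## single chain: centre it in the box
    placed[[1]] <- transform_system(
      placed[[1]],
      translation = rep(box / 2, 3) - colMeans(placed[[1]]$xyz))
  }
  combine_systems(placed, box = rep(box, 3))
}
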