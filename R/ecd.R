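#' Split a trajectory window into analysis segments
#'
#' The ECD descriptors are computed from many short segments and averaged;
#' this returns the maximal set of non-overlapping consecutive segments of
#' `seg_len` ps covering the window, dropping any trailing partial segment.
#'
#' @param traj An [md_trajectory].
#' @param seg_len Segment length in ps.
#' @param window Window spec (see [resolve_window()]).
#' @return List of integer frame-index vectors, one per segment.
#' @export
ecd_segments <- function(traj, seg_len = 200, window = "all") {
  idx <- resolve_window(window, frame_times(traj))
  per_seg <- max(1L, as.integer(round(seg_len / traj$dt)))
  n_seg <- length(idx) %/% per_seg
  if (n_seg < 1) abort(sprintf(
    "window (%d frames) shorter than one %g ps segment (%d frames)",
    length(idx), seg_len, per_seg))
  lapply(seq_len(n_seg), function(s) idx[((s - 1) * per_seg + 1):(s * per_seg)])
}

## Iterated-mean alignment of a frame block (rows = frames): superpose onto
## the block mean, recompute the mean, superpose once more.
align_to_mean <- function(coords, selection) {
  m0 <- matrix(colMeans(coords), ncol = 3, byrow = TRUE)
  coords <- superpose(coords, m0, selection)$traj
  m1 <- matrix(colMeans(coords), ncol = 3, byrow = TRUE)
  superpose(coords, m1, selection)$traj
}

#' Segment covariance matrix of atomic positions
#'
#' `C = (1/T) sum_t dr dr^T` with `dr` the deviation of the selected atoms'
#' coordinates from the segment mean; `3N x 3N`, symmetric positive
#' semidefinite, in nm^2. With `align = TRUE` (default) frames are first
#' rigid-body superposed onto the segment mean (iterated once) so rigid
#' motion does not masquerade as internal covariance.
#'
#' @param traj An [md_trajectory] or T x 3N coordinate matrix.
#' @param frames Frame indices forming the segment (>= 2).
#' @param selection Atom indices (default all).
#' @param align Remove rigid-body motion first.
#' @return The covariance matrix with attribute `"mean"` (segment mean
#'   coordinates of the selection).
#' @export
ecd_covariance <- function(traj, frames = NULL, selection = NULL,
                           align = TRUE) {
  coords <- if (inherits(traj, "md_trajectory")) traj$coords else
    as.matrix(traj)
  frames <- frames %||% seq_len(nrow(coords))
  if (length(frames) < 2) abort("covariance needs at least 2 frames")
  n <- ncol(coords) / 3
  selection <- selection %||% seq_len(n)
  block <- coords[frames, , drop = FALSE]
  if (align) block <- align_to_mean(block, selection)
  cols <- sel_cols(selection)
  x <- block[, cols, drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / nrow(xc)
  attr(cv, "mean") <- mu
  cv
}

## Coordinate columns of an atom selection in the T x 3N layout
sel_cols <- function(selection) {
  as.numeric(t(cbind((selection - 1) * 3 + 1, (selection - 1) * 3 + 2,
                     (selection - 1) * 3 + 3)))
}

#' Principal eigenpairs of a covariance matrix
#'
#' Top-`d` eigenvalues/eigenvectors (descending, orthonormal) plus the total
#' variance (trace) and the cumulative variance fraction `f_d`. A warning is
#' logged when `f_d` falls below 0.95, the usual adequacy yardstick for a
#' 10-mode essential subspace.
#'
#' @param cv Covariance matrix (symmetric PSD), or a T x 3N centred/uncentred
#'   data block via [essential_modes_traj()].
#' @param d Number of modes to keep.
#' @return Object of class `essential_modes`: `values` (length d, nm^2),
#'   `vectors` (3N x d), `trace`, `fraction` (f_d), `d`.
#' @export
essential_modes <- function(cv, d = 10) {
  if (d > ncol(cv)) abort(sprintf("d = %d exceeds dimension %d", d, ncol(cv)))
  eg <- eigen(cv, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  tr <- sum(diag(cv))
  fd <- if (tr > 0) sum(values[seq_len(d)]) / tr else 1
  if (fd < 0.95) {
    inform(sprintf("top %d modes capture %.1f%% of total displacement (< 95%%)",
                   d, 100 * fd))
  }
  structure(list(values = values[seq_len(d)],
                 vectors = eg$vectors[, seq_len(d), drop = FALSE],
                 trace = tr, fraction = fd, d = d),
            class = "essential_modes")
}

#' @export
print.essential_modes <- function(x, ...) {
  cat(sprintf("<essential_modes> d = %d, f_d = %.3f, trace = %.4g nm^2\n",
              x$d, x$fraction, x$trace))
  invisible(x)
}

## Top-d modes of one segment straight from the frame block via SVD of the
## centred data matrix -- avoids forming the 3N x 3N covariance when the
## segment has far fewer frames than coordinates. Identical eigenpairs to
## essential_modes(ecd_covariance(...)) up to eigenvector sign.
essential_modes_traj <- function(coords, frames, selection, d = 10,
                                 align = TRUE) {
  block <- coords[frames, , drop = FALSE]
  n <- ncol(coords) / 3
  if (align) block <- align_to_mean(block, selection %||% seq_len(n))
  x <- block[, sel_cols(selection %||% seq_len(n)), drop = FALSE]
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc / sqrt(nrow(xc)), nu = 0, nv = min(d, ncol(xc)))
  values <- sv$d^2
  tr <- sum(xc^2) / nrow(xc)
  keep <- seq_len(min(d, length(values)))
  fd <- if (tr > 0) sum(values[keep]) / tr else 1
  vec <- sv$v
  if (ncol(vec) < d) {
    vec <- cbind(vec, matrix(0, nrow(vec), d - ncol(vec)))
  }
  structure(list(values = c(values[keep], rep(0, d - length(keep))),
                 vectors = vec[, seq_len(d), drop = FALSE], trace = tr,
                 fraction = fd, d = d),
            class = "essential_modes")
}

#' Atom images in essential-coordinate space
#'
#' Maps each selected atom to a point in `R^{3d}`: the concatenation of its
#' 3-component sub-vectors of the top-d eigenvectors, each weighted by
#' `sqrt(lambda_k)`, normalised by the square root of the total retained
#' variance. Images are dimensionless and comparable across segments;
#' proximity of two images means persistently correlated motion. The mapping
#' is the package's documented strategy (`weighting = "sqrt"`); an
#' unweighted variant is provided for sensitivity checks.
#'
#' @param modes An `essential_modes` object.
#' @param weighting `"sqrt"` (default) or `"none"`.
#' @return Matrix of class `atom_images`, one row per atom of the selection
#'   the modes were computed on, 3d columns.
#' @export
atom_images <- function(modes, weighting = c("sqrt", "none")) {
  weighting <- match.arg(weighting)
  d <- modes$d
  n <- nrow(modes$vectors) / 3
  w <- switch(weighting, sqrt = sqrt(modes$values), none = rep(1, d))
  ## degenerate segment (no variance at all): every atom images to the
  ## origin rather than to an arbitrary direction of numerical noise
  if (modes$trace < 1e-18) {
    img <- matrix(0, n, 3 * d)
    class(img) <- c("atom_images", class(img))
    return(img)
  }
  norm <- sqrt(sum(modes$values))
  if (norm == 0) norm <- 1
  img <- matrix(0, n, 3 * d)
  for (k in seq_len(d)) {
    sub <- matrix(modes$vectors[, k], ncol = 3, byrow = TRUE)
    img[, (3 * k - 2):(3 * k)] <- w[k] * sub
  }
  img <- img / norm
  class(img) <- c("atom_images", class(img))
  img
}

## Images per segment for a selection, averaged-distance machinery shared by
## the pair-correlation, flexibility and domain descriptors.
segment_images <- function(traj, selection, seg_len = 200, window = "all",
                           d = 10, align = TRUE) {
  segs <- ecd_segments(traj, seg_len = seg_len, window = window)
  lapply(segs, function(fr) {
    m <- essential_modes_traj(traj$coords, fr, selection, d = d, align = align)
    atom_images(m)
  })
}

#' ECD pair-correlation map
#'
#' Image-space distance `rho_ij = ||chi_i - chi_j||`, averaged over the
#' segments of the window, between the Calpha atoms of the selection. Small
#' distance = strongly correlated motion.
#'
#' @param traj An [md_trajectory].
#' @param selection Atom indices (default: all Calpha atoms).
#' @param seg_len Segment length in ps.
#' @param window Window spec.
#' @param d Number of essential modes.
#' @param align Remove rigid-body motion per segment.
#' @return Object of class `pair_correlation`: symmetric zero-diagonal
#'   matrix with the selection as attribute.
#' @export
ecd_pair_correlation <- function(traj, selection = NULL, seg_len = 200,
                                 window = "all", d = 10, align = TRUE) {
  selection <- selection %||% select_atoms(traj$system, names = "CA")
  imgs <- segment_images(traj, selection, seg_len, window, d, align)
  acc <- NULL
  for (im in imgs) {
    dm <- as.matrix(dist(im))
    acc <- if (is.null(acc)) dm else acc + dm
  }
  rho <- acc / length(imgs)
  dimnames(rho) <- NULL
  structure(rho, class = c("pair_correlation", "matrix"),
            selection = selection,
            atoms = traj$system$atoms[selection, c("chain", "resid")])
}

#' ECD main-chain flexibility profile
#'
#' Per-residue flexibility: the image-space distance of a residue's Calpha
#' from the centroid of all main-chain images, averaged over segments. High
#' values mark residues moving independently of the aggregate (loops,
#' termini); the C-terminal value per chain is the usual tabulated summary.
#'
#' @inheritParams ecd_pair_correlation
#' @return Tibble of class `flexibility_profile`: `chain`, `resid`,
#'   `flexibility`; attribute `"c_terminal"` holds the per-chain C-terminal
#'   values and their mean over amyloid-beta chains.
#' @export
ecd_flexibility <- function(traj, selection = NULL, seg_len = 200,
                            window = "all", d = 10, align = TRUE) {
  selection <- selection %||% select_atoms(traj$system, names = "CA")
  imgs <- segment_images(traj, selection, seg_len, window, d, align)
  f <- numeric(length(selection))
  for (im in imgs) {
    cen <- colMeans(im)
    f <- f + sqrt(rowSums(sweep(im, 2, cen)^2))
  }
  f <- f / length(imgs)
  at <- traj$system$atoms[selection, ]
  out <- tibble::tibble(chain = at$chain, resid = at$resid, flexibility = f)
  cterm <- dplyr::summarise(
    dplyr::group_by(out, .data$chain),
    flexibility = .data$flexibility[which.max(.data$resid)], .groups = "drop")
  sp <- species_of(traj$system)
  ab <- cterm$flexibility[sp[cterm$chain] %in% AB_SPECIES]
  attr(out, "c_terminal") <- list(
    per_chain = cterm,
    abeta_mean = if (length(ab)) mean(ab) else NA_real_)
  class(out) <- c("flexibility_profile", class(out))
  out
}

#' Domains of correlated motion
#'
#' Single-linkage agglomerative clustering of the segment-averaged
#' image-space distance matrix, cut at `threshold`; clusters smaller than
#' `min_size` atoms are off-domain. Domains are ranked by size (rank 1
#' largest). The published threshold for this style of analysis is 0.008,
#' but its scale depends on the image normalisation, so calibrate against
#' the distance distribution of your own system (see the package vignette).
#'
#' @inheritParams ecd_pair_correlation
#' @param threshold Linkage cut height in image-space distance units.
#' @param min_size Minimum atoms per domain.
#' @return Tibble of class `domain_assignment`: `atom`, `chain`, `resid`,
#'   `name`, `domain` (integer rank, `NA` = off-domain).
#' @export
ecd_domains <- function(traj, selection = NULL, threshold = 0.008,
                        min_size = 20, seg_len = 200, window = "all",
                        d = 10, align = TRUE) {
  if (threshold <= 0) abort("threshold must be positive")
  selection <- selection %||% seq_len(n_atoms(traj$system))
  rho <- ecd_pair_correlation(traj, selection, seg_len, window, d, align)
  cluster_images(rho, selection, traj$system, threshold, min_size)
}

## shared by ecd_domains and direct image clustering in tests
cluster_images <- function(rho, selection, system, threshold, min_size) {
  hc <- hclust(as.dist(rho), method = "single")
  memb <- cutree(hc, h = threshold)
  sizes <- table(memb)
  big <- names(sizes)[sizes >= min_size]
  rank_map <- setNames(rep(NA_integer_, length(sizes)), names(sizes))
  ord <- big[order(-sizes[big], as.integer(big))]
  rank_map[ord] <- seq_along(ord)
  at <- system$atoms[selection, ]
  out <- tibble::tibble(atom = selection, chain = at$chain, resid = at$resid,
                        name = at$name,
                        domain = unname(rank_map[as.character(memb)]))
  class(out) <- c("domain_assignment", class(out))
  out
}
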