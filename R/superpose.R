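## Kabsch rotation: optimal rotation mapping centred point set P onto
## centred Q (both n x 3), via SVD with a reflection guard.
kabsch_rotation <- function(p, q) {
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rigid-body superposition onto a reference frame
#'
#' Least-squares (Kabsch) superposition of each trajectory frame onto a
#' reference coordinate set, fitting on a selection. All atoms of each frame
#' receive the fitted rotation/translation; the RMSD is reported on the
#' selection, in nm.
#'
#' @param traj An [md_trajectory], or a T x 3N coordinate matrix.
#' @param reference N x 3 reference coordinates in nm (defaults to the first
#'   frame).
#' @param selection Integer atom indices to fit on (default: all atoms).
#' @return A list with `traj` (aligned trajectory or matrix, same type as the
#'   input) and `rmsd` (numeric vector, nm, one value per frame).
#' @export
superpose <- function(traj, reference = NULL, selection = NULL) {
  is_traj <- inherits(traj, "md_trajectory")
  coords <- if (is_traj) traj$coords else as.matrix(traj)
  n <- ncol(coords) / 3
  selection <- selection %||% seq_len(n)
  if (length(selection) < 3) abort("selection must contain at least 3 atoms")
  if (is.null(reference)) {
    reference <- matrix(coords[1, ], ncol = 3, byrow = TRUE)
  }
  ref_sel <- reference[selection, , drop = FALSE]
  if (degenerate_points(ref_sel)) {
    abort("reference selection is degenerate (coincident or collinear)")
  }
  ref_c <- colMeans(ref_sel)
  ref0 <- sweep(ref_sel, 2, ref_c)
  rmsd <- numeric(nrow(coords))
  cols <- as.numeric(t(cbind((selection - 1) * 3 + 1, (selection - 1) * 3 + 2,
                             (selection - 1) * 3 + 3)))
  for (t in seq_len(nrow(coords))) {
    fr <- matrix(coords[t, ], ncol = 3, byrow = TRUE)
    mob <- fr[selection, , drop = FALSE]
    mob_c <- colMeans(mob)
    r <- kabsch_rotation(sweep(mob, 2, mob_c), ref0)
    aligned <- sweep(sweep(fr, 2, mob_c) %*% t(r), 2, ref_c, "+")
    coords[t, ] <- as.numeric(t(aligned))
    dev <- aligned[selection, , drop = FALSE] - ref_sel
    rmsd[t] <- sqrt(mean(rowSums(dev^2)))
  }
  if (is_traj) {
    traj$coords <- coords
    list(traj = traj, rmsd = rmsd)
  } else {
    list(traj = coords, rmsd = rmsd)
  }
}

## Coincident or collinear point set (rank of centred coordinates < 2)
degenerate_points <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = 0, nv = 0)$d
  sum(sv > max(sv[1], 1e-12) * 1e-8) < 2
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b N x 3 matrices in nm.
#' @param fit Superpose `a` onto `b` first (default `FALSE`).
#' @return RMSD in nm.
#' @export
rmsd <- function(a, b, fit = FALSE) {
  if (fit) {
    ac <- colMeans(a); bc <- colMeans(b)
    r <- kabsch_rotation(sweep(a, 2, ac), sweep(b, 2, bc))
    a <- sweep(sweep(a, 2, ac) %*% t(r), 2, bc, "+")
  }
  sqrt(mean(rowSums((a - b)^2)))
}
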