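# Essential dynamics: rigid-body superposition followed by principal
# component analysis of the Cartesian coordinate covariance. Leading
# eigenvectors describe the dominant collective motions of the atoms.

#' Least-squares superposition of a trajectory
#'
#' Each frame is superposed (optimal rotation + translation, Kabsch) onto a
#' reference using the fit selection. With `reference = "mean"` the fit is
#' iterated: frames are first fitted to frame 1, the mean structure is
#' computed, and frames are re-fitted to that mean (two passes).
#'
#' @param traj trajectory_view (>= 2 frames).
#' @param reference `"mean"` (default) or `"first_frame"`.
#' @param fit_selection selection used for fitting, default `"name CA"`;
#'   must resolve >= 3 non-collinear atoms.
#' @return superposed trajectory_view (all atoms transformed).
#' @export
superpose_trajectory <- function(traj, reference = c("mean", "first_frame"),
                                 fit_selection = "name CA") {
  reference <- match.arg(reference)
  if (n_frames(traj) < 2L) stop("need at least 2 frames", call. = FALSE)
  idx <- select_atoms(traj$atoms, fit_selection)
  if (length(idx) < 3L)
    stop("fit selection must resolve at least 3 atoms", call. = FALSE)
  pts <- frame_coords(traj, 1L)[idx, , drop = FALSE]
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  if (sv$d[2] < 1e-8)
    stop("degenerate fit selection: atoms are collinear", call. = FALSE)
  xyz_inds <- as.vector(t(outer(idx - 1L, 1:3, function(i, k) 3L * i + k)))
  fit_once <- function(xyz, ref_xyz) {
    bio3d::fit.xyz(fixed = ref_xyz, mobile = xyz,
                   fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  }
  xyz <- fit_once(traj$xyz, traj$xyz[1, ])
  if (reference == "mean") {
    xyz <- fit_once(xyz, colMeans(xyz))
  }
  trajectory_view(traj$atoms, xyz, traj$times)
}

#' Covariance eigenmodes of coordinate fluctuations
#'
#' Covariance of the Cartesian coordinates about their mean (population
#' normalisation, so the eigenvalue sum equals the mean squared fluctuation)
#' followed by symmetric eigendecomposition; modes sorted by decreasing
#' eigenvalue.
#'
#' @param traj superposed trajectory_view, or a list of such views to
#'   concatenate (monomers with the same interface type analysed jointly).
#' @param selection atom selection for the analysis, default `"name CA"`.
#' @return object of class `mode_set`: `mean_coords` (3N vector),
#'   `eigenvalues` (A^2, descending), `eigenvectors` (3N x 3N, orthonormal
#'   columns), `n_frames`.
#' @export
covariance_and_modes <- function(traj, selection = "name CA") {
  if (inherits(traj, "trajectory_view")) traj <- list(traj)
  xyz <- do.call(rbind, lapply(traj, function(tv)
    subset_trajectory(tv, selection)$xyz))
  if (nrow(xyz) < 2L) stop("need at least 2 frames", call. = FALSE)
  mu <- colMeans(xyz)
  ctr <- sweep(xyz, 2, mu)
  C <- crossprod(ctr) / nrow(ctr)
  eig <- eigen(C, symmetric = TRUE)
  ev <- eig$values
  if (any(ev < -1e-9)) stop("covariance eigenvalues are negative", call. = FALSE)
  ev[ev < 0] <- 0
  structure(list(mean_coords = mu, eigenvalues = ev,
                 eigenvectors = eig$vectors, n_frames = nrow(xyz)),
            class = "mode_set")
}

#' Cumulative fluctuation fraction of the first k modes
#'
#' @param modes mode_set.
#' @param k number of leading modes, `1 <= k <=` number of modes.
#' @return sum of the first k eigenvalues over the sum of all, in `[0, 1]`.
#' @export
cumulative_fluctuation_fraction <- function(modes, k) {
  if (k < 1 || k > length(modes$eigenvalues))
    stop("k out of range", call. = FALSE)
  sum(modes$eigenvalues[seq_len(k)]) / sum(modes$eigenvalues)
}

#' Projections of frames onto a mode
#'
#' @param modes mode_set.
#' @param traj trajectory_view restricted to the same selection used for
#'   the modes (or the selection to apply).
#' @param mode_index mode number.
#' @param selection selection applied to `traj`, default `"name CA"`.
#' @return numeric vector of per-frame projections in Angstrom.
#' @export
mode_projections <- function(modes, traj, mode_index = 1L,
                             selection = "name CA") {
  if (mode_index < 1 || mode_index > length(modes$eigenvalues))
    stop("mode index out of range", call. = FALSE)
  xyz <- subset_trajectory(traj, selection)$xyz
  as.vector(sweep(xyz, 2, modes$mean_coords) %*%
              modes$eigenvectors[, mode_index])
}

#' Extreme structures along a principal mode
#'
#' Returns the coordinate sets at the extremes of the motion along one
#' mode: either the trajectory frames with minimal/maximal projection, or
#' (with `quantile`) reconstructions `mean +/- q * sigma * mode`.
#'
#' @param modes mode_set.
#' @param traj trajectory_view (same atom selection as the modes).
#' @param mode_index mode number, default 1.
#' @param selection selection applied to `traj`, default `"name CA"`.
#' @param quantile if non-`NULL`, reconstruct `mean +/- quantile * sigma`
#'   along the mode instead of picking observed frames.
#' @return list with `min_coords`, `max_coords` (N x 3 matrices),
#'   `displacement` (per-atom 3-vectors from min to max), `projections`,
#'   `mode_index`.
#' @export
extreme_projections <- function(modes, traj, mode_index = 1L,
                                selection = "name CA", quantile = NULL) {
  proj <- mode_projections(modes, traj, mode_index, selection)
  v <- modes$eigenvectors[, mode_index]
  if (is.null(quantile)) {
    sub <- subset_trajectory(traj, selection)
    lo <- frame_coords(sub, which.min(proj))
    hi <- frame_coords(sub, which.max(proj))
  } else {
    s <- quantile * sd(proj)
    lo <- matrix(modes$mean_coords - s * v, ncol = 3, byrow = TRUE)
    hi <- matrix(modes$mean_coords + s * v, ncol = 3, byrow = TRUE)
  }
  list(min_coords = lo, max_coords = hi, displacement = hi - lo,
       projections = proj, mode_index = mode_index)
}

#' Write extreme structures as a two-model PDB
#'
#' @param extremes result of [extreme_projections()].
#' @param atoms atom table matching the analysed selection.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_extremes_pdb <- function(extremes, atoms, path) {
  xyz <- rbind(as.vector(t(extremes$min_coords)),
               as.vector(t(extremes$max_coords)))
  write_trajectory_pdb(trajectory_view(atoms, xyz, c(0, 1)), path)
}
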