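# Channel coordinate system: axis, origin, boundary planes, lateral cutoff.
#
# Convention: the axial origin (z = 0) sits at the NPA region of the channel
# and z increases toward the extracellular side, so the ar/R selectivity
# filter of an aquaporin lies near z = +10 A.

#' Construct a channel geometry
#'
#' @param axis unit 3-vector (membrane normal).
#' @param origin 3-vector, projection reference in Angstrom (NPA region).
#' @param z_lower,z_upper axial boundary planes in Angstrom (`z_lower < 0 <
#'   z_upper`).
#' @param lateral_cutoff radius around the pore axis in Angstrom defining
#'   "inside the channel".
#' @param pore_length length L in Angstrom used by the collective coordinate;
#'   defaults to `z_upper - z_lower`.
#' @return object of class `channel_geometry`.
#' @export
channel_geometry <- function(axis = c(0, 0, 1), origin = c(0, 0, 0),
                             z_lower = -15, z_upper = 15, lateral_cutoff = 6,
                             pore_length = NULL) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (abs(nrm) < 1e-12) stop("axis must be a non-zero vector", call. = FALSE)
  axis <- axis / nrm
  if (z_lower >= z_upper) stop("z_lower must be < z_upper", call. = FALSE)
  if (!(z_lower < 0 && z_upper > 0))
    stop("boundary planes must bracket the origin: z_lower < 0 < z_upper",
         call. = FALSE)
  if (lateral_cutoff <= 0) stop("lateral_cutoff must be > 0", call. = FALSE)
  structure(list(axis = axis, origin = as.numeric(origin),
                 z_lower = z_lower, z_upper = z_upper,
                 lateral_cutoff = lateral_cutoff,
                 pore_length = pore_length %||% (z_upper - z_lower)),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel_geometry: axis (%.3f, %.3f, %.3f), origin (%.2f, %.2f, %.2f)\n",
              x$axis[1], x$axis[2], x$axis[3], x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  z in [%.1f, %.1f] A, lateral cutoff %.1f A, L = %.1f A\n",
              x$z_lower, x$z_upper, x$lateral_cutoff, x$pore_length))
  invisible(x)
}

#' Define the channel coordinate system from anchor atoms
#'
#' The origin is the centroid of the anchor atoms averaged over all frames
#' (for aquaporins, backbone atoms of the two NPA motifs). The axis is the
#' global z axis (`fixed_z`, the membrane normal in a standard bilayer setup)
#' or the first principal axis of the pooled anchor coordinates
#' (`principal_axis`, for tilted channels).
#'
#' @param traj trajectory_view.
#' @param anchor_selection selection resolving to >= 3 atoms.
#' @param axis_mode `"fixed_z"` or `"principal_axis"`.
#' @param z_lower,z_upper,lateral_cutoff,pore_length see [channel_geometry()].
#' @return channel_geometry.
#' @export
define_channel_geometry <- function(traj, anchor_selection = "all",
                                    axis_mode = c("fixed_z", "principal_axis"),
                                    z_lower = -15, z_upper = 15,
                                    lateral_cutoff = 6, pore_length = NULL) {
  axis_mode <- match.arg(axis_mode)
  idx <- select_atoms(traj$atoms, anchor_selection)
  if (length(idx) < 3L)
    stop("anchor selection must resolve to at least 3 atoms", call. = FALSE)
  sub <- subset_trajectory(traj, idx)
  pooled <- do.call(rbind, lapply(seq_len(n_frames(sub)),
                                  function(f) frame_coords(sub, f)))
  origin <- colMeans(pooled)
  if (axis_mode == "fixed_z") {
    axis <- c(0, 0, 1)
  } else {
    ctr <- sweep(pooled, 2, origin)
    sv <- svd(ctr, nu = 0, nv = 3)
    ev <- sv$d^2
    if (ev[1] < 1e-12)
      stop("degenerate anchor: coincident points give no principal axis",
           call. = FALSE)
    if (nrow(pooled) > 3 && (ev[1] - ev[2]) / ev[1] < 1e-9)
      stop("degenerate anchor: leading principal axis is not unique",
           call. = FALSE)
    axis <- sv$v[, 1]
    if (sum(axis * c(0, 0, 1)) < 0) axis <- -axis
  }
  channel_geometry(axis = axis, origin = origin, z_lower = z_lower,
                   z_upper = z_upper, lateral_cutoff = lateral_cutoff,
                   pore_length = pore_length)
}

# Axial (z) and lateral coordinates of a set of atoms in every frame.
# Returns list(z = frames x atoms matrix, lateral = frames x atoms matrix).
axial_coordinates <- function(tv, geom) {
  nf <- n_frames(tv); na <- n_atoms(tv)
  xi <- seq(1, 3 * na, by = 3)
  X <- tv$xyz[, xi, drop = FALSE] - geom$origin[1]
  Y <- tv$xyz[, xi + 1, drop = FALSE] - geom$origin[2]
  Z <- tv$xyz[, xi + 2, drop = FALSE] - geom$origin[3]
  z <- X * geom$axis[1] + Y * geom$axis[2] + Z * geom$axis[3]
  lat2 <- pmax(X^2 + Y^2 + Z^2 - z^2, 0)
  list(z = z, lateral = sqrt(lat2))
}

#' Classify waters inside the channel, frame by frame
#'
#' A water is inside at a frame iff `z_lower <= z <= z_upper` (closed on both
#' planes) and its lateral distance from the axis is `<= lateral_cutoff`,
#' both computed from the water oxygen position.
#'
#' @param traj trajectory_view.
#' @param geom channel_geometry.
#' @param water_selection selection resolving water oxygen atoms, default
#'   `"water and element O"`.
#' @return list with one integer vector of atom ids per frame.
#' @export
classify_channel_waters <- function(traj, geom,
                                    water_selection = "water and element O") {
  wat <- subset_trajectory(traj, water_selection)
  ax <- axial_coordinates(wat, geom)
  inside <- ax$z >= geom$z_lower & ax$z <= geom$z_upper &
    ax$lateral <= geom$lateral_cutoff
  lapply(seq_len(nrow(inside)),
         function(f) wat$atoms$atom_id[inside[f, ]])
}
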