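# Pore radius profiling by maximal inscribed sphere, HOLE-style but with the
# sphere centre constrained to planes perpendicular to a fixed channel axis.
#
# At each axial position z the profiler maximises
#   f(x, y) = min_i ( |p - a_i| - vdw_i ),   p = origin + z*axis + x*e1 + y*e2
# over in-plane coordinates (x, y), i.e. the radius of the largest sphere
# centred in the plane that touches no atom surface. The optimiser is a
# seeded multi-start simulated-annealing search with a final pattern-search
# polish.

# Orthonormal in-plane basis perpendicular to the axis.
.plane_basis <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Clearance radius at in-plane point xy given wall atoms (rows) and vdw.
.clearance <- function(xy, base, e1, e2, wall, vdw) {
  p <- base + xy[1] * e1 + xy[2] * e2
  dx <- wall[, 1] - p[1]; dy <- wall[, 2] - p[2]; dz <- wall[, 3] - p[3]
  min(sqrt(dx * dx + dy * dy + dz * dz) - vdw)
}

#' Maximal inscribed sphere radius at one axial position
#'
#' @param wall N x 3 matrix of wall-atom positions (Angstrom).
#' @param vdw numeric vector of van der Waals radii, one per wall atom.
#' @param geom channel_geometry.
#' @param z axial position in Angstrom, within `[z_lower, z_upper]`.
#' @param init_xy starting in-plane point `(x, y)` in the plane basis,
#'   default the axis `(0, 0)`.
#' @param rng_seed integer seed for the stochastic search (restarts and
#'   proposals); `NULL` uses the current RNG state.
#' @param n_restarts random restarts in addition to `init_xy`, default 3.
#' @param restart_mode `"local"` (default): restarts and proposals stay
#'   within `local_radius` of `init_xy`, so the search tracks the pore
#'   basin around the centreline (a pore-following profiler must not
#'   tunnel through the wall into open space); `"global"`: restarts sample
#'   the whole allowed disk, for globally multimodal slices.
#' @param max_offset hard constraint on the centre's distance from the
#'   axis, default `2 * geom$lateral_cutoff`.
#' @param local_radius trust region around `init_xy` in local mode, in
#'   Angstrom; default 2.5 (generous against the centreline drift between
#'   adjacent slices at the default `z_step`).
#' @param step_init initial proposal step in Angstrom, default 1.
#' @param cooling step/temperature reduction factor per stage, default 0.9.
#' @param step_min convergence threshold on the step size in Angstrom,
#'   default 0.01.
#' @param slab_halfwidth only atoms within this axial distance of the plane
#'   are considered walls, default 15 Angstrom.
#' @return object of class `pore_slice`: list with `z`, `center_xy` (plane
#'   coordinates), `center` (3-vector), `radius` (Angstrom; may be <= 0 when
#'   the plane is occluded), `converged`.
#' @export
max_inscribed_radius_at_z <- function(wall, vdw, geom, z, init_xy = c(0, 0),
                                      rng_seed = NULL, n_restarts = 3,
                                      restart_mode = c("local", "global"),
                                      max_offset = NULL, local_radius = 2.5,
                                      step_init = 1, cooling = 0.9,
                                      step_min = 0.01, slab_halfwidth = 15) {
  restart_mode <- match.arg(restart_mode)
  if (nrow(wall) < 4L) stop("need at least 4 wall atoms", call. = FALSE)
  if (z < geom$z_lower - 1e-9 || z > geom$z_upper + 1e-9)
    stop("z outside [z_lower, z_upper]", call. = FALSE)
  b <- .plane_basis(geom$axis)
  az <- (wall[, 1] - geom$origin[1]) * geom$axis[1] +
        (wall[, 2] - geom$origin[2]) * geom$axis[2] +
        (wall[, 3] - geom$origin[3]) * geom$axis[3]
  near <- abs(az - z) <= slab_halfwidth
  if (!any(near))
    stop("empty slice: no wall atoms within ", slab_halfwidth,
         " A of the plane at z = ", z, call. = FALSE)
  w <- wall[near, , drop = FALSE]; vr <- vdw[near]
  base <- geom$origin + z * geom$axis
  rmax <- max_offset %||% (2 * geom$lateral_cutoff)
  allowed <- function(p) {
    sum(p^2) <= rmax^2 &&
      (restart_mode == "global" ||
         sum((p - init_xy)^2) <= local_radius^2)
  }
  with_seed(rng_seed, {
    starts <- if (restart_mode == "local") {
      s <- rbind(init_xy,
                 sweep(matrix(rnorm(2 * n_restarts, 0, local_radius / 2),
                              ncol = 2), 2, init_xy, `+`))
      # clip jittered starts into the trust region
      r <- sqrt(rowSums(sweep(s, 2, init_xy)^2))
      ex <- r > local_radius
      s[ex, ] <- init_xy + (s[ex, , drop = FALSE] - rep(init_xy, each = sum(ex))) *
        (local_radius / r[ex])
      s
    } else {
      ang <- runif(n_restarts, 0, 2 * pi)
      rad <- rmax * sqrt(runif(n_restarts))
      rbind(init_xy, cbind(rad * cos(ang), rad * sin(ang)))
    }
    best <- init_xy; fbest <- -Inf
    for (s in seq_len(nrow(starts))) {
      cur <- starts[s, ]
      if (!allowed(cur)) cur <- init_xy
      fcur <- .clearance(cur, base, b$e1, b$e2, w, vr)
      step <- step_init
      while (step > step_min) {
        temp <- 0.1 * step
        for (k in 1:16) {
          prop <- cur + rnorm(2) * step
          if (!allowed(prop)) next
          fp <- .clearance(prop, base, b$e1, b$e2, w, vr)
          if (fp > fcur || runif(1) < exp((fp - fcur) / temp)) {
            cur <- prop; fcur <- fp
            if (fp > fbest) { best <- prop; fbest <- fp }
          }
        }
        step <- step * cooling
      }
      if (fcur > fbest) { best <- cur; fbest <- fcur }
    }
    # deterministic pattern-search polish
    step <- step_min
    while (step > 1e-4) {
      moved <- FALSE
      for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
        prop <- best + d
        if (!allowed(prop)) next
        fp <- .clearance(prop, base, b$e1, b$e2, w, vr)
        if (fp > fbest) { best <- prop; fbest <- fp; moved <- TRUE }
      }
      if (!moved) step <- step / 2
    }
    structure(list(z = z, center_xy = best,
                   center = base + best[1] * b$e1 + best[2] * b$e2,
                   radius = fbest, converged = TRUE),
              class = "pore_slice")
  })
}

#' Pore radius profile of a single frame
#'
#' Slices the channel from `z_lower` to `z_upper` at `z_step`; each slice's
#' search starts from the previous slice's centre (centreline continuity).
#'
#' @param traj trajectory_view of the wall atoms (typically
#'   `"protein and heavy"`); pass a pre-subset view.
#' @param geom channel_geometry.
#' @param frame frame index, default 1.
#' @param z_step axial sampling step in Angstrom, default 0.5.
#' @param rng_seed integer seed for the per-slice searches.
#' @param ... further arguments to [max_inscribed_radius_at_z()].
#' @return data.frame of class `pore_profile`: columns `z`, `x`, `y`
#'   (plane coordinates of the centre), `radius`, `converged`.
#' @export
radius_profile_frame <- function(traj, geom, frame = 1L, z_step = 0.5,
                                 rng_seed = NULL, ...) {
  wall <- frame_coords(traj, frame)
  vdw <- traj$atoms$vdw
  zs <- seq(geom$z_lower, geom$z_upper, by = z_step)
  init <- c(0, 0)
  out <- vector("list", length(zs))
  seeds <- if (is.null(rng_seed)) rep(list(NULL), length(zs))
           else as.list(rng_seed + seq_along(zs))
  for (i in seq_along(zs)) {
    sl <- max_inscribed_radius_at_z(wall, vdw, geom, zs[i], init_xy = init,
                                    rng_seed = seeds[[i]], ...)
    init <- sl$center_xy
    out[[i]] <- data.frame(z = sl$z, x = sl$center_xy[1], y = sl$center_xy[2],
                           radius = sl$radius, converged = sl$converged)
  }
  structure(do.call(rbind, out), class = c("pore_profile", "data.frame"))
}

#' Temporal pore radius profile
#'
#' Per-snapshot radius profiles (snapshots every `snapshot_stride_ps`)
#' averaged within time bins of `time_bin_ns` and across monomers, giving a
#' 2D (time-bin x axial-position) radius map.
#'
#' @param traj trajectory_view containing all monomers.
#' @param geom channel_geometry, or a list of one geometry per monomer.
#' @param monomers list of wall selections, one per monomer (e.g.
#'   `list("chain A and heavy", "chain B and heavy")`).
#' @param snapshot_stride_ps snapshot stride in ps, default 10.
#' @param time_bin_ns time bin width in ns, default 2.
#' @param z_step axial step in Angstrom, default 0.5.
#' @param rng_seed integer seed.
#' @param ... further arguments to [max_inscribed_radius_at_z()].
#' @return object of class `temporal_radius_profile`: list with
#'   `time_bin_edges_ns`, `z_grid`, `radius` (time-bin x z matrix, `NA`
#'   where no data), `n_samples` (matching counts matrix),
#'   `n_monomers_averaged`.
#' @export
temporal_radius_profile <- function(traj, geom, monomers,
                                    snapshot_stride_ps = 10, time_bin_ns = 2,
                                    z_step = 0.5, rng_seed = NULL, ...) {
  if (length(monomers) == 0L) stop("empty monomer list", call. = FALSE)
  geoms <- if (inherits(geom, "channel_geometry"))
    rep(list(geom), length(monomers)) else geom
  if (length(geoms) != length(monomers))
    stop("need one geometry per monomer (or a single shared geometry)",
         call. = FALSE)
  times <- traj$times
  dt <- if (length(times) > 1) diff(times)[1] else snapshot_stride_ps
  step <- max(1L, round(snapshot_stride_ps / dt))
  snaps <- seq(1L, length(times), by = step)
  span_ps <- times[length(times)] - times[1] + dt
  n_tbins <- max(1L, ceiling(span_ps / (time_bin_ns * 1000)))
  if (span_ps < time_bin_ns * 1000 - 1e-9 && length(times) > 1)
    n_tbins <- 1L
  edges_ns <- (times[1] + (0:n_tbins) * time_bin_ns * 1000) / 1000
  g0 <- geoms[[1]]
  zs <- seq(g0$z_lower, g0$z_upper, by = z_step)
  acc <- matrix(0, n_tbins, length(zs))
  cnt <- matrix(0L, n_tbins, length(zs))
  for (m in seq_along(monomers)) {
    sub <- subset_trajectory(traj, monomers[[m]])
    seed_m <- if (is.null(rng_seed)) NULL else rng_seed + 1000L * m
    for (s in snaps) {
      tb <- min(n_tbins, 1L + floor((times[s] - times[1]) / (time_bin_ns * 1000)))
      prof <- radius_profile_frame(sub, geoms[[m]], frame = s, z_step = z_step,
                                   rng_seed = if (is.null(seed_m)) NULL else seed_m + s,
                                   ...)
      acc[tb, ] <- acc[tb, ] + prof$radius
      cnt[tb, ] <- cnt[tb, ] + 1L
    }
  }
  radius <- acc / cnt
  radius[cnt == 0L] <- NA_real_
  structure(list(time_bin_edges_ns = edges_ns, z_grid = zs, radius = radius,
                 n_samples = cnt, n_monomers_averaged = length(monomers)),
            class = "temporal_radius_profile")
}
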