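# Potential of mean force along the channel axis by Boltzmann inversion of
# the average axial water occupancy: G(z) = -kB*T*ln(<n(z)>).

#' Construct an occupancy histogram
#'
#' @param z_edges bin edges in Angstrom (length nbins + 1, increasing).
#' @param mean_count average number of waters per frame per bin.
#' @param n_frames number of frames averaged.
#' @return object of class `occupancy_histogram`.
#' @export
occupancy_histogram_obj <- function(z_edges, mean_count, n_frames) {
  if (length(mean_count) != length(z_edges) - 1L)
    stop("mean_count must have one entry per bin", call. = FALSE)
  if (any(mean_count < 0)) stop("mean_count must be >= 0", call. = FALSE)
  structure(list(z_edges = as.numeric(z_edges),
                 mean_count = as.numeric(mean_count),
                 n_frames = n_frames),
            class = "occupancy_histogram")
}

#' Axial water occupancy histogram
#'
#' Bins the axial coordinate of every inside water over frames taken at a
#' given time stride; `mean_count` is the per-frame average occupancy of
#' each bin.
#'
#' @param traj trajectory_view.
#' @param geom channel_geometry.
#' @param water_selection selection for water oxygens.
#' @param bin_width axial bin width in Angstrom, default 0.5.
#' @param frame_stride_ps time stride between counted frames in ps, default
#'   10 (i.e. use every snapshot of a 10 ps-spaced trajectory).
#' @return occupancy_histogram.
#' @export
occupancy_histogram <- function(traj, geom,
                                water_selection = "water and element O",
                                bin_width = 0.5, frame_stride_ps = 10) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  tr <- extract_axial_traces(traj, geom, water_selection)
  dt <- if (length(tr$times) > 1) diff(tr$times)[1] else frame_stride_ps
  step <- max(1L, round(frame_stride_ps / dt))
  use <- seq(1L, length(tr$times), by = step)
  if (length(use) == 0L) stop("no frames at the requested stride", call. = FALSE)
  nb <- max(1L, round((geom$z_upper - geom$z_lower) / bin_width))
  edges <- geom$z_lower + (geom$z_upper - geom$z_lower) * (0:nb) / nb
  inside <- tr$state[use, , drop = FALSE] == .ST_INSIDE
  zin <- tr$z[use, , drop = FALSE][inside]
  counts <- if (length(zin)) {
    bi <- pmin(pmax(findInterval(zin, edges, rightmost.closed = TRUE), 1L), nb)
    tabulate(bi, nbins = nb)
  } else rep(0, nb)
  occupancy_histogram_obj(edges, counts / length(use), length(use))
}

#' PMF profile by Boltzmann inversion of occupancy
#'
#' `G(z) = -kB*T*ln(<n(z)>)` per bin (kB*T = 2.577 kJ/mol at 310 K).
#' Zero-occupancy bins are reported as `NA` (undefined), not infinite.
#' Under the `min_zero` convention the minimum over defined bins is shifted
#' to zero; `raw` leaves the absolute values.
#'
#' @param hist occupancy_histogram.
#' @param temperature_K temperature in kelvin, default 310.
#' @param offset_convention `"min_zero"` (default) or `"raw"`.
#' @return object of class `pmf_profile`: `z_centers`, `G` (kJ/mol, `NA`
#'   where undefined), `temperature_K`, `offset_convention`.
#' @export
pmf_from_occupancy <- function(hist, temperature_K = 310,
                               offset_convention = c("min_zero", "raw")) {
  offset_convention <- match.arg(offset_convention)
  mc <- hist$mean_count
  if (all(mc == 0))
    stop("degenerate input: occupancy is zero in every bin", call. = FALSE)
  G <- ifelse(mc > 0, -kBT(temperature_K) * log(mc), NA_real_)
  if (offset_convention == "min_zero") G <- G - min(G, na.rm = TRUE)
  structure(list(z_centers = (hist$z_edges[-1] + hist$z_edges[-length(hist$z_edges)]) / 2,
                 G = G, temperature_K = temperature_K,
                 offset_convention = offset_convention),
            class = "pmf_profile")
}

#' Average PMF over monomers by pooling occupancies
#'
#' Occupancies of several monomer channels are pooled as frame-weighted
#' averages and Boltzmann inversion is applied once to the pooled occupancy
#' (merge-then-invert, i.e. the trajectories are merged, not the PMFs
#' averaged).
#'
#' @param histograms list of occupancy_histogram with identical binning.
#' @param temperature_K temperature in kelvin.
#' @param offset_convention see [pmf_from_occupancy()].
#' @return pmf_profile of the pooled occupancy.
#' @export
average_pmf_over_monomers <- function(histograms, temperature_K = 310,
                                      offset_convention = c("min_zero", "raw")) {
  stopifnot(length(histograms) >= 1)
  e0 <- histograms[[1]]$z_edges
  for (h in histograms)
    if (length(h$z_edges) != length(e0) || any(abs(h$z_edges - e0) > 1e-9))
      stop("histograms have mismatched bin edges", call. = FALSE)
  w <- vapply(histograms, function(h) h$n_frames, numeric(1))
  pooled <- Reduce(`+`, Map(function(h, wi) h$mean_count * wi, histograms, w)) / sum(w)
  pmf_from_occupancy(occupancy_histogram_obj(e0, pooled, sum(w)),
                     temperature_K, match.arg(offset_convention))
}

#' Barrier height of a PMF profile
#'
#' Maximum minus minimum of G over defined bins; offset-free, so independent
#' of the offset convention.
#'
#' @param profile pmf_profile.
#' @return barrier height in kJ/mol.
#' @export
pmf_barrier <- function(profile) {
  g <- profile$G[!is.na(profile$G)]
  max(g) - min(g)
}
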