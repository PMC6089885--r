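# Permeation-event counting and collective-diffusion osmotic permeability.
#
# Complete permeation: a water goes from one bulk side (below the lower
# boundary plane) through the channel interior to the other bulk side, with
# no intervening retreat to its entry side. The osmotic permeability is
# pf = vw * Dn, where Dn is the diffusion constant of the dimensionless
# collective coordinate n(t) (Einstein relation on its mean-squared
# displacement) and vw the volume of one water molecule.

# Region-state codes used throughout this file.
.ST_BELOW <- -1L; .ST_INSIDE <- 0L; .ST_ABOVE <- 1L; .ST_OUTLAT <- 2L

#' Extract per-water axial traces
#'
#' For every selected water, records the axial coordinate and a per-frame
#' region state: `below` (z below the lower plane), `above` (z above the
#' upper plane), `inside` (within the slab and within the lateral cutoff) or
#' `outside_lateral` (within the slab but laterally beyond the cutoff,
#' i.e. bypassing the pore).
#'
#' @param traj trajectory_view.
#' @param geom channel_geometry.
#' @param water_selection selection for water oxygens.
#' @return object of class `axial_traces`: list with `times` (ps), `z` and
#'   `lateral` (frames x waters matrices), `state` (integer-coded matrix),
#'   `water_ids`, and the geometry.
#' @export
extract_axial_traces <- function(traj, geom,
                                 water_selection = "water and element O") {
  wat <- subset_trajectory(traj, water_selection)
  ax <- axial_coordinates(wat, geom)
  st <- matrix(.ST_INSIDE, nrow = nrow(ax$z), ncol = ncol(ax$z))
  st[ax$z < geom$z_lower] <- .ST_BELOW
  st[ax$z > geom$z_upper] <- .ST_ABOVE
  slab <- st == .ST_INSIDE
  st[slab & ax$lateral > geom$lateral_cutoff] <- .ST_OUTLAT
  structure(list(times = wat$times, z = ax$z, lateral = ax$lateral,
                 state = st, water_ids = wat$atoms$atom_id, geom = geom),
            class = "axial_traces")
}

#' Region states of one trace as a factor
#'
#' @param traces axial_traces.
#' @param i water column index.
#' @return factor with levels below/inside/above/outside_lateral.
#' @export
trace_states <- function(traces, i) {
  factor(c("below", "inside", "above", "outside_lateral")[match(
    traces$state[, i], c(.ST_BELOW, .ST_INSIDE, .ST_ABOVE, .ST_OUTLAT))],
    levels = c("below", "inside", "above", "outside_lateral"))
}

#' Count complete permeation events
#'
#' Per water, an `up` event is recorded when the state history shows below,
#' then one or more inside frames, then above, with no intervening retreat
#' to the entry side; `down` is symmetric. A lateral exit while inside
#' resets the water to the side given by the sign of its z coordinate (such
#' a bypass never completes an event). Multiple events per water are
#' allowed.
#'
#' @param traces axial_traces.
#' @return list with `events` (data.frame: water_id, direction, entry_time,
#'   exit_time), `total_events`, `up_events`, `down_events`.
#' @export
count_permeation_events <- function(traces) {
  if (is.unsorted(traces$times, strictly = TRUE))
    stop("trace timestamps are not strictly increasing", call. = FALSE)
  times <- traces$times
  evs <- vector("list", ncol(traces$state))
  for (j in seq_len(ncol(traces$state))) {
    st <- traces$state[, j]
    ni <- which(st != .ST_INSIDE)           # non-inside frames
    if (length(ni) < 2L) next
    side <- st[ni]
    side[side == .ST_OUTLAT] <- ifelse(traces$z[ni[side == .ST_OUTLAT], j] <= 0,
                                       .ST_BELOW, .ST_ABOVE)
    real <- st[ni] != .ST_OUTLAT            # lateral exits arm but never complete
    k <- seq_along(ni)[-1]
    hit <- real[k] & side[k] != side[k - 1L] & (ni[k] - ni[k - 1L] > 1L)
    if (!any(hit)) next
    kk <- k[hit]
    evs[[j]] <- data.frame(
      water_id = traces$water_ids[j],
      direction = ifelse(side[kk] == .ST_ABOVE, "up", "down"),
      entry_time = times[ni[kk - 1L] + 1L],
      exit_time = times[ni[kk]],
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, evs)
  if (is.null(events))
    events <- data.frame(water_id = integer(0), direction = character(0),
                         entry_time = numeric(0), exit_time = numeric(0))
  list(events = events,
       total_events = nrow(events),
       up_events = sum(events$direction == "up"),
       down_events = sum(events$direction == "down"))
}

#' Collective water coordinate n(t)
#'
#' Per frame step, `dn = sum_i dz_i / L` over waters inside the channel at
#' both step endpoints; `n(t)` is the cumulative sum with `n(0) = 0`. A net
#' single-file crossing advances n by 1.
#'
#' @param traces axial_traces.
#' @param geom channel_geometry (for the pore length L); defaults to the
#'   geometry stored in `traces`.
#' @return object of class `collective_series`: list with `times`, `n`,
#'   `pore_length`.
#' @export
collective_coordinate <- function(traces, geom = traces$geom) {
  L <- geom$pore_length
  if (is.null(L) || L <= 0) stop("pore length L must be > 0", call. = FALSE)
  inside <- traces$state == .ST_INSIDE
  nf <- nrow(inside)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  both <- inside[-1, , drop = FALSE] & inside[-nf, , drop = FALSE]
  dz <- traces$z[-1, , drop = FALSE] - traces$z[-nf, , drop = FALSE]
  dn <- rowSums(dz * both) / L
  structure(list(times = traces$times, n = c(0, cumsum(dn)), pore_length = L),
            class = "collective_series")
}

#' Osmotic permeability from the collective coordinate
#'
#' Splits n(t) into contiguous windows of `bin_width_ps`, computes the
#' mean-squared displacement MSD(tau) within each window, averages the MSD
#' over windows, and fits a least-squares line through the origin over lags
#' from one frame to half the window. `Dn = slope / 2` (Einstein relation),
#' and `pf = vw * Dn`.
#'
#' @param series collective_series.
#' @param bin_width_ps window width in ps, default 200.
#' @param v_w single-water volume in cm^3, default 2.99e-23 (18.015 g/mol at
#'   0.997 g/cm^3).
#' @return object of class `permeability_result`: `D_n` (1/ns), `v_w` (cm^3),
#'   `p_f` (units of 1e-14 cm^3/s), `fit_window` (ps), `n_bins`, `msd`
#'   (data.frame tau_ps/msd), `clamped` flag.
#' @export
osmotic_permeability <- function(series, bin_width_ps = 200, v_w = 2.99e-23) {
  times <- series$times
  dt <- diff(times)[1]
  fpb <- max(2L, round(bin_width_ps / dt))     # frames per window
  n_bins <- floor(length(series$n) / fpb)
  if (n_bins < 5L)
    stop("insufficient data: need at least 5 windows of ", bin_width_ps,
         " ps (have ", n_bins, ")", call. = FALSE)
  max_lag <- max(1L, floor(fpb / 2))
  n <- series$n[seq_len(n_bins * fpb)]
  win <- rep(seq_len(n_bins), each = fpb)
  msd <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    i <- seq_len(length(n) - lag)
    ok <- win[i] == win[i + lag]
    d <- n[i + lag][ok] - n[i][ok]
    msd[lag] <- mean(d * d)
  }
  tau <- dt * seq_len(max_lag)
  slope <- sum(tau * msd) / sum(tau * tau)     # through the origin
  clamped <- FALSE
  if (slope < 0) { slope <- 0; clamped <- TRUE
    warning("negative fitted MSD slope; D_n clamped to 0") }
  D_n <- slope / 2 * 1000                       # 1/ps -> 1/ns
  p_f <- v_w * D_n * 1e9 / 1e-14                # in 1e-14 cm^3/s
  structure(list(D_n = D_n, v_w = v_w, p_f = p_f,
                 fit_window = c(dt, dt * max_lag), n_bins = n_bins,
                 msd = data.frame(tau_ps = tau, msd = msd),
                 clamped = clamped),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("collective diffusion: D_n = %.4g /ns, p_f = %.4g x 1e-14 cm^3/s (%d windows)\n",
              x$D_n, x$p_f, x$n_bins))
  invisible(x)
}
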