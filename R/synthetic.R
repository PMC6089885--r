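# Seeded synthetic-trajectory generators with ground-truth records.
#
# Each generator emulates the statistics one pipeline stage consumes --
# single-file Brownian water with a known collective diffusion constant,
# Boltzmann-distributed axial occupancy under a known free-energy profile,
# pseudo-atom channel walls with analytic pore radius, planted interface
# contacts, and low-rank harmonic coordinate fluctuations -- so every stage
# can be scored against known truth without running molecular dynamics.
# Output is bitwise reproducible for a fixed seed.

.water_atoms <- function(n) {
  data.frame(atom_id = seq_len(n), name = "OW", element = "O",
             resname = "HOH", resid = seq_len(n), chain = "W",
             is_heavy = TRUE, vdw = vdw_radius("O"),
             stringsAsFactors = FALSE)
}

#' Synthetic single-file channel trajectory (Brownian waters)
#'
#' Waters perform independent 1D Brownian motion along the channel axis
#' over a domain extending `margin` beyond both boundary planes, with
#' periodic re-injection at the far boundary so crossings occur at a
#' sustained rate. The per-step displacement variance is set so that the
#' collective coordinate n(t) diffuses with `D_n_true`:
#' `sigma^2 = 2 * D_n_true * dt * L^2 / E[waters inside]`, with
#' `E[waters inside] = n_waters * L / domain_length` (uniform stationary
#' density). The truth record carries `D_n_true` and the generator's own
#' crossing log, obtained by boundary-sequence tracking, independent of the
#' package's event counter.
#'
#' @param D_n_true collective diffusion constant in 1/ns.
#' @param L pore length in Angstrom (boundaries at -L/2, +L/2), default 30.
#' @param n_waters number of waters, default 100.
#' @param n_frames number of frames, default 2000.
#' @param dt_ps frame spacing in ps, default 10.
#' @param margin bulk margin beyond each boundary plane in Angstrom,
#'   default 10.
#' @param lateral_cutoff channel lateral cutoff in Angstrom, default 6.
#' @param seed integer seed.
#' @return list with `traj` (trajectory_view), `geom` (channel_geometry)
#'   and `truth` (`D_n_true`, `events_up`, `events_down`, `events_total`,
#'   `sigma_step`).
#' @export
gen_single_file_channel <- function(D_n_true = 1.0, L = 30, n_waters = 100,
                                    n_frames = 2000, dt_ps = 10, margin = 10,
                                    lateral_cutoff = 6, seed = 1) {
  stopifnot(D_n_true >= 0, L > 0, n_waters >= 1, n_frames >= 2, dt_ps > 0)
  lo <- -L / 2 - margin; hi <- L / 2 + margin
  Ltot <- hi - lo
  n_in <- n_waters * L / Ltot
  sigma <- L * sqrt(2 * (D_n_true / 1000) * dt_ps / n_in)
  with_seed(seed, {
    z0 <- runif(n_waters, lo, hi)
    dz <- matrix(rnorm((n_frames - 1) * n_waters, 0, sigma),
                 n_frames - 1, n_waters)
    zc <- apply(dz, 2, cumsum)
    if (is.null(dim(zc))) zc <- matrix(zc, nrow = 1)
    zraw <- rbind(z0, sweep(zc, 2, z0, `+`))       # unwrapped
    z <- lo + (zraw - lo) %% Ltot                  # periodic re-injection
    # independent crossing log: consecutive boundary-region visits per
    # water, with the history reset at re-injection (wrap) frames
    up <- 0L; down <- 0L
    wrap <- abs(z[-1, , drop = FALSE] - z[-n_frames, , drop = FALSE]) > Ltot / 2
    for (j in seq_len(n_waters)) {
      zb <- z[, j]
      mark <- ifelse(zb < -L / 2, -1L, ifelse(zb > L / 2, 1L, 0L))
      seg_id <- findInterval(seq_len(n_frames), which(wrap[, j]) + 1L)
      ni <- which(mark != 0L)
      if (length(ni) >= 2L) {
        m <- mark[ni]; sg <- seg_id[ni]
        len <- length(m)
        trans <- m[-1] != m[-len] & sg[-1] == sg[-len]
        up <- up + sum(trans & m[-1] == 1L)
        down <- down + sum(trans & m[-1] == -1L)
      }
    }
    xyz <- matrix(0, n_frames, 3 * n_waters)
    xyz[, seq(1, 3 * n_waters, by = 3)] <- 0.5   # on-axis, within cutoff
    xyz[, seq(3, 3 * n_waters, by = 3)] <- z
    list(traj = trajectory_view(.water_atoms(n_waters), xyz,
                                dt_ps * (seq_len(n_frames) - 1)),
         geom = channel_geometry(z_lower = -L / 2, z_upper = L / 2,
                                 lateral_cutoff = lateral_cutoff,
                                 pore_length = L),
         truth = list(D_n_true = D_n_true, events_up = up, events_down = down,
                      events_total = up + down, sigma_step = sigma))
  })
}

#' Synthetic trajectory with planted permeation events
#'
#' Deterministic piecewise-linear water paths: `n_up` waters cross the
#' channel upward, `n_down` downward, `n_retreat` enter from below and
#' retreat to their entry side, and `n_bypass` traverse the slab axially
#' but outside the lateral cutoff (and so must not be counted). The truth
#' record carries the planted counts.
#'
#' @param n_up,n_down,n_retreat,n_bypass water counts per behaviour.
#' @param n_frames frames, default 200.
#' @param dt_ps frame spacing in ps, default 1.
#' @param L pore length in Angstrom, default 30.
#' @param lateral_cutoff lateral cutoff in Angstrom, default 6.
#' @param seed integer seed (jitters path phases).
#' @return list with `traj`, `geom`, `truth` (`events_up`, `events_down`,
#'   `events_total`).
#' @export
gen_planted_crossings <- function(n_up = 5, n_down = 3, n_retreat = 4,
                                  n_bypass = 0, n_frames = 200, dt_ps = 1,
                                  L = 30, lateral_cutoff = 6, seed = 1) {
  n <- n_up + n_down + n_retreat + n_bypass
  stopifnot(n >= 1, n_frames >= 20)
  half <- L / 2 + 5
  with_seed(seed, {
    phase <- runif(n, 0, 0.2)
    z <- matrix(0, n_frames, n)
    lat <- matrix(0.5, n_frames, n)
    tgrid <- seq(0, 1, length.out = n_frames)
    col <- 0L
    for (k in seq_len(n_up)) {
      col <- col + 1L
      s <- pmin(pmax((tgrid - phase[col]) / 0.6, 0), 1)
      z[, col] <- -half + 2 * half * s
    }
    for (k in seq_len(n_down)) {
      col <- col + 1L
      s <- pmin(pmax((tgrid - phase[col]) / 0.6, 0), 1)
      z[, col] <- half - 2 * half * s
    }
    for (k in seq_len(n_retreat)) {
      col <- col + 1L
      s <- pmin(pmax((tgrid - phase[col]) / 0.6, 0), 1)
      z[, col] <- -half + 2 * half * ifelse(s < 0.5, s, 1 - s)  # to z=0, back
    }
    for (k in seq_len(n_bypass)) {
      col <- col + 1L
      s <- pmin(pmax((tgrid - phase[col]) / 0.6, 0), 1)
      z[, col] <- -half + 2 * half * s
      lat[, col] <- lateral_cutoff + 2    # outside the pore
    }
    xyz <- matrix(0, n_frames, 3 * n)
    xyz[, seq(1, 3 * n, by = 3)] <- lat
    xyz[, seq(3, 3 * n, by = 3)] <- z
    list(traj = trajectory_view(.water_atoms(n), xyz,
                                dt_ps * (seq_len(n_frames) - 1)),
         geom = channel_geometry(z_lower = -L / 2, z_upper = L / 2,
                                 lateral_cutoff = lateral_cutoff,
                                 pore_length = L),
         truth = list(events_up = as.integer(n_up),
                      events_down = as.integer(n_down),
                      events_total = as.integer(n_up + n_down)))
  })
}

#' Boltzmann-sampled axial occupancy under a known free-energy profile
#'
#' Samples axial positions from the density `exp(-G_true(z) / kB T)` by
#' inverse-CDF on a fine grid and bins them into an occupancy histogram, so
#' Boltzmann inversion should recover `G_true` up to an additive constant.
#'
#' @param G_true function z (Angstrom) -> free energy (kJ/mol).
#' @param n_samples number of samples, default 1e6.
#' @param temperature_K temperature in kelvin, default 310.
#' @param bin_width histogram bin width in Angstrom, default 0.5.
#' @param z_range `c(lo, hi)` in Angstrom, default `c(-15, 15)`.
#' @param n_frames nominal frame count for the per-frame average, default
#'   1000 (scales `mean_count` only; the PMF shape is unaffected).
#' @param seed integer seed.
#' @return list with `hist` (occupancy_histogram) and `truth`
#'   (`G_fun`, `G_centers` on the bin centres, `barrier` = max - min).
#' @export
gen_boltzmann_axial <- function(G_true, n_samples = 1e6, temperature_K = 310,
                                bin_width = 0.5, z_range = c(-15, 15),
                                n_frames = 1000, seed = 1) {
  stopifnot(is.function(G_true), n_samples >= 1)
  grid <- seq(z_range[1], z_range[2], length.out = 4001)
  h <- diff(grid)[1]
  dens <- exp(-G_true(grid) / kBT(temperature_K))
  with_seed(seed, {
    idx <- sample.int(length(grid), n_samples, replace = TRUE, prob = dens)
    zs <- grid[idx] + runif(n_samples, -h / 2, h / 2)
    zs <- pmin(pmax(zs, z_range[1]), z_range[2])
    nb <- round((z_range[2] - z_range[1]) / bin_width)
    edges <- z_range[1] + (z_range[2] - z_range[1]) * (0:nb) / nb
    bi <- pmin(pmax(findInterval(zs, edges, rightmost.closed = TRUE), 1L), nb)
    counts <- tabulate(bi, nbins = nb)
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    gt <- G_true(centers)
    list(hist = occupancy_histogram_obj(edges, counts / n_frames, n_frames),
         truth = list(G_fun = G_true, G_centers = gt - min(gt),
                      barrier = max(gt) - min(gt)))
  })
}

#' Pseudo-atom channel walls with analytic radius profile
#'
#' Builds rings of pseudo-atoms whose inner van der Waals surface realises
#' `profile(z)`: at each z, `atoms_per_ring` atoms at in-plane distance
#' `profile(z) + vdw` from the axis, with a random azimuthal offset per
#' ring.
#'
#' @param profile function z (Angstrom) -> pore radius (Angstrom).
#' @param vdw pseudo-atom van der Waals radius in Angstrom, default 1.5.
#' @param atoms_per_ring atoms per ring, default 12.
#' @param ring_step axial ring spacing in Angstrom, default 1.
#' @param z_range `c(lo, hi)`, default `c(-17, 17)` (walls extend past the
#'   analysis slab).
#' @param axis,origin channel axis (unit vector after normalisation) and
#'   origin.
#' @param lateral_cutoff geometry cutoff, default 6.
#' @param seed integer seed for the azimuthal offsets.
#' @return list with `traj` (single-frame trajectory_view; `vdw` column set
#'   to the pseudo-atom radius), `geom`, `truth`: `profile` (the requested
#'   surface) and `inscribed` (the analytic maximal-inscribed-sphere radius
#'   on the axis, `min over z' of sqrt((profile(z') + vdw)^2 + (z' - z)^2)
#'   - vdw`; on steep flanks this is smaller than `profile` because the
#'   sphere touches the wall of neighbouring sections first).
#' @export
gen_pore_geometry <- function(profile, vdw = 1.5, atoms_per_ring = 12,
                              ring_step = 1, z_range = c(-17, 17),
                              axis = c(0, 0, 1), origin = c(0, 0, 0),
                              lateral_cutoff = 6, seed = 1) {
  stopifnot(is.function(profile))
  axis <- axis / sqrt(sum(axis^2))
  b <- .plane_basis(axis)
  zs <- seq(z_range[1], z_range[2], by = ring_step)
  with_seed(seed, {
    offs <- runif(length(zs), 0, 2 * pi)
    pts <- vector("list", length(zs))
    for (i in seq_along(zs)) {
      R <- profile(zs[i]) + vdw
      th <- offs[i] + 2 * pi * (0:(atoms_per_ring - 1)) / atoms_per_ring
      pts[[i]] <- t(vapply(th, function(a)
        origin + zs[i] * axis + R * cos(a) * b$e1 + R * sin(a) * b$e2,
        numeric(3)))
    }
    P <- do.call(rbind, pts)
    n <- nrow(P)
    atoms <- data.frame(atom_id = seq_len(n), name = "PS", element = "C",
                        resname = "PSD", resid = rep(seq_along(zs),
                                                     each = atoms_per_ring),
                        chain = "X", is_heavy = TRUE, vdw = vdw,
                        stringsAsFactors = FALSE)
    zl <- max(-15, z_range[1] + 2); zu <- min(15, z_range[2] - 2)
    inscribed <- function(z) {
      vapply(z, function(zi) {
        zp <- seq(zi - 12, zi + 12, by = 0.01)
        zp <- zp[zp >= z_range[1] & zp <= z_range[2]]
        min(sqrt((profile(zp) + vdw)^2 + (zp - zi)^2)) - vdw
      }, numeric(1))
    }
    list(traj = trajectory_view(atoms, matrix(as.vector(t(P)), nrow = 1), 0),
         geom = channel_geometry(axis = axis, origin = origin, z_lower = zl,
                                 z_upper = zu, lateral_cutoff = lateral_cutoff),
         truth = list(profile = profile, inscribed = inscribed, vdw = vdw))
  })
}

#' Two pseudo-monomer interface with planted contacts
#'
#' Builds two pseudo-monomers (chains A and B) of single-atom residues.
#' Each planted pair sits at 3.5 A for its stated fraction of frames and at
#' 6 A otherwise; all other cross-monomer distances are >= 15 A.
#'
#' @param pair_fractions numeric vector: contact fraction per planted pair
#'   (one pair per A/B residue, residue i of A with residue i of B).
#' @param n_frames frames, default 100.
#' @param dt_ps frame spacing, default 10.
#' @param seed integer seed (shuffles which frames are in contact).
#' @return list with `traj`, `truth` (`fractions`, `persistent_resA`,
#'   `persistent_resB`, indices of pairs with fraction >= 0.70).
#' @export
gen_interface_toy <- function(pair_fractions = c(1, 0.8, 0.5), n_frames = 100,
                              dt_ps = 10, seed = 1) {
  np <- length(pair_fractions)
  stopifnot(np >= 1, n_frames >= 10)
  atoms <- rbind(
    data.frame(atom_id = seq_len(np), name = "CA", element = "C",
               resname = "ALA", resid = seq_len(np), chain = "A",
               is_heavy = TRUE, vdw = vdw_radius("C")),
    data.frame(atom_id = np + seq_len(np), name = "CA", element = "C",
               resname = "GLY", resid = seq_len(np), chain = "B",
               is_heavy = TRUE, vdw = vdw_radius("C")))
  with_seed(seed, {
    xyz <- matrix(0, n_frames, 3 * 2 * np)
    for (k in seq_len(np)) {
      ax <- 20 * (k - 1)                       # well-separated pair slots
      xyz[, 3 * (k - 1) + 1] <- ax             # A atom fixed
      n_on <- round(pair_fractions[k] * n_frames)
      on <- sample.int(n_frames, n_on)
      y <- rep(6, n_frames); y[on] <- 3.5      # B atom toggles distance
      xyz[, 3 * (np + k - 1) + 1] <- ax
      xyz[, 3 * (np + k - 1) + 2] <- y
    }
    keep <- round(pair_fractions * n_frames) / n_frames >= 0.70 - 1e-12
    list(traj = trajectory_view(atoms, xyz, dt_ps * (seq_len(n_frames) - 1)),
         truth = list(fractions = round(pair_fractions * n_frames) / n_frames,
                      persistent_pairs = which(keep),
                      persistent_resA = paste0("ALA", which(keep)),
                      persistent_resB = paste0("GLY", which(keep))))
  })
}

#' Harmonic-mode trajectory with known covariance structure
#'
#' Frames are `mean + sum_k a_k(t) v_k` with `a_k ~ N(0, variance_k)` and
#' orthonormal mode vectors; optionally each frame is then rigidly rotated
#' and translated to exercise the superposition stage.
#'
#' @param n_atoms atoms, default 30.
#' @param mode_variances vector of mode variances in Angstrom^2,
#'   default `c(4, 1)`.
#' @param n_frames frames, default 1000.
#' @param dt_ps frame spacing, default 10.
#' @param rigid_noise if `TRUE`, apply a random rigid rotation+translation
#'   per frame.
#' @param seed integer seed.
#' @return list with `traj`, `truth` (`mean_coords`, `mode_vectors` (3N x k,
#'   orthonormal), `mode_variances`, `amplitudes` (frames x k)).
#' @export
gen_harmonic_modes <- function(n_atoms = 30, mode_variances = c(4, 1),
                               n_frames = 1000, dt_ps = 10,
                               rigid_noise = FALSE, seed = 1) {
  k <- length(mode_variances)
  stopifnot(n_atoms >= 4, k >= 1, n_frames >= 2)
  with_seed(seed, {
    # non-degenerate mean structure: a loose helix
    t0 <- seq(0, 4 * pi, length.out = n_atoms)
    mean_xyz <- cbind(8 * cos(t0), 8 * sin(t0), seq(0, 30, length.out = n_atoms))
    mu <- as.vector(t(mean_xyz))
    # internal modes must be orthogonal to the 6 rigid-body directions
    # (3 translations + 3 infinitesimal rotations about the centroid),
    # otherwise least-squares superposition absorbs part of their variance
    ctr <- sweep(mean_xyz, 2, colMeans(mean_xyz))
    rigid <- matrix(0, 3 * n_atoms, 6)
    for (d in 1:3) rigid[seq(d, 3 * n_atoms, by = 3), d] <- 1
    rigid[, 4] <- as.vector(t(cbind(0, -ctr[, 3], ctr[, 2])))   # about x
    rigid[, 5] <- as.vector(t(cbind(ctr[, 3], 0, -ctr[, 1])))   # about y
    rigid[, 6] <- as.vector(t(cbind(-ctr[, 2], ctr[, 1], 0)))   # about z
    B <- qr.Q(qr(rigid))
    V <- matrix(rnorm(3 * n_atoms * k), 3 * n_atoms, k)
    V <- V - B %*% crossprod(B, V)
    V <- qr.Q(qr(V))
    A <- matrix(rnorm(n_frames * k), n_frames, k) %*% diag(sqrt(mode_variances), k)
    xyz <- matrix(mu, n_frames, 3 * n_atoms, byrow = TRUE) + A %*% t(V)
    if (rigid_noise) {
      for (f in seq_len(n_frames)) {
        M <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
        if (det(M) < 0) M[, 1] <- -M[, 1]
        co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) %*% M
        co <- sweep(co, 2, rnorm(3, 0, 5), `+`)
        xyz[f, ] <- as.vector(t(co))
      }
    }
    atoms <- data.frame(atom_id = seq_len(n_atoms), name = "CA",
                        element = "C", resname = "ALA",
                        resid = seq_len(n_atoms), chain = "A",
                        is_heavy = TRUE, vdw = vdw_radius("C"),
                        stringsAsFactors = FALSE)
    list(traj = trajectory_view(atoms, xyz, dt_ps * (seq_len(n_frames) - 1)),
         truth = list(mean_coords = mu, mode_vectors = V,
                      mode_variances = mode_variances, amplitudes = A))
  })
}
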