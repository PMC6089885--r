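make_single_water_traj <- function(z, lateral = 0.5) {
  n <- length(z)
  atoms <- data.frame(atom_id = 1L, name = "OW", element = "O",
                      resname = "HOH", resid = 1L, chain = "W",
                      is_heavy = TRUE, vdw = 1.52)
  trajectory_view(atoms, cbind(rep(lateral, n), 0, z), seq_len(n) - 1)
}

test_that("axial traces assign the documented region states", {
  geom <- channel_geometry()
  tv <- make_single_water_traj(seq(-20, 20, length.out = 41))
  tr <- extract_axial_traces(tv, geom)
  st <- as.character(trace_states(tr, 1))
  expect_equal(st[1], "below")
  expect_equal(st[41], "above")
  expect_true(all(st[abs(seq(-20, 20, length.out = 41)) < 15] == "inside"))

  still <- extract_axial_traces(make_single_water_traj(rep(0, 10)), geom)
  expect_true(all(as.character(trace_states(still, 1)) == "inside"))

  # in-slab but laterally outside the cutoff
  byp <- extract_axial_traces(make_single_water_traj(rep(0, 5), lateral = 9),
                              geom)
  expect_true(all(as.character(trace_states(byp, 1)) == "outside_lateral"))
})

test_that("random-walk state sequences match brute-force classification", {
  set.seed(21)
  n <- 50; nf <- 80
  atoms <- data.frame(atom_id = seq_len(n), name = "OW", element = "O",
                      resname = "HOH", resid = seq_len(n), chain = "W",
                      is_heavy = TRUE, vdw = 1.52)
  xyz <- matrix(rnorm(nf * 3 * n, 0, 8), nf, 3 * n)
  tv <- trajectory_view(atoms, xyz, seq_len(nf) - 1)
  geom <- channel_geometry()
  tr <- extract_axial_traces(tv, geom)
  want <- brute_states(tv, geom)
  got <- vapply(seq_len(n), function(j) as.character(trace_states(tr, j)),
                character(nf))
  expect_identical(got, want)
})

test_that("event machine counts crossings and ignores retreats and bypasses", {
  geom <- channel_geometry()
  up <- count_permeation_events(extract_axial_traces(
    make_single_water_traj(seq(-20, 20, length.out = 41)), geom))
  expect_equal(up$total_events, 1L)
  expect_equal(up$up_events, 1L)

  retreat <- count_permeation_events(extract_axial_traces(
    make_single_water_traj(c(seq(-20, 0, 2), seq(-2, -20, -2))), geom))
  expect_equal(retreat$total_events, 0L)

  bypass <- count_permeation_events(extract_axial_traces(
    make_single_water_traj(seq(-20, 20, length.out = 41), lateral = 9), geom))
  expect_equal(bypass$total_events, 0L)

  g <- gen_planted_crossings(5, 3, 4, n_frames = 400, seed = 2)
  ev <- count_permeation_events(extract_axial_traces(g$traj, g$geom))
  expect_equal(ev$total_events, 8L)
  expect_equal(ev$up_events, 5L)
  expect_equal(ev$down_events, 3L)
})

test_that("vectorised event counter equals the per-frame FSM oracle on random walks", {
  for (seed in c(4, 17)) {
    g <- gen_single_file_channel(D_n_true = 2, n_waters = 40, n_frames = 400,
                                 seed = seed)
    tr <- extract_axial_traces(g$traj, g$geom)
    got <- count_permeation_events(tr)
    st <- vapply(seq_len(ncol(tr$z)),
                 function(j) as.character(trace_states(tr, j)),
                 character(length(tr$times)))
    want <- brute_count_events(st, tr$z)
    expect_equal(got$up_events, want$up)
    expect_equal(got$down_events, want$down)
  }
})

test_that("time reversal swaps up and down events and preserves the total", {
  g <- gen_single_file_channel(D_n_true = 1.5, n_waters = 30, n_frames = 500,
                               seed = 13)
  tr <- extract_axial_traces(g$traj, g$geom)
  fwd <- count_permeation_events(tr)
  rev_traj <- trajectory_view(g$traj$atoms,
                              g$traj$xyz[rev(seq_len(nrow(g$traj$xyz))), ],
                              g$traj$times)
  bwd <- count_permeation_events(extract_axial_traces(rev_traj, g$geom))
  expect_equal(bwd$up_events, fwd$down_events)
  expect_equal(bwd$down_events, fwd$up_events)
  expect_equal(bwd$total_events, fwd$total_events)
})

test_that("doubling the frame rate of a continuous path leaves the count unchanged", {
  z_fine <- seq(-20, 20, length.out = 161)
  z_coarse <- z_fine[seq(1, 161, by = 2)]
  geom <- channel_geometry()
  a <- count_permeation_events(extract_axial_traces(
    make_single_water_traj(z_fine), geom))
  b <- count_permeation_events(extract_axial_traces(
    make_single_water_traj(z_coarse), geom))
  expect_equal(a$total_events, b$total_events)
})

test_that("collective coordinate accumulates only inside displacements", {
  geom <- channel_geometry()
  # never inside: n identically zero
  out <- collective_coordinate(extract_axial_traces(
    make_single_water_traj(rep(20, 10)), geom))
  expect_true(all(out$n == 0))

  # one inside water displaced by +L in one step increments n by exactly 1
  # (both endpoints on the closed boundary planes, so inside at both)
  tr <- extract_axial_traces(make_single_water_traj(c(-15, 15)), geom)
  cc <- collective_coordinate(tr)
  expect_equal(cc$n, c(0, 1))
})

test_that("collective MSD slope matches the generator diffusion constant", {
  g <- gen_single_file_channel(D_n_true = 1, n_waters = 50, n_frames = 20000,
                               dt_ps = 10, seed = 31)
  cc <- collective_coordinate(extract_axial_traces(g$traj, g$geom))
  # per-step variance of dn should equal 2 * D_n * dt
  dn <- diff(cc$n)
  slope <- var(dn) / 10          # per ps
  expect_lt(abs(slope - 2 * 1 / 1000) / (2 / 1000), 0.15)
})

test_that("osmotic permeability converts D_n with the molar water volume", {
  # v_w from 18.015 g/mol / (0.997 g/cm3 * 6.022e23 /mol)
  expect_equal(18.015 / (0.997 * 6.022e23), 2.99e-23, tolerance = 2e-3)

  flat <- structure(list(times = 10 * (0:4999), n = rep(0, 5000),
                         pore_length = 30), class = "collective_series")
  pf <- osmotic_permeability(flat)
  expect_equal(pf$D_n, 0)
  expect_equal(pf$p_f, 0)

  short <- structure(list(times = 10 * (0:59), n = rnorm(60),
                          pore_length = 30), class = "collective_series")
  expect_error(osmotic_permeability(short), "insufficient")
})

test_that("permeation counts and D_n are invariant under rigid transformation", {
  g <- gen_single_file_channel(D_n_true = 1, n_waters = 30, n_frames = 2000,
                               seed = 23)
  R <- random_rotation(7); tt <- c(-4, 9, 2)
  tv2 <- rigid_transform_traj(g$traj, R, tt)
  geom2 <- rigid_transform_geom(g$geom, R, tt)
  ev1 <- count_permeation_events(extract_axial_traces(g$traj, g$geom))
  ev2 <- count_permeation_events(extract_axial_traces(tv2, geom2))
  expect_equal(ev1$total_events, ev2$total_events)
  pf1 <- osmotic_permeability(collective_coordinate(extract_axial_traces(g$traj, g$geom)))
  pf2 <- osmotic_permeability(collective_coordinate(extract_axial_traces(tv2, geom2)))
  expect_equal(pf1$D_n, pf2$D_n, tolerance = 1e-6)
})
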