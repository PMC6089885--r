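test_that("an atom ring yields the analytic inscribed circle", {
  th <- 2 * pi * (0:11) / 12
  wall <- cbind(5 * cos(th), 5 * sin(th), 0)
  sl <- max_inscribed_radius_at_z(wall, rep(1.5, 12), channel_geometry(), 0,
                                  rng_seed = 3)
  expect_equal(sl$radius, 3.5, tolerance = 0.05 / 3.5)
  expect_lt(sqrt(sum(sl$center_xy^2)), 0.05)

  # a single atom on the axis occludes the slice
  occ <- max_inscribed_radius_at_z(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, -1),
                                         c(0.2, 0, 0)),
                                   rep(1.5, 4), channel_geometry(), 0,
                                   rng_seed = 3, local_radius = 0.5)
  expect_lte(occ$radius, 0)

  # no wall atoms near the plane
  far <- cbind(rep(0, 4), rep(8, 4), c(40, 41, 42, 43))
  expect_error(max_inscribed_radius_at_z(far, rep(1.5, 4), channel_geometry(),
                                         0, rng_seed = 1),
               "empty slice")
})

test_that("optimizer matches a dense grid-search oracle on random slices", {
  geom <- channel_geometry()
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(15:40, 1)
    ang <- runif(n, 0, 2 * pi); rad <- runif(n, 3.5, 9)
    wall <- cbind(rad * cos(ang), rad * sin(ang), runif(n, -2.5, 2.5))
    vdw <- runif(n, 1.2, 1.9)
    sl <- max_inscribed_radius_at_z(wall, vdw, geom, 0, rng_seed = seed + 50,
                                    restart_mode = "global", n_restarts = 12,
                                    max_offset = 6)
    want <- grid_slice_radius(wall, vdw, 0, rmax = 6)
    expect_equal(sl$radius, want, tolerance = 0.05 / abs(want))
  }
})

test_that("cylinder and hourglass fixtures are recovered within 0.05 A", {
  g <- gen_pore_geometry(function(z) 4, vdw = 1.5, seed = 5)
  pr <- radius_profile_frame(g$traj, g$geom, z_step = 1, rng_seed = 11)
  expect_lt(max(abs(pr$radius - g$truth$inscribed(pr$z))), 0.05)

  prof <- function(z) 4 - 2.5 * exp(-(z - 10)^2 / 8)
  gh <- gen_pore_geometry(prof, vdw = 1.5, ring_step = 0.5, seed = 5)
  ph <- radius_profile_frame(gh$traj, gh$geom, z_step = 0.5, rng_seed = 11)
  expect_lt(max(abs(ph$radius - gh$truth$inscribed(ph$z))), 0.05)
  expect_equal(ph$z[which.min(ph$radius)], 10, tolerance = 0.26)
})

test_that("radii are invariant under rigid transformation of wall and geometry", {
  g <- gen_pore_geometry(function(z) 4, vdw = 1.5, seed = 6)
  R <- random_rotation(19); tt <- c(5, -3, 8)
  tv2 <- rigid_transform_traj(g$traj, R, tt)
  g2 <- rigid_transform_geom(g$geom, R, tt)
  p1 <- radius_profile_frame(g$traj, g$geom, z_step = 2, rng_seed = 7)
  p2 <- radius_profile_frame(tv2, g2, z_step = 2, rng_seed = 7)
  expect_lt(max(abs(p1$radius - p2$radius)), 0.05)
})

test_that("inflating all vdw radii shrinks every slice radius by the same amount", {
  th <- 2 * pi * (0:11) / 12
  wall <- rbind(cbind(5 * cos(th), 5 * sin(th), 0),
                cbind(5 * cos(th + 0.26), 5 * sin(th + 0.26), 1),
                cbind(5 * cos(th - 0.26), 5 * sin(th - 0.26), -1))
  s1 <- max_inscribed_radius_at_z(wall, rep(1.5, 36), channel_geometry(), 0,
                                  rng_seed = 2)
  s2 <- max_inscribed_radius_at_z(wall, rep(1.9, 36), channel_geometry(), 0,
                                  rng_seed = 2)
  expect_equal(s1$radius - s2$radius, 0.4, tolerance = 0.05)
})

test_that("temporal profile averages snapshots within time bins and across monomers", {
  # rigid cylinder, 4 ns at 100 ps spacing: two identical 2 ns columns
  g <- gen_pore_geometry(function(z) 4, vdw = 1.5, seed = 5)
  nfr <- 40
  xyz <- matrix(rep(g$traj$xyz[1, ], nfr), nfr, byrow = TRUE)
  tv <- trajectory_view(g$traj$atoms, xyz, 100 * (0:(nfr - 1)))
  trp <- temporal_radius_profile(tv, g$geom, monomers = list("all"),
                                 snapshot_stride_ps = 1000, time_bin_ns = 2,
                                 z_step = 5, rng_seed = 4)
  expect_equal(dim(trp$radius), c(2L, length(trp$z_grid)))
  expect_equal(trp$radius[1, ], trp$radius[2, ], tolerance = 0.02)
  expect_error(temporal_radius_profile(tv, g$geom, monomers = list()),
               "empty monomer")

  # radius switch 4 -> 6 at 2 ns shows up as two distinct bins
  g6 <- gen_pore_geometry(function(z) 6, vdw = 1.5, seed = 5)
  xyz2 <- rbind(matrix(rep(g$traj$xyz[1, ], 20), 20, byrow = TRUE),
                matrix(rep(g6$traj$xyz[1, ], 20), 20, byrow = TRUE))
  tv2 <- trajectory_view(g$traj$atoms, xyz2, 100 * (0:39))
  trp2 <- temporal_radius_profile(tv2, g$geom, monomers = list("all"),
                                  snapshot_stride_ps = 1000, time_bin_ns = 2,
                                  z_step = 5, rng_seed = 4)
  expect_equal(mean(trp2$radius[1, ]), 4, tolerance = 0.02)
  expect_equal(mean(trp2$radius[2, ]), 6, tolerance = 0.02)
})
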