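test_that("superposition removes planted rigid motions", {
  g <- gen_harmonic_modes(n_atoms = 20, mode_variances = 1e-12,
                          n_frames = 2, seed = 1)
  # build frames that are pure rigid motions of frame 1
  base <- g$traj$xyz[1, ]
  R <- random_rotation(5)
  co <- matrix(base, ncol = 3, byrow = TRUE)
  moved <- sweep(co %*% R, 2, c(3, -2, 7), `+`)
  xyz <- rbind(base, as.vector(t(moved)))
  tv <- trajectory_view(g$traj$atoms, xyz, c(0, 10))
  fit <- superpose_trajectory(tv, reference = "first_frame",
                              fit_selection = "all")
  rmsd <- sqrt(mean((fit$xyz[2, ] - fit$xyz[1, ])^2))
  expect_lt(rmsd, 1e-6)

  # idempotence
  fit2 <- superpose_trajectory(fit, reference = "first_frame",
                               fit_selection = "all")
  expect_equal(fit2$xyz, fit$xyz, tolerance = 1e-9)
})

test_that("a single planted mode captures essentially all variance", {
  g <- gen_harmonic_modes(n_atoms = 15, mode_variances = 4, n_frames = 300,
                          seed = 7)
  modes <- covariance_and_modes(g$traj, selection = "all")
  expect_gt(cumulative_fluctuation_fraction(modes, 1), 0.999)
  # static trajectory: all eigenvalues zero
  xyz <- matrix(rep(g$traj$xyz[1, ], 5), 5, byrow = TRUE)
  static <- trajectory_view(g$traj$atoms, xyz, 10 * (0:4))
  m0 <- covariance_and_modes(static, selection = "all")
  expect_lt(max(m0$eigenvalues), 1e-12)
})

test_that("planted 4:1 mode variances and directions are recovered", {
  g <- gen_harmonic_modes(n_atoms = 30, mode_variances = c(4, 1),
                          n_frames = 10000, seed = 3)
  modes <- covariance_and_modes(g$traj, selection = "all")
  ratio <- modes$eigenvalues[1] / modes$eigenvalues[2]
  expect_equal(ratio, 4, tolerance = 0.05)
  ang <- subspace_angle_deg(modes$eigenvectors[, 1:2], g$truth$mode_vectors)
  expect_lt(ang, 5)
})

test_that("eigenvalue sum equals the mean squared fluctuation", {
  g <- gen_harmonic_modes(n_atoms = 12, mode_variances = c(2, 0.5, 0.1),
                          n_frames = 500, seed = 9)
  modes <- covariance_and_modes(g$traj, selection = "all")
  xyz <- g$traj$xyz
  msf <- mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
  expect_equal(sum(modes$eigenvalues), msf, tolerance = 1e-6)
  # orthonormal eigenvectors
  VtV <- crossprod(modes$eigenvectors)
  expect_lt(max(abs(VtV - diag(nrow(VtV)))), 1e-8)
})

test_that("PCA is invariant to frame order permutation", {
  g <- gen_harmonic_modes(n_atoms = 10, mode_variances = c(3, 1),
                          n_frames = 200, seed = 21)
  m1 <- covariance_and_modes(g$traj, selection = "all")
  set.seed(2)
  perm <- sample(nrow(g$traj$xyz))
  tv2 <- trajectory_view(g$traj$atoms, g$traj$xyz[perm, ], g$traj$times)
  m2 <- covariance_and_modes(tv2, selection = "all")
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
})

test_that("cumulative fraction closed forms hold", {
  modes <- structure(list(mean_coords = rep(0, 9),
                          eigenvalues = c(4, 1, 0),
                          eigenvectors = diag(9)[, 1:3], n_frames = 10),
                     class = "mode_set")
  expect_equal(cumulative_fluctuation_fraction(modes, 1), 0.8)
  expect_equal(cumulative_fluctuation_fraction(modes, 3), 1.0)
  expect_error(cumulative_fluctuation_fraction(modes, 0), "out of range")
  expect_error(cumulative_fluctuation_fraction(modes, 4), "out of range")
})

test_that("superposition removes rigid noise before PCA", {
  clean <- gen_harmonic_modes(n_atoms = 25, mode_variances = c(4, 1),
                              n_frames = 3000, seed = 17, rigid_noise = FALSE)
  noisy <- gen_harmonic_modes(n_atoms = 25, mode_variances = c(4, 1),
                              n_frames = 3000, seed = 17, rigid_noise = TRUE)
  m_clean <- covariance_and_modes(clean$traj, selection = "all")
  fit <- superpose_trajectory(noisy$traj, reference = "mean",
                              fit_selection = "all")
  m_fit <- covariance_and_modes(fit, selection = "all")
  # spectra agree closely after the rigid noise is fitted out
  expect_equal(m_fit$eigenvalues[1:2], m_clean$eigenvalues[1:2],
               tolerance = 0.05)
  expect_lt(sum(m_fit$eigenvalues[-(1:2)]), 0.05 * sum(m_fit$eigenvalues))
})

test_that("extreme projections bracket the mean antisymmetrically", {
  g <- gen_harmonic_modes(n_atoms = 10, mode_variances = 2, n_frames = 500,
                          seed = 5)
  modes <- covariance_and_modes(g$traj, selection = "all")
  # projection of the mean structure on any mode is zero
  mu_tv <- trajectory_view(g$traj$atoms,
                           rbind(modes$mean_coords, modes$mean_coords),
                           c(0, 10))
  expect_lt(max(abs(mode_projections(modes, mu_tv, 1, selection = "all"))),
            1e-9)
  ext <- extreme_projections(modes, g$traj, 1, selection = "all",
                             quantile = 2)
  mid <- (ext$min_coords + ext$max_coords) / 2
  expect_equal(as.vector(t(mid)), modes$mean_coords, tolerance = 1e-9)
  # observed-frame extremes are the argmin/argmax frames
  ext2 <- extreme_projections(modes, g$traj, 1, selection = "all")
  f <- which.max(ext2$projections)
  expect_equal(as.vector(t(ext2$max_coords)), g$traj$xyz[f, ])
})
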