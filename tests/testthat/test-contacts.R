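two_atom_traj <- function(dist, n_frames = 12) {
  atoms <- data.frame(atom_id = 1:2, name = "CA", element = "C",
                      resname = c("ALA", "GLY"), resid = c(1L, 1L),
                      chain = c("A", "B"), is_heavy = TRUE, vdw = 1.7)
  xyz <- matrix(rep(c(0, 0, 0, dist, 0, 0), n_frames), n_frames, byrow = TRUE)
  trajectory_view(atoms, xyz, 10 * (seq_len(n_frames) - 1))
}

test_that("frame contacts apply the distance cutoff exactly", {
  expect_equal(nrow(frame_contacts(two_atom_traj(3.5), 1, "chain A", "chain B")), 1L)
  expect_equal(nrow(frame_contacts(two_atom_traj(4.5), 1, "chain A", "chain B")), 0L)
  expect_error(frame_contacts(two_atom_traj(3.5), 1, "chain A", "all"),
               "overlap")
})

test_that("frame contacts equal the O(n^2) brute force on random coordinates", {
  set.seed(14)
  nA <- 60; nB <- 60
  atoms <- data.frame(atom_id = 1:(nA + nB), name = "CA", element = "C",
                      resname = "ALA", resid = 1:(nA + nB),
                      chain = rep(c("A", "B"), c(nA, nB)),
                      is_heavy = TRUE, vdw = 1.7)
  xyz <- matrix(runif(3 * (nA + nB), 0, 25), nrow = 1)
  tv <- trajectory_view(atoms, xyz, 0)
  got <- frame_contacts(tv, 1, "chain A", "chain B")
  co <- frame_coords(tv, 1)
  want <- list()
  for (i in seq_len(nA)) for (j in nA + seq_len(nB)) {
    if (sqrt(sum((co[i, ] - co[j, ])^2)) <= 4.0)
      want[[length(want) + 1L]] <- c(i, j)
  }
  want <- do.call(rbind, want)
  got_sorted <- got[order(got$atom_A, got$atom_B), ]
  expect_equal(nrow(got), NROW(want))
  if (NROW(want)) {
    expect_equal(got_sorted$atom_A, want[, 1])
    expect_equal(got_sorted$atom_B, want[, 2])
  }
})

test_that("the persistence criterion is a sharp >= 70% boundary", {
  g <- gen_interface_toy(pair_fractions = c(1, 0.71, 0.70, 0.69, 0.60, 0.2),
                         n_frames = 100, seed = 4)
  cm <- persistent_contact_map(g$traj, "chain A", "chain B")
  want_rows <- g$truth$persistent_resA
  got_rows <- rownames(which(cm$persistent, arr.ind = TRUE))
  expect_setequal(got_rows, want_rows)
  # fractions 1, 0.71, 0.70 pass; 0.69 and below fail
  expect_true(all(c("ALA1", "ALA2", "ALA3") %in% got_rows))
  expect_false(any(c("ALA4", "ALA5", "ALA6") %in% got_rows))
  # the planted pairs are recovered exactly, diagonal only
  hits <- which(cm$persistent, arr.ind = TRUE)
  expect_equal(unname(hits[, 1]), unname(hits[, 2]))
})

test_that("pair within cutoff in 60% of frames is not persistent, 100% is", {
  g <- gen_interface_toy(pair_fractions = c(0.6, 1), n_frames = 20, seed = 2)
  cm <- persistent_contact_map(g$traj, "chain A", "chain B")
  expect_false(cm$persistent["ALA1", "GLY1"])
  expect_true(cm$persistent["ALA2", "GLY2"])
  expect_equal(cm$frequency["ALA2", "GLY2"], 1)
})

test_that("contact maps are symmetric under swapping monomers", {
  g <- gen_interface_toy(pair_fractions = c(1, 0.9, 0.3), seed = 8)
  ab <- persistent_contact_map(g$traj, "chain A", "chain B")
  ba <- persistent_contact_map(g$traj, "chain B", "chain A")
  expect_equal(unname(ab$frequency), unname(t(ba$frequency)))
})

test_that("relaxing criteria never removes a persistent contact", {
  g <- gen_interface_toy(pair_fractions = c(1, 0.75, 0.72, 0.5), seed = 5)
  strict <- persistent_contact_map(g$traj, "chain A", "chain B",
                                   contact_criteria(4.0, 0.70))
  looser_frac <- persistent_contact_map(g$traj, "chain A", "chain B",
                                        contact_criteria(4.0, 0.45))
  looser_dist <- persistent_contact_map(g$traj, "chain A", "chain B",
                                        contact_criteria(6.5, 0.70))
  expect_true(all(looser_frac$persistent[strict$persistent]))
  expect_true(all(looser_dist$persistent[strict$persistent]))
})

test_that("difference maps subtract cellwise with antisymmetry and mapping", {
  g <- gen_interface_toy(pair_fractions = c(1, 0.9), seed = 3)
  m <- persistent_contact_map(g$traj, "chain A", "chain B")
  zero <- contact_difference_map(m, m)
  expect_true(all(zero == 0))

  g2 <- gen_interface_toy(pair_fractions = c(1, 0.9, 1), seed = 3)
  m2 <- persistent_contact_map(g2$traj, "chain A", "chain B")
  d <- contact_difference_map(m2, m)
  expect_equal(sum(d != 0), 1L)
  expect_equal(d["ALA3", "GLY3"], m2$frequency["ALA3", "GLY3"])
  expect_equal(contact_difference_map(m, m2), -d[rownames(d), colnames(d)])

  # label mapping renames map2 into map1's residue system
  mapped <- contact_difference_map(
    m2, m, mapping = list(rows = c(ALA1 = "ALA1", ALA2 = "ALA2"),
                          cols = c(GLY1 = "GLY1", GLY2 = "GLY2")))
  expect_equal(sum(mapped != 0), 1L)
  expect_error(contact_difference_map(m2, m,
                                      mapping = list(rows = c(ALA1 = "X"))),
               "unmappable")
})
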