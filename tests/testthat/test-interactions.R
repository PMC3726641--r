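# interactions: geometric detectors and Table-style summaries

mini_topology <- function(acceptor_class = "ON") {
  atoms <- data.frame(atom_id = 1:3, name = c("N", "H", "O"),
                      element = c("N", "H", if (acceptor_class == "S") "S" else "O"),
                      residue_name = "UNK", residue_index = c(1L, 1L, 2L),
                      chain_id = "A", stringsAsFactors = FALSE)
  structure(list(
    atoms = atoms,
    donors = data.frame(heavy = 1L, hydrogen = 2L),
    acceptors = data.frame(atom = 3L, class = acceptor_class,
                           stringsAsFactors = FALSE),
    rings = list(),
    residues = data.frame(residue_index = 1:2, residue_name = "UNK",
                          chain_id = "A", charge_class = "neutral",
                          molecule_class = "protein",
                          stringsAsFactors = FALSE),
    equivalence_groups = list(), dihedrals = list()), class = "Topology")
}

test_that("hbond_frame applies the distance and angle criteria", {
  topo <- mini_topology()
  # linear N(0) H(1) O(2.9): one bond
  hb <- hbond_frame(topo, rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.9)
  expect_equal(hb$angle, 180)
  # acceptor at 3.6 exceeds the 3.5 cutoff
  hb <- hbond_frame(topo, rbind(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0)))
  expect_equal(nrow(hb), 0L)
  # boundary is strict: exactly 3.5 is out
  hb <- hbond_frame(topo, rbind(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0)))
  expect_equal(nrow(hb), 0L)
  # sulphur acceptor at 3.8 is allowed by the 4.0 rule
  ts <- mini_topology("S")
  hb <- hbond_frame(ts, rbind(c(0, 0, 0), c(1, 0, 0), c(3.8, 0, 0)))
  expect_equal(nrow(hb), 1L)
  # angle rule: 90 degrees at the hydrogen vertex fails
  hb <- hbond_frame(topo, rbind(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0)))
  expect_equal(nrow(hb), 0L)
})

test_that("detector equals the exhaustive oracle on random frames", {
  for (seed in 1:8) {
    fx <- random_contact_fixture(seed)
    hb <- hbond_frame(fx$topology, fx$positions)
    expect_identical(hbond_keys(hb), oracle_hbonds(fx$topology, fx$positions))
    pp <- pipi_frame(fx$topology, fx$positions)
    expect_identical(pipi_keys(pp), oracle_pipi(fx$topology, fx$positions))
  }
})

test_that("criteria are monotone: looser thresholds never drop a bond", {
  fx <- random_contact_fixture(42)
  base <- hbond_keys(hbond_frame(fx$topology, fx$positions))
  looser <- hbond_keys(hbond_frame(fx$topology, fx$positions,
                                   hbond_criteria(da_cutoff = 4.2,
                                                  da_cutoff_sulphur = 4.7,
                                                  dha_min_angle = 100)))
  expect_true(all(base %in% looser))
})

test_that("pipi_frame detects parallel stacking and folds the normal angle", {
  hexa <- function(center, tilt = 0) {
    th <- (0:5) * pi / 3
    ring <- cbind(1.39 * cos(th), 1.39 * sin(th), 0)
    if (tilt != 0) {
      R <- cleftscope:::rot_axis_angle(c(1, 0, 0), tilt * pi / 180)
      ring <- ring %*% t(R)
    }
    sweep(ring, 2, center, "+")
  }
  atoms <- data.frame(atom_id = 1:12, name = paste0("C", 1:12),
                      element = "C", residue_name = "UNK",
                      residue_index = rep(1:2, each = 6), chain_id = "A",
                      stringsAsFactors = FALSE)
  topo <- structure(list(
    atoms = atoms, donors = data.frame(heavy = integer(0), hydrogen = integer(0)),
    acceptors = data.frame(atom = integer(0), class = character(0)),
    rings = list(r1 = 1:6, r2 = 7:12),
    residues = data.frame(residue_index = 1:2, residue_name = "UNK",
                          chain_id = "A", charge_class = "neutral",
                          molecule_class = "protein", stringsAsFactors = FALSE),
    equivalence_groups = list(), dihedrals = list()), class = "Topology")

  # parallel offset 3.5 along the normal: one contact at angle 0
  pos <- rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 3.5)))
  pp <- pipi_frame(topo, pos)
  expect_equal(nrow(pp), 1L)
  expect_lt(pp$angle, 1e-6)
  # perpendicular rings: angle 90 fails
  pos <- rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 3.5), tilt = 90))
  expect_equal(nrow(pipi_frame(topo, pos)), 0L)
  # parallel at 5.2: distance fails
  pos <- rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 5.2)))
  expect_equal(nrow(pipi_frame(topo, pos)), 0L)
  # flipping one ring's vertex order (normal sign) changes nothing
  pos <- rbind(hexa(c(0, 0, 0)), hexa(c(0, 0, 3.5))[6:1, ])
  expect_equal(nrow(pipi_frame(topo, pos)), 1L)
})

test_that("summaries decompose by partner class and track lifetimes", {
  cx <- make_toy_complex()
  ints <- list(
    planted_interaction("hbond", donor = toy_atom(cx, 201, "O5A"),
                        hydrogen = toy_atom(cx, 201, "HO5A"),
                        acceptor = toy_atom(cx, 401, "O"),
                        target_occupancy = 0.6, episode_length = 30),
    planted_interaction("hbond", donor = toy_atom(cx, 201, "O3B"),
                        hydrogen = toy_atom(cx, 201, "HO3B"),
                        acceptor = toy_atom(cx, 161, "OE1"),
                        target_occupancy = 0.3, episode_length = 10),
    planted_interaction("hbond", donor = toy_atom(cx, 201, "O3G"),
                        hydrogen = toy_atom(cx, 201, "HO3G"),
                        acceptor = toy_atom(cx, 402, "O"),
                        target_occupancy = 0.08, episode_length = 80))
  tr <- plant_trajectory(fixture_spec(31, 1000, 10, 0), ints, complex = cx)
  sm <- summarize_interactions(tr)
  expect_equal(unname(sm$class_means["solvent"]), 0.68)
  expect_equal(unname(sm$class_means["protein"]), 0.30)
  expect_equal(sum(sm$class_means), sm$total_mean)
  # single 80-frame episode in 1000 frames: lifetime fraction 0.08
  lf <- sm$pairs$lifetime_fraction[sm$pairs$occupancy == 0.08]
  expect_equal(lf, 0.08)
  # empty window errors
  expect_error(summarize_interactions(tr, window = c(1e6, 2e6)), "no frames")
})

test_that("salt bridges are charged side-chain bonds; percentage truncates", {
  cx <- make_toy_complex()
  ints <- list(
    planted_interaction("saltbridge", donor = toy_atom(cx, 158, "NZ"),
                        hydrogen = toy_atom(cx, 158, "HZ1"),
                        acceptor = toy_atom(cx, 161, "OE2"),
                        target_occupancy = 0.75, episode_length = 25),
    planted_interaction("hbond", donor = toy_atom(cx, 159, "N"),
                        hydrogen = toy_atom(cx, 159, "H"),
                        acceptor = toy_atom(cx, 161, "OE1"),
                        target_occupancy = 0.25, episode_length = 25))
  tr <- plant_trajectory(fixture_spec(41, 400, 10, 0), ints, complex = cx)
  sm <- summarize_interactions(tr, focus = "ligand")
  sb <- salt_bridge_filter(sm$records, tr$topology)
  # only the NZ->OE2 bond qualifies (backbone N-H donor is excluded)
  expect_equal(nrow(sb) / sm$n_frames, 0.75)
  expect_equal(unique(sb$donor_residue), "LYS158")

  # printed-table convention: truncation toward zero
  expect_equal(salt_bridge_percentage(11.2, 8.8)$percentage, 78L)
  expect_equal(salt_bridge_percentage(15.9, 11.5)$percentage, 72L)
  expect_equal(salt_bridge_percentage(10.6, 8.5)$percentage, 80L)
  # no hydrogen bonds: undefined and flagged, not zero
  p0 <- salt_bridge_percentage(0, 0)
  expect_false(p0$defined)
  expect_true(is.na(p0$percentage))
  # no charged partners: zero salt bridges
  fx <- random_contact_fixture(7)
  hb <- hbond_frame(fx$topology, fx$positions)
  expect_equal(nrow(salt_bridge_filter(hb, fx$topology)), 0L)
})
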