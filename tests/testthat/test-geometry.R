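# geometry: superposition, RMSD/RMSF, ion mobility, dihedral populations

test_that("superpose recovers rigid motions and handles reflections", {
  set.seed(2)
  X <- matrix(rnorm(30, sd = 3), 10, 3)
  expect_lt(superpose(X, X)$rmsd, 1e-12)
  expect_equal(superpose(X, X)$rotation, diag(3))

  R <- cleftscope:::rot_axis_angle(c(2, -1, 0.5), 1.2)
  Y <- X %*% t(R) + matrix(c(4, -7, 2), 10, 3, byrow = TRUE)
  sp <- superpose(X, Y)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1)
  expect_lt(max(abs(apply_superposition(sp, Y) - X)), 1e-9)

  # near-reflection input still yields a proper rotation
  Ym <- Y; Ym[, 3] <- -Ym[, 3]
  spm <- superpose(X, Ym)
  expect_equal(det(spm$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(X[1:2, ], X[1:2, ]), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superposition matches a rotation-grid + refinement oracle", {
  rmsd_rot <- function(ang, Xc, Yc) {
    R <- cleftscope:::rot_axis_angle(c(1, 0, 0), ang[1]) %*%
      cleftscope:::rot_axis_angle(c(0, 1, 0), ang[2]) %*%
      cleftscope:::rot_axis_angle(c(0, 0, 1), ang[3])
    sqrt(mean(rowSums((Yc %*% t(R) - Xc)^2)))
  }
  set.seed(8)
  for (rep in 1:3) {
    X <- matrix(rnorm(24, sd = 2), 8, 3)
    Y <- X + matrix(rnorm(24, sd = 0.4), 8, 3)
    Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
    grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, by = pi / 6),
                                  b = seq(0, pi, by = pi / 6),
                                  c = seq(0, 2 * pi, by = pi / 6)))
    vals <- apply(grid, 1, rmsd_rot, Xc = Xc, Yc = Yc)
    best <- stats::optim(grid[which.min(vals), ], rmsd_rot, Xc = Xc, Yc = Yc,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
    expect_lt(abs(superpose(X, Y)$rmsd - best$value), 1e-3)
  }
})

test_that("rmsd_series tracks displacement against direct recomputation", {
  cx <- make_toy_complex(n_water = 0)
  tr <- plant_trajectory(fixture_spec(3, 30, 1, 0.3), complex = cx)
  sel <- which(tr$atoms$chain_id == "A")
  rs <- rmsd_series(tr, selection = sel)
  expect_equal(nrow(rs), 30L)
  # rigid trajectory gives zeros
  tr0 <- plant_trajectory(fixture_spec(3, 5, 1, 0), complex = cx)
  expect_lt(max(rmsd_series(tr0, selection = sel)$rmsd), 1e-12)
  # direct recomputation of one frame
  direct <- superpose(tr$frames[[1]]$positions,
                      tr$frames[[17]]$positions, sel)$rmsd
  expect_equal(rs$rmsd[17], direct)
  # planted-scale recovery: jitter sigma 0.3 over the protein selection
  expect_equal(attr(rs, "mean"), sqrt(3) * 0.3 * sqrt(1 - 2 / length(sel)) *
                 sqrt(2),                      # both frames jittered
               tolerance = 0.1)
})

test_that("rmsf recovers isotropic jitter and orders mobile tails", {
  set.seed(14)
  na <- 60; nf <- 1500; sig <- 0.5
  base <- matrix(runif(na * 3, 0, 25), na, 3)
  atoms <- data.frame(atom_id = seq_len(na), name = "CA", element = "C",
                      residue_name = "GLY", residue_index = seq_len(na),
                      chain_id = "A", stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nf), function(i)
    new_frame(i - 1, base + matrix(rnorm(na * 3, 0, sig), na, 3)))
  tr <- new_trajectory(atoms, frames)
  rf <- rmsf(tr)
  expect_equal(mean(rf$per_atom$rmsf), sqrt(3) * sig * sqrt(1 - 2 / na),
               tolerance = 0.02)
  # rigid trajectory: zero
  tr0 <- new_trajectory(atoms, lapply(1:3, function(i) new_frame(i - 1, base)))
  expect_lt(max(rmsf(tr0)$per_atom$rmsf), 1e-12)
  # planted mobile tail exceeds the rigid core
  frames2 <- lapply(seq_len(300), function(i) {
    p <- base
    p[41:60, ] <- p[41:60, ] + matrix(rnorm(60, 0, 1.2), 20, 3)
    p[1:40, ] <- p[1:40, ] + matrix(rnorm(120, 0, 0.1), 40, 3)
    new_frame(i - 1, p)
  })
  rf2 <- rmsf(new_trajectory(atoms, frames2))
  expect_gt(mean(rf2$per_atom$rmsf[41:60]), mean(rf2$per_atom$rmsf[1:40]))
})

test_that("terminal_strand_rmsf summarises the chain ends", {
  set.seed(3)
  na <- 24
  base <- cbind(seq_len(na) * 3, 0, 0)
  atoms <- data.frame(atom_id = seq_len(na), name = "CA", element = "C",
                      residue_name = "GLY", residue_index = seq_len(na),
                      chain_id = "B", stringsAsFactors = FALSE)
  frames <- lapply(seq_len(400), function(i) {
    p <- base + matrix(rnorm(na * 3, 0, 0.1), na, 3)
    p[17:24, ] <- p[17:24, ] + matrix(rnorm(24, 0, 1), 8, 3)
    new_frame(i - 1, p)
  })
  tr <- new_trajectory(atoms, frames)
  ts <- terminal_strand_rmsf(tr, chain = "B", n_terminal = 8)
  expect_equal(ts$strand, c("N", "C"))
  expect_gt(ts$rmsf[ts$strand == "C"], ts$rmsf[ts$strand == "N"])
})

test_that("ion displacements distinguish a drifting site", {
  cx <- make_toy_complex(n_water = 0)
  tr <- plant_trajectory(fixture_spec(9, 500, 10, 0),
                         ions = list(ion_site_model("I", sigma = 0.2),
                                     ion_site_model("II", sigma = 0.2,
                                                    drift = c(1.2, 0, 0))),
                         complex = cx)
  align <- which(tr$atoms$chain_id == "A" &
                   tr$atoms$name %in% c("N", "CA", "C", "O"))
  res <- ion_displacement_distribution(tr, cx$ion_sites, align)
  expect_gt(mean(res$series$II), mean(res$series$I))
  expect_equal(sum(res$histogram), 1)
  # static ions: point mass in the first bin
  tr0 <- plant_trajectory(fixture_spec(9, 50, 10, 0), complex = cx)
  r0 <- ion_displacement_distribution(tr0, cx$ion_sites, align)
  expect_equal(unname(r0$histogram[1, 1]), 1)
  expect_error(ion_displacement_distribution(tr, c(I = 9999L), align),
               "index")
})

test_that("dihedral angles follow the signed convention and its symmetries", {
  expect_equal(cleftscope:::torsion_angle(c(1, 0, 0), c(0, 0, 0),
                                          c(0, 1.5, 0), c(1, 1.5, 0)), 0)
  expect_equal(abs(cleftscope:::torsion_angle(c(1, 0, 0), c(0, 0, 0),
                                              c(0, 1.5, 0), c(-1, 1.5, 0))),
               180)
  # constructed 90-degree geometry, exact to 1e-6
  p90 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1.5, 0), c(0, 1.5, -1))
  expect_equal(cleftscope:::torsion_angle(p90[1, ], p90[2, ], p90[3, ],
                                          p90[4, ]), 90, tolerance = 1e-6)
  set.seed(6)
  for (i in 1:10) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    a <- cleftscope:::torsion_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    # reversal invariance (the standard torsion convention)
    expect_equal(cleftscope:::torsion_angle(p[4, ], p[3, ], p[2, ], p[1, ]),
                 a, tolerance = 1e-9)
    # mirror antisymmetry
    pm <- p; pm[, 3] <- -pm[, 3]
    expect_equal(cleftscope:::torsion_angle(pm[1, ], pm[2, ], pm[3, ],
                                            pm[4, ]), -a, tolerance = 1e-9)
  }
})

test_that("dihedral_series reports planted mode populations", {
  set.seed(77)
  n <- 2000
  is_major <- runif(n) < 0.85
  angles <- ifelse(is_major, rnorm(n, 90, 6), rnorm(n, 150, 6))
  tr <- dihedral_trajectory(angles)
  ds <- dihedral_series(tr, 1:4)
  expect_equal(sum(ds$histogram$prob), 1)
  expect_equal(nrow(ds$modes), 2L)
  expect_equal(ds$modes$angle[1], 90, tolerance = 5)
  expect_equal(ds$modes$angle[2], 150, tolerance = 5)
  p_hat <- mean(is_major)
  expect_equal(ds$modes$fraction[1], p_hat, tolerance = 0.02)
  expect_equal(ds$modes$fraction[2], 1 - p_hat, tolerance = 0.02)
  # collinear frames are flagged, not fatal
  tr2 <- dihedral_trajectory(c(90, 90))
  tr2$frames[[1]]$positions[4, ] <- c(0, 3, 0)   # D on the BC line
  ds2 <- dihedral_series(tr2, 1:4)
  expect_equal(ds2$n_flagged, 1L)
  # two-fold folding maps 0 and 180 together
  trf <- dihedral_trajectory(c(rep(2, 10), rep(178, 10), rep(-178, 10)))
  dsf <- dihedral_series(trf, 1:4, fold = TRUE)
  expect_equal(sum(dsf$histogram$prob), 1)
})

test_that("ligand dihedrals of the toy complex evaluate over trajectories", {
  cx <- make_toy_complex(n_water = 0)
  tr <- plant_trajectory(fixture_spec(15, 10, 1, 0.02), complex = cx)
  for (nm in c("chi1", "chi2", "chi3")) {
    ds <- dihedral_series(tr, nm)
    expect_equal(nrow(ds$angles), 10L)
    expect_false(anyNA(ds$angles$angle))
  }
  expect_error(dihedral_series(tr, "chi9"), "chi9")
})
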