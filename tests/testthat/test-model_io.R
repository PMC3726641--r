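# model_io: PDB / XYZ / HILLS readers and writers, topology annotation

test_that("read_pdb parses single- and multi-model files and flags errors", {
  tmp <- withr::local_tempdir()
  p1 <- file.path(tmp, "one.pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.100   1.300   0.000  1.00  0.00           C",
    "END"), p1)
  st <- read_pdb(p1)
  expect_s3_class(st, "Structure")
  expect_equal(nrow(st$atoms), 3L)
  expect_equal(st$atoms$name, c("N", "CA", "C"))
  expect_equal(unname(st$positions[2, 1]), 1.45)

  p2 <- file.path(tmp, "two.pdb")
  writeLines(c("MODEL        1",
               "ATOM      1  CA  GLY A   1       0.000   0.000   0.000",
               "ENDMDL", "MODEL        2",
               "ATOM      1  CA  GLY A   1       1.000   0.000   0.000",
               "ENDMDL", "END"), p2)
  tr <- read_pdb(p2, timestep = 5)
  expect_s3_class(tr, "Trajectory")
  expect_equal(n_frames(tr), 2L)
  expect_equal(frame_times(tr), c(0, 5))

  p3 <- file.path(tmp, "ragged.pdb")
  writeLines(c("MODEL        1",
               "ATOM      1  CA  GLY A   1       0.000   0.000   0.000",
               "ATOM      2  CB  GLY A   1       1.000   0.000   0.000",
               "ENDMDL", "MODEL        2",
               "ATOM      1  CA  GLY A   1       1.000   0.000   0.000",
               "ENDMDL"), p3)
  expect_error(read_pdb(p3), "MODEL block 2")

  p4 <- file.path(tmp, "bad.pdb")
  writeLines(c("ATOM      1  CA  GLY A   1       0.000   xxx     0.000"), p4)
  expect_error(read_pdb(p4), "line 1")
  p5 <- file.path(tmp, "empty.pdb")
  writeLines("END", p5)
  expect_error(read_pdb(p5), "no ATOM")
})

test_that("PDB round-trip preserves fields to the printed precision", {
  tmp <- withr::local_tempdir()
  cx <- make_toy_complex(n_water = 2)
  f <- file.path(tmp, "rt.pdb")
  write_pdb(cx$structure, f)
  back <- read_pdb(f)
  expect_identical(back$atoms$name, cx$structure$atoms$name)
  expect_identical(back$atoms$residue_name, cx$structure$atoms$residue_name)
  expect_identical(back$atoms$residue_index, cx$structure$atoms$residue_index)
  expect_lt(max(abs(back$positions - cx$structure$positions)), 5e-4 + 1e-12)

  # format rule: 8.3 columns round to 3 decimals
  st <- new_structure(cx$structure$atoms[1, ], matrix(c(12.3456, 0, 0), 1))
  write_pdb(st, f)
  line <- grep("^ATOM", readLines(f), value = TRUE)[1]
  expect_equal(substr(line, 31, 38), "  12.346")

  tr <- plant_trajectory(fixture_spec(2, 2, 1, 0.05), complex = cx)
  write_pdb(tr, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 2L)
})

test_that("XYZ trajectories round-trip with time stamps", {
  tmp <- withr::local_tempdir()
  cx <- make_toy_complex(n_water = 0)
  tr <- plant_trajectory(fixture_spec(3, 5, 2.5, 0.1), complex = cx)
  f <- file.path(tmp, "t.xyz")
  write_xyz_trajectory(tr, f)
  back <- read_xyz_trajectory(f, atoms = tr$atoms)
  expect_equal(n_frames(back), 5L)
  expect_equal(frame_times(back), frame_times(tr))
  expect_lt(max(abs(back$frames[[5]]$positions - tr$frames[[5]]$positions)),
            1e-5)

  lines <- readLines(f)
  writeLines(lines[1:(length(lines) - 3)], f)   # truncate the last frame
  expect_error(read_xyz_trajectory(f), "truncated")
})

test_that("HILLS files parse per header and survive a round-trip", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "HILLS")
  writeLines(c("#! FIELDS time cv1 sigma_cv1 height biasf",
               "1.0 0.5 0.2 0.1 10",
               "2.0 0.6 0.2 0.09 10",
               "3.0 0.7 0.2 0.085 10"), f)
  h <- read_hills(f)
  expect_equal(nrow(h), 3L)
  expect_equal(hills_dim(h), 1L)
  expect_equal(h$height, c(0.1, 0.09, 0.085))

  f3 <- file.path(tmp, "HILLS3")
  writeLines(c("#! FIELDS time cv1 cv2 cv3 sigma_cv1 sigma_cv2 sigma_cv3 height biasf",
               "1.0 0.5 1.5 2.5 0.2 0.2 0.2 0.1 10"), f3)
  h3 <- read_hills(f3)
  expect_equal(hills_dim(h3), 3L)
  expect_equal(as.numeric(hills_centers(h3)), c(0.5, 1.5, 2.5))

  writeLines(c("#! FIELDS time cv1 sigma_cv1 height biasf",
               "1.0 0.5 0.2 oops 10"), f)
  expect_error(read_hills(f), "non-numeric")
  writeLines(c("#! FIELDS time cv1 sigma_cv1 height biasf",
               "1.0 0.5 0.2 0.1"), f)
  expect_error(read_hills(f), "columns")

  # round-trip preserves 6 significant digits
  set.seed(4)
  h0 <- new_hills(cumsum(runif(20)), matrix(runif(20), 20),
                  matrix(0.2, 20, 1), runif(20, 0.01, 0.1), 10)
  write_hills(h0, f)
  hb <- read_hills(f)
  expect_equal(as.data.frame(hb), as.data.frame(h0), tolerance = 1e-7)
})

test_that("annotate_topology applies template rules deterministically", {
  cx <- make_toy_complex()
  topo <- cx$topology
  at <- topo$atoms

  # GLU side-chain oxygens are acceptors, residue negative
  oe <- which(at$residue_index == 161 & at$name %in% c("OE1", "OE2"))
  expect_true(all(oe %in% topo$acceptors$atom))
  expect_equal(topo$residues$charge_class[topo$residues$residue_index == 161],
               "negative")
  # MET SD carries the sulphur class
  sd <- which(at$residue_index == 120 & at$name == "SD")
  expect_equal(topo$acceptors$class[topo$acceptors$atom == sd], "S")
  # PHE registers one 6-membered ring
  phe_rings <- grep("^PHE156", names(topo$rings))
  expect_length(phe_rings, 1L)
  expect_length(topo$rings[[phe_rings]], 6L)
  # LYS positive, HOH water
  expect_equal(topo$residues$charge_class[topo$residues$residue_index == 158],
               "positive")
  expect_equal(topo$residues$charge_class[topo$residues$residue_name == "HOH"][1],
               "water")

  # determinism
  t2 <- annotate_topology(cx$structure)
  expect_identical(topo$donors, t2$donors)
  expect_identical(topo$rings, t2$rings)

  # unknown residue is a named hard error
  bad <- cx$structure
  bad$atoms$residue_name[1] <- "XXX"
  expect_error(annotate_topology(bad), "XXX")
})
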