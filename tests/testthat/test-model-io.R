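test_that("PDB round trip preserves coordinates and identity", {
  m <- mixed_helix()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(m2$xyz - round(m$xyz, 3))), 1e-9)
  expect_identical(m2$atoms$chain, m$atoms$chain)
  expect_identical(m2$atoms$res_seq, m$atoms$res_seq)
  expect_identical(m2$atoms$atom, m$atoms$atom)
})

test_that("mmCIF round trip and chain typing work", {
  m <- mixed_helix()
  r <- rna5()
  r$atoms$chain <- "B"
  mixed <- atomic_model(rbind(m$atoms, r$atoms), rbind(m$xyz, r$xyz))
  f <- withr::local_tempfile(fileext = ".cif")
  gmmrefine:::write_mmcif(mixed, f)
  m2 <- read_model(f)
  expect_equal(unname(m2$chain_types["A"]), "protein")
  expect_equal(unname(m2$chain_types["B"]), "rna")
  expect_lt(max(abs(m2$xyz - round(mixed$xyz, 3))), 1e-9)
})

test_that("hydrogens, waters and low-occupancy altlocs are stripped on read", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  H   ALA A   1      -0.500   0.800   0.000  1.00  0.00           H",
    "ATOM      4  CB AALA A   1       2.000   1.400   0.100  0.60  0.00           C",
    "ATOM      5  CB BALA A   1       2.000   1.400   0.900  0.40  0.00           C",
    "ATOM      6  O   HOH A   2       5.000   5.000   5.000  1.00  0.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_model(f)
  expect_equal(nrow(m$atoms), 3)             # N, CA, CB(A); no H, no water
  cb <- m$xyz[m$atoms$atom == "CB", ]
  expect_equal(unname(cb[3]), 0.1)           # the 0.6-occupancy conformer
})

test_that("series output writes MODEL records in order", {
  m <- helix10()
  models <- lapply(1:5, function(k) set_coords(m, m$xyz + k))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_series(models, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 5)
  expect_equal(sum(grepl("^ENDMDL", txt)), 5)
  bad <- models
  bad[[2]] <- set_coords(atomic_model(m$atoms[-1, ], m$xyz[-1, ]),
                         m$xyz[-1, ])
  expect_error(write_series(bad, f), "atom counts")
})

test_that("MRC maps round trip bit-exactly and honor the header", {
  map <- fx("iomap", function()
    simulate_map(helix10(), resolution = 6, voxel = 1.2, box = 24))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(map, f)
  m2 <- read_map(f)
  expect_equal(m2$voxel, 1.2, tolerance = 1e-6)
  # float32 storage: compare after the same truncation
  expect_equal(m2$data, array(readBin(writeBin(
    as.numeric(map$data), raw(), size = 4), "numeric",
    length(map$data), size = 4), dim(map$data)))
  expect_equal(m2$origin, map$origin, tolerance = 1e-5)
})

test_that("permuted-axis MRC files normalize to the canonical grid", {
  map <- fx("iomap", function()
    simulate_map(helix10(), resolution = 6, voxel = 1.2, box = 24))
  f <- withr::local_tempfile(fileext = ".mrc")
  write_map(map, f)
  # rewrite with axes stored as (z, x, y): mapc=3, mapr=1, maps=2
  raw <- readBin(f, "raw", file.size(f))
  perm <- aperm(map$data, c(3, 1, 2))
  con <- file(f, "r+b")
  seek(con, 64, rw = "write")
  writeBin(c(3L, 1L, 2L), con, size = 4, endian = "little")
  seek(con, 1024, rw = "write")
  writeBin(as.numeric(perm), con, size = 4, endian = "little")
  close(con)
  m2 <- read_map(f)
  expect_equal(m2$data, array(readBin(writeBin(
    as.numeric(map$data), raw(), size = 4), "numeric",
    length(map$data), size = 4), dim(map$data)))
})

test_that("model_to_gmm maps atoms to Gaussians with atomic-number amplitudes", {
  m <- make_toy_structure("AC", "protein", "helix")  # ALA + CYS (has S)
  gmm <- model_to_gmm(m, resolution = 8)
  expect_equal(nrow(gmm$centers), nrow(m$atoms))
  expect_equal(gmm$centers, m$xyz)
  aS <- gmm$amplitudes[m$atoms$element == "S"][1]
  aC <- gmm$amplitudes[m$atoms$element == "C"][1]
  expect_equal(aS / aC, 16 / 6)
  expect_equal(model_to_gmm(m, 8)$width, sigma_from_resolution(8))
})

test_that("hydrogen placement is deterministic and rigid-motion covariant", {
  m <- helix10()
  topo <- compile_topology(m)
  h1 <- place_hydrogens(m$xyz, topo)
  # N-H bond length close to the template value
  hp <- topo$hydrogens
  iN <- which(hp$h == "H")[1]
  dNH <- sqrt(sum((h1[iN, ] - m$xyz[hp$ib[iN], ])^2))
  expect_lt(abs(dNH - hp$dist[iN]), 0.05)
  # rigid motion of the model transforms H identically
  x2 <- rigid_move(m$xyz)
  h2 <- place_hydrogens(x2, topo)
  expect_lt(max(abs(rigid_move(h1) - h2)), 1e-6)
  # GLY: 2 HA + backbone amide H, plus the charged N-terminal extras
  g <- make_toy_structure("G", "protein", "helix")
  hg <- add_hydrogens(g)
  expect_equal(nrow(hg$xyz), 5)
})

test_that("methyl hydrogens ride rigidly on chi rotations", {
  m <- make_toy_structure("AL", "protein", "helix")
  topo <- compile_topology(m)
  info <- gmmrefine:::chi_info(topo)
  h0 <- place_hydrogens(m$xyz, topo)
  x2 <- gmmrefine:::apply_chi(m$xyz, info, c(120, 0))
  h2 <- place_hydrogens(x2, topo)
  # hydrogens of the rotated sidechain stay at fixed internal coordinates:
  # distances from each H to its parent are unchanged
  d0 <- sqrt(rowSums((h0 - m$xyz[topo$hydrogens$ib, ])^2))
  d2 <- sqrt(rowSums((h2 - x2[topo$hydrogens$ib, ])^2))
  expect_lt(max(abs(d0 - d2)), 1e-9)
})
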