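test_that("toy structures are reproducible and reject unknown letters", {
  a <- make_toy_structure("ASLD", "protein", "helix")
  b <- make_toy_structure("ASLD", "protein", "helix")
  expect_identical(a$xyz, b$xyz)
  expect_error(make_toy_structure("AXB", "protein"), "unknown residue")
  expect_error(make_toy_structure("ACGT", "rna"), "unknown nucleotide")
  expect_error(make_toy_structure("", "protein"), "empty")
})

test_that("ideal fixtures report zero outliers in every class", {
  for (m in list(helix40(), mixed_helix(),
                 make_toy_structure("ASLDAETVAL", "protein", "extended"))) {
    rep <- geometry_report(m)
    expect_equal(rep$bond_outliers, 0)
    expect_equal(rep$angle_outliers, 0)
    expect_equal(rep$planarity_violations, 0)
    expect_equal(rep$rama_outlier_fraction, 0)
    expect_equal(rep$rotamer_outlier_fraction, 0)
    expect_equal(rep$clash_count, 0)
  }
  rrep <- geometry_report(rna5())
  expect_equal(rrep$bond_outliers, 0)
  expect_equal(rrep$clash_count, 0)
  expect_equal(rrep$rna_suite_outliers, 0)
  expect_gt(rrep$rna_suite_score, 0.99)
})

test_that("simulated maps are centered and self-consistent", {
  onem <- atomic_model(
    data.frame(atom = "CA", element = "C", res_name = "ALA", res_seq = 1,
               ins = "", chain = "A", occ = 1),
    rbind(c(1.1, -0.6, 0.4)))
  map <- simulate_map(onem, resolution = 8, voxel = 2, box = 24,
                      center = c(0, 0, 0))
  peak <- which(map$data == max(map$data), arr.ind = TRUE)[1, ]
  pos <- map$origin + (peak - 1) * map$voxel
  expect_lt(max(abs(pos - c(1.1, -0.6, 0.4))), map$voxel / 2 + 1e-9)
  # identical settings give identical maps, hence FRC 1 everywhere
  m2 <- simulate_map(onem, resolution = 8, voxel = 2, box = 24,
                     center = c(0, 0, 0))
  expect_identical(map$data, m2$data)
  expect_error(simulate_map(helix10(), box = 8, voxel = 1), "fit")
})

test_that("perturbations are seeded and sized as specified", {
  m <- helix40()
  p1 <- perturb(m, hinge = list(residues = 21:40, angle = 15,
                                axis = c(0, 0, 1)))
  expect_gt(attr(p1, "rmsd"), 2)
  # intra-fragment geometry unchanged: pairwise distances inside the moved
  # fragment are preserved
  sel <- m$atoms$res_seq >= 25
  expect_lt(max(abs(dist(p1$xyz[sel, ]) - dist(m$xyz[sel, ]))), 1e-9)
  expect_error(perturb(m, hinge = list(residues = 99, angle = 5)), "empty")

  j1 <- perturb(m, jitter_sd = 0.1, seed = 3)
  j2 <- perturb(m, jitter_sd = 0.1, seed = 3)
  expect_identical(j1$xyz, j2$xyz)
  # mean 3D displacement follows the chi_3 mean, sigma * 2 sqrt(2/pi)
  big <- perturb(helix40(), jitter_sd = 0.1, seed = 11)
  disp <- sqrt(rowSums((big$xyz - helix40()$xyz)^2))
  expect_equal(mean(disp), 0.1 * 2 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("motion series interpolate the hinge with valid ground truths", {
  m <- helix40()
  ms <- fx("series40", function()
    make_motion_series(helix40(),
                       hinge = list(residues = 21:40, angle = 20,
                                    axis = c(0, -0.5, sqrt(3) / 2)),
                       n_states = 5, resolution = 8, voxel = 2, box = 48))
  expect_length(ms$series$maps, 5)
  expect_equal(as.numeric(ms$series$latents), seq(0, 1, length.out = 5))
  # hinge angles are uniform: RMSD to state 1 grows ~linearly
  r <- vapply(ms$truth, function(t) coord_rmsd(ms$truth[[1]]$xyz, t$xyz), 0)
  expect_true(all(diff(r) > 0))
  expect_equal(r[3] / r[5], 0.5, tolerance = 0.05)
  # end-state maps differ while all share one frame
  f <- frc(ms$series$maps[[1]]$data[, , 24] * 0 +
           gmmrefine:::cpp_project_map(as.numeric(ms$series$maps[[1]]$data),
                                       dim(ms$series$maps[[1]]$data), 2,
                                       diag(3), 48, 2),
           gmmrefine:::cpp_project_map(as.numeric(ms$series$maps[[5]]$data),
                                       dim(ms$series$maps[[5]]$data), 2,
                                       diag(3), 48, 2),
           pixel = 2, cutoff_res = 8)
  expect_lt(f$mean_to_cutoff, 0.95)
  # ground truths are outlier-free
  for (t in ms$truth[c(1, 3, 5)]) {
    rep <- geometry_report(t)
    expect_equal(rep$bond_outliers, 0)
    expect_equal(rep$rama_outlier_fraction, 0)
    expect_equal(rep$clash_count, 0)
  }
})
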