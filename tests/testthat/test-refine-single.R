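test_that("decoder backpropagation matches finite differences", {
  net <- decoder_new(4, 6, width = 8, seed = 2)
  # make the final layer nonzero so the output is nontrivial
  net$W[[5]][] <- rnorm(length(net$W[[5]]), 0, 0.1)
  x <- c(1, 1, 1, 1)
  tgt <- rnorm(6)
  loss <- function(p) {
    n2 <- gmmrefine:::decoder_set_params(net, p)
    sum((decoder_forward(n2, x) - tgt)^2)
  }
  p <- gmmrefine:::decoder_params(net)
  out <- decoder_forward(net, x, keep_cache = TRUE)
  g <- decoder_backward(net, out, 2 * (out - tgt))
  gp <- gmmrefine:::decoder_grads_as_params(g)
  for (nm in c("W1", "W3", "b2", "W5", "b5")) {
    gnum <- gp[[nm]] * 0
    for (i in seq_len(min(6, length(gnum)))) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + 1e-6
      p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - 1e-6
      gnum[i] <- (loss(p2) - loss(p3)) / 2e-6
      expect_lt(abs(gnum[i] - gp[[nm]][i]) / max(abs(gnum[i]), 1e-6), 1e-3)
    }
  }
})

test_that("zero-initialized decoders start as the identity deformation", {
  m <- helix10()
  h <- deform_head("group", groups = list(1:20, 21:nrow(m$atoms)),
                   x0 = m$xyz, seed = 1)
  out <- decoder_forward(h$net, c(1, 1, 1, 1))
  expect_true(all(out == 0))
  D <- gmmrefine:::head_displacement(h, as.numeric(out), m$xyz)
  expect_true(all(D == 0))
})

test_that("group-transform backward matches finite differences", {
  m <- helix10()
  x0 <- m$xyz
  h <- deform_head("group", groups = list(1:20, 21:nrow(x0)), x0 = x0)
  set.seed(4)
  par <- rnorm(12, 0, 0.2)
  dD <- matrix(rnorm(length(x0)), ncol = 3)
  g <- gmmrefine:::head_backward(h, par, x0, dD)
  f <- function(p) sum(gmmrefine:::head_displacement(h, p, x0) * dD)
  for (i in seq_along(par)) {
    p2 <- par; p2[i] <- p2[i] + 1e-6
    p3 <- par; p3[i] <- p3[i] - 1e-6
    num <- (f(p2) - f(p3)) / 2e-6
    expect_lt(abs(num - g[i]) / max(abs(num), 1e-6), 1e-3)
  }
})

test_that("K-means patches keep residues together and saturate correctly", {
  m <- helix40()
  pp <- partition_patches(m, 64, seed = 1)
  expect_equal(length(pp$atom_groups), 40)   # lowered to the residue count
  # all atoms of a residue share a patch
  rid <- m$atoms$res_seq
  for (g in pp$atom_groups) expect_true(all(table(rid[g]) %in%
    table(rid)[unique(rid[g])]))
  # two far-apart domains split cleanly at k = 2
  two <- atomic_model(m$atoms, rbind(m$xyz[1:100, ],
                                     m$xyz[101:nrow(m$xyz), ] + 100))
  p2 <- partition_patches(two, 2, seed = 1)
  lab <- rep(seq_along(p2$atom_groups), lengths(p2$atom_groups))
  ord <- order(unlist(p2$atom_groups))
  lab <- lab[ord]
  expect_equal(length(unique(lab[1:100])), 1)
  expect_equal(length(unique(lab[101:length(lab)])), 1)
  expect_true(lab[1] != lab[length(lab)])
})

test_that("the weight-balancing rule follows the probe arithmetic", {
  expect_equal(balance_rule(0.02, 0.04), 0.5)
  expect_equal(balance_rule(0.04, 0.02), 2)
  expect_warning(w <- balance_rule(0.02, 0), "default weight")
  expect_equal(w, 1)
  expect_equal(balance_rule(1, 1e6), 1e-6)   # raw rule, unclamped
})

test_that("geometry-only refinement heals a jittered model", {
  m <- fx("geomfix", function()
    make_toy_structure(strrep("A", 8), "protein", "helix"))
  bad <- perturb(m, jitter_sd = 0.06, seed = 2)
  topo <- compile_topology(bad)
  expect_gt(bond_angle_score(bad$xyz, topo, grad = FALSE)$bond_outliers, 0)
  cfg <- refinement_config(target_resolution = 8, n_patches = 4, seed = 3,
                           iters = c(coarse = 50, residue = 50,
                                     rotamer = 50, full = 500))
  res <- refine(bad, config = cfg, geometry_only = TRUE)
  expect_equal(res$report$bond_outliers, 0)
  expect_equal(res$report$angle_outliers, 0)
})

test_that("refinement is a near fixed point on a self-consistent input", {
  m <- fx("geomfix", function()
    make_toy_structure(strrep("A", 8), "protein", "helix"))
  map <- simulate_map(m, resolution = 8, voxel = 2, box = 32)
  cfg <- refinement_config(target_resolution = 8, n_patches = 4, seed = 5,
                           n_projections = 12,
                           iters = c(coarse = 120, residue = 120,
                                     rotamer = 50, full = 150))
  res <- suppressWarnings(refine(m, map = map, config = cfg))
  expect_lt(coord_rmsd(m$xyz, res$model$xyz), 0.1)
})

test_that("rotamer rebuild recovers a planted rotamer from the map", {
  truth <- make_toy_structure("ALA", "protein", "extended")
  topo <- compile_topology(truth)
  info <- gmmrefine:::chi_info(topo)
  peaks <- rotamer_peaks("LEU")
  cur <- gmmrefine:::dihedrals(truth$xyz,
    as.matrix(info$tab[, c("i1", "i2", "i3", "i4")]))$value
  # plant a different rotamer as the "true" state and simulate its map
  alt <- peaks[which.max(rowSums(
    abs(gmmrefine:::wrap180(sweep(peaks, 2, cur))) > 90)), ]
  xt <- gmmrefine:::apply_chi(truth$xyz, info, gmmrefine:::wrap180(alt - cur))
  planted <- set_coords(truth, xt)
  map <- simulate_map(planted, resolution = 3, voxel = 1, box = 32)
  rebuilt <- rebuild_rotamers(truth, map, topo)
  chis <- gmmrefine:::dihedrals(rebuilt$xyz,
    as.matrix(info$tab[, c("i1", "i2", "i3", "i4")]))$value
  expect_lt(max(abs(gmmrefine:::wrap180(chis - alt))), 15)
  # no map: a strict no-op
  expect_identical(rebuild_rotamers(truth, NULL, topo)$xyz, truth$xyz)
  # GLY/ALA-only models are untouched
  g <- make_toy_structure("GAGA", "protein", "helix")
  expect_identical(rebuild_rotamers(g, map, compile_topology(g))$xyz, g$xyz)
})

test_that("training stages are deterministic under a fixed seed", {
  m <- fx("geomfix", function()
    make_toy_structure(strrep("A", 8), "protein", "helix"))
  bad <- perturb(m, jitter_sd = 0.04, seed = 7)
  cfg <- refinement_config(target_resolution = 8, n_patches = 4, seed = 11,
                           iters = c(coarse = 30, residue = 30,
                                     rotamer = 30, full = 60))
  r1 <- refine(bad, config = cfg, geometry_only = TRUE)
  r2 <- refine(bad, config = cfg, geometry_only = TRUE)
  expect_lt(max(abs(r1$model$xyz - r2$model$xyz)), 1e-12)
})
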