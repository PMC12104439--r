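test_that("ideal fixtures sit at the likelihood minimum with zero outliers", {
  m <- helix10()
  topo <- compile_topology(m)
  ba <- bond_angle_score(m$xyz, topo)
  expect_equal(ba$bond_outliers, 0)
  expect_equal(ba$angle_outliers, 0)
  expect_lt(ba$max_bond_z, 1)
  # near the minimum: tiny gradient norm
  expect_lt(max(abs(ba$grad)), 0.5)
})

test_that("bond hinge activates at 4.5 sigma but reports outliers at 5", {
  m <- fx("alaala", function() make_toy_structure("AA", "protein", "helix"))
  topo <- compile_topology(m)
  stretch <- function(nsig) {
    b <- 1  # first template bond of residue 1
    i <- topo$bond_idx[b, 1]; j <- topo$bond_idx[b, 2]
    x <- m$xyz
    dir <- (x[j, ] - x[i, ]) / sqrt(sum((x[j, ] - x[i, ])^2))
    x[j, ] <- x[i, ] + dir * (topo$bond_mu[b] + nsig * topo$bond_sigma[b])
    x
  }
  base <- bond_angle_score(m$xyz, topo, grad = FALSE)
  s47 <- bond_angle_score(stretch(4.7), topo, grad = FALSE)
  s60 <- bond_angle_score(stretch(6), topo, grad = FALSE)
  expect_equal(s47$bond_outliers, 0)       # 4.7 < 5: not reported
  expect_equal(s60$bond_outliers, 1)       # 6 > 5: reported
  # the hinge at 4.7 contributes beyond the pure likelihood term
  lik47 <- 0.5 * 4.7^2 / (length(topo$bond_mu) + length(topo$angle_mu))
  expect_gt(s47$value - base$value, lik47 * 0.999)
})

test_that("planarity thresholds are 30 deg for omega and 10 deg otherwise", {
  mk_topo <- function(cls, ideal) {
    structure(list(planar_idx = rbind(1:4),
                   planar_class = cls, planar_ideal = ideal,
                   planar_thresh = ifelse(cls == "peptide_omega", 30, 10)),
              class = "topology_tables")
  }
  quad <- function(ang) {
    # dihedral(1,2,3,4) = ang (degrees) by construction
    rbind(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0),
          gmmrefine:::nerf_place(c(1, 1, 0), c(0, 1, 0), c(0, -1, 0),
                                 1.5, 109, ang))
  }
  tw <- mk_topo("peptide_omega", 180)
  expect_equal(planarity_score(quad(178), tw, grad = FALSE)$violations, 0)
  expect_equal(planarity_score(quad(140), tw, grad = FALSE)$violations, 1)
  tp <- mk_topo("other_planar", 0)
  expect_equal(planarity_score(quad(12), tp, grad = FALSE)$violations, 1)
  expect_equal(planarity_score(quad(8), tp, grad = FALSE)$violations, 0)
  # cis-peptide measures deviation from the nearer plane
  expect_equal(planarity_score(quad(2), tw, grad = FALSE)$violations, 0)
})

test_that("Ramachandran scoring matches the histogram oracle and class rules", {
  m <- helix40()
  topo <- compile_topology(m)
  ra <- rama_score(m$xyz, topo, grad = FALSE)
  expect_equal(ra$outlier_fraction, 0)
  expect_equal(ra$favored_fraction, 1)
  # (60, -120) in the General class is an outlier by the discrete histogram
  hg <- rama_histogram("General", step = 2)
  bin <- c(which.min(abs(hg$phi - 60)), which.min(abs(hg$psi + 120)))
  expect_lt(hg$values[bin[1], bin[2]], 5e-4)
  sc <- eval_surface(rama_surfaces()$General, cbind(60, -120))$score
  expect_lt(sc, gmmrefine:::outlier_log_threshold())
  # helix center agrees with the oracle in the other direction
  bin2 <- c(which.min(abs(hg$phi + 63)), which.min(abs(hg$psi + 43)))
  expect_gt(hg$values[bin2[1], bin2[2]], 5e-4)
  # residues before proline get the pre-Pro class
  mp <- make_toy_structure("AAPA", "protein", "helix")
  tp <- compile_topology(mp)
  expect_equal(tp$rama_class[2], "pre-Pro")
  expect_equal(tp$rama_class[3], "trans-Pro")
  expect_equal(compile_topology(helix10())$rama_class[2], "General")
})

test_that("rotamer scoring flags chi vectors far from every peak", {
  mg <- make_toy_structure("GAGA", "protein", "helix")
  tg <- compile_topology(mg)
  rg <- rotamer_score(mg$xyz, tg, grad = FALSE)
  expect_equal(rg$n_scored, 0)            # GLY/ALA: no chi
  ml <- make_toy_structure("ALA", "protein", "helix")  # ALA-LEU-ALA
  tl <- compile_topology(ml)
  r0 <- rotamer_score(ml$xyz, tl, grad = FALSE)
  expect_equal(r0$outlier_fraction, 0)    # built at a library peak
  info <- gmmrefine:::chi_info(tl)
  x2 <- gmmrefine:::apply_chi(ml$xyz, info, c(55, 55))
  r2 <- rotamer_score(x2, tl, grad = FALSE)
  expect_equal(r2$outlier_fraction, 1)    # 55 deg off every library peak
  # oracle: the displaced chi vector has near-zero library density
  ca <- gmmrefine:::chi_angles(x2, tl)
  dens <- gmmrefine:::surface_density(rotamer_surfaces()$LEU,
                                      rbind(ca$dh$value))$density
  expect_lt(dens, 5e-4)
})

test_that("clash detection applies the 0.4 A rule and the H-bond allowance", {
  m <- fx("alaala2", function() {
    a <- make_toy_structure("A", "protein", "helix")
    b <- make_toy_structure("A", "protein", "helix", chain = "B")
    b <- set_coords(b, b$xyz + 10)
    atomic_model(rbind(a$atoms, b$atoms), rbind(a$xyz, b$xyz))
  })
  topo <- compile_topology(m)
  topo <- refresh_neighbors(m$xyz, topo)
  cl0 <- clash_score(m$xyz, topo)
  expect_equal(cl0$clash_count, 0)
  expect_lt(cl0$value, 1e-8)   # soft hinge tail only
  # slide chain B so two carbons overlap by 0.5 A (> 0.4 rule)
  iCB1 <- which(m$atoms$atom == "CB" & m$atoms$chain == "A")
  iCB2 <- which(m$atoms$atom == "CB" & m$atoms$chain == "B")
  x <- m$xyz
  vdw <- load_vdw()
  target <- 2 * vdw["C"] - 0.5
  shift <- x[iCB2, ] - x[iCB1, ]
  x[m$atoms$chain == "B", ] <- sweep(x[m$atoms$chain == "B", ], 2,
    shift * (1 - target / sqrt(sum(shift^2))), "-")
  topo2 <- refresh_neighbors(x, topo)
  cl1 <- clash_score(x, topo2)
  expect_gte(cl1$clash_count, 1)
  expect_equal(cl1$score_per_1000, 1000 * cl1$clash_count / cl1$n_atoms)
  # H-bond pairs get the extra 0.4 A allowance in the pair thresholds
  e <- topo2$elem_all
  pr <- topo2$neighbor_idx
  hb <- topo2$pair_hb
  r <- topo2$vdw_radius
  expect_true(all(abs(topo2$pair_thresh[hb] -
    (r[pr[hb, 1]] + r[pr[hb, 2]] - 0.8)) < 1e-12))
  expect_true(all(abs(topo2$pair_thresh[!hb] -
    (r[pr[!hb, 1]] + r[pr[!hb, 2]] - 0.4)) < 1e-12))
})

test_that("neighbor refresh is deterministic and sees new contacts", {
  m <- helix10()
  topo <- compile_topology(m)
  t1 <- refresh_neighbors(m$xyz, topo)
  t2 <- refresh_neighbors(m$xyz, topo)
  expect_identical(t1$neighbor_idx, t2$neighbor_idx)
  # bring a second copy into contact: cross pairs appear after refresh
  far <- rbind(m$atoms, within(m$atoms, chain <- "B"))
  x_far <- rbind(m$xyz, m$xyz + 50)
  mf <- atomic_model(far, x_far)
  tf <- compile_topology(mf)
  tf <- refresh_neighbors(x_far, tf)
  n_far <- nrow(tf$neighbor_idx)
  x_near <- rbind(m$xyz, m$xyz + 4)
  tn <- refresh_neighbors(x_near, tf)
  cross <- sum(tn$neighbor_idx[, 1] <= nrow(m$xyz) &
               tn$neighbor_idx[, 2] > nrow(m$xyz) &
               tn$neighbor_idx[, 2] <= 2 * nrow(m$xyz))
  expect_gt(cross, 0)
  cl <- clash_score(x_near, tn, grad = FALSE)
  expect_gt(cl$clash_count, 0)
})

test_that("RNA suite scoring assigns nearest centers and retains outliers in the loss", {
  r <- rna5()
  topo <- compile_topology(r)
  rs <- rna_suite_score(r$xyz, topo, grad = FALSE)
  expect_gt(rs$mean_suite_score, 0.99)    # built on the A-form center
  expect_equal(rs$outlier_count, 0)
  # exhaustive-search oracle for the assignment
  suites <- load_suites()
  idx <- as.matrix(topo$rna[, c("i1", "i2", "i3", "i4")])
  dh <- gmmrefine:::dihedrals(r$xyz, idx)
  for (b in unique(topo$rna$base)) {
    th <- dh$value[topo$rna$base == b]
    d2 <- apply(suites$centers, 1, function(cc)
      sum((gmmrefine:::wrap180(cc - th) / suites$width)^2))
    expect_equal(rs$assignment[match(b, unique(topo$rna$base))],
                 rownames(suites$centers)[which.min(d2)])
  }
  # wreck one base: excluded from the reported mean, still in the loss
  x2 <- r$xyz
  i <- topo$res_index[[3]]
  x2[i, ] <- rigid_move(x2[i, ], angle = 2.4)
  rs2 <- rna_suite_score(x2, topo, grad = FALSE)
  expect_gt(rs2$outlier_count, 0)
  expect_gt(rs2$value, rs$value)          # loss includes the outlier base
})

test_that("combined loss is a weighted sum with linear weights", {
  m <- helix10()
  topo <- compile_topology(m)
  topo <- refresh_neighbors(m$xyz, topo)
  x <- m$xyz + 0.05
  w0 <- gmmrefine:::GEOM_WEIGHTS_DEFAULT
  l1 <- combined_geometry_loss(x, topo, w0, grad = FALSE)
  w2 <- w0; w2["bond_angle"] <- 2
  l2 <- combined_geometry_loss(x, topo, w2, grad = FALSE)
  expect_equal(unname(l2$value - l1$value), l1$terms$bond_angle$value,
               tolerance = 1e-10)
  expect_error(combined_geometry_loss(x, topo, c(bond_angle = -1)),
               "nonnegative")
})

test_that("all geometry losses are rigid-motion invariant", {
  m <- mixed_helix()
  topo <- compile_topology(m)
  topo <- refresh_neighbors(m$xyz, topo)
  x <- m$xyz
  x2 <- rigid_move(x)
  for (f in list(
    function(z) bond_angle_score(z, topo, grad = FALSE)$value,
    function(z) planarity_score(z, topo, grad = FALSE)$value,
    function(z) rama_score(z, topo, grad = FALSE)$value,
    function(z) rotamer_score(z, topo, grad = FALSE)$value,
    function(z) clash_score(z, topo, grad = FALSE)$value))
    expect_lt(abs(f(x2) - f(x)), 1e-6)
  r <- rna5()
  tr <- compile_topology(r)
  expect_lt(abs(rna_suite_score(rigid_move(r$xyz), tr, grad = FALSE)$value -
                rna_suite_score(r$xyz, tr, grad = FALSE)$value), 1e-6)
})

test_that("reference surfaces are periodic", {
  s <- rama_surfaces()$General
  a <- eval_surface(s, cbind(-170, 33))$score
  b <- eval_surface(s, cbind(-170 + 360, 33))$score
  cc <- eval_surface(s, cbind(-170, 33 - 360))$score
  expect_lt(abs(a - b), 1e-9)
  expect_lt(abs(a - cc), 1e-9)
})
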