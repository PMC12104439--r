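test_that("templates cover the standard residue set with correct chi counts", {
  tpl <- load_templates()
  expect_length(tpl, 24)
  nchi <- function(r) {
    cd <- tpl[[r]]$chi_definitions
    if (is.null(cd)) 0L else nrow(cd)
  }
  expect_equal(nchi("GLY"), 0L)
  expect_equal(nchi("ALA"), 0L)
  expect_equal(nchi("ARG"), 4L)
  expect_equal(nchi("LYS"), 4L)
  expect_equal(nchi("SER"), 1L)
  # bonded atoms are template atoms, sigmas positive
  for (r in c("ALA", "ARG", "TRP", "G", "U")) {
    tp <- tpl[[r]]
    expect_true(all(c(tp$bonds$a1, tp$bonds$a2) %in% rownames(tp$xyz)))
    expect_true(all(tp$bonds$sigma > 0))
    expect_true(all(tp$angles$sigma > 0))
  }
  expect_error(load_templates("other"), "dialect")
})

test_that("VdW radii are physically plausible", {
  v <- load_vdw()
  expect_true(all(v > 0.8 & v < 2.5))
  expect_error(load_vdw("weird"), "dialect")
})

test_that("topology compiles peptide links, omega quads and chi quads", {
  m <- fx("alaala", function() make_toy_structure("AA", "protein", "helix"))
  topo <- compile_topology(m)
  # exactly one inter-residue C-N bond at the peptide ideal length
  inter <- which(abs(topo$bond_mu - 1.329) < 1e-6)
  expect_length(inter, 1)
  at <- m$atoms
  expect_equal(at$atom[topo$bond_idx[inter, 1]], "C")
  expect_equal(at$atom[topo$bond_idx[inter, 2]], "N")
  # the peptide planar quad is classed peptide_omega with a 30 deg threshold
  io <- which(topo$planar_class == "peptide_omega")
  expect_length(io, 1)
  expect_equal(topo$planar_thresh[io], 30)
  # bond count = intra template bonds + one link
  tpl <- load_templates()
  expect_equal(nrow(topo$bond_idx), 2 * nrow(tpl$ALA$bonds) + 1)
  # chi quads: one per chi per residue
  ml <- make_toy_structure("LL", "protein", "helix")
  tl <- compile_topology(ml)
  expect_equal(nrow(tl$chi), 4L)  # 2 residues x 2 chi
})

test_that("chain breaks suppress the inter-residue link", {
  m <- make_toy_structure("AAAA", "protein", "helix")
  x <- m$xyz
  sel <- m$atoms$res_seq >= 3
  x[sel, ] <- x[sel, ] + 20
  m2 <- set_coords(m, x)
  expect_message(topo <- compile_topology(m2, verbose = TRUE), "chain break")
  expect_equal(sum(abs(topo$bond_mu - 1.329) < 1e-6), 2)  # 3 links - 1 break
})

test_that("unsupported residues are reported by name", {
  m <- helix10()
  m$atoms$res_name[m$atoms$res_seq == 3] <- "XYZ"
  expect_error(compile_topology(m), "XYZ")
})

test_that("neighbor lists are capped, exclude near-bonded pairs, and match brute force", {
  m <- helix10()
  topo <- compile_topology(m)
  topo <- refresh_neighbors(m$xyz, topo)
  pr <- topo$neighbor_idx
  n_heavy <- topo$n_heavy
  counts <- tabulate(c(pr[, 1], pr[, 2]), nbins = n_heavy + topo$n_hydrogen)
  expect_true(all(counts <= 2 * 128))

  # BFS oracle: no pair within 3 covalent bonds
  edges <- topo$bond_graph
  nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  within3 <- function(i, j) {
    seen <- i; frontier <- i
    for (d in 1:3) {
      frontier <- setdiff(unique(unlist(nb[as.character(frontier)])), seen)
      if (j %in% frontier) return(TRUE)
      seen <- c(seen, frontier)
    }
    FALSE
  }
  set.seed(5)
  for (q in sample(nrow(pr), 40)) {
    expect_false(within3(pr[q, 1], pr[q, 2]))
  }

  # brute-force k-nearest eligible oracle on the full (heavy + H) atom set
  h <- place_hydrogens(m$xyz, topo)
  allx <- rbind(m$xyz, h)
  D <- as.matrix(dist(allx))
  diag(D) <- Inf
  keyset <- paste(pr[, 1], pr[, 2])
  for (i in c(1, 10, 25)) {
    elig <- setdiff(order(D[i, ]), i)
    elig <- elig[!vapply(elig, function(j) within3(i, j), TRUE)]
    nearest <- head(elig, 5)
    for (j in nearest) {
      key <- paste(min(i, j), max(i, j))
      expect_true(key %in% keyset)
    }
  }
})

test_that("topology compilation is deterministic", {
  m <- mixed_helix()
  t1 <- compile_topology(m)
  t2 <- compile_topology(m)
  expect_identical(t1$bond_idx, t2$bond_idx)
  expect_identical(t1$angle_mu, t2$angle_mu)
  expect_identical(t1$hydrogens, t2$hydrogens)
})

test_that("suite library has 46 distinct centers", {
  s <- load_suites()
  expect_equal(nrow(s$centers), 46)
  expect_equal(nrow(unique(s$centers)), 46)
  expect_equal(s$threshold, 0.001)
})
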