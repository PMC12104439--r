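test_that("map projections are deterministic and physically consistent", {
  map <- helix40_map()
  p1 <- make_projections(map, 6, seed = 4)
  p2 <- make_projections(map, 6, seed = 4)
  expect_identical(p1$images, p2$images)
  expect_equal(length(p1$images), 6)

  # spherically symmetric map: projections agree from every view
  onem <- atomic_model(
    data.frame(atom = "CA", element = "C", res_name = "ALA", res_seq = 1,
               ins = "", chain = "A", occ = 1),
    rbind(c(0, 0, 0)))
  smap <- simulate_map(onem, resolution = 10, voxel = 1, box = 32,
                       center = c(0, 0, 0))
  ps <- make_projections(smap, 8, seed = 1)
  ref <- ps$images[[1]]
  for (img in ps$images[-1]) {
    expect_lt(sqrt(mean((img - ref)^2)) / sqrt(mean(ref^2)), 0.01)
  }
})

test_that("single-Gaussian projections match the analytic formula", {
  gmm <- structure(list(centers = rbind(c(2, -1, 3)), amplitudes = 1.5,
                        width = 2), class = "gaussian_mixture")
  img <- project_gmm(gmm, diag(3), npix = 48, pixel = 1)
  ix <- (0:47) - 24
  ana <- outer(ix, ix, function(u, v)
    1.5 * 2 * sqrt(2 * pi) * exp(-((u - 2)^2 + (v + 1)^2) / (2 * 4)))
  expect_lt(max(abs(img - ana)), 1e-3)
  # max at the projected center pixel for the origin Gaussian
  g0 <- structure(list(centers = rbind(c(0, 0, 0)), amplitudes = 1,
                       width = 2), class = "gaussian_mixture")
  i0 <- project_gmm(g0, diag(3), npix = 32, pixel = 1)
  expect_equal(which(i0 == max(i0), arr.ind = TRUE)[1, ],
               c(row = 17, col = 17))
  # superposition along the view axis: two stacked Gaussians, one peak of
  # double intensity
  g2 <- structure(list(centers = rbind(c(0, 0, -4), c(0, 0, 4)),
                       amplitudes = c(1, 1), width = 2),
                  class = "gaussian_mixture")
  i2 <- project_gmm(g2, diag(3), npix = 32, pixel = 1)
  expect_lt(max(abs(i2 - 2 * i0)), 1e-10)
})

test_that("FRC is 1 on self, scale-free, and filtering-insensitive", {
  map <- helix40_map()
  ps <- make_projections(map, 2, seed = 2)
  a <- ps$images[[1]]
  f <- frc(a, a)
  expect_true(all(abs(f$per_ring - 1) < 1e-9 | f$per_ring == 0))
  expect_equal(frc(a, 3.7 * a)$per_ring, f$per_ring, tolerance = 1e-12)
  # radially symmetric (B-factor-like) filtering leaves the FRC at 1
  n <- nrow(a)
  ri <- gmmrefine:::ring_index(n)
  filt <- exp(-0.02 * pmax(ri, 0)^2)
  blurred <- Re(fft(fft(a) * filt, inverse = TRUE)) / n^2
  fb <- frc(a, blurred)
  expect_true(all(abs(fb$per_ring[1:(n %/% 2)] - 1) < 1e-6))
  # a zero image has no ring power: correlation defined as 0
  fz <- frc(a, a * 0)
  expect_true(all(fz$per_ring == 0))
})

test_that("FRC matches an independent ring-masked correlation oracle", {
  map <- helix40_map()
  ps <- make_projections(map, 2, seed = 9)
  a <- ps$images[[1]][1:32, 1:32]
  b <- ps$images[[2]][1:32, 1:32]
  f <- frc(a, b)
  A <- fft(a); B <- fft(b)
  k <- c(0:16, -15:-1)
  kx <- matrix(k, 32, 32); ky <- t(kx)
  rr <- round(sqrt(kx^2 + ky^2))
  for (r in 1:16) {
    m <- rr == r
    oracle <- Re(sum(A[m] * Conj(B[m]))) /
      sqrt(sum(Mod(A[m])^2) * sum(Mod(B[m])^2))
    expect_lt(abs(f$per_ring[r] - oracle), 1e-6)
  }
})

test_that("frc_loss is near -1 at self-consistency and worsens off-target", {
  m <- helix40()
  map <- helix40_map()
  ps <- make_projections(map, 8, seed = 3)
  gmm <- model_to_gmm(m, 8)
  l0 <- frc_loss(gmm, ps, 8)$value
  expect_lt(abs(l0 - (-1)), 0.05)
  g2 <- gmm
  g2$centers <- gmm$centers + c(10, 0, 0)
  expect_gt(frc_loss(g2, ps, 8)$value, l0 + 0.05)
  # Nyquist guard
  expect_error(frc_loss(gmm, ps, 3), "Nyquist")
})

test_that("frc_loss gradients pass finite-difference checks", {
  m <- helix10()
  map <- fx("h10map", function()
    simulate_map(helix10(), resolution = 8, voxel = 2, box = 32))
  ps <- make_projections(map, 4, seed = 5)
  gmm <- model_to_gmm(m, 8)
  gmm$centers <- gmm$centers + matrix(rnorm(length(gmm$centers), 0, 0.3),
                                      ncol = 3)
  fl <- frc_loss(gmm, ps, 8, grad = TRUE)
  err <- fd_max_rel(function(z) {
    g <- gmm; g$centers <- matrix(z, ncol = 3)
    frc_loss(g, ps, 8)$value
  }, as.numeric(gmm$centers), as.numeric(fl$g_centers), h = 1e-4)
  expect_lt(err, 1e-3)
  # width gradient
  gp <- gm <- gmm
  gp$width <- gmm$width + 1e-4
  gm$width <- gmm$width - 1e-4
  errw <- abs((frc_loss(gp, ps, 8)$value - frc_loss(gm, ps, 8)$value) /
              2e-4 - fl$g_width)
  expect_lt(errw / max(abs(fl$g_width), 1e-6), 1e-2)
})

test_that("frc_loss is invariant to ring-wise rescaling of the reference", {
  map <- helix40_map()
  ps <- make_projections(map, 4, seed = 6)
  gmm <- model_to_gmm(helix40(), 8)
  l0 <- frc_loss(gmm, ps, 8)$value
  n <- nrow(ps$images[[1]])
  ri <- gmmrefine:::ring_index(n)
  filt <- exp(0.01 * pmax(ri, 0))       # sharpening-like radial boost
  ps2 <- ps
  ps2$images <- lapply(ps$images, function(im)
    Re(fft(fft(im) * filt, inverse = TRUE)) / n^2)
  expect_lt(abs(frc_loss(gmm, ps2, 8)$value - l0), 1e-6)
})
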