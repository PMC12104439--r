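# Differentiable map-model similarity: analytic 2D projection of the GMM,
# Fourier ring correlation (FRC) between projections, and the FRC loss with
# analytic gradients with respect to Gaussian centers, amplitudes and width.

golden_angle <- pi * (3 - sqrt(5))

#' Quasi-uniform rotation sampling
#'
#' View directions on a Fibonacci sphere with golden-ratio in-plane angles;
#' a seeded random offset decorrelates repeated draws.
#'
#' @param n number of rotations
#' @param seed integer seed
#' @return list of 3 x 3 rotation matrices
#' @export
sample_rotations <- function(n, seed = 1) {
  set.seed(seed)
  off <- stats::runif(3, 0, 2 * pi)
  lapply(seq_len(n) - 1, function(i) {
    z <- 1 - 2 * (i + 0.5) / n
    th <- acos(z)
    ph <- i * golden_angle + off[1]
    ps <- i * golden_angle * 0.618 + off[2]
    rotz(ps) %*% roty(th) %*% rotz(ph)
  })
}

rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)

#' Project a density map into a set of 2D images
#'
#' Images are line integrals of the map along quasi-uniformly sampled view
#' axes, rotated about the physical center of the box.
#'
#' @param map a `density_map`
#' @param n_orientations number of projections
#' @param seed seed for the orientation sampling
#' @return object of class `projection_set`: `images` (list of square
#'   matrices), `rots`, `pixel` (Angstrom), `center` (rotation center, Angstrom)
#' @export
make_projections <- function(map, n_orientations = 32, seed = 1) {
  stopifnot(n_orientations >= 1)
  rots <- sample_rotations(n_orientations, seed)
  n <- dim(map$data)[1]
  imgs <- lapply(rots, function(R)
    cpp_project_map(as.numeric(map$data), dim(map$data), map$voxel, R,
                    n, map$voxel))
  structure(list(images = imgs, rots = rots, pixel = map$voxel,
                 center = map_center(map)), class = "projection_set")
}

#' Analytic projection of a Gaussian mixture
#'
#' Each 3D Gaussian projects to a 2D Gaussian of the same width; the image
#' is the exact line integral of the mixture along the rotated z axis.
#'
#' @param gmm a `gaussian_mixture`
#' @param rot 3 x 3 rotation (model frame to projection frame)
#' @param npix image side length in pixels
#' @param pixel pixel size in Angstrom
#' @param center rotation center in Angstrom
#' @return npix x npix image matrix
#' @export
project_gmm <- function(gmm, rot = diag(3), npix = 64, pixel = 1,
                        center = c(0, 0, 0)) {
  ctr <- sweep(gmm$centers, 2, center)
  cpp_render_gmm(ctr, gmm$amplitudes, gmm$width, rot, as.integer(npix), pixel)
}

# ring index per FFT pixel (unshifted layout); cached per size
ring_index <- function(n) {
  key <- paste0("ring", n)
  r <- .gmmrefine_cache[[key]]
  if (!is.null(r)) return(r)
  k <- c(0:(n %/% 2), seq_len(n - n %/% 2 - 1) - (n - n %/% 2))
  kx <- matrix(k, n, n)
  ky <- matrix(k, n, n, byrow = TRUE)
  r <- round(sqrt(kx^2 + ky^2))
  r[r > n %/% 2] <- -1L  # corner frequencies outside the Nyquist disc
  .gmmrefine_cache[[key]] <- r
  r
}

#' Fourier ring correlation between two images
#'
#' Per-ring normalized complex correlation of the Fourier coefficients
#' (ring width one Fourier pixel); rings with zero power in either image
#' get correlation 0.
#'
#' @param a,b square matrices of equal size
#' @param pixel pixel size in Angstrom (for the cutoff frequency)
#' @param cutoff_res resolution cutoff in Angstrom; `mean_to_cutoff`
#'   averages rings up to 1/cutoff_res (default: all rings)
#' @return object of class `frc_result`: `per_ring`, `mean_to_cutoff`,
#'   `cutoff_frequency` (1/Angstrom)
#' @export
frc <- function(a, b, pixel = 1, cutoff_res = NULL) {
  n <- nrow(a)
  stopifnot(all(dim(a) == dim(b)), n == ncol(a))
  A <- stats::fft(a); B <- stats::fft(b)
  ri <- ring_index(n)
  nr <- n %/% 2
  per <- numeric(nr)
  for (r in seq_len(nr)) {
    m <- ri == r
    num <- sum(Re(A[m] * Conj(B[m])))
    pa <- sum(Mod(A[m])^2); pb <- sum(Mod(B[m])^2)
    per[r] <- if (pa > 0 && pb > 0) num / sqrt(pa * pb) else 0
  }
  rcut <- if (is.null(cutoff_res)) nr else max(1, min(nr, floor(n * pixel / cutoff_res)))
  structure(list(per_ring = per,
                 mean_to_cutoff = mean(per[seq_len(rcut)]),
                 cutoff_frequency = rcut / (n * pixel)),
            class = "frc_result")
}

# cutoff ring for a target resolution
cutoff_ring <- function(n, pixel, target_res) {
  if (pixel > target_res / 2)
    stop("Nyquist violation: pixel size ", pixel,
         " A exceeds half the target resolution ", target_res, " A")
  max(1, min(n %/% 2, floor(n * pixel / target_res)))
}

#' FRC loss of a GMM against a projection set
#'
#' Negative mean FRC over a batch of projections, rings restricted to
#' frequencies at or below 1/target_resolution. With `grad = TRUE` the
#' analytic gradient with respect to Gaussian centers, amplitudes and the
#' shared width is returned alongside.
#'
#' @param gmm a `gaussian_mixture`
#' @param pset a `projection_set`
#' @param target_res target resolution, Angstrom
#' @param batch indices of projections to use (default all)
#' @param grad compute gradients?
#' @return list with `value` and, when `grad`, `g_centers` (N x 3),
#'   `g_amps`, `g_width`
#' @export
frc_loss <- function(gmm, pset, target_res, batch = NULL, grad = FALSE) {
  n <- nrow(pset$images[[1]])
  rcut <- cutoff_ring(n, pset$pixel, target_res)
  if (is.null(batch)) batch <- seq_along(pset$images)
  ri <- ring_index(n)
  ctr <- sweep(gmm$centers, 2, pset$center)
  loss <- 0
  gC <- if (grad) matrix(0, nrow(ctr), 3)
  gA <- if (grad) numeric(nrow(ctr))
  gW <- 0
  ring_masks <- lapply(seq_len(rcut), function(r) ri == r)
  for (k in batch) {
    R <- pset$rots[[k]]
    img <- cpp_render_gmm(ctr, gmm$amplitudes, gmm$width, R, n, pset$pixel)
    A <- stats::fft(img)
    B <- stats::fft(pset$images[[k]])
    G <- if (grad) matrix(0 + 0i, n, n)
    fsum <- 0
    for (r in seq_len(rcut)) {
      m <- ring_masks[[r]]
      Am <- A[m]; Bm <- B[m]
      pa <- sum(Mod(Am)^2); pb <- sum(Mod(Bm)^2)
      if (pa <= 0 || pb <= 0) next
      num <- sum(Re(Am * Conj(Bm)))
      sq <- sqrt(pa * pb)
      fsum <- fsum + num / sq
      if (grad) {
        # d(corr_r)/dA = B/sqrt(pa*pb) - num/(pa^(3/2) pb^(1/2)) * A
        G[m] <- G[m] + (-1 / rcut) *
          (Bm / sq - (num / (pa * sq)) * Am)
      }
    }
    loss <- loss - fsum / rcut
    if (grad) {
      dldi <- Re(stats::fft(G, inverse = TRUE))
      gr <- cpp_render_gmm_grad(ctr, gmm$amplitudes, gmm$width, R, n,
                                pset$pixel, dldi)
      gC <- gC + gr$dcenters %*% R
      gA <- gA + gr$damps
      gW <- gW + gr$dwidth
    }
  }
  nb <- length(batch)
  out <- list(value = loss / nb)
  if (grad) {
    out$g_centers <- gC / nb
    out$g_amps <- gA / nb
    out$g_width <- gW / nb
  }
  out
}

#' Map-model similarity score (mean FRC to cutoff)
#'
#' @inheritParams frc_loss
#' @return scalar mean FRC over the batch (higher is better)
#' @export
map_model_frc <- function(gmm, pset, target_res, batch = NULL) {
  -frc_loss(gmm, pset, target_res, batch)$value
}
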