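# Continuous, differentiable reference surfaces for backbone and sidechain
# torsion preferences. A surface is a Gaussian mixture over a periodic
# torsion space evaluated in the log domain ln(R + C), C = exp(-10), so
# that the tiny outlier level used by validation (0.0005 on a max-1
# histogram) stays resolvable with usable gradients.

LOG_C <- -10
OUTLIER_LEVEL <- 5e-4              # histogram level below which = outlier
ALLOWED_LEVEL <- 0.02              # favored/allowed boundary (max-1 scale)
outlier_log_threshold <- function() log(OUTLIER_LEVEL + exp(LOG_C))
allowed_log_threshold <- function() log(ALLOWED_LEVEL + exp(LOG_C))

RAMA_CLASSES <- c("General", "Gly", "trans-Pro", "cis-Pro", "pre-Pro", "Ile")

# favored-region component definitions per class: center phi, center psi,
# sigma (deg), amplitude. A broad low-amplitude halo around each favored
# center supplies the "allowed" shoulder.
rama_region_defs <- function(class) {
  base <- switch(class,
    "General" = rbind(c(-63, -43, 14, 1.0), c(-118, 132, 20, 0.9),
                      c(-65, 147, 15, 0.85), c(57, 42, 11, 0.3)),
    "Gly" = rbind(c(-63, -41, 15, 1.0), c(63, 41, 15, 0.9),
                  c(-90, 150, 22, 0.7), c(90, -150, 22, 0.7),
                  c(180, 180, 25, 0.4)),
    "trans-Pro" = rbind(c(-61, -38, 11, 1.0), c(-62, 145, 12, 0.9)),
    "cis-Pro" = rbind(c(-76, 158, 11, 1.0), c(-85, -5, 11, 0.6)),
    "pre-Pro" = rbind(c(-64, -40, 13, 1.0), c(-120, 130, 18, 0.9),
                      c(-135, 75, 14, 0.5)),
    "Ile" = rbind(c(-62, -45, 12, 1.0), c(-115, 127, 17, 0.9)),
    stop("unknown Ramachandran class: ", class))
  halo <- cbind(base[, 1:2, drop = FALSE], base[, 3] * 2.6, base[, 4] * 0.04)
  rbind(base, halo)
}

new_surface <- function(kind, label, centers, sigma, amps, norm = 1) {
  structure(list(kind = kind, label = label,
                 centers = as.matrix(centers), sigma = sigma, amps = amps,
                 norm = norm,
                 outlier_threshold = outlier_log_threshold(),
                 allowed_threshold = allowed_log_threshold()),
            class = "geom_surface")
}

# mixture density (max approximately 1) and gradient on a periodic domain
surface_density <- function(surf, X) {
  X <- rbind(X)
  m <- nrow(X); d <- ncol(X)
  K <- nrow(surf$centers)
  R <- numeric(m)
  Gr <- matrix(0, m, d)
  for (k in seq_len(K)) {
    D <- wrap180(sweep(X, 2, surf$centers[k, ], "-"))
    s2 <- surf$sigma[k]^2
    e <- surf$amps[k] * exp(-rowSums(D^2) / (2 * s2))
    R <- R + e
    Gr <- Gr - e * D / s2
  }
  list(density = R / surf$norm, grad = Gr / surf$norm)
}

#' Evaluate a reference surface in the log domain
#'
#' @param surf a `geom_surface`
#' @param X m x d matrix of torsion angles in degrees
#' @return list with `score` = ln(R + C) per row and `grad` (m x d,
#'   per degree)
#' @export
eval_surface <- function(surf, X) {
  sd <- surface_density(surf, rbind(X))
  denom <- sd$density + exp(LOG_C)
  list(score = log(denom), grad = sd$grad / denom)
}

#' Bundled Ramachandran surfaces
#'
#' Six residue classes (General, Gly, trans-Pro, cis-Pro, pre-Pro, Ile),
#' each a Gaussian mixture over (phi, psi) normalized to maximum 1,
#' evaluated as ln(R + C). Built from the shipped region definitions and
#' cached.
#'
#' @return named list of `geom_surface`
#' @export
rama_surfaces <- function() {
  s <- .gmmrefine_cache$rama_surf
  if (!is.null(s)) return(s)
  grid <- as.matrix(expand.grid(phi = seq(-180, 178, 2),
                                psi = seq(-180, 178, 2)))
  s <- lapply(RAMA_CLASSES, function(cl) {
    def <- rama_region_defs(cl)
    surf <- new_surface("rama", cl, def[, 1:2], def[, 3], def[, 4])
    surf$norm <- max(surface_density(surf, grid)$density)
    surf
  })
  names(s) <- RAMA_CLASSES
  .gmmrefine_cache$rama_surf <- s
  s
}

#' Discrete Ramachandran histogram (the lookup oracle)
#'
#' The binned form of a bundled surface: density on a regular (phi, psi)
#' grid, max-normalized. Used as the discrete reference that hard outlier
#' calls are validated against.
#'
#' @param class one of the six residue classes
#' @param step grid step in degrees
#' @return list with `phi`, `psi` (bin centers) and `values` (matrix)
#' @export
rama_histogram <- function(class = "General", step = 2) {
  surf <- rama_surfaces()[[class]]
  phi <- seq(-180, 180 - step, step); psi <- phi
  g <- as.matrix(expand.grid(phi = phi, psi = psi))
  v <- matrix(surface_density(surf, g)$density, length(phi), length(psi))
  list(phi = phi, psi = psi, values = v / max(v))
}

# chi-angle peak values per chi index; aromatics have a two-fold chi2
rotamer_chi_candidates <- function(res, chi_idx) {
  if (res %in% c("PHE", "TYR", "TRP", "HIS") && chi_idx == 2) return(c(-90, 90))
  c(-60, 60, 180)
}

#' Rotamer peak library for one residue type
#'
#' @param res 3-letter residue name
#' @return matrix of peak chi vectors (degrees), one row per rotamer, or
#'   NULL for residues without chi angles
#' @export
rotamer_peaks <- function(res) {
  tpl <- load_templates()[[res]]
  nchi <- if (is.null(tpl$chi_definitions)) 0 else nrow(tpl$chi_definitions)
  if (nchi == 0) return(NULL)
  if (res == "PRO") {
    # ring pucker states: the template ring conformation and its mirror
    cd <- tpl$chi_definitions
    idx <- function(a) match(a, rownames(tpl$xyz))
    ch <- vapply(seq_len(nchi), function(k)
      dihedrals(tpl$xyz, rbind(c(idx(cd$a1[k]), idx(cd$a2[k]),
                                 idx(cd$a3[k]), idx(cd$a4[k]))))$value,
      numeric(1))
    return(rbind(ch, -ch))
  }
  cand <- lapply(seq_len(nchi), function(k) rotamer_chi_candidates(res, k))
  as.matrix(expand.grid(cand))
}

#' Bundled rotamer surfaces
#'
#' One Gaussian mixture per residue type with chi angles: peaks at the
#' library rotamers, width 12 degrees per chi, evaluated as ln(R + C).
#'
#' @return named list of `geom_surface` (residues with no chi omitted)
#' @export
rotamer_surfaces <- function() {
  s <- .gmmrefine_cache$rot_surf
  if (!is.null(s)) return(s)
  s <- list()
  for (res in AA3) {
    pk <- rotamer_peaks(res)
    if (is.null(pk)) next
    surf <- new_surface("rotamer", res, pk, rep(12, nrow(pk)),
                        rep(1, nrow(pk)))
    surf$norm <- max(surface_density(surf, pk)$density)
    surf$peaks <- pk
    s[[res]] <- surf
  }
  .gmmrefine_cache$rot_surf <- s
  s
}

#' Fit a Gaussian-mixture surface to a gridded histogram
#'
#' Turns a discrete 2D histogram (max-normalized) into a continuous
#' differentiable surface by gradient-descent fitting of a Gaussian
#' mixture, optionally in the log domain ln(H + C), with an optional
#' boundary penalty that forces every histogram-outlier bin to evaluate
#' below the surface outlier threshold.
#'
#' @param histogram list with `phi`, `psi` (bin centers, degrees) and
#'   `values` (matrix, max 1)
#' @param n_components number of Gaussians
#' @param log_domain fit ln(H + C) (shifted to be nonnegative) instead of H
#' @param boundary_penalty add the outlier-boundary hinge during fitting
#' @param seed seed for the k-means initialization
#' @param iters Adam iterations
#' @param label label stored on the surface
#' @return a `geom_surface` with attributes `rmsd` (fit RMSD in the fitted
#'   domain) and `converged`
#' @export
fit_reference_gmm <- function(histogram, n_components = 100,
                              log_domain = TRUE, boundary_penalty = TRUE,
                              seed = 1, iters = 800, label = "fitted") {
  H <- histogram$values
  stopifnot(all(H >= 0))
  grid <- as.matrix(expand.grid(phi = histogram$phi, psi = histogram$psi))
  Tgt <- if (log_domain) log(as.numeric(H) + exp(LOG_C)) - LOG_C
         else as.numeric(H)
  out_bins <- as.numeric(H) < OUTLIER_LEVEL
  thr_fit <- if (log_domain) outlier_log_threshold() - LOG_C else OUTLIER_LEVEL
  B <- nrow(grid); K <- n_components

  set.seed(seed)
  hi <- which(as.numeric(H) >= max(OUTLIER_LEVEL, 0.02 * max(H)))
  if (length(hi) < 2) {
    # degenerate (near-zero) histogram: flat zero surface
    surf <- new_surface("fitted", label, matrix(0, 1, 2), 30, 1e-8)
    surf$form <- "shifted_log"; surf$shift <- LOG_C
    attr(surf, "rmsd") <- sqrt(mean(Tgt^2)); attr(surf, "converged") <- TRUE
    return(surf)
  }
  samp <- sample(hi, min(length(hi), 50 * K), replace = TRUE,
                 prob = as.numeric(H)[hi])
  km <- suppressWarnings(stats::kmeans(grid[samp, , drop = FALSE],
                                       centers = min(K, length(unique(samp))),
                                       iter.max = 50, nstart = 3))
  ctr <- km$centers
  if (nrow(ctr) < K)
    ctr <- rbind(ctr, grid[sample(hi, K - nrow(ctr), replace = TRUE), ,
                           drop = FALSE] + stats::rnorm((K - nrow(ctr)) * 2, 0, 3))
  lsg <- rep(log(12), K)
  lam <- rep(log(0.5 * max(Tgt) + 1e-6), K)

  comp_mat <- function(ctr, sig) {
    E <- matrix(0, B, K)
    for (k in seq_len(K)) {
      D <- wrap180(sweep(grid, 2, ctr[k, ], "-"))
      E[, k] <- exp(-rowSums(D^2) / (2 * sig[k]^2))
    }
    E
  }
  pack <- function(ctr, lsg, lam) c(as.numeric(ctr), lsg, lam)
  unpack <- function(p) list(ctr = matrix(p[1:(2 * K)], K, 2),
                             lsg = p[2 * K + 1:K], lam = p[3 * K + 1:K])
  # residuals: fit misfit everywhere + boundary hinge on outlier bins
  make_resid <- function(pen_w) function(p) {
    u <- unpack(p)
    E <- comp_mat(u$ctr, exp(u$lsg))
    G <- as.numeric(E %*% exp(u$lam))
    r <- G - Tgt
    if (pen_w > 0) {
      over <- pmax(G[out_bins] - thr_fit * 0.75, 0)
      r <- c(r, sqrt(pen_w) * over)
    }
    r
  }
  make_jac <- function(pen_w) function(p) {
    u <- unpack(p)
    sig <- exp(u$lsg); amp <- exp(u$lam)
    E <- comp_mat(u$ctr, sig)
    G <- as.numeric(E %*% amp)
    J <- matrix(0, B, 4 * K)
    for (k in seq_len(K)) {
      D <- wrap180(sweep(grid, 2, u$ctr[k, ], "-"))
      ea <- E[, k] * amp[k]
      J[, k] <- ea * D[, 1] / sig[k]^2          # d/d ctr_phi
      J[, K + k] <- ea * D[, 2] / sig[k]^2      # d/d ctr_psi
      J[, 2 * K + k] <- ea * rowSums(D^2) / sig[k]^2  # d/d log sigma
      J[, 3 * K + k] <- ea                      # d/d log amp
    }
    if (pen_w > 0) {
      act <- as.numeric(G[out_bins] > thr_fit * 0.75)
      J <- rbind(J, sqrt(pen_w) * act * J[which(out_bins), , drop = FALSE])
    }
    J
  }
  fit_pass <- function(p, pen_w, maxit) {
    minpack.lm::nls.lm(p, fn = make_resid(pen_w), jac = make_jac(pen_w),
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxit, ptol = 1e-12, ftol = 1e-12))$par
  }
  p <- pack(ctr, lsg, lam)
  p <- fit_pass(p, 0, iters)
  if (boundary_penalty) {
    pen_w <- 10
    for (round in 1:5) {
      u <- unpack(p)
      G <- as.numeric(comp_mat(u$ctr, exp(u$lsg)) %*% exp(u$lam))
      if (all(G[out_bins] < thr_fit)) break
      p <- fit_pass(p, pen_w, max(50, iters %/% 4))
      pen_w <- pen_w * 10
    }
  }
  u <- unpack(p)
  ctr <- u$ctr; sig <- exp(u$lsg); amp <- exp(u$lam)
  G <- as.numeric(comp_mat(ctr, sig) %*% amp)
  rmsd <- sqrt(mean((G - Tgt)^2))
  surf <- new_surface("fitted", label, ctr, sig, amp)
  if (log_domain) { surf$form <- "shifted_log"; surf$shift <- LOG_C }
  conv <- rmsd < 0.02 * max(diff(range(Tgt)), 1e-6)
  if (!conv) warning("reference GMM fit did not fully converge (RMSD = ",
                     signif(rmsd, 3), ")")
  attr(surf, "rmsd") <- rmsd
  attr(surf, "converged") <- conv
  surf
}

#' Evaluate a fitted (shifted-log) surface
#'
#' For surfaces produced by [fit_reference_gmm()] in the log domain the
#' mixture itself represents ln(H + C) - ln(C); this returns ln(H + C).
#' For density-form surfaces it matches [eval_surface()].
#'
#' @inheritParams eval_surface
#' @return list with `score` and `grad`
#' @export
eval_surface_log <- function(surf, X) {
  if (is.null(surf$form)) return(eval_surface(surf, X))
  sd <- surface_density(surf, rbind(X))
  list(score = sd$density * surf$norm + surf$shift, grad = sd$grad * surf$norm)
}
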