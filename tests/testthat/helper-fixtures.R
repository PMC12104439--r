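# Shared fixtures, built once per test run and cached.

.fx <- new.env()

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

helix10 <- function() fx("helix10", function()
  make_toy_structure(strrep("A", 10), "protein", "helix"))

helix40 <- function() fx("helix40", function()
  make_toy_structure(strrep("A", 40), "protein", "helix"))

mixed_helix <- function() fx("mixed", function()
  make_toy_structure("ASLAAETAAL", "protein", "helix"))

rna5 <- function() fx("rna5", function()
  make_toy_structure("GGGCC", "rna"))

helix40_map <- function() fx("helix40_map", function()
  simulate_map(helix40(), resolution = 8, voxel = 2, box = 48,
               center = colMeans(helix40()$xyz)))

# central finite-difference check of an analytic gradient
fd_max_rel <- function(f, x, g, h = 1e-5, n = 20, seed = 1) {
  set.seed(seed)
  idx <- sample(length(x), min(n, length(x)))
  rel <- 0
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    num <- (f(xp) - f(xm)) / (2 * h)
    if (abs(num) < 1e-10 && abs(g[i]) < 1e-10) next
    rel <- max(rel, abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-8))
  }
  rel
}

# rigid-body transform of a coordinate matrix
rigid_move <- function(x, angle = 0.7, axis = c(1, 2, 3), shift = c(5, -3, 2)) {
  ax <- axis / sqrt(sum(axis^2))
  R <- gmmrefine:::rotvec_to_mat(ax * angle)
  sweep(x %*% t(R), 2, shift, "+")
}
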