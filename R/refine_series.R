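# Continuous model series refinement: the three decoders are conditioned
# on the latent conformation coordinate of each reconstruction (padded to
# the 4-vector decoder input, with small seeded Gaussian noise during
# training), trained jointly in three stages with persistent weights, then
# polished with geometry-only rounds over the latent trajectory. Unlike
# single-model refinement, the trained weights ARE the artifact: they map
# any latent point to a model.

#' Construct a conformation series
#'
#' @param latents M x d matrix (d <= 4) of latent conformation coordinates
#' @param maps list of M `density_map` objects sharing box and voxel size
#' @return a `conformation_series`
#' @export
conformation_series <- function(latents, maps) {
  latents <- as.matrix(latents)
  if (length(maps) != nrow(latents))
    stop("one latent point per reconstruction required")
  if (length(maps) < 2) stop("need at least 2 maps for a continuum")
  if (ncol(latents) > 4) stop("latent dimension must be <= 4")
  dm <- vapply(maps, function(m) c(dim(m$data), m$voxel), numeric(4))
  if (any(apply(dm, 1, function(r) max(r) - min(r)) > 1e-9))
    stop("all maps must share box and voxel size")
  structure(list(latents = latents, maps = maps),
            class = "conformation_series")
}

# pad latent rows to the 4-vector decoder input; unused slots are held at 1
# so the single-model constant input is the degenerate case
pad_latent <- function(L) {
  L <- rbind(L)
  d <- ncol(L)
  cbind(L, matrix(1, nrow(L), 4 - d))
}

#' Refine a continuous model series
#'
#' Trains the decoder stack conditioned on the latent coordinate of each
#' projection's source map: first the patch decoder alone, then patch +
#' residue with the basic geometry terms, then all three decoders with
#' every constraint. A small seeded Gaussian perturbation on the latent
#' input enforces continuity between the discretely sampled maps.
#'
#' @param model an `atomic_model` pre-refined against the neutral map
#' @param series a [conformation_series()]
#' @param config a [refinement_config()] (series defaults: 16
#'   projections per map)
#' @param noise_scale latent noise as a fraction of the latent range
#' @param projections_per_map projections made from each reconstruction
#' @return a `series_refiner`
#' @export
refine_series <- function(model, series, config = refinement_config(),
                          noise_scale = 0.05, projections_per_map = 16) {
  cfg <- config
  topo <- compile_topology(model, neighbor_k = cfg$neighbor_k)
  M <- length(series$maps)
  psets <- lapply(seq_len(M), function(m)
    make_projections(series$maps[[m]], projections_per_map,
                     seed = cfg$seed + m))
  # flatten into one projection set with a latent row per image
  images <- do.call(c, lapply(psets, `[[`, "images"))
  rots <- do.call(c, lapply(psets, `[[`, "rots"))
  pset <- structure(list(images = images, rots = rots,
                         pixel = psets[[1]]$pixel, center = psets[[1]]$center),
                    class = "projection_set")
  img_lat <- series$latents[rep(seq_len(M), each = projections_per_map), ,
                            drop = FALSE]
  lat_range <- apply(series$latents, 2, function(v) diff(range(v)))
  lat_range[lat_range == 0] <- 1
  noise_sd <- noise_scale * lat_range

  inputs <- function(batch) {
    L <- img_lat[batch, , drop = FALSE]
    L <- L + matrix(stats::rnorm(length(L), 0, rep(noise_sd, each = nrow(L))),
                    nrow(L))
    pad_latent(L)
  }

  x0 <- with_gmm_attrs(model$xyz, model, cfg$target_resolution)
  pp <- partition_patches(model, cfg$n_patches, cfg$seed)
  heads <- list(
    deform_head("group", groups = pp$atom_groups, x0 = model$xyz,
                width = cfg$width, seed = cfg$seed),
    deform_head("group", groups = residue_groups(model), x0 = model$xyz,
                width = cfg$width, seed = cfg$seed + 1),
    deform_head("atom", n_atoms = nrow(model$atoms), width = cfg$width,
                seed = cfg$seed + 2))
  gweight <- balance_weights(model, topo, pset, cfg)
  history <- list()

  # stage 1: patch decoder only, map term only
  st <- train_stage(x0, topo, pset, heads[1], cfg, "coarse",
                    geom_weights = GEOM_WEIGHTS_DEFAULT * 0, geom_scale = 0,
                    inputs = inputs)
  heads[[1]] <- st$heads[[1]]
  history$coarse <- st$history

  # stage 2: patch + residue decoders, basic geometry
  w_basic <- c(bond_angle = 1, planarity = 1, rama = 0, rotamer = 0,
               clash = 1, rna = 0)
  st <- train_stage(x0, topo, pset, heads[1:2], cfg, "residue",
                    geom_weights = w_basic, geom_scale = gweight,
                    inputs = inputs)
  heads[1:2] <- st$heads
  topo <- st$topo
  history$residue <- st$history

  # stage 3: all three decoders, all constraints
  st <- train_stage(x0, topo, pset, heads, cfg, "full",
                    geom_weights = GEOM_WEIGHTS_DEFAULT, geom_scale = gweight,
                    inputs = inputs)
  heads <- st$heads
  topo <- st$topo
  history$full <- st$history

  structure(list(heads = heads, x0 = x0, model = model, topo = topo,
                 cfg = cfg, latent_dim = ncol(series$latents),
                 trajectory = apply(series$latents, 2, range),
                 geometry_weight = gweight, noise_scale = noise_scale,
                 history = history),
            class = "series_refiner")
}

#' Geometry-only polish over the latent trajectory
#'
#' Additional training rounds with the geometry loss alone, on latent
#' inputs drawn uniformly over the trajectory range, so frames between the
#' sampled maps also meet the stereochemistry targets.
#'
#' @param refiner a `series_refiner`
#' @param iters polish iterations
#' @param trajectory 2 x d matrix of latent bounds (default: stored bounds)
#' @return the polished refiner
#' @export
geometry_polish <- function(refiner, iters = 400, trajectory = NULL) {
  cfg <- refiner$cfg
  cfg$neighbor_refresh <- 25   # latent-dependent contacts churn quickly
  traj <- if (is.null(trajectory)) refiner$trajectory else trajectory
  traj <- as.matrix(traj)
  d <- refiner$latent_dim
  inputs <- function(batch) {
    L <- vapply(seq_len(d), function(j)
      stats::runif(length(batch), traj[1, j], traj[2, j]),
      numeric(length(batch)))
    pad_latent(matrix(L, ncol = d))
  }
  # local polish: the coarse patch decoder is frozen so the large-scale
  # (map-facing) conformation is preserved; clashes get extra weight since
  # residual inter-frame contacts are the dominant defect at unsampled
  # latents
  w <- GEOM_WEIGHTS_DEFAULT
  w["clash"] <- 30
  st <- train_stage(refiner$x0, refiner$topo, NULL, refiner$heads[-1], cfg,
                    "polish", geom_weights = w,
                    geom_scale = 1, map_weight = 0, inputs = inputs,
                    iters = iters, lr = cfg$lr[["full"]],
                    frozen = refiner$heads[1])
  refiner$heads[-1] <- st$heads
  refiner$topo <- st$topo
  refiner$polish_history <- st$history
  refiner
}

#' Sample models along the latent space
#'
#' Deterministic decoder evaluation (no latent noise): one model per
#' latent point, sharing the input atom ordering.
#'
#' @param refiner a `series_refiner`
#' @param latents m x d matrix (or vector for d = 1) of latent points
#' @return list of `atomic_model` in input order
#' @export
sample_series <- function(refiner, latents) {
  latents <- as.matrix(latents)
  if (ncol(latents) != refiner$latent_dim)
    stop("latent dimensionality mismatch: refiner expects ",
         refiner$latent_dim)
  inp <- pad_latent(latents)
  lapply(seq_len(nrow(inp)), function(m) {
    x <- refiner$x0
    attr(x, "amps") <- NULL; attr(x, "width") <- NULL
    for (h in refiner$heads) {
      out <- decoder_forward(h$net, inp[m, ])
      x <- x + head_displacement(h, as.numeric(out), refiner$x0)
    }
    set_coords(refiner$model, x)
  })
}

#' Save / load a series refiner
#'
#' The decoder weights are the artifact of series refinement; reloading
#' reproduces sampled models bit-identically.
#'
#' @param refiner a `series_refiner`
#' @param path file path
#' @return `path` (save) or the refiner (load)
#' @export
refiner_save <- function(refiner, path) {
  saveRDS(refiner, path)
  invisible(path)
}

#' @rdname refiner_save
#' @export
refiner_load <- function(path) readRDS(path)
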