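# Single-model refinement: a five-step protocol driven by three small
# decoder networks. Step 1 precompiles topology; step 2 trains a patch-level
# decoder (K-means patches, map term only); step 3 adds a residue-level
# decoder and the basic geometry terms; step 4 rebuilds/optimizes sidechain
# rotamers; step 5 trains all decoders plus free chi torsions with every
# constraint. Each step's output model is the next step's baseline.

#' Refinement configuration
#'
#' @param target_resolution target resolution in Angstrom (FRC cutoff)
#' @param outlier_sigma bond/angle hinge activation (sigmas)
#' @param n_patches patches for the coarse morphing decoder
#' @param neighbor_k clash neighbor candidates per atom
#' @param neighbor_refresh neighbor list rebuild cadence (iterations)
#' @param batch_size projections per training iteration
#' @param n_projections projections made from the input map
#' @param iters iteration budget per trainable step (coarse, residue,
#'   rotamer, full)
#' @param lr Adam learning rates per trainable step
#' @param width decoder hidden width
#' @param rebuild_rotamers enumerate library rotamers against the map
#' @param seed master seed
#' @return a `refinement_config` list
#' @export
refinement_config <- function(target_resolution = 3, outlier_sigma = 4.5,
                              n_patches = 64, neighbor_k = 128,
                              neighbor_refresh = 100, batch_size = 4,
                              n_projections = 32,
                              iters = c(coarse = 400, residue = 300,
                                        rotamer = 200, full = 600),
                              lr = c(coarse = 0.002, residue = 0.002,
                                     rotamer = 0.005, full = 0.001),
                              width = 64, rebuild_rotamers = FALSE,
                              seed = 1) {
  structure(list(target_resolution = target_resolution,
                 outlier_sigma = outlier_sigma, n_patches = n_patches,
                 neighbor_k = neighbor_k, neighbor_refresh = neighbor_refresh,
                 batch_size = batch_size, n_projections = n_projections,
                 iters = iters, lr = lr, width = width,
                 rebuild_rotamers = rebuild_rotamers, seed = seed),
            class = "refinement_config")
}

#' K-means patch decomposition
#'
#' Residue centers of mass are clustered into `n_patches` groups; all atoms
#' of a residue share its patch.
#'
#' @param model an `atomic_model`
#' @param n_patches requested patches (lowered to the residue count)
#' @param seed clustering seed
#' @return list with `assignment` (per residue), `atom_groups` (list of
#'   atom index vectors), `centers`
#' @export
partition_patches <- function(model, n_patches = 64, seed = 1) {
  rid <- residue_ids(model)
  ridx <- split(seq_len(nrow(model$atoms)), factor(rid, levels = unique(rid)))
  rc <- t(vapply(ridx, function(i) colMeans(model$xyz[i, , drop = FALSE]),
                 numeric(3)))
  k <- min(n_patches, nrow(rc))
  set.seed(seed)
  km <- if (k == nrow(rc)) list(cluster = seq_len(k), centers = rc)
        else suppressWarnings(stats::kmeans(rc, k, iter.max = 100, nstart = 5))
  groups <- lapply(seq_len(k), function(g)
    sort(unlist(ridx[km$cluster == g], use.names = FALSE)))
  groups <- groups[lengths(groups) > 0]
  list(assignment = km$cluster, atom_groups = groups,
       centers = km$centers)
}

# residue-level groups (one group per residue)
residue_groups <- function(model) {
  rid <- residue_ids(model)
  unname(split(seq_len(nrow(model$atoms)), factor(rid, levels = unique(rid))))
}

# chi rotation machinery: axis and distal atom set per chi row
chi_info <- function(topo) {
  tab <- topo$chi
  if (is.null(tab)) return(NULL)
  edges <- topo$bond_idx
  adj <- list()
  for (q in seq_len(nrow(edges))) {
    i <- edges[q, 1]; j <- edges[q, 2]
    adj[[as.character(i)]] <- c(adj[[as.character(i)]], j)
    adj[[as.character(j)]] <- c(adj[[as.character(j)]], i)
  }
  ord <- order(tab$res, tab$chi)
  tab <- tab[ord, ]
  distal <- vector("list", nrow(tab))
  for (q in seq_len(nrow(tab))) {
    a2 <- tab$i2[q]; a3 <- tab$i3[q]
    seen <- c(a2, a3)
    queue <- setdiff(adj[[as.character(a3)]], seen)
    reach <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v); reach <- c(reach, v)
      queue <- c(queue, setdiff(adj[[as.character(v)]], seen))
    }
    distal[[q]] <- sort(reach)
  }
  list(tab = tab, distal = distal)
}

# apply chi deltas (degrees) sequentially (chi1 before chi2 within a residue)
apply_chi <- function(x, info, delta) {
  if (is.null(info) || !length(delta)) return(x)
  for (q in seq_along(delta)) {
    d <- delta[q]
    if (abs(d) < 1e-12) next
    p <- x[info$tab$i2[q], ]; ax <- x[info$tab$i3[q], ] - p
    ax <- ax / sqrt(sum(ax^2))
    R <- rotvec_to_mat(ax * deg2rad(d))
    i <- info$distal[[q]]
    x[i, ] <- sweep(sweep(x[i, , drop = FALSE], 2, p) %*% t(R), 2, p, "+")
  }
  x
}

# exact torsion gradient: dL/d(chi_q) from dL/dx at the current coords
chi_gradient <- function(x, info, dLdx) {
  g <- numeric(nrow(info$tab))
  for (q in seq_along(g)) {
    p <- x[info$tab$i2[q], ]; ax <- x[info$tab$i3[q], ] - p
    ax <- ax / sqrt(sum(ax^2))
    i <- info$distal[[q]]
    rel <- sweep(x[i, , drop = FALSE], 2, p)
    rot <- rowcross(matrix(ax, length(i), 3, byrow = TRUE), rel)
    g[q] <- sum(rot * dLdx[i, , drop = FALSE]) * pi / 180
  }
  g
}

# shared decoder training stage; `inputs` NULL means the constant
# single-model input [1,1,1,1]; otherwise a function(batch) returning one
# conformation row per batch image (series mode).
train_stage <- function(x0, topo, pset, heads, cfg, stage,
                        geom_weights, geom_scale, map_weight = 1,
                        chi = NULL, chi_vals = NULL, inputs = NULL,
                        iters = NULL, lr = NULL, frozen = list()) {
  if (is.null(iters)) iters <- cfg$iters[[stage]]
  if (is.null(lr)) lr <- cfg$lr[[stage]]
  set.seed(cfg$seed + match(stage, c("coarse", "residue", "rotamer", "full",
                                     "series", "polish")) * 1000L)
  gmm_amp <- attr(x0, "amps")
  opts <- lapply(heads, function(h) adam_new(decoder_params(h$net), lr))
  chi_opt <- if (!is.null(chi)) adam_new(list(chi = chi_vals), lr * 10)
  use_geom <- geom_scale > 0 && any(geom_weights > 0)
  n_img <- if (!is.null(pset)) length(pset$images) else 0
  # with no projections but conditioned inputs (geometry polish), iterate
  # over virtual samples so the input sampler still gets a batch
  virtual <- is.null(pset) && !is.null(inputs)
  if (virtual) n_img <- cfg$batch_size
  history <- numeric(0)

  current_coords <- function(inp_row, cv) {
    xc <- if (!is.null(chi)) apply_chi(x0, chi, cv) else x0
    for (h in frozen) {
      out <- decoder_forward(h$net, inp_row)
      xc <- xc + head_displacement(h, as.numeric(out), x0)
    }
    outs <- lapply(heads, function(h) decoder_forward(h$net, inp_row,
                                                      keep_cache = TRUE))
    for (k in seq_along(heads))
      xc <- xc + head_displacement(heads[[k]], as.numeric(outs[[k]]), x0)
    list(x = xc, outs = outs)
  }

  ones <- c(1, 1, 1, 1)
  for (it in seq_len(iters)) {
    batch <- if (n_img) sample.int(n_img, min(cfg$batch_size, n_img))
             else integer(0)
    inp <- if (is.null(inputs)) NULL else inputs(batch)
    if (use_geom && geom_weights["clash"] > 0 &&
        (is.null(topo$neighbor_idx) || it %% cfg$neighbor_refresh == 1 ||
         cfg$neighbor_refresh == 1)) {
      # refresh at a conformation of the current batch so latent-dependent
      # contacts are visible to the clash term
      ref_inp <- if (is.null(inp)) ones else inp[1, ]
      st <- current_coords(ref_inp, chi_vals)
      topo <- refresh_neighbors(st$x, topo)
    }
    loss_it <- 0
    gheads <- lapply(heads, function(h)
      lapply(decoder_params(h$net), function(p) p * 0))
    gchi <- if (!is.null(chi)) chi_vals * 0

    eval_one <- function(inp_row, imgs, weight) {
      st <- current_coords(inp_row, chi_vals)
      gx <- matrix(0, nrow(x0), 3)
      lv <- 0
      if (map_weight > 0 && length(imgs)) {
        gmm <- structure(list(centers = st$x, amplitudes = gmm_amp,
                              width = attr(x0, "width")),
                         class = "gaussian_mixture")
        fr <- frc_loss(gmm, pset, cfg$target_resolution, batch = imgs,
                       grad = TRUE)
        lv <- lv + map_weight * fr$value
        gx <- gx + map_weight * fr$g_centers
      }
      if (use_geom) {
        gl <- combined_geometry_loss(st$x, topo, geom_weights,
                                     cfg$outlier_sigma, grad = TRUE,
                                     clash_margin = 0.1)
        lv <- lv + geom_scale * gl$value
        gx <- gx + geom_scale * gl$grad
      }
      if (!is.finite(lv))
        stop("non-finite loss at ", stage, " iteration ", it)
      # backprop into decoder weights
      for (k in seq_along(heads)) {
        dpar <- head_backward(heads[[k]], as.numeric(st$outs[[k]]), x0, gx)
        gb <- decoder_backward(heads[[k]]$net, st$outs[[k]], rbind(dpar))
        gp <- decoder_grads_as_params(gb)
        for (nm in names(gp))
          gheads[[k]][[nm]] <<- gheads[[k]][[nm]] + weight * gp[[nm]]
      }
      if (!is.null(chi))
        gchi <<- gchi + weight * chi_gradient(st$x, chi, gx)
      loss_it <<- loss_it + weight * lv
      invisible(NULL)
    }

    if (is.null(inputs)) {
      eval_one(ones, batch, 1)
    } else {
      for (m in seq_along(batch))
        eval_one(inp[m, ], batch[m], 1 / length(batch))
    }

    for (k in seq_along(heads)) {
      pk <- decoder_params(heads[[k]]$net)
      stp <- adam_step(opts[[k]], pk, gheads[[k]])
      opts[[k]] <- stp$opt
      heads[[k]]$net <- decoder_set_params(heads[[k]]$net, stp$params)
    }
    if (!is.null(chi)) {
      stp <- adam_step(chi_opt, list(chi = chi_vals), list(chi = gchi))
      chi_opt <- stp$opt; chi_vals <- stp$params$chi
    }
    history <- c(history, loss_it)
  }
  final <- current_coords(ones, chi_vals)
  list(heads = heads, chi_vals = chi_vals, coords = final$x, topo = topo,
       history = history)
}

# attach GMM metadata used by the trainer to a coordinate matrix
with_gmm_attrs <- function(x, model, resolution) {
  gmm <- model_to_gmm(model, resolution)
  attr(x, "amps") <- gmm$amplitudes
  attr(x, "width") <- gmm$width
  x
}

#' Balance the map and geometry loss weights
#'
#' Runs two probe iterations of map-only patch refinement, measures the
#' ratio of the map-similarity gain to the geometry-likelihood degradation,
#' and returns its reciprocal as the geometry weight. The probe decoders
#' are discarded (the refinement restarts re-initialized).
#'
#' @param model an `atomic_model` (current baseline)
#' @param topo compiled topology
#' @param pset projection set of the target map
#' @param cfg a `refinement_config`
#' @return geometry weight scalar
#' @export
balance_weights <- function(model, topo, pset, cfg) {
  x0 <- with_gmm_attrs(model$xyz, model, cfg$target_resolution)
  pp <- partition_patches(model, cfg$n_patches, cfg$seed)
  heads <- list(deform_head("group", groups = pp$atom_groups, x0 = model$xyz,
                            width = cfg$width, seed = cfg$seed))
  topo2 <- refresh_neighbors(model$xyz, topo)
  gmm <- model_to_gmm(model, cfg$target_resolution)
  map0 <- map_model_frc(gmm, pset, cfg$target_resolution)
  geo0 <- geometry_likelihood(model$xyz, topo2)
  # the probe runs full-batch so two iterations give a reliable descent
  # direction and both deltas are measurable (the probe state is discarded)
  cfgp <- cfg
  cfgp$batch_size <- min(length(pset$images), 32)
  st <- train_stage(x0, topo2, pset, heads, cfgp, "coarse",
                    geom_weights = GEOM_WEIGHTS_DEFAULT * 0, geom_scale = 0,
                    iters = 2, lr = cfg$lr[["coarse"]])
  gmm$centers <- st$coords
  map1 <- map_model_frc(gmm, pset, cfg$target_resolution)
  geo1 <- geometry_likelihood(st$coords, topo2)
  dmap <- map1 - map0
  dgeo <- geo1 - geo0
  w <- balance_rule(dmap, dgeo)
  if (dgeo <= 1e-12 || dmap <= 0) return(w)   # fallback path, unclamped
  # a probe from a near-ideal-geometry start over- or under-estimates the
  # ratio (its geometry delta is curvature-dominated); clamp into the band
  # where the weighted geometry term moves within an order of magnitude of
  # the map term (measured on the bundled fixtures; methods vignette)
  min(max(w, 0.005), 0.05)
}

#' Geometry-weight balancing rule
#'
#' The probe ratio is the geometry degradation per unit of map-similarity
#' gain; the geometry weight is its reciprocal, so the weighted geometry
#' term moves at the map term's scale during training. A probe with no
#' geometry change falls back to weight 1 with a warning. The raw rule is
#' returned here; [balance_weights()] additionally clamps the computed
#' ratio into the band where map and weighted-geometry deltas actually
#' stay within an order of magnitude on desk-scale problems.
#'
#' @param dmap map-similarity gain over the two probe iterations
#' @param dgeo geometry-likelihood degradation over the same iterations
#' @return geometry weight scalar
#' @export
balance_rule <- function(dmap, dgeo) {
  if (dgeo <= 1e-12 || dmap <= 0) {
    warning("geometry score unchanged in probe; using default weight 1")
    return(1)
  }
  dmap / dgeo
}

#' Rebuild sidechain rotamers against a map
#'
#' For each chi-bearing residue, every library rotamer peak is instantiated
#' and scored by the local map density at its sidechain atoms; the best
#' peak is kept (ties keep the input rotamer). Without a map this is a
#' no-op.
#'
#' @param model an `atomic_model`
#' @param map a `density_map` (or NULL)
#' @param topo compiled topology
#' @return the model with reassigned chi angles
#' @export
rebuild_rotamers <- function(model, map, topo = NULL) {
  if (is.null(map)) return(model)
  if (is.null(topo)) topo <- compile_topology(model)
  info <- chi_info(topo)
  if (is.null(info)) return(model)
  x <- model$xyz
  for (r in unique(info$tab$res)) {
    rows <- which(info$tab$res == r)
    rt <- info$tab$res_name[rows[1]]
    pk <- rotamer_peaks(rt)
    if (is.null(pk)) next
    side <- sort(unique(unlist(info$distal[rows])))
    side <- c(side, info$tab$i3[rows])    # include the pivot atoms
    cur <- dihedrals(x, as.matrix(info$tab[rows, c("i1", "i2", "i3", "i4")]))$value
    score0 <- sum(map_trilinear(map, x[side, , drop = FALSE]))
    best <- NULL; best_s <- score0 + 1e-9
    for (p in seq_len(nrow(pk))) {
      dl <- numeric(length(cur))
      xt <- x
      for (qq in seq_along(rows)) {
        q <- rows[qq]
        curq <- dihedrals(xt, rbind(as.matrix(
          info$tab[q, c("i1", "i2", "i3", "i4")])))$value
        d <- wrap180(pk[p, qq] - curq)
        pax <- xt[info$tab$i2[q], ]; ax <- xt[info$tab$i3[q], ] - pax
        ax <- ax / sqrt(sum(ax^2))
        R <- rotvec_to_mat(ax * deg2rad(d))
        i <- info$distal[[q]]
        xt[i, ] <- sweep(sweep(xt[i, , drop = FALSE], 2, pax) %*% t(R), 2,
                         pax, "+")
      }
      s <- sum(map_trilinear(map, xt[side, , drop = FALSE]))
      if (s > best_s) { best_s <- s; best <- xt }
    }
    if (!is.null(best)) x <- best
  }
  set_coords(model, x)
}

# trilinear map interpolation at physical positions (rows of X)
map_trilinear <- function(map, X) {
  g <- sweep(X, 2, map$origin) / map$voxel
  n <- dim(map$data)
  v <- numeric(nrow(g))
  for (q in seq_len(nrow(g))) {
    p <- g[q, ]
    if (any(p < 0) || any(p > n - 2)) next
    i0 <- floor(p); f <- p - i0; i0 <- as.integer(i0) + 1L
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * map$data[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    v[q] <- acc
  }
  v
}

#' Refine a single model against a map
#'
#' The five-step protocol: (1) topology precompilation, (2) patch-level
#' morphing (map term only), (3) joint patch + residue refinement with the
#' basic geometry terms, (4) rotamer rebuild and chi optimization, (5) full
#' refinement with all three decoders, free chi torsions and every
#' constraint. With `geometry_only = TRUE` (or no map) only step 5 runs,
#' without the map term.
#'
#' @param model an `atomic_model`, roughly fitted to the map frame
#' @param map a `density_map` (optional if `projections` given)
#' @param projections a `projection_set` (made from `map` if missing)
#' @param config a [refinement_config()]
#' @param geometry_only skip the map entirely and only polish geometry
#' @return list with `model` (refined), `report` (a `geometry_report`),
#'   `geometry_weight`, `history`
#' @export
refine <- function(model, map = NULL, projections = NULL,
                   config = refinement_config(), geometry_only = FALSE) {
  cfg <- config
  templates <- load_templates()
  topo <- compile_topology(model, templates, neighbor_k = cfg$neighbor_k)
  have_map <- !geometry_only && (!is.null(map) || !is.null(projections))
  if (have_map && is.null(projections)) {
    if (cfg$target_resolution < 2 * map$voxel)
      stop("Nyquist violation: target resolution ", cfg$target_resolution,
           " A needs pixels at most half that; map voxel is ", map$voxel, " A")
    projections <- make_projections(map, cfg$n_projections, cfg$seed)
  }
  history <- list()
  cur <- model

  gweight <- 1
  if (have_map) {
    gweight <- balance_weights(cur, topo, projections, cfg)

    # step 2: large-scale patch morphing, map only
    x0 <- with_gmm_attrs(cur$xyz, cur, cfg$target_resolution)
    pp <- partition_patches(cur, cfg$n_patches, cfg$seed)
    heads <- list(deform_head("group", groups = pp$atom_groups, x0 = cur$xyz,
                              width = cfg$width, seed = cfg$seed))
    st <- train_stage(x0, topo, projections, heads, cfg, "coarse",
                      geom_weights = GEOM_WEIGHTS_DEFAULT * 0, geom_scale = 0)
    cur <- set_coords(cur, st$coords)
    history$coarse <- st$history

    # step 3: patch + residue decoders, basic geometry terms
    x0 <- with_gmm_attrs(cur$xyz, cur, cfg$target_resolution)
    pp <- partition_patches(cur, cfg$n_patches, cfg$seed)
    heads <- list(
      deform_head("group", groups = pp$atom_groups, x0 = cur$xyz,
                  width = cfg$width, seed = cfg$seed),
      deform_head("group", groups = residue_groups(cur), x0 = cur$xyz,
                  width = cfg$width, seed = cfg$seed + 1))
    w_basic <- c(bond_angle = 1, planarity = 1, rama = 0, rotamer = 0,
                 clash = 1, rna = 0)
    st <- train_stage(x0, topo, projections, heads, cfg, "residue",
                      geom_weights = w_basic, geom_scale = gweight)
    cur <- set_coords(cur, st$coords)
    topo <- st$topo
    history$residue <- st$history

    # step 4: rotamer rebuild + direct chi optimization
    if (cfg$rebuild_rotamers && !is.null(topo$chi)) {
      if (!is.null(map)) cur <- rebuild_rotamers(cur, map, topo)
      info <- chi_info(topo)
      x0 <- with_gmm_attrs(cur$xyz, cur, cfg$target_resolution)
      w_rot <- c(bond_angle = 1, planarity = 0, rama = 0, rotamer = 1,
                 clash = 1, rna = 0)
      st <- train_stage(x0, topo, projections, list(), cfg, "rotamer",
                        geom_weights = w_rot, geom_scale = gweight,
                        chi = info, chi_vals = numeric(nrow(info$tab)))
      cur <- set_coords(cur, st$coords)
      topo <- st$topo
      history$rotamer <- st$history
    }
  }

  # step 5: full-atom refinement with all constraints (runs map-free in
  # geometry-only mode)
  x0 <- with_gmm_attrs(cur$xyz, cur, cfg$target_resolution)
  pp <- partition_patches(cur, cfg$n_patches, cfg$seed)
  heads <- list(
    deform_head("group", groups = pp$atom_groups, x0 = cur$xyz,
                width = cfg$width, seed = cfg$seed),
    deform_head("group", groups = residue_groups(cur), x0 = cur$xyz,
                width = cfg$width, seed = cfg$seed + 1),
    deform_head("atom", n_atoms = nrow(cur$atoms),
                width = cfg$width, seed = cfg$seed + 2))
  info <- if (!is.null(topo$chi)) chi_info(topo)
  st <- train_stage(x0, topo, if (have_map) projections, heads, cfg, "full",
                    geom_weights = GEOM_WEIGHTS_DEFAULT, geom_scale = gweight,
                    map_weight = if (have_map) 1 else 0,
                    chi = info,
                    chi_vals = if (!is.null(info)) numeric(nrow(info$tab)))
  cur <- set_coords(cur, st$coords)
  topo <- st$topo
  history$full <- st$history

  list(model = cur, report = geometry_report(cur, topo),
       geometry_weight = gweight, history = history)
}
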