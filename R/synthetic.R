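# Synthetic fixtures: toy polypeptides / polynucleotides built from the
# shipped templates at ideal geometry, simulated density maps, seeded
# perturbations (hinge rotations, coordinate jitter), and two-state motion
# map series with ground-truth models. Everything is bit-reproducible from
# (spec, seed).

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

RECIPES <- list(helix = c(phi = -63, psi = -43),
                strand = c(phi = -118, psi = 132),
                extended = c(phi = -75, psi = 145))

# A-form RNA inter-residue backbone torsions (degrees)
AFORM <- c(alpha = -68, beta = 178, gamma = 54, epsilon = -153, zeta = -71)

tpl_dist <- function(tp, a, b) sqrt(sum((tp$xyz[a, ] - tp$xyz[b, ])^2))
tpl_angle <- function(tp, a, b, c_) {
  bond_angles(tp$xyz, cbind(match(a, rownames(tp$xyz)),
                            match(b, rownames(tp$xyz)),
                            match(c_, rownames(tp$xyz))))$value
}

#' Build a toy structure with ideal geometry
#'
#' Protein chains are built residue by residue from internal coordinates at
#' the recipe's backbone dihedrals, with sidechains grafted from the
#' templates and set to library rotamer peaks (greedily choosing the peak
#' with the fewest steric contacts against the already-built atoms). RNA
#' chains are built on an A-form backbone. The result scores zero outliers
#' in every geometry class.
#'
#' @param sequence 1-letter sequence (protein) or ACGU string (RNA)
#' @param type `"protein"` or `"rna"`
#' @param recipe backbone recipe for proteins: `"helix"`, `"strand"`,
#'   `"extended"`, or a length-2 vector c(phi, psi) in degrees
#' @param chain chain identifier
#' @param seed seed (rotamer tie-breaks are deterministic anyway)
#' @return an `atomic_model`
#' @export
make_toy_structure <- function(sequence, type = c("protein", "rna"),
                               recipe = "helix", chain = "A", seed = 1) {
  type <- match.arg(type)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (!length(letters1)) stop("empty sequence")
  templates <- load_templates()
  if (type == "protein") {
    bad <- setdiff(letters1, names(AA1TO3))
    if (length(bad)) stop("unknown residue letter(s): ",
                          paste(unique(bad), collapse = ", "))
    res3 <- AA1TO3[letters1]
    if (is.character(recipe)) {
      if (!recipe %in% names(RECIPES)) stop("unknown recipe: ", recipe)
      pp <- RECIPES[[recipe]]
    } else pp <- c(phi = recipe[1], psi = recipe[2])
    phis <- rep(pp["phi"], length(res3))
    phis[res3 == "PRO"] <- -65       # proline phi is ring-constrained
    build_protein(res3, phis, rep(pp["psi"], length(res3)), templates, chain)
  } else {
    bad <- setdiff(letters1, NT1)
    if (length(bad)) stop("unknown nucleotide letter(s): ",
                          paste(unique(bad), collapse = ", "))
    build_rna(letters1, templates, chain)
  }
}

build_protein <- function(res3, phis, psis, templates, chain = "A") {
  n <- length(res3)
  atoms <- list(); coords <- list()
  bbN <- bbCA <- bbC <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tp <- templates[[res3[i]]]
    if (i == 1) {
      dNCA <- tpl_dist(tp, "N", "CA"); dCAC <- tpl_dist(tp, "CA", "C")
      aNCAC <- tpl_angle(tp, "N", "CA", "C")
      bbN[1, ] <- c(0, 0, 0)
      bbCA[1, ] <- c(dNCA, 0, 0)
      th <- deg2rad(180 - aNCAC)
      bbC[1, ] <- bbCA[1, ] + dCAC * c(cos(th), sin(th), 0)
    } else {
      tpp <- templates[[res3[i - 1]]]
      bbN[i, ] <- nerf_place(bbN[i - 1, ], bbCA[i - 1, ], bbC[i - 1, ],
                             PEPTIDE_BOND["mu"], INTER_ANGLES[["CA|C|N"]][1],
                             psis[i - 1])
      bbCA[i, ] <- nerf_place(bbCA[i - 1, ], bbC[i - 1, ], bbN[i, ],
                              tpl_dist(tp, "N", "CA"),
                              INTER_ANGLES[["C|N|CA"]][1], 180)
      bbC[i, ] <- nerf_place(bbC[i - 1, ], bbN[i, ], bbCA[i, ],
                             tpl_dist(tp, "CA", "C"),
                             tpl_angle(tp, "N", "CA", "C"), phis[i])
    }
  }
  built_xyz <- NULL
  for (i in seq_len(n)) {
    tp <- templates[[res3[i]]]
    k <- kabsch(tp$xyz[c("N", "CA", "C"), ],
                rbind(bbN[i, ], bbCA[i, ], bbC[i, ]))
    hx <- tp$xyz[tp$atom_names, , drop = FALSE] %*% k$R
    hx <- sweep(hx, 2, k$t, "+")
    rownames(hx) <- tp$atom_names
    hx["N", ] <- bbN[i, ]; hx["CA", ] <- bbCA[i, ]; hx["C", ] <- bbC[i, ]
    # carbonyl O in the peptide plane, anti to the next N (psi + 180)
    hx["O", ] <- nerf_place(bbN[i, ], bbCA[i, ], bbC[i, ],
                            tpl_dist(tp, "C", "O"),
                            tpl_angle(tp, "CA", "C", "O"), psis[i] + 180)
    # sidechain rotamer: greedy peak choice against already-built atoms
    # proline keeps its template ring; other sidechains get a library peak
    pk <- if (res3[i] == "PRO") NULL else rotamer_peaks(res3[i])
    if (!is.null(pk))
      hx <- set_template_chis(hx, tp, pick_rotamer(hx, tp, pk, built_xyz))
    atoms[[i]] <- data.frame(atom = unname(tp$atom_names),
                             element = unname(element_from_tpl(tp)),
                             res_name = unname(res3[i]), res_seq = i, ins = "",
                             chain = chain, occ = 1, stringsAsFactors = FALSE)
    coords[[i]] <- hx
    built_xyz <- rbind(built_xyz, hx)
  }
  atomic_model(do.call(rbind, atoms), do.call(rbind, coords))
}

element_from_tpl <- function(tp) {
  e <- substr(tp$atom_names, 1, 1)
  ifelse(e %in% c("C", "N", "O", "S", "P"), e, "C")
}

# rotate the template-grafted sidechain to the target chi vector
set_template_chis <- function(hx, tp, target) {
  cd <- tp$chi_definitions
  if (is.null(cd)) return(hx)
  bonds <- tp$bonds
  adj <- split(c(bonds$a2, bonds$a1), c(bonds$a1, bonds$a2))
  for (q in seq_len(nrow(cd))) {
    quad <- c(cd$a1[q], cd$a2[q], cd$a3[q], cd$a4[q])
    cur <- dihedrals(hx, rbind(match(quad, rownames(hx))))$value
    d <- wrap180(target[q] - cur)
    if (abs(d) < 1e-9) next
    # distal atoms: connected to a3 without passing through a2
    seen <- c(cd$a2[q], cd$a3[q])
    queue <- setdiff(adj[[cd$a3[q]]], seen)
    reach <- character(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% seen) next
      seen <- c(seen, v); reach <- c(reach, v)
      queue <- c(queue, setdiff(adj[[v]], seen))
    }
    p <- hx[cd$a2[q], ]; ax <- hx[cd$a3[q], ] - p
    ax <- ax / sqrt(sum(ax^2))
    R <- rotvec_to_mat(ax * deg2rad(d))
    reach <- intersect(reach, rownames(hx))
    hx[reach, ] <- sweep(sweep(hx[reach, , drop = FALSE], 2, p) %*% t(R),
                         2, p, "+")
  }
  hx
}

pick_rotamer <- function(hx, tp, pk, built_xyz) {
  vdw <- load_vdw()
  side <- setdiff(rownames(hx), c("N", "CA", "C", "O"))
  if (!length(side)) return(pk[1, ])
  # intra-residue pairs more than 3 covalent bonds apart (template graph)
  nm <- rownames(hx)
  adj <- split(c(tp$bonds$a2, tp$bonds$a1), c(tp$bonds$a1, tp$bonds$a2))
  near3 <- lapply(nm, function(a) {
    d1 <- adj[[a]]; d2 <- unique(unlist(adj[d1])); d3 <- unique(unlist(adj[d2]))
    unique(c(a, d1, d2, d3))
  })
  names(near3) <- nm
  rad <- vdw[element_from_tpl(tp)]
  names(rad) <- nm
  best <- 1; best_n <- Inf
  for (p in seq_len(nrow(pk))) {
    cand <- set_template_chis(hx, tp, pk[p, ])
    ncl <- 0
    for (a in side) for (b in nm) {
      if (a == b || (b %in% side && a > b) || b %in% near3[[a]]) next
      d <- sqrt(sum((cand[a, ] - cand[b, ])^2))
      if (d < rad[a] + rad[b] - 0.4) ncl <- ncl + 1
    }
    if (!is.null(built_xyz)) {
      d <- as.matrix(stats::dist(rbind(cand[side, , drop = FALSE], built_xyz)))
      ns <- length(side)
      ncl <- ncl + sum(d[seq_len(ns), -seq_len(ns), drop = FALSE] < 2.9)
    }
    if (ncl < best_n) { best_n <- ncl; best <- p }
    if (best_n == 0) break
  }
  pk[best, ]
}

build_rna <- function(letters1, templates, chain = "A") {
  n <- length(letters1)
  atoms <- list(); coords <- list()
  prev <- NULL  # previous residue's placed coords (named)
  for (i in seq_len(n)) {
    tp <- templates[[letters1[i]]]
    if (i == 1) {
      hx <- tp$xyz[tp$atom_names, , drop = FALSE]
    } else {
      P <- nerf_place(prev["C4'", ], prev["C3'", ], prev["O3'", ],
                      PHOSPHODIESTER_BOND["mu"],
                      INTER_ANGLES[["C3'|O3'|P"]][1], AFORM["epsilon"])
      O5 <- nerf_place(prev["C3'", ], prev["O3'", ], P,
                       tpl_dist(tp, "P", "O5'"),
                       INTER_ANGLES[["O3'|P|O5'"]][1], AFORM["zeta"])
      C5 <- nerf_place(prev["O3'", ], P, O5, tpl_dist(tp, "O5'", "C5'"),
                       tpl_angle(tp, "P", "O5'", "C5'"), AFORM["alpha"])
      C4 <- nerf_place(P, O5, C5, tpl_dist(tp, "C5'", "C4'"),
                       tpl_angle(tp, "O5'", "C5'", "C4'"), AFORM["beta"])
      C3 <- nerf_place(O5, C5, C4, tpl_dist(tp, "C4'", "C3'"),
                       tpl_angle(tp, "C5'", "C4'", "C3'"), AFORM["gamma"])
      k <- kabsch(tp$xyz[c("C5'", "C4'", "C3'"), ], rbind(C5, C4, C3))
      hx <- sweep(tp$xyz[tp$atom_names, , drop = FALSE] %*% k$R, 2, k$t, "+")
      rownames(hx) <- tp$atom_names
      hx["C5'", ] <- C5; hx["C4'", ] <- C4; hx["C3'", ] <- C3
      hx["O5'", ] <- O5; hx["P", ] <- P
      # phosphate oxygens about the placed P
      hx["OP1", ] <- nerf_place(prev["O3'", ], O5, P,
                                tpl_dist(tp, "P", "OP1"),
                                tpl_angle(tp, "O5'", "P", "OP1"), 115)
      hx["OP2", ] <- nerf_place(prev["O3'", ], O5, P,
                                tpl_dist(tp, "P", "OP2"),
                                tpl_angle(tp, "O5'", "P", "OP2"), -130)
    }
    atoms[[i]] <- data.frame(atom = unname(tp$atom_names),
                             element = unname(element_from_tpl(tp)),
                             res_name = letters1[i], res_seq = i, ins = "",
                             chain = chain, occ = 1, stringsAsFactors = FALSE)
    coords[[i]] <- hx
    prev <- hx
  }
  atomic_model(do.call(rbind, atoms), do.call(rbind, coords))
}

#' Simulate a density map from a model
#'
#' Gaussian density per heavy atom (amplitude proportional to atomic
#' number, width set from the stated resolution), accumulated on a cubic
#' grid; optional white noise.
#'
#' @param model an `atomic_model`
#' @param resolution emulated resolution, Angstrom
#' @param voxel voxel size, Angstrom
#' @param box grid side length (voxels)
#' @param center physical center of the box (default: model centroid)
#' @param noise_sd white-noise sigma relative to the map maximum
#' @param seed noise seed
#' @return a [density_map()]
#' @export
simulate_map <- function(model, resolution = 8, voxel = 2, box = 48,
                         center = NULL, noise_sd = 0, seed = 1) {
  if (is.null(center)) center <- colMeans(model$xyz)
  rel <- sweep(model$xyz, 2, center)
  half <- box / 2 * voxel
  if (any(abs(rel) > half - 2 * voxel))
    stop("model does not fit in the simulation box")
  gmm <- model_to_gmm(model, resolution)
  vol <- cpp_simulate_map(rel, gmm$amplitudes, gmm$width,
                          as.integer(box), voxel)
  arr <- array(vol, dim = c(box, box, box))
  if (noise_sd > 0) {
    set.seed(seed)
    arr <- arr + stats::rnorm(length(arr), 0, noise_sd * max(arr))
  }
  density_map(arr, voxel, origin = center - (box %/% 2) * voxel)
}

#' Perturb a model (hinge rotation and/or jitter)
#'
#' @param model an `atomic_model`
#' @param hinge list with `residues` (residue sequence numbers to rotate),
#'   `angle` (degrees), and optional `axis` (length-3) and `origin`
#'   (defaults: z axis through the first hinge residue's first atom)
#' @param jitter_sd per-coordinate Gaussian jitter sigma, Angstrom
#' @param seed jitter seed
#' @return the perturbed model; attribute `rmsd` holds the RMSD to the input
#' @export
perturb <- function(model, hinge = NULL, jitter_sd = 0, seed = 1) {
  x <- model$xyz
  if (!is.null(hinge)) {
    sel <- which(model$atoms$res_seq %in% hinge$residues)
    if (!length(sel)) stop("empty hinge residue range")
    ax <- if (is.null(hinge$axis)) c(0, 0, 1) else hinge$axis
    ax <- ax / sqrt(sum(ax^2))
    org <- if (is.null(hinge$origin)) x[sel[1], ] else hinge$origin
    R <- rotvec_to_mat(ax * deg2rad(hinge$angle))
    x[sel, ] <- sweep(sweep(x[sel, , drop = FALSE], 2, org) %*% t(R),
                      2, org, "+")
  }
  if (jitter_sd > 0) {
    set.seed(seed)
    x <- x + matrix(stats::rnorm(length(x), 0, jitter_sd), nrow(x), 3)
  }
  out <- set_coords(model, x)
  attr(out, "rmsd") <- coord_rmsd(model$xyz, x)
  out
}

#' Locally re-idealize selected residues (geometry-only minimization)
#'
#' Direct Adam minimization of the geometry loss with gradients masked to
#' the selected residues' atoms; used to heal hinge junctions so that
#' ground-truth fixtures are outlier-free.
#'
#' @param model an `atomic_model`
#' @param residues residue sequence numbers allowed to move
#' @param iters optimization iterations
#' @param lr Adam learning rate (Angstrom scale)
#' @return the re-idealized model
#' @export
idealize_local <- function(model, residues, iters = 300, lr = 0.01) {
  topo <- compile_topology(model)
  topo <- refresh_neighbors(model$xyz, topo)
  mask <- model$atoms$res_seq %in% residues
  x <- model$xyz
  opt <- adam_new(list(x = x * 0), lr)
  for (it in seq_len(iters)) {
    gl <- combined_geometry_loss(x, topo, grad = TRUE, clash_margin = 0.1)
    g <- gl$grad
    g[!mask, ] <- 0
    st <- adam_step(opt, list(x = x), list(x = g))
    opt <- st$opt; x <- st$params$x
  }
  set_coords(model, x)
}

#' Build a two-state hinge-motion map series
#'
#' States interpolate the hinge angle uniformly; every map shares one box
#' and physical frame; latents are the normalized state index in [0, 1].
#'
#' @param model an `atomic_model` (the neutral state)
#' @param hinge hinge spec as in [perturb()] (`angle` = total sweep)
#' @param n_states number of states (>= 2)
#' @param resolution,voxel,box map simulation parameters
#' @param idealize_junction re-idealize the two junction residues of the
#'   ground-truth models
#' @return list with `series` (a `conformation_series`: `latents`, `maps`)
#'   and `truth` (list of ground-truth models)
#' @export
make_motion_series <- function(model, hinge, n_states = 5, resolution = 8,
                               voxel = 2, box = 48,
                               idealize_junction = TRUE) {
  stopifnot(n_states >= 2)
  angles <- seq(0, hinge$angle, length.out = n_states)
  center <- colMeans(model$xyz)
  jres <- range(hinge$residues)
  junction <- (jres[1] - 3):(jres[1] + 2)
  truth <- lapply(angles, function(a) {
    h <- hinge; h$angle <- a
    m <- perturb(model, hinge = h)
    if (idealize_junction && a != 0)
      m <- idealize_local(m, junction, iters = 200)
    m
  })
  maps <- lapply(truth, simulate_map, resolution = resolution, voxel = voxel,
                 box = box, center = center)
  series <- structure(list(latents = matrix(seq(0, 1, length.out = n_states)),
                           maps = maps),
                      class = "conformation_series")
  list(series = series, truth = truth)
}
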