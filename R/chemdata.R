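# Bundled chemical reference tables: residue templates (atoms, ideal
# coordinates including hydrogens, bonds), chi definitions, planar groups,
# VdW radii, and the RNA suite library. Templates are compiled per model
# into flat index tables (TopologyTables) used by the differentiable
# geometry scores.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
NT1 <- c("A", "C", "G", "U")

# default restraint sigmas (stated in the methods vignette)
BOND_SIGMA <- 0.02     # Angstrom
ANGLE_SIGMA <- 2.0     # degrees
PEPTIDE_BOND <- c(mu = 1.329, sigma = 0.014)        # C(i)-N(i+1)
PHOSPHODIESTER_BOND <- c(mu = 1.607, sigma = 0.015) # O3'(i)-P(i+1)
# inter-residue angle ideals keyed by "a|b|c" atom names across the link
INTER_ANGLES <- list(
  "CA|C|N" = c(117.2, 2.2), "O|C|N" = c(122.7, 1.6),
  "C|N|CA" = c(121.7, 2.5), "C|N|CD" = c(126.0, 2.5),
  "C3'|O3'|P" = c(120.5, 2.0), "O3'|P|O5'" = c(104.0, 2.0),
  "O3'|P|OP1" = c(108.0, 3.0), "O3'|P|OP2" = c(108.0, 3.0))

ext_file <- function(...) {
  system.file("extdata", ..., package = "gmmrefine", mustWork = TRUE)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load the bundled residue templates
#'
#' Reads the shipped reference tables and assembles one template per residue
#' type: the 20 amino acids and 4 RNA nucleotides. Each template carries the
#' ordered atom list with ideal coordinates (hydrogens included), the bond
#' list with ideal lengths and sigmas, all bond angles derived from the bond
#' graph with ideal values from the ideal coordinates, planarity groups,
#' chi definitions and hydrogen internal-coordinate placements.
#'
#' @param dialect name of the bundled table set; only `"default"` is shipped
#' @return a named list of residue templates (class `residue_templates`)
#' @export
load_templates <- function(dialect = "default") {
  if (!identical(dialect, "default"))
    stop("unknown template dialect: ", dialect)
  cache <- .gmmrefine_cache
  if (!is.null(cache$templates)) return(cache$templates)

  atoms <- read_tsv(ext_file("residue_atoms.tsv"))
  bonds <- read_tsv(ext_file("residue_bonds.tsv"))
  chis <- read_tsv(ext_file("chi_definitions.tsv"))
  planar <- read_tsv(ext_file("planar_groups.tsv"))

  tpl <- list()
  for (res in c(AA3, NT1)) {
    at <- atoms[atoms$res == res, ]
    bd <- bonds[bonds$res == res, ]
    xyz <- as.matrix(at[, c("x", "y", "z")])
    rownames(xyz) <- at$atom
    is_h <- at$element == "H"
    heavy <- at$atom[!is_h]

    # polymeric amino acids keep a single amide H; PRO has none
    if (res %in% AA3) {
      drop_h <- character(0)
      if (res == "PRO") drop_h <- c(drop_h, "H")
      keep <- !(at$atom %in% drop_h)
      at <- at[keep, ]; bd <- bd[bd$atom1 %in% at$atom & bd$atom2 %in% at$atom, ]
      xyz <- xyz[at$atom, , drop = FALSE]; is_h <- at$element == "H"
    }

    # heavy-atom bond list with ideal lengths from the ideal coordinates
    hb <- bd[bd$atom1 %in% heavy & bd$atom2 %in% heavy, ]
    blen <- rownorm(xyz[hb$atom2, , drop = FALSE] - xyz[hb$atom1, , drop = FALSE])
    bonds_df <- data.frame(a1 = hb$atom1, a2 = hb$atom2, mu = blen,
                           sigma = BOND_SIGMA, stringsAsFactors = FALSE)

    # all heavy-atom angle triples from the intra-residue bond graph
    adj <- split(c(hb$atom2, hb$atom1), c(hb$atom1, hb$atom2))
    ang <- list()
    for (b in names(adj)) {
      nb <- sort(unique(adj[[b]]))
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        for (q in seq_len(ncol(cmb)))
          ang[[length(ang) + 1]] <- c(cmb[1, q], b, cmb[2, q])
      }
    }
    if (length(ang)) {
      am <- do.call(rbind, ang)
      av <- bond_angles(xyz, cbind(match(am[, 1], rownames(xyz)),
                                   match(am[, 2], rownames(xyz)),
                                   match(am[, 3], rownames(xyz))))$value
      angles_df <- data.frame(a1 = am[, 1], a2 = am[, 2], a3 = am[, 3],
                              mu = av, sigma = ANGLE_SIGMA,
                              stringsAsFactors = FALSE)
    } else angles_df <- NULL

    # planarity groups: quads are bonded 4-atom paths within the group
    pg <- planar[planar$res == res, ]
    planar_quads <- NULL
    if (nrow(pg)) {
      for (g in seq_len(nrow(pg))) {
        gat <- strsplit(pg$atoms[g], ",")[[1]]
        gat <- gat[gat %in% at$atom]
        quads <- bonded_paths4(hb, gat)
        if (!is.null(quads)) {
          dv <- dihedrals(xyz, cbind(match(quads[, 1], rownames(xyz)),
                                     match(quads[, 2], rownames(xyz)),
                                     match(quads[, 3], rownames(xyz)),
                                     match(quads[, 4], rownames(xyz))))$value
          ideal <- ifelse(abs(wrap180(dv)) < 90, 0, 180)
          planar_quads <- rbind(planar_quads,
            data.frame(a1 = quads[, 1], a2 = quads[, 2], a3 = quads[, 3],
                       a4 = quads[, 4], class = "other_planar", ideal = ideal,
                       stringsAsFactors = FALSE))
        }
      }
    }

    # hydrogen placements: internal coordinates from the ideal geometry
    hp <- NULL
    hat <- at$atom[is_h]
    if (length(hat)) {
      full_adj <- split(c(bd$atom2, bd$atom1), c(bd$atom1, bd$atom2))
      hp <- hydrogen_placements(res, hat, full_adj, xyz, heavy)
    }

    chi_df <- chis[chis$res == res, c("chi", "a1", "a2", "a3", "a4")]
    tpl[[res]] <- list(
      residue_name = res,
      type = if (res %in% AA3) "protein" else "rna",
      atom_names = heavy,
      xyz = xyz,
      bonds = bonds_df,
      angles = angles_df,
      planar = planar_quads,
      chi_definitions = if (nrow(chi_df)) chi_df else NULL,
      h_placements = hp)
  }
  class(tpl) <- "residue_templates"
  cache$templates <- tpl
  tpl
}

# environment-level cache (templates are deterministic)
.gmmrefine_cache <- new.env(parent = emptyenv())

# enumerate bonded 4-atom paths a-b-c-d restricted to a planar group
bonded_paths4 <- function(bonds, group) {
  eb <- bonds[bonds$atom1 %in% group & bonds$atom2 %in% group, ]
  if (!nrow(eb)) return(NULL)
  adj <- split(c(eb$atom2, eb$atom1), c(eb$atom1, eb$atom2))
  out <- list()
  for (b in group) for (c_ in setdiff(adj[[b]], b)) {
    if (!c_ %in% group) next
    for (a in setdiff(adj[[b]], c(b, c_))) for (d in setdiff(adj[[c_]], c(b, a, c_))) {
      if (!(a %in% group) || !(d %in% group)) next
      key <- paste(sort(c(a, b, c_, d)), collapse = "|")
      if (a < d)  # one orientation per path
        out[[paste(a, b, c_, d)]] <- c(a, b, c_, d)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# derive NeRF internal coordinates for each hydrogen from ideal coordinates
hydrogen_placements <- function(res, hat, adj, xyz, heavy) {
  rows <- list()
  for (h in hat) {
    b <- intersect(adj[[h]], heavy)
    if (length(b) != 1) next
    if (res %in% AA3 && h == "H" && b == "N") {
      # backbone amide H: referenced to the previous residue's C
      rows[[h]] <- data.frame(h = h, b = b, c = "CA", a = "-C",
                              dist = rownorm(rbind(xyz[h, ] - xyz[b, ])),
                              ang = 118.2, tor = 180, stringsAsFactors = FALSE)
      next
    }
    cns <- setdiff(intersect(adj[[b]], heavy), h)
    if (!length(cns)) next
    c_ <- sort(cns)[1]
    ans <- setdiff(intersect(adj[[c_]], heavy), b)
    if (!length(ans)) { # linear fragment; fall back to another H-free frame
      ans <- setdiff(cns, c_)
      if (!length(ans)) next
      a_ <- sort(ans)[1]
    } else a_ <- sort(ans)[1]
    p <- rbind(xyz[h, ])
    d <- rownorm(rbind(p - xyz[b, ]))
    angv <- bond_angles(xyz, cbind(match(c_, rownames(xyz)),
                                   match(b, rownames(xyz)),
                                   match(h, rownames(xyz))))$value
    torv <- dihedrals(xyz, cbind(match(a_, rownames(xyz)),
                                 match(c_, rownames(xyz)),
                                 match(b, rownames(xyz)),
                                 match(h, rownames(xyz))))$value
    rows[[h]] <- data.frame(h = h, b = b, c = c_, a = a_, dist = d,
                            ang = angv, tor = torv, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Load the bundled van der Waals radius table
#'
#' @param dialect table set name, `"default"` only
#' @return named numeric vector of radii (Angstrom) keyed by element
#' @export
load_vdw <- function(dialect = "default") {
  if (!identical(dialect, "default"))
    stop("unknown VdW dialect: ", dialect)
  v <- read_tsv(ext_file("vdw_radii.tsv"))
  r <- stats::setNames(v$radius, v$atom_type)
  stopifnot(all(r > 0.8 & r < 2.5))
  r
}

#' Load the synthetic RNA suite library
#'
#' 46 cluster centers in the 7D backbone-dihedral space
#' (delta-1, epsilon-1, zeta-1, alpha, beta, gamma, delta). The first center
#' is the canonical A-form suite; the rest are a synthetic stand-in for the
#' reference suite set (see the package vignette).
#'
#' @param assignment_threshold scores below this never count as assigned
#' @param width Gaussian kernel width per angle, degrees
#' @return object of class `suite_library`
#' @export
load_suites <- function(assignment_threshold = 0.001, width = 28) {
  s <- read_tsv(ext_file("rna_suites_synthetic.tsv"))
  centers <- as.matrix(s[, -1])
  rownames(centers) <- s$suite
  structure(list(centers = centers, threshold = assignment_threshold,
                 width = width), class = "suite_library")
}

residue_ids <- function(model) {
  paste(model$atoms$chain, model$atoms$res_seq, model$atoms$ins, sep = "|")
}

#' Compile per-model topology tables
#'
#' Turns templates plus an atomic model into flat integer index tables:
#' bonds, angles, planar quads, phi/psi/omega backbone quads, chi quads,
#' RNA backbone dihedral quads, hydrogen placements, and the clash neighbor
#' candidate list. Inter-residue peptide / phosphodiester bonds are added
#' between consecutive residues of a chain; a consecutive pair whose link
#' distance exceeds 2.5 Angstrom is treated as a chain break (no link, a
#' message is logged).
#'
#' @param model an `atomic_model`
#' @param templates result of [load_templates()]
#' @param neighbor_k number of clash neighbor candidates per atom
#' @param verbose print chain-break messages
#' @return object of class `topology_tables`
#' @export
compile_topology <- function(model, templates = load_templates(),
                             neighbor_k = 128, verbose = FALSE) {
  at <- model$atoms
  stopifnot(all(is.finite(model$xyz)))
  rid <- residue_ids(model)
  ridx <- split(seq_len(nrow(at)), factor(rid, levels = unique(rid)))
  res_names <- vapply(ridx, function(i) at$res_name[i[1]], "")
  res_chain <- vapply(ridx, function(i) at$chain[i[1]], "")
  nres <- length(ridx)

  miss <- setdiff(unique(res_names), names(templates))
  if (length(miss))
    stop("no template for residue type(s): ", paste(miss, collapse = ", "))

  glob <- function(r, nm) {  # residue-local atom name -> global index
    i <- ridx[[r]]
    i[match(nm, at$atom[i])]
  }

  bond_i <- list(); bond_mu <- list(); bond_sd <- list()
  ang_i <- list(); ang_mu <- list(); ang_sd <- list()
  pl_i <- list(); pl_cls <- list(); pl_ideal <- list()
  chi_rows <- list()
  h_rows <- list()

  for (r in seq_len(nres)) {
    tp <- templates[[res_names[r]]]
    present <- at$atom[ridx[[r]]]
    bd <- tp$bonds[tp$bonds$a1 %in% present & tp$bonds$a2 %in% present, ]
    if (nrow(bd)) {
      bond_i[[r]] <- cbind(glob(r, bd$a1), glob(r, bd$a2))
      bond_mu[[r]] <- bd$mu; bond_sd[[r]] <- bd$sigma
    }
    an <- tp$angles
    if (!is.null(an)) {
      an <- an[an$a1 %in% present & an$a2 %in% present & an$a3 %in% present, ]
      if (nrow(an)) {
        ang_i[[r]] <- cbind(glob(r, an$a1), glob(r, an$a2), glob(r, an$a3))
        ang_mu[[r]] <- an$mu; ang_sd[[r]] <- an$sigma
      }
    }
    pq <- tp$planar
    if (!is.null(pq)) {
      pq <- pq[pq$a1 %in% present & pq$a2 %in% present &
               pq$a3 %in% present & pq$a4 %in% present, ]
      if (nrow(pq)) {
        pl_i[[r]] <- cbind(glob(r, pq$a1), glob(r, pq$a2),
                           glob(r, pq$a3), glob(r, pq$a4))
        pl_cls[[r]] <- pq$class; pl_ideal[[r]] <- pq$ideal
      }
    }
    cd <- tp$chi_definitions
    if (!is.null(cd)) {
      ok <- cd$a1 %in% present & cd$a2 %in% present &
            cd$a3 %in% present & cd$a4 %in% present
      cd <- cd[ok, ]
      if (nrow(cd))
        chi_rows[[r]] <- data.frame(
          res = r, chi = cd$chi, res_name = res_names[r],
          i1 = glob(r, cd$a1), i2 = glob(r, cd$a2),
          i3 = glob(r, cd$a3), i4 = glob(r, cd$a4), row.names = NULL)
    }
    hp <- tp$h_placements
    if (!is.null(hp)) h_rows[[r]] <- data.frame(res = r, hp)
  }

  # inter-residue links and backbone dihedral quads
  omega_q <- list(); phi_q <- list(); psi_q <- list()
  rna_rows <- list()
  linked <- rep(FALSE, nres)  # residue r linked to r-1
  for (r in seq_len(nres - 1)) {
    if (res_chain[r] != res_chain[r + 1]) next
    tpa <- templates[[res_names[r]]]; tpb <- templates[[res_names[r + 1]]]
    if (tpa$type != tpb$type) next
    if (tpa$type == "protein") { a1 <- "C"; a2 <- "N"; ref <- PEPTIDE_BOND }
    else { a1 <- "O3'"; a2 <- "P"; ref <- PHOSPHODIESTER_BOND }
    i1 <- glob(r, a1); i2 <- glob(r + 1, a2)
    if (is.na(i1) || is.na(i2)) next
    dd <- sqrt(sum((model$xyz[i1, ] - model$xyz[i2, ])^2))
    if (dd > 2.5) {
      if (verbose) message("chain break between residues ", r, " and ", r + 1,
                           " (", round(dd, 2), " A)")
      next
    }
    linked[r + 1] <- TRUE
    k <- length(bond_i) + 1
    bond_i[[k]] <- cbind(i1, i2)
    bond_mu[[k]] <- ref["mu"]; bond_sd[[k]] <- ref["sigma"]
    # inter-residue angles around the link
    bonded_in <- function(tp, x, y) {
      any((tp$bonds$a1 == x & tp$bonds$a2 == y) |
          (tp$bonds$a1 == y & tp$bonds$a2 == x))
    }
    for (key in names(INTER_ANGLES)) {
      p <- strsplit(key, "|", fixed = TRUE)[[1]]
      if (p[2] == a1 && p[3] == a2) {        # x - C | N  (angle at C in res r)
        if (!bonded_in(tpa, p[1], a1)) next
        ia <- glob(r, p[1]); ib <- i1; ic <- i2
      } else if (p[1] == a1 && p[2] == a2) { # C | N - x  (angle at N in res r+1)
        if (!bonded_in(tpb, a2, p[3])) next
        ia <- i1; ib <- i2; ic <- glob(r + 1, p[3])
      } else next
      if (any(is.na(c(ia, ib, ic)))) next
      k2 <- length(ang_i) + 1
      ang_i[[k2]] <- cbind(ia, ib, ic)
      ang_mu[[k2]] <- INTER_ANGLES[[key]][1]
      ang_sd[[k2]] <- INTER_ANGLES[[key]][2]
    }
    if (tpa$type == "protein") {
      q <- c(glob(r, "CA"), glob(r, "C"), glob(r + 1, "N"), glob(r + 1, "CA"))
      if (!anyNA(q)) {
        k3 <- length(pl_i) + 1
        pl_i[[k3]] <- rbind(q); pl_cls[[k3]] <- "peptide_omega"
        pl_ideal[[k3]] <- 180
        omega_q[[r + 1]] <- q  # omega of the bond entering residue r+1
      }
    }
  }
  for (r in seq_len(nres)) {
    if (res_names[r] %in% AA3) {
      if (linked[r]) {
        q <- c(glob(r - 1, "C"), glob(r, "N"), glob(r, "CA"), glob(r, "C"))
        if (!anyNA(q)) phi_q[[r]] <- q
      }
      if (r < nres && linked[r + 1]) {
        q <- c(glob(r, "N"), glob(r, "CA"), glob(r, "C"), glob(r + 1, "N"))
        if (!anyNA(q)) psi_q[[r]] <- q
      }
    } else if (res_names[r] %in% NT1 && linked[r]) {
      # 7 suite dihedrals for base r: delta-1, epsilon-1, zeta-1,
      # alpha, beta, gamma, delta
      p <- r - 1
      qs <- list(
        delta_m1   = c(glob(p, "C5'"), glob(p, "C4'"), glob(p, "C3'"), glob(p, "O3'")),
        epsilon_m1 = c(glob(p, "C4'"), glob(p, "C3'"), glob(p, "O3'"), glob(r, "P")),
        zeta_m1    = c(glob(p, "C3'"), glob(p, "O3'"), glob(r, "P"), glob(r, "O5'")),
        alpha      = c(glob(p, "O3'"), glob(r, "P"), glob(r, "O5'"), glob(r, "C5'")),
        beta       = c(glob(r, "P"), glob(r, "O5'"), glob(r, "C5'"), glob(r, "C4'")),
        gamma      = c(glob(r, "O5'"), glob(r, "C5'"), glob(r, "C4'"), glob(r, "C3'")),
        delta      = c(glob(r, "C5'"), glob(r, "C4'"), glob(r, "C3'"), glob(r, "O3'")))
      if (!anyNA(unlist(qs)))
        rna_rows[[r]] <- data.frame(base = r, angle = names(qs),
                                    do.call(rbind, lapply(qs, rbind)) |>
                                      (\(m) {colnames(m) <- paste0("i", 1:4); m})())
    }
  }

  bond_idx <- do.call(rbind, bond_i)
  topo <- list(
    n_heavy = nrow(at),
    res_index = ridx, res_names = res_names, res_chain = res_chain,
    bond_idx = bond_idx,
    bond_mu = unlist(bond_mu, use.names = FALSE),
    bond_sigma = unlist(bond_sd, use.names = FALSE),
    angle_idx = do.call(rbind, ang_i),
    angle_mu = unlist(ang_mu, use.names = FALSE),
    angle_sigma = unlist(ang_sd, use.names = FALSE),
    planar_idx = do.call(rbind, pl_i),
    planar_class = unlist(pl_cls, use.names = FALSE),
    planar_ideal = unlist(pl_ideal, use.names = FALSE),
    planar_thresh = NULL,
    phi = phi_q, psi = psi_q, omega = omega_q,
    chi = if (length(chi_rows)) do.call(rbind, chi_rows) else NULL,
    rna = if (length(rna_rows)) do.call(rbind, rna_rows) else NULL,
    h_place = if (length(h_rows)) do.call(rbind, h_rows) else NULL,
    neighbor_k = neighbor_k)
  topo$planar_thresh <- ifelse(topo$planar_class == "peptide_omega", 30, 10)
  topo$rama_class <- rama_classes(topo, model)

  # resolve hydrogen placement parent indices to global atom indices
  if (!is.null(topo$h_place)) {
    hp <- topo$h_place
    n <- nrow(hp)
    ib <- ic <- ia <- integer(n)
    for (q in seq_len(n)) {
      r <- hp$res[q]
      ib[q] <- glob(r, hp$b[q]); ic[q] <- glob(r, hp$c[q])
      ia[q] <- if (hp$a[q] == "-C") {
        if (r > 1 && linked[r]) glob(r - 1, "C") else NA_integer_
      } else glob(r, hp$a[q])
    }
    keep <- !is.na(ib) & !is.na(ic) & !is.na(ia)
    # N-terminal amide N: three staggered H (charged terminus)
    nterm <- which(hp$b == "N" & hp$a == "-C" & !keep)
    extra <- list()
    for (q in nterm) {
      r <- hp$res[q]
      iN <- glob(r, "N"); iCA <- glob(r, "CA"); iC <- glob(r, "C")
      if (anyNA(c(iN, iCA, iC))) next
      for (t in c(180, 60, -60))
        extra[[length(extra) + 1]] <- data.frame(
          h = paste0("H", length(extra) + 1), ib = iN, ic = iCA, ia = iC,
          dist = 1.01, ang = 109.5, tor = t)
    }
    hdf <- data.frame(h = hp$h[keep], ib = ib[keep], ic = ic[keep],
                      ia = ia[keep], dist = hp$dist[keep],
                      ang = hp$ang[keep], tor = hp$tor[keep])
    if (length(extra)) hdf <- rbind(hdf, do.call(rbind, extra))
    topo$hydrogens <- hdf
  } else topo$hydrogens <- NULL

  # covalent bond graph including hydrogens (H bonded to its parent) for
  # the within-3-bonds clash exclusion
  nH <- if (is.null(topo$hydrogens)) 0L else nrow(topo$hydrogens)
  topo$n_hydrogen <- nH
  hedges <- if (nH) cbind(topo$n_heavy + seq_len(nH), topo$hydrogens$ib) else NULL
  topo$bond_graph <- rbind(bond_idx, hedges)

  # per-atom VdW radii and H-bond element flags (heavy atoms then H);
  # polar hydrogens (parent N/O/S) get the smaller polar-H radius
  vdw <- load_vdw()
  elem <- c(at$element, rep("H", nH))
  topo$vdw_radius <- unname(vdw[elem])
  if (nH) {
    hpar <- at$element[topo$hydrogens$ib]
    topo$vdw_radius[topo$n_heavy + which(hpar %in% c("N", "O", "S"))] <-
      unname(vdw["H_polar"])
  }
  topo$elem_all <- elem
  topo$excl <- bond_exclusions(topo$bond_graph, topo$n_heavy + nH)

  topo$neighbor_idx <- NULL  # built on first refresh
  class(topo) <- "topology_tables"
  topo
}

# set of atom pairs connected within 3 covalent bonds (as a sorted key vector)
bond_exclusions <- function(edges, n_atoms) {
  adj <- vector("list", n_atoms)
  for (q in seq_len(nrow(edges))) {
    i <- edges[q, 1]; j <- edges[q, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  keys <- character(0)
  for (i in seq_len(n_atoms)) {
    # BFS to depth 3
    d1 <- adj[[i]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    reach <- setdiff(unique(c(d1, d2, d3)), i)
    reach <- reach[reach > i]
    if (length(reach)) keys <- c(keys, paste(i, reach))
  }
  keys
}

# per-residue Ramachandran class: General, Gly, trans-Pro, cis-Pro,
# pre-Pro, Ile (Ile/Val)
rama_classes <- function(topo, model) {
  nres <- length(topo$res_index)
  cls <- rep("General", nres)
  cls[topo$res_names == "GLY"] <- "Gly"
  cls[topo$res_names %in% c("ILE", "VAL")] <- "Ile"
  pro <- which(topo$res_names == "PRO")
  for (r in pro) {
    omega <- topo$omega[[r]]
    if (!is.null(omega)) {
      w <- dihedrals(model$xyz, rbind(omega))$value
      cls[r] <- if (abs(wrap180(w)) < 90) "cis-Pro" else "trans-Pro"
    } else cls[r] <- "trans-Pro"
  }
  if (length(pro)) {
    prev <- pro - 1
    prev <- prev[prev >= 1]
    prev <- prev[topo$res_names[prev] %in% AA3 & cls[prev] == "General"]
    cls[prev] <- "pre-Pro"
  }
  cls
}

#' Place hydrogens from heavy-atom coordinates
#'
#' Deterministic zero-torsion hydrogen placement: every hydrogen is placed
#' from its template internal coordinates relative to three parent heavy
#' atoms with rotatable torsions fixed at the template values, matching the
#' convention of validation-style clash scoring.
#'
#' @param xyz N x 3 heavy-atom coordinates
#' @param topo compiled `topology_tables`
#' @return nH x 3 matrix of hydrogen coordinates (possibly 0 rows)
#' @export
place_hydrogens <- function(xyz, topo) {
  hp <- topo$hydrogens
  if (is.null(hp) || !nrow(hp)) return(matrix(0, 0, 3))
  nerf_place(xyz[hp$ia, , drop = FALSE], xyz[hp$ic, , drop = FALSE],
             xyz[hp$ib, , drop = FALSE], hp$dist, hp$ang, hp$tor)
}
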