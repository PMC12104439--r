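# Differentiable stereochemical scoring. Every term returns its scalar
# loss, the analytic gradient with respect to the heavy-atom coordinates,
# and the hard-threshold report quantities used by validation-style
# reporting. Soft hinges (softplus) make the outlier penalties
# differentiable while the report uses the exact thresholds.

softplus <- function(x, sharp = 10) {
  # numerically stable softplus(sharp*x)/sharp
  y <- x * sharp
  ifelse(y > 30, x, log1p(exp(pmin(y, 30))) / sharp)
}
softplus_d <- function(x, sharp = 10) stats::plogis(x * sharp)
sigmoid <- function(x) stats::plogis(x)

# scatter-add V (m x 3) into G (n x 3) at rows i (duplicates accumulate)
index_add <- function(G, i, V) {
  for (d in 1:3) {
    s <- rowsum(V[, d], i)
    r <- as.integer(rownames(s))
    G[r, d] <- G[r, d] + s[, 1]
  }
  G
}

#' Bond length and angle score
#'
#' Gaussian negative log-likelihood of every bond length and bond angle
#' against its ideal mean and sigma, plus a soft hinge penalty activated
#' beyond `outlier_sigma` standard deviations (default 4.5, slightly
#' tighter than the 5-sigma reporting threshold).
#'
#' @param coords N x 3 heavy-atom coordinates
#' @param topo compiled `topology_tables`
#' @param outlier_sigma hinge activation threshold in sigmas
#' @param grad compute the coordinate gradient?
#' @return list with `value`, `grad`, `bond_outliers`, `angle_outliers`
#'   (counts at the 5-sigma reporting threshold), `max_bond_z`,
#'   `max_angle_z`
#' @export
bond_angle_score <- function(coords, topo, outlier_sigma = 4.5, grad = TRUE) {
  G <- if (grad) matrix(0, nrow(coords), 3)
  tot <- 0; nb <- 0
  out <- c(bond = 0, angle = 0); maxz <- c(bond = 0, angle = 0)
  pen_w <- 10

  bl <- bond_lengths(coords, topo$bond_idx)
  z <- (bl$value - topo$bond_mu) / topo$bond_sigma
  az <- abs(z)
  sp <- softplus(az - outlier_sigma)
  tot <- tot + sum(0.5 * z^2 + pen_w * sp^2)
  nb <- nb + length(z)
  out["bond"] <- sum(az > 5)
  maxz["bond"] <- max(az)
  if (grad) {
    dz <- (z + 2 * pen_w * sp * softplus_d(az - outlier_sigma) * sign(z)) /
      topo$bond_sigma
    G <- index_add(G, topo$bond_idx[, 1], -dz * bl$dir)
    G <- index_add(G, topo$bond_idx[, 2], dz * bl$dir)
  }

  an <- bond_angles(coords, topo$angle_idx)
  za <- (an$value - topo$angle_mu) / topo$angle_sigma
  aza <- abs(za)
  spa <- softplus(aza - outlier_sigma)
  tot <- tot + sum(0.5 * za^2 + pen_w * spa^2)
  nb <- nb + length(za)
  out["angle"] <- sum(aza > 5)
  maxz["angle"] <- max(aza)
  if (grad) {
    dza <- (za + 2 * pen_w * spa * softplus_d(aza - outlier_sigma) * sign(za)) /
      topo$angle_sigma
    G <- index_add(G, topo$angle_idx[, 1], dza * an$gi)
    G <- index_add(G, topo$angle_idx[, 2], dza * an$gj)
    G <- index_add(G, topo$angle_idx[, 3], dza * an$gk)
  }

  list(value = tot / nb, grad = if (grad) G / nb,
       bond_outliers = unname(out["bond"]),
       angle_outliers = unname(out["angle"]),
       max_bond_z = unname(maxz["bond"]), max_angle_z = unname(maxz["angle"]))
}

#' Planarity score
#'
#' Angular deviation of each planar quad's dihedral from planarity (the
#' nearer of 0 or 180 degrees): a weak harmonic term keeps planes flat and
#' a soft hinge activates beyond the class threshold (30 degrees for the
#' peptide omega, 10 degrees for other planar groups).
#'
#' @inheritParams bond_angle_score
#' @return list with `value`, `grad`, `violations`, `max_dev`
#' @export
planarity_score <- function(coords, topo, grad = TRUE) {
  if (is.null(topo$planar_idx) || !nrow(topo$planar_idx))
    return(list(value = 0, grad = if (grad) matrix(0, nrow(coords), 3),
                violations = 0, max_dev = 0))
  dh <- dihedrals(coords, topo$planar_idx)
  w <- wrap180(dh$value)
  dev <- 90 - abs(90 - abs(w))             # distance to nearer of {0, 180}
  thr <- topo$planar_thresh
  sp <- softplus(dev - thr)
  sig <- thr / 3
  tot <- sum(0.5 * (dev / sig)^2 + 10 * sp^2)
  n <- length(dev)
  viol <- sum(dev > thr)
  if (grad) {
    # d(dev)/d(dihedral): sign chain through the two folds
    ddev <- sign(w) * sign(90 - abs(w))
    dd <- (dev / sig^2 + 20 * sp * softplus_d(dev - thr)) * ddev
    G <- matrix(0, nrow(coords), 3)
    G <- index_add(G, topo$planar_idx[, 1], dd * dh$g1)
    G <- index_add(G, topo$planar_idx[, 2], dd * dh$g2)
    G <- index_add(G, topo$planar_idx[, 3], dd * dh$g3)
    G <- index_add(G, topo$planar_idx[, 4], dd * dh$g4)
    G <- G / n
  } else G <- NULL
  list(value = tot / n, grad = G, violations = viol, max_dev = max(dev))
}

# phi/psi per residue; returns data frame (res, phi, psi) plus quad rows
backbone_phipsi <- function(coords, topo) {
  rs <- intersect(which(!vapply(topo$phi, is.null, TRUE)),
                  which(!vapply(topo$psi, is.null, TRUE)))
  if (!length(rs)) return(NULL)
  qphi <- do.call(rbind, topo$phi[rs])
  qpsi <- do.call(rbind, topo$psi[rs])
  dphi <- dihedrals(coords, qphi)
  dpsi <- dihedrals(coords, qpsi)
  list(res = rs, qphi = qphi, qpsi = qpsi, dphi = dphi, dpsi = dpsi)
}

#' Ramachandran score
#'
#' Per-residue (phi, psi) evaluated against the class surface (General,
#' Gly, trans-Pro, cis-Pro, pre-Pro, Ile). The differentiable loss is the
#' soft fraction of outlier residues (level 0.0005 on the max-1 histogram)
#' plus a smaller soft allowed-fraction term; the report uses the hard
#' thresholds. Terminal residues (no phi or psi) are skipped.
#'
#' @inheritParams bond_angle_score
#' @param surfaces result of [rama_surfaces()]
#' @return list with `value`, `grad`, `outlier_fraction`,
#'   `allowed_fraction`, `favored_fraction`, `n_scored`
#' @export
rama_score <- function(coords, topo, surfaces = rama_surfaces(), grad = TRUE) {
  bb <- backbone_phipsi(coords, topo)
  if (is.null(bb))
    return(list(value = 0, grad = if (grad) matrix(0, nrow(coords), 3),
                outlier_fraction = 0, allowed_fraction = 0,
                favored_fraction = 0, n_scored = 0))
  cls <- topo$rama_class[bb$res]
  n <- length(bb$res)
  S <- numeric(n); dSdphi <- numeric(n); dSdpsi <- numeric(n)
  for (cl in unique(cls)) {
    i <- which(cls == cl)
    ev <- eval_surface(surfaces[[cl]], cbind(bb$dphi$value[i], bb$dpsi$value[i]))
    S[i] <- ev$score; dSdphi[i] <- ev$grad[, 1]; dSdpsi[i] <- ev$grad[, 2]
  }
  thr_o <- surfaces[[1]]$outlier_threshold
  thr_a <- surfaces[[1]]$allowed_threshold
  k <- 2
  so <- sigmoid(k * (thr_o - S)); sa <- sigmoid(k * (thr_a - S))
  tot <- mean(so) + 0.25 * mean(sa)
  if (grad) {
    dS <- (-k * so * (1 - so) - 0.25 * k * sa * (1 - sa)) / n
    G <- matrix(0, nrow(coords), 3)
    cphi <- dS * dSdphi; cpsi <- dS * dSdpsi
    G <- index_add(G, bb$qphi[, 1], cphi * bb$dphi$g1)
    G <- index_add(G, bb$qphi[, 2], cphi * bb$dphi$g2)
    G <- index_add(G, bb$qphi[, 3], cphi * bb$dphi$g3)
    G <- index_add(G, bb$qphi[, 4], cphi * bb$dphi$g4)
    G <- index_add(G, bb$qpsi[, 1], cpsi * bb$dpsi$g1)
    G <- index_add(G, bb$qpsi[, 2], cpsi * bb$dpsi$g2)
    G <- index_add(G, bb$qpsi[, 3], cpsi * bb$dpsi$g3)
    G <- index_add(G, bb$qpsi[, 4], cpsi * bb$dpsi$g4)
  } else G <- NULL
  list(value = tot, grad = G,
       outlier_fraction = mean(S < thr_o),
       allowed_fraction = mean(S >= thr_o & S < thr_a),
       favored_fraction = mean(S >= thr_a), n_scored = n)
}

# chi angles for all chi-bearing residues; list per residue
chi_angles <- function(coords, topo) {
  ch <- topo$chi
  if (is.null(ch)) return(NULL)
  idx <- as.matrix(ch[, c("i1", "i2", "i3", "i4")])
  dh <- dihedrals(coords, idx)
  list(tab = ch, idx = idx, dh = dh)
}

#' Sidechain rotamer score
#'
#' Chi-angle vectors evaluated against the per-residue-type rotamer
#' surfaces: likelihood term plus soft outlier hinge for the loss, hard
#' outlier threshold for the report.
#'
#' @inheritParams rama_score
#' @param surfaces result of [rotamer_surfaces()]
#' @return list with `value`, `grad`, `outlier_fraction`, `n_scored`
#' @export
rotamer_score <- function(coords, topo, surfaces = rotamer_surfaces(),
                          grad = TRUE) {
  ca <- chi_angles(coords, topo)
  if (is.null(ca))
    return(list(value = 0, grad = if (grad) matrix(0, nrow(coords), 3),
                outlier_fraction = 0, n_scored = 0))
  tab <- ca$tab
  resid <- unique(tab$res)
  n <- length(resid)
  thr_o <- outlier_log_threshold()
  k <- 2
  tot <- 0; n_out <- 0
  G <- if (grad) matrix(0, nrow(coords), 3)
  for (r in resid) {
    rows <- which(tab$res == r)
    rows <- rows[order(tab$chi[rows])]
    rt <- tab$res_name[rows[1]]
    surf <- surfaces[[rt]]
    if (is.null(surf)) next
    X <- rbind(ca$dh$value[rows])
    ev <- eval_surface(surf, X)
    S <- ev$score
    so <- sigmoid(k * (thr_o - S))
    tot <- tot + 0.05 * (-S) + so
    n_out <- n_out + (S < thr_o)
    if (grad) {
      dS <- (-0.05 - k * so * (1 - so)) / n
      for (q in seq_along(rows)) {
        cq <- dS * ev$grad[1, q]
        j <- rows[q]
        g <- ca$dh
        G <- index_add(G, ca$idx[j, 1], rbind(cq * g$g1[j, ]))
        G <- index_add(G, ca$idx[j, 2], rbind(cq * g$g2[j, ]))
        G <- index_add(G, ca$idx[j, 3], rbind(cq * g$g3[j, ]))
        G <- index_add(G, ca$idx[j, 4], rbind(cq * g$g4[j, ]))
      }
    }
  }
  list(value = tot / max(n, 1), grad = G,
       outlier_fraction = n_out / max(n, 1), n_scored = n)
}

#' Rebuild the clash neighbor candidate list
#'
#' k-nearest spatial neighbors per atom (hydrogens included), excluding
#' pairs connected within 3 covalent bonds. Called at the start of
#' refinement and every `neighbor_refresh` iterations thereafter.
#'
#' @param coords N x 3 heavy-atom coordinates
#' @param topo `topology_tables`
#' @param k neighbor candidates per atom (default from the topology)
#' @return the topology with `neighbor_idx` (m x 2 pairs, i < j),
#'   `pair_thresh` (clash distance per pair) and `pair_hb` (H-bond pairs)
#' @export
refresh_neighbors <- function(coords, topo, k = topo$neighbor_k) {
  hxyz <- place_hydrogens(coords, topo)
  all_xyz <- rbind(coords, hxyz)
  n <- nrow(all_xyz)
  D <- as.matrix(stats::dist(all_xyz))
  diag(D) <- Inf
  excl <- topo$excl
  pairs <- matrix(0L, 0, 2)
  plist <- vector("list", n)
  kk <- min(k, n - 1)
  ord <- apply(D, 1, function(row) order(row)[seq_len(kk)])
  for (i in seq_len(n)) {
    js <- ord[, i]
    keep <- js > i
    js <- js[keep]
    if (length(js)) {
      key <- paste(i, js)
      js <- js[!(key %in% excl)]
    }
    if (length(js)) plist[[i]] <- cbind(i, js)
  }
  pairs <- do.call(rbind, plist)
  if (is.null(pairs)) pairs <- matrix(0L, 0, 2)
  r <- topo$vdw_radius
  e <- topo$elem_all
  hb <- (e[pairs[, 1]] == "H" & e[pairs[, 2]] %in% c("O", "N")) |
        (e[pairs[, 2]] == "H" & e[pairs[, 1]] %in% c("O", "N"))
  topo$neighbor_idx <- pairs
  topo$pair_thresh <- r[pairs[, 1]] + r[pairs[, 2]] - 0.4 - 0.4 * hb
  topo$pair_hb <- hb
  topo
}

#' Clash score
#'
#' A pair of non-bonded atoms clashes when its distance is below the sum of
#' VdW radii minus 0.4 Angstrom; for potential H-bond pairs (H with O/N,
#' not covalently linked) the allowance is 0.8 Angstrom. Hydrogens are
#' placed on the fly from the heavy atoms and their gradient contribution
#' is chained back to the parent atoms. The clash score is clashes per
#' 1000 atoms, hydrogens included.
#'
#' @inheritParams bond_angle_score
#' @param margin extra hinge activation distance in Angstrom: the loss
#'   starts penalizing pairs `margin` before the reported clash threshold
#'   (training tighter than reporting, as for the 4.5 vs 5 sigma bond rule);
#'   the reported counts always use the exact threshold
#' @return list with `value`, `grad`, `clash_count`, `score_per_1000`,
#'   `n_atoms`
#' @export
clash_score <- function(coords, topo, grad = TRUE, margin = 0) {
  if (is.null(topo$neighbor_idx))
    stop("neighbor list not built; call refresh_neighbors() first")
  hxyz <- place_hydrogens(coords, topo)
  all_xyz <- rbind(coords, hxyz)
  nH <- nrow(hxyz); nh <- nrow(coords)
  pr <- topo$neighbor_idx
  if (!nrow(pr))
    return(list(value = 0, grad = if (grad) matrix(0, nh, 3),
                clash_count = 0, score_per_1000 = 0, n_atoms = nh + nH))
  bl <- bond_lengths(all_xyz, pr)
  overlap <- topo$pair_thresh - bl$value
  sp <- softplus(overlap + margin)
  tot <- sum(sp^2)
  cnt <- sum(overlap > 0)
  np <- nh + nH   # per-atom normalization keeps the term's scale
                  # independent of the neighbor-list size
  if (grad) {
    dov <- 2 * sp * softplus_d(overlap + margin)   # d(loss)/d(overlap)
    Gall <- matrix(0, nh + nH, 3)
    Gall <- index_add(Gall, pr[, 1], dov * bl$dir)     # d(overlap)/d xi = +dir
    Gall <- index_add(Gall, pr[, 2], -dov * bl$dir)
    G <- Gall[seq_len(nh), , drop = FALSE]
    if (nH > 0) {
      hp <- topo$hydrogens
      G <- G + cpp_hplace_backprop(coords, hp$ia, hp$ib, hp$ic, hp$dist,
                                   hp$ang, hp$tor,
                                   Gall[nh + seq_len(nH), , drop = FALSE], nh)
    }
    G <- G / np
  } else G <- NULL
  list(value = tot / np, grad = G, clash_count = cnt,
       score_per_1000 = 1000 * cnt / (nh + nH), n_atoms = nh + nH)
}

#' RNA backbone suite score
#'
#' Seven backbone dihedrals per base (delta-1 through delta) compared to
#' the 46 suite cluster centers with a Gaussian kernel on the wrapped
#' per-angle distance. The reported mean mimics validation (bases whose
#' best score is below the assignment threshold are excluded); the loss
#' includes every base so outliers keep being penalized.
#'
#' @inheritParams bond_angle_score
#' @param suites a `suite_library`
#' @return list with `value`, `grad`, `mean_suite_score`, `outlier_count`,
#'   `assignment` (suite name per base), `n_scored`
#' @export
rna_suite_score <- function(coords, topo, suites = load_suites(),
                            grad = TRUE) {
  rn <- topo$rna
  if (is.null(rn))
    return(list(value = 0, grad = if (grad) matrix(0, nrow(coords), 3),
                mean_suite_score = NA_real_, outlier_count = 0,
                assignment = character(0), n_scored = 0))
  idx <- as.matrix(rn[, c("i1", "i2", "i3", "i4")])
  dh <- dihedrals(coords, idx)
  bases <- unique(rn$base)
  nb <- length(bases)
  ctr <- suites$centers; w <- suites$width
  best <- numeric(nb); assigned <- character(nb); ssum <- numeric(nb)
  G <- if (grad) matrix(0, nrow(coords), 3)
  tot <- 0
  for (bi in seq_len(nb)) {
    rows <- which(rn$base == bases[bi])      # 7 rows in angle order
    th <- dh$value[rows]
    D <- wrap180(sweep(ctr, 2, th, "-"))     # 46 x 7
    sc <- exp(-rowSums((D / w)^2))
    best[bi] <- max(sc)
    assigned[bi] <- rownames(ctr)[which.max(sc)]
    ssum[bi] <- sum(sc)
    tot <- tot - log(ssum[bi] + exp(LOG_C))
    if (grad) {
      # d/d(theta_j) of sum_c exp(-sum (wrap(c-theta)/w)^2) = sum_c sc * 2 D_cj / w^2
      dth <- colSums(sc * 2 * D / w^2)       # length 7
      coef <- -dth / (ssum[bi] + exp(LOG_C))
      for (q in seq_along(rows)) {
        j <- rows[q]
        G <- index_add(G, idx[j, 1], rbind(coef[q] * dh$g1[j, ]))
        G <- index_add(G, idx[j, 2], rbind(coef[q] * dh$g2[j, ]))
        G <- index_add(G, idx[j, 3], rbind(coef[q] * dh$g3[j, ]))
        G <- index_add(G, idx[j, 4], rbind(coef[q] * dh$g4[j, ]))
      }
    }
  }
  ok <- best >= suites$threshold
  list(value = tot / nb, grad = if (grad) G / nb,
       mean_suite_score = if (any(ok)) mean(best[ok]) else 0,
       outlier_count = sum(!ok),
       assignment = assigned, n_scored = nb)
}

GEOM_WEIGHTS_DEFAULT <- c(bond_angle = 1, planarity = 1, rama = 1,
                          rotamer = 1, clash = 1, rna = 1)

#' Combined differentiable geometry loss
#'
#' Weighted sum of the stereochemistry terms with end-to-end gradients.
#'
#' @inheritParams bond_angle_score
#' @param weights named weights for `bond_angle`, `planarity`, `rama`,
#'   `rotamer`, `clash`, `rna` (all nonnegative)
#' @param outlier_sigma passed to [bond_angle_score()]
#' @param clash_margin passed to [clash_score()]
#' @return list with `value`, `grad`, and the per-term results under
#'   `terms`
#' @export
combined_geometry_loss <- function(coords, topo,
                                   weights = GEOM_WEIGHTS_DEFAULT,
                                   outlier_sigma = 4.5, grad = TRUE,
                                   clash_margin = 0) {
  w <- GEOM_WEIGHTS_DEFAULT
  w[names(weights)] <- weights
  if (any(w < 0)) stop("geometry weights must be nonnegative")
  terms <- list()
  tot <- 0
  G <- if (grad) matrix(0, nrow(coords), 3)
  addterm <- function(nm, res) {
    terms[[nm]] <<- res
    if (w[nm] > 0) {
      tot <<- tot + w[nm] * res$value
      if (grad) G <<- G + w[nm] * res$grad
    }
  }
  addterm("bond_angle", bond_angle_score(coords, topo, outlier_sigma, grad = grad))
  addterm("planarity", planarity_score(coords, topo, grad = grad))
  addterm("rama", rama_score(coords, topo, grad = grad))
  addterm("rotamer", rotamer_score(coords, topo, grad = grad))
  if (w["clash"] > 0 && !is.null(topo$neighbor_idx))
    addterm("clash", clash_score(coords, topo, grad = grad,
                                 margin = clash_margin))
  if (!is.null(topo$rna))
    addterm("rna", rna_suite_score(coords, topo, grad = grad))
  list(value = tot, grad = G, terms = terms)
}

#' Validation-style geometry report
#'
#' Hard-threshold summary of all stereochemistry metrics for a model.
#'
#' @param model an `atomic_model`
#' @param topo optional precompiled topology (built if missing)
#' @return object of class `geometry_report`
#' @export
geometry_report <- function(model, topo = NULL) {
  if (is.null(topo)) topo <- compile_topology(model)
  if (is.null(topo$neighbor_idx)) topo <- refresh_neighbors(model$xyz, topo)
  co <- model$xyz
  ba <- bond_angle_score(co, topo, grad = FALSE)
  pl <- planarity_score(co, topo, grad = FALSE)
  ra <- rama_score(co, topo, grad = FALSE)
  ro <- rotamer_score(co, topo, grad = FALSE)
  cl <- clash_score(co, topo, grad = FALSE)
  rn <- rna_suite_score(co, topo, grad = FALSE)
  structure(list(
    bond_outliers = ba$bond_outliers, angle_outliers = ba$angle_outliers,
    planarity_violations = pl$violations,
    rama_outlier_fraction = ra$outlier_fraction,
    rama_allowed_fraction = ra$allowed_fraction,
    rama_favored_fraction = ra$favored_fraction,
    rotamer_outlier_fraction = ro$outlier_fraction,
    clash_count = cl$clash_count, clash_score = cl$score_per_1000,
    rna_suite_score = rn$mean_suite_score,
    rna_suite_outliers = rn$outlier_count,
    n_atoms = cl$n_atoms, n_rama = ra$n_scored, n_rotamer = ro$n_scored),
    class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Geometry report\n")
  cat(sprintf("  bond outliers        : %d\n", x$bond_outliers))
  cat(sprintf("  angle outliers       : %d\n", x$angle_outliers))
  cat(sprintf("  planarity violations : %d\n", x$planarity_violations))
  cat(sprintf("  Ramachandran outliers: %.2f %% (favored %.1f %%, n = %d)\n",
              100 * x$rama_outlier_fraction, 100 * x$rama_favored_fraction,
              x$n_rama))
  cat(sprintf("  rotamer outliers     : %.2f %% (n = %d)\n",
              100 * x$rotamer_outlier_fraction, x$n_rotamer))
  cat(sprintf("  clash score          : %.2f per 1000 atoms (%d clashes, %d atoms)\n",
              x$clash_score, x$clash_count, x$n_atoms))
  if (!is.na(x$rna_suite_score))
    cat(sprintf("  RNA suite score      : %.3f (%d outliers)\n",
                x$rna_suite_score, x$rna_suite_outliers))
  invisible(x)
}

#' Unweighted geometry likelihood score (for weight balancing)
#' @inheritParams bond_angle_score
#' @return scalar sum of the likelihood-style terms (lower is better)
#' @export
geometry_likelihood <- function(coords, topo) {
  combined_geometry_loss(coords, topo, grad = FALSE)$value
}
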