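# Group rigid transforms: the decoders output per-patch / per-residue
# translation + rotation-vector pairs that deform the baseline coordinates.
# Forward and backward passes are exact (Rodrigues rotation and its
# derivative), so decoder training backpropagates through the deformation.

# derivative of the Rodrigues rotation R(r) applied to a fixed point set:
# d(R p)/dr_k (Gallego & Yezzi 2015); at r ~ 0 the limit [e_k]_x.
rodrigues_jacobian <- function(r, P) {
  # P: m x 3 points; returns list of three m x 3 matrices dRP[[k]]
  th <- sqrt(sum(r^2))
  R <- rotvec_to_mat(r)
  RP <- P %*% t(R)
  out <- vector("list", 3)
  if (th < 1e-8) {
    for (k in 1:3) {
      e <- numeric(3); e[k] <- 1
      out[[k]] <- rowcross(matrix(e, nrow(P), 3, byrow = TRUE), P)
    }
    return(out)
  }
  Imat <- diag(3)
  for (k in 1:3) {
    e <- numeric(3); e[k] <- 1
    v <- r[k] * r + crossprod3(r, as.numeric((Imat - R) %*% e))
    # dR/dr_k = [v]_x R / th^2 ; applied to points: cross(v, RP)/th^2
    out[[k]] <- rowcross(matrix(v, nrow(P), 3, byrow = TRUE), RP) / th^2
  }
  out
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Create a deformation head
#'
#' A head couples a decoder to a deformation parameterization:
#' `"group"` (per-group rigid transform about the group center: patches or
#' residues) or `"atom"` (per-atom offsets).
#'
#' @param type `"group"` or `"atom"`
#' @param groups list of atom-index vectors (group type)
#' @param x0 baseline coordinates (used for group centers)
#' @param n_atoms number of atoms (atom type)
#' @param width decoder hidden width
#' @param seed decoder init seed
#' @return a `deform_head`
#' @export
deform_head <- function(type = c("group", "atom"), groups = NULL, x0 = NULL,
                        n_atoms = NULL, width = 64, seed = 1) {
  type <- match.arg(type)
  if (type == "group") {
    stopifnot(!is.null(groups), !is.null(x0))
    centers <- t(vapply(groups, function(i) colMeans(x0[i, , drop = FALSE]),
                        numeric(3)))
    n_out <- 6 * length(groups)
    h <- list(type = type, groups = groups, centers = centers,
              n_out = n_out)
  } else {
    stopifnot(!is.null(n_atoms))
    h <- list(type = type, n_atoms = n_atoms, n_out = 3 * n_atoms)
  }
  h$net <- decoder_new(4, h$n_out, width = width, seed = seed)
  class(h) <- "deform_head"
  h
}

# forward: displacement field for one output-parameter row
head_displacement <- function(head, par_row, x0) {
  if (head$type == "atom")
    return(matrix(par_row, ncol = 3))
  D <- matrix(0, nrow(x0), 3)
  P <- length(head$groups)
  pm <- matrix(par_row, P, 6, byrow = TRUE)  # per group: t(3), r(3)
  for (g in seq_len(P)) {
    i <- head$groups[[g]]
    mu <- head$centers[g, ]
    r <- pm[g, 4:6]
    R <- rotvec_to_mat(r)
    rel <- sweep(x0[i, , drop = FALSE], 2, mu)
    D[i, ] <- rel %*% t(R) - rel +
      matrix(pm[g, 1:3], length(i), 3, byrow = TRUE)
  }
  D
}

# backward: dL/d(par_row) given dL/d(displacement)
head_backward <- function(head, par_row, x0, dD) {
  if (head$type == "atom")
    return(as.numeric(dD))
  P <- length(head$groups)
  pm <- matrix(par_row, P, 6, byrow = TRUE)
  g_out <- matrix(0, P, 6)
  for (g in seq_len(P)) {
    i <- head$groups[[g]]
    gi <- dD[i, , drop = FALSE]
    g_out[g, 1:3] <- colSums(gi)
    rel <- sweep(x0[i, , drop = FALSE], 2, head$centers[g, ])
    J <- rodrigues_jacobian(pm[g, 4:6], rel)
    for (k in 1:3) g_out[g, 3 + k] <- sum(J[[k]] * gi)
  }
  as.numeric(t(g_out))
}
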