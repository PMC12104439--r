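# Low-level vectorised geometry: distances, angles, dihedrals and their
# analytic gradients with respect to Cartesian coordinates. All functions
# operate on index matrices into an N x 3 coordinate matrix so that whole
# restraint lists are evaluated in one call.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to (-180, 180]
#' @param x numeric vector of angles in degrees
#' @return wrapped angles
#' @keywords internal
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

rowdot <- function(a, b) rowSums(a * b)

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(a) sqrt(rowSums(a * a))

#' Pairwise bond lengths with gradients
#'
#' @param coords N x 3 matrix (Angstrom)
#' @param idx m x 2 integer matrix of atom indices
#' @return list with `value` (lengths) and, the unit displacement `dir`
#'   such that d(len)/d(coords[i,]) = -dir and d/d(coords[j,]) = +dir
#' @keywords internal
bond_lengths <- function(coords, idx) {
  d <- coords[idx[, 2], , drop = FALSE] - coords[idx[, 1], , drop = FALSE]
  len <- rownorm(d)
  list(value = len, dir = d / pmax(len, 1e-12))
}

#' Bond angles (degrees) with gradients
#'
#' @param coords N x 3 matrix
#' @param idx m x 3 integer matrix (i, j, k); angle at j
#' @return list with `value` (degrees) and gradient blocks `gi`, `gj`, `gk`
#'   (degrees per Angstrom)
#' @keywords internal
bond_angles <- function(coords, idx) {
  u <- coords[idx[, 1], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  v <- coords[idx[, 3], , drop = FALSE] - coords[idx[, 2], , drop = FALSE]
  nu <- pmax(rownorm(u), 1e-12); nv <- pmax(rownorm(v), 1e-12)
  uh <- u / nu; vh <- v / nv
  ct <- pmin(pmax(rowdot(uh, vh), -1 + 1e-12), 1 - 1e-12)
  st <- sqrt(1 - ct^2)
  th <- acos(ct)
  # d(theta)/d(p_i) = (ct*uh - vh) / (nu*st); symmetric for k; j = -(i+k)
  gi <- (ct * uh - vh) / (nu * st)
  gk <- (ct * vh - uh) / (nv * st)
  gj <- -(gi + gk)
  s <- 180 / pi
  list(value = rad2deg(th), gi = gi * s, gj = gj * s, gk = gk * s)
}

#' Dihedral angles (degrees) with gradients
#'
#' @param coords N x 3 matrix
#' @param idx m x 4 integer matrix (i, j, k, l)
#' @return list with `value` in (-180, 180] and gradient blocks
#'   `g1`..`g4` (degrees per Angstrom)
#' @keywords internal
dihedrals <- function(coords, idx) {
  p1 <- coords[idx[, 1], , drop = FALSE]; p2 <- coords[idx[, 2], , drop = FALSE]
  p3 <- coords[idx[, 3], , drop = FALSE]; p4 <- coords[idx[, 4], , drop = FALSE]
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
  nb2 <- pmax(rownorm(b2), 1e-12)
  m1 <- rowcross(n1, b2 / nb2)
  x <- rowdot(n1, n2); y <- -rowdot(m1, n2)   # IUPAC sign convention
  phi <- atan2(y, x)
  n1sq <- pmax(rowSums(n1 * n1), 1e-12)
  n2sq <- pmax(rowSums(n2 * n2), 1e-12)
  g1 <- -nb2 / n1sq * n1
  g4 <- nb2 / n2sq * n2
  c12 <- rowdot(b1, b2) / nb2^2
  c32 <- rowdot(b3, b2) / nb2^2
  g2 <- -(1 + c12) * g1 + c32 * g4
  g3 <- c12 * g1 - (1 + c32) * g4
  s <- 180 / pi
  list(value = rad2deg(phi), g1 = g1 * s, g2 = g2 * s, g3 = g3 * s, g4 = g4 * s)
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Places point D given reference atoms A, B, C, a bond length |CD|, the
#' angle B-C-D and the dihedral A-B-C-D.
#'
#' @param a,b,c reference coordinates (length-3) or m x 3 matrices
#' @param dist bond length(s) in Angstrom
#' @param ang angle(s) B-C-D in degrees
#' @param tor dihedral(s) A-B-C-D in degrees
#' @return placed coordinates, m x 3
#' @keywords internal
nerf_place <- function(a, b, c, dist, ang, tor) {
  a <- rbind(a); b <- rbind(b); c <- rbind(c)
  th <- deg2rad(ang); ph <- deg2rad(tor)
  bc <- c - b; bc <- bc / pmax(rownorm(bc), 1e-12)
  ab <- b - a; ab <- ab / pmax(rownorm(ab), 1e-12)
  n <- rowcross(ab, bc); n <- n / pmax(rownorm(n), 1e-12)
  m <- rowcross(n, bc)
  d2 <- cbind(-dist * cos(th), dist * sin(th) * cos(ph),
              dist * sin(th) * sin(ph))
  c + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * n
}

#' Rodrigues rotation matrix from a rotation vector
#' @param r length-3 rotation vector (axis * angle in radians)
#' @return 3 x 3 rotation matrix
#' @keywords internal
rotvec_to_mat <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid-superpose source points onto target points (Kabsch)
#' @param src,tgt m x 3 matrices of paired points
#' @return list with rotation `R` and translation `t`; maps x to x R + t
#' @keywords internal
kabsch <- function(src, tgt) {
  cs <- colMeans(src); ct <- colMeans(tgt)
  H <- t(sweep(src, 2, cs)) %*% sweep(tgt, 2, ct)
  sv <- svd(H)
  d <- sign(det(t(sv$v %*% t(sv$u))))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, t = ct - as.numeric(cs %*% R))
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b N x 3 matrices with matched rows
#' @param fit if TRUE, superpose b onto a first
#' @return RMSD in Angstrom
#' @export
coord_rmsd <- function(a, b, fit = FALSE) {
  if (fit) {
    k <- kabsch(b, a)
    b <- sweep(b %*% k$R, 2, k$t, "+")
  }
  sqrt(mean(rowSums((a - b)^2)))
}
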