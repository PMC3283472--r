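#' Beam element constructor
#'
#' 3D two-node Euler-Bernoulli beam (no shear deformation) with axial,
#' torsional and two bending stiffnesses; 6 DOF per node.
#'
#' @param n1,n2 node ids.
#' @param E Young's modulus (MPa), `G` shear modulus (MPa).
#' @param A cross-section area (mm^2).
#' @param Iy,Iz bending second moments (mm^4), `J` torsion constant (mm^4).
#' @param orientation reference vector (not parallel to the axis) fixing the
#'   local cross-section frame.
#' @param region label used for bookkeeping.
#' @return a `beam_element` list.
#' @export
beam_element <- function(n1, n2, E, G, A, Iy, Iz, J,
                         orientation = c(0, 0, 1), region = "beam") {
  stopifnot(E > 0, G > 0, A > 0, Iy > 0, Iz > 0, J > 0)
  structure(list(n1 = n1, n2 = n2, E = E, G = G, A = A, Iy = Iy, Iz = Iz,
                 J = J, orientation = orientation, region = region),
            class = "beam_element")
}

# local 12x12 Euler-Bernoulli stiffness; DOF order
# (u1x u1y u1z r1x r1y r1z u2x u2y u2z r2x r2y r2z), local x along the axis
.beam_local_stiffness <- function(E, G, A, Iy, Iz, J, L) {
  k <- matrix(0, 12, 12)
  ax <- E * A / L
  tor <- G * J / L
  bz <- E * Iz / L^3   # bending about local z (displacement in local y)
  by <- E * Iy / L^3   # bending about local y (displacement in local z)
  k[c(1, 7), c(1, 7)] <- ax * matrix(c(1, -1, -1, 1), 2)
  k[c(4, 10), c(4, 10)] <- tor * matrix(c(1, -1, -1, 1), 2)
  iy <- c(2, 6, 8, 12)  # v1, rz1, v2, rz2
  k[iy, iy] <- bz * matrix(c(
    12, 6 * L, -12, 6 * L,
    6 * L, 4 * L^2, -6 * L, 2 * L^2,
    -12, -6 * L, 12, -6 * L,
    6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  iz <- c(3, 5, 9, 11)  # w1, ry1, w2, ry2 (sign convention flips rotations)
  k[iz, iz] <- by * matrix(c(
    12, -6 * L, -12, -6 * L,
    -6 * L, 4 * L^2, 6 * L, 2 * L^2,
    -12, 6 * L, 12, 6 * L,
    -6 * L, 2 * L^2, 6 * L, 4 * L^2), 4, 4, byrow = TRUE)
  k
}

#' Beam element stiffness in the global frame
#'
#' @param element a [beam_element()].
#' @param node_positions 2 x 3 matrix: positions of `n1`, `n2` (mm).
#' @return symmetric 12 x 12 stiffness matrix, global frame, DOF order
#'   (ux uy uz rx ry rz) per node.
#' @export
beam_element_stiffness <- function(element, node_positions) {
  p1 <- as.numeric(node_positions[1, ])
  p2 <- as.numeric(node_positions[2, ])
  d <- p2 - p1
  L <- sqrt(sum(d^2))
  if (L < 1e-9) stop("zero-length beam element")
  ex <- d / L
  v <- element$orientation
  cy <- c(v[2] * ex[3] - v[3] * ex[2],
          v[3] * ex[1] - v[1] * ex[3],
          v[1] * ex[2] - v[2] * ex[1])   # v x ex
  if (sqrt(sum(cy^2)) < 1e-8) {
    v <- if (abs(ex[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    cy <- c(v[2] * ex[3] - v[3] * ex[2],
            v[3] * ex[1] - v[1] * ex[3],
            v[1] * ex[2] - v[2] * ex[1])
  }
  ey <- cy / sqrt(sum(cy^2))
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  T <- matrix(0, 12, 12)
  for (b in 0:3) T[b * 3 + 1:3, b * 3 + 1:3] <- R
  kl <- .beam_local_stiffness(element$E, element$G, element$A,
                              element$Iy, element$Iz, element$J, L)
  k <- t(T) %*% kl %*% T
  (k + t(k)) / 2
}

#' Axial spring element constructor
#'
#' @param n1,n2 node ids.
#' @param k axial stiffness (N/mm), >= 0.
#' @param tension_only if `TRUE` the spring carries no load in compression
#'   (resolved by the active-set iteration, [resolve_tension_only()]).
#' @param region label.
#' @return a `spring_element` list.
#' @export
spring_element <- function(n1, n2, k, tension_only = FALSE,
                           region = "ligament") {
  stopifnot(k >= 0)
  structure(list(n1 = n1, n2 = n2, k = k, tension_only = tension_only,
                 region = region), class = "spring_element")
}

#' Axial spring stiffness in the global frame (translations only)
#'
#' @param element a [spring_element()].
#' @param node_positions 2 x 3 matrix of node positions.
#' @return 6 x 6 matrix over (u1x u1y u1z u2x u2y u2z).
#' @export
spring_element_stiffness <- function(element, node_positions) {
  d <- as.numeric(node_positions[2, ] - node_positions[1, ])
  L <- sqrt(sum(d^2))
  if (L < 1e-9) stop("zero-length spring element")
  a <- d / L
  aa <- element$k * (a %o% a)
  rbind(cbind(aa, -aa), cbind(-aa, aa))
}

# trilinear hex: natural coordinates of the 8 corner nodes (VTK ordering)
.hex_xi <- matrix(c(
  -1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
  -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1), 8, 3, byrow = TRUE)

# shape function derivatives wrt natural coords at point (xi, eta, zeta): 8 x 3
.hex_dN <- function(xi, eta, zeta) {
  g <- .hex_xi
  cbind(g[, 1] * (1 + g[, 2] * eta) * (1 + g[, 3] * zeta),
        g[, 2] * (1 + g[, 1] * xi) * (1 + g[, 3] * zeta),
        g[, 3] * (1 + g[, 1] * xi) * (1 + g[, 2] * eta)) / 8
}

.gauss_pts <- {
  a <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-a, a), eta = c(-a, a), zeta = c(-a, a)))
}

# isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx)
.isotropic_D <- function(E, nu) {
  stopifnot(E > 0, nu > 0, nu < 0.5)
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# strain-displacement matrix (6 x 24) from cartesian shape gradients (8 x 3)
.hex_B <- function(dNx) {
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, by = 3)
  B[1, ix] <- dNx[, 1]
  B[2, ix + 1] <- dNx[, 2]
  B[3, ix + 2] <- dNx[, 3]
  B[4, ix] <- dNx[, 2]; B[4, ix + 1] <- dNx[, 1]
  B[5, ix + 1] <- dNx[, 3]; B[5, ix + 2] <- dNx[, 2]
  B[6, ix] <- dNx[, 3]; B[6, ix + 2] <- dNx[, 1]
  B
}

#' Hexahedral element constructor
#'
#' 8-node trilinear hexahedron (standard VTK corner ordering), isotropic
#' linear-elastic material, 2x2x2 Gauss integration.
#'
#' @param nodes integer vector of 8 node ids.
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param region material region label.
#' @return a `hex_element` list.
#' @export
hex_element <- function(nodes, E, nu, region = "solid") {
  stopifnot(length(nodes) == 8, E > 0, nu > 0, nu < 0.5)
  structure(list(nodes = as.integer(nodes), E = E, nu = nu, region = region),
            class = "hex_element")
}

#' Hexahedral element stiffness
#'
#' @param element a [hex_element()].
#' @param node_positions 8 x 3 matrix of corner positions (element ordering).
#' @return symmetric positive semidefinite 24 x 24 matrix (3 translational
#'   DOF per node) with exactly 6 rigid-body zero-energy modes.
#' @export
hex_element_stiffness <- function(element, node_positions) {
  X <- as.matrix(node_positions)
  D <- .isotropic_D(element$E, element$nu)
  K <- matrix(0, 24, 24)
  for (g in seq_len(nrow(.gauss_pts))) {
    dN <- .hex_dN(.gauss_pts[g, 1], .gauss_pts[g, 2], .gauss_pts[g, 3])
    Jm <- t(dN) %*% X                 # 3 x 3 Jacobian
    detJ <- det(Jm)
    if (detJ <= 0) {
      stop(sprintf("inverted hexahedral element (det J = %.3g at Gauss point %d)",
                   detJ, g))
    }
    dNx <- dN %*% t(solve(Jm))        # cartesian gradients
    B <- .hex_B(dNx)
    K <- K + crossprod(B, D %*% B) * detJ
  }
  (K + t(K)) / 2
}
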