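test_that("beam element reproduces Euler-Bernoulli closed forms", {
  L <- 120; E <- 2000; A <- 80; I <- 3000; G <- 800; J <- 6000
  el <- beam_element(1, 2, E, G, A, I, I, J)
  pos <- rbind(c(0, 0, 0), c(L, 0, 0))
  K <- beam_element_stiffness(el, pos)

  expect_equal(dim(K), c(12, 12))
  expect_lt(max(abs(K - t(K))), 1e-9 * max(abs(K)))

  # rigid translations and rotations produce no force
  rigid <- cbind(
    rep(c(1, 0, 0, 0, 0, 0), 2), rep(c(0, 1, 0, 0, 0, 0), 2),
    rep(c(0, 0, 1, 0, 0, 0), 2),
    c(0, 0, 0, 1, 0, 0, 0, 0, 0, 1, 0, 0),
    c(0, 0, L / 2, 0, 1, 0, 0, 0, -L / 2, 0, 1, 0),   # rotation about mid, y
    c(0, -L / 2, 0, 0, 0, 1, 0, L / 2, 0, 0, 0, 1))   # rotation about mid, z
  expect_lt(max(abs(K %*% rigid)), 1e-8 * max(abs(K)))

  sys <- beam_cantilever_system(1, L = L, E = E, A = A, I = I, G = G, J = J)
  u_ax <- solve_static(sys, data.frame(node = 2, dof = 1, value = 10))
  expect_equal(u_ax[2, 1], 10 * L / (E * A), tolerance = 1e-9)
  u_tr <- solve_static(sys, data.frame(node = 2, dof = 2, value = 7))
  expect_equal(u_tr[2, 2], 7 * L^3 / (3 * E * I), tolerance = 1e-9)

  expect_error(beam_element_stiffness(el, rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero-length")
})

test_that("hex element is symmetric PSD with exactly 6 rigid-body modes", {
  set.seed(21)
  X <- .5 * matrix(c(-1, -1, -1, 1, -1, -1, 1, 1, -1, -1, 1, -1,
                     -1, -1, 1, 1, -1, 1, 1, 1, 1, -1, 1, 1),
                   8, 3, byrow = TRUE) + 0.5
  X <- X + matrix(runif(24, -0.08, 0.08), 8, 3)     # distorted brick
  K <- hex_element_stiffness(hex_element(1:8, 150, 0.3), X)
  expect_lt(max(abs(K - t(K))), 1e-12 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_gt(min(ev), -1e-8 * max(ev))               # positive semidefinite

  # small linearized rigid rotation about z -> ~zero nodal forces
  th <- 1e-9
  u <- t(apply(X, 1, function(p) c(-th * p[2], th * p[1], 0)))
  expect_lt(max(abs(K %*% as.vector(t(u)))), 1e-6 * max(abs(K)) * th)

  Xbad <- X; Xbad[c(1, 2), ] <- X[c(2, 1), ]        # inverted element
  expect_error(hex_element_stiffness(hex_element(1:8, 150, 0.3), Xbad),
               "inverted")
})

test_that("hex patch test: a linear displacement field gives the exact constant stress", {
  # distorted 2x2x2 block: boundary nodes get the linear field prescribed,
  # the interior node is solved for; stresses must equal D %*% eps exactly
  set.seed(22)
  pts <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2)) / 2
  interior <- which(apply(pts, 1, function(p) all(p > 0.1 & p < 0.9)))
  pts[-interior, ] <- pts[-interior, ] + matrix(runif(3 * 26, -0.04, 0.04), 26, 3)
  pts[interior, ] <- pts[interior, ] + runif(3, -0.05, 0.05)
  id <- function(i, j, k) i + 3L * (j - 1L) + 9L * (k - 1L)
  conn <- NULL
  for (k in 1:2) for (j in 1:2) for (i in 1:2) {
    conn <- rbind(conn, c(id(i, j, k), id(i + 1, j, k), id(i + 1, j + 1, k),
                          id(i, j + 1, k), id(i, j, k + 1), id(i + 1, j, k + 1),
                          id(i + 1, j + 1, k + 1), id(i, j + 1, k + 1)))
  }
  mesh <- spine_mesh(pts, hex_conn = conn, hex_region = rep("trabecular", 8),
                     hex_structure = rep("patch", 8))
  mat <- default_material_library()
  E <- mat$E[mat$region == "trabecular"]; nu <- mat$nu[mat$region == "trabecular"]

  G <- matrix(c(1e-3, 4e-4, -2e-4,
                3e-4, -5e-4, 6e-4,
                -1e-4, 2e-4, 8e-4), 3, 3, byrow = TRUE)  # displacement gradient
  ufield <- pts %*% t(G)
  sys <- assemble_global_stiffness(mesh, mat)
  bc <- bc_set(fixed = expand.grid(node = setdiff(seq_len(27), interior),
                                   dof = 1:3))
  sys <- apply_boundary_conditions(sys, bc)
  # prescribe nonzero boundary displacements via equivalent forces on the
  # free (interior) DOFs: f_free = -K[free, fixed] %*% u_fixed
  u_full <- numeric(sys$n_dof)
  act <- sys$dof_map[, 1:3]
  u_full[as.vector(t(act))] <- as.vector(t(ufield))
  fixed <- sort(sys$fixed)
  free <- setdiff(seq_len(sys$n_dof), fixed)
  f <- numeric(sys$n_dof)
  f[free] <- -as.numeric(sys$K[free, fixed] %*% u_full[fixed])
  U <- solve_static(sys, f)
  U[-interior, 1:3] <- ufield[-interior, ]   # solved interior + prescribed rim

  sf <- recover_hex_stresses(mesh, U, mat)
  eps <- c(G[1, 1], G[2, 2], G[3, 3],
           G[1, 2] + G[2, 1], G[2, 3] + G[3, 2], G[1, 3] + G[3, 1])
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  expected <- c(2 * mu * eps[1:3] + lam * sum(eps[1:3]), mu * eps[4:6])
  for (e in 1:8) expect_equal(unname(sf$S[e, ]), expected, tolerance = 1e-6)
})

test_that("stress recovery reproduces uniform states", {
  mat <- default_material_library()
  E <- mat$E[mat$region == "trabecular"]; nu <- mat$nu[mat$region == "trabecular"]
  mesh <- hex_column_mesh(2)
  sys <- assemble_global_stiffness(mesh, mat)
  sys <- apply_boundary_conditions(sys, column_uniaxial_bcs(mesh))
  top <- which(abs(mesh$nodes[, 3] - 2) < 1e-9)
  U <- solve_static(sys, data.frame(node = top, dof = 3, value = -0.25))
  sf <- recover_hex_stresses(mesh, U, mat)
  expect_equal(unname(sf$S[, "zz"]), c(-1, -1), tolerance = 1e-6)
  expect_lt(max(abs(sf$S[, c("xx", "yy", "xy", "yz", "zx")])), 1e-6)

  # prescribed simple shear gamma -> tau = G gamma
  gam <- 1e-3
  Us <- matrix(0, nrow(mesh$nodes), 6)
  Us[, 1] <- gam * mesh$nodes[, 3]
  sfs <- recover_hex_stresses(mesh, Us, mat)
  expect_equal(unname(sfs$S[, "zx"]), rep(E / (2 * (1 + nu)) * gam, 2),
               tolerance = 1e-9)
  expect_lt(max(abs(sfs$S[, c("xx", "yy", "zz", "xy", "yz")])), 1e-12)
})

test_that("spring elements assemble in series with the reciprocal-sum stiffness", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  springs <- data.frame(n1 = c(1, 2), n2 = c(2, 3), k = c(30, 70),
                        tension_only = FALSE, region = "facet")
  mesh <- spine_mesh(nodes, springs = springs)
  sys <- assemble_global_stiffness(mesh)
  sys <- apply_boundary_conditions(sys, bc_set(fixed = rbind(
    data.frame(node = 1, dof = 1:3),
    expand.grid(node = 2:3, dof = 2:3))))
  F <- 5
  u <- solve_static(sys, data.frame(node = 3, dof = 1, value = F))
  expect_equal(u[3, 1], F / (30 * 70 / (30 + 70)), tolerance = 1e-9)
})
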