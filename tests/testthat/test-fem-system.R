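test_that("global assembly is symmetric and energy-additive over elements", {
  set.seed(31)
  mesh <- hex_column_mesh(10)
  mat <- default_material_library()
  sys <- assemble_global_stiffness(mesh, mat)
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-12)

  # strain energy of a random displacement field equals the sum of the
  # per-element energies computed one element at a time (brute force)
  u <- rnorm(sys$n_dof, sd = 0.01)
  total <- as.numeric(0.5 * (u %*% (sys$K %*% u)))
  per_el <- 0
  for (e in seq_len(nrow(mesh$hex_conn))) {
    nd <- mesh$hex_conn[e, ]
    ke <- hex_element_stiffness(
      hex_element(nd, mat$E[mat$region == "trabecular"],
                  mat$nu[mat$region == "trabecular"]),
      mesh$nodes[nd, ])
    idx <- as.vector(t(sys$dof_map[nd, 1:3]))
    per_el <- per_el + 0.5 * sum(u[idx] * (ke %*% u[idx]))
  }
  expect_equal(total, per_el, tolerance = 1e-9)
})

test_that("boundary conditions eliminate DOFs and add point-spring stiffness", {
  sys <- beam_cantilever_system(2)
  n_free0 <- sys$n_dof - length(sys$fixed)
  sys2 <- apply_boundary_conditions(sys, bc_set(fixed = data.frame(node = 3, dof = 1:6)))
  expect_equal(length(sys2$fixed) - length(sys$fixed), 6)

  k <- 123.4
  d <- sys$dof_map[2, 5]
  sys3 <- apply_boundary_conditions(sys, bc_set(springs = data.frame(node = 2, dof = 5, k = k)))
  expect_equal(sys3$K[d, d] - sys$K[d, d], k, tolerance = 1e-12)

  mesh <- hex_column_mesh(1)
  hsys <- assemble_global_stiffness(mesh)
  expect_error(apply_boundary_conditions(
    hsys, bc_set(fixed = data.frame(node = 1, dof = 5))), "nonexistent DOF")
})

test_that("solver is consistent, accurate on a beam chain, and flags singular systems", {
  sys <- beam_cantilever_system(10)
  free <- setdiff(seq_len(sys$n_dof), sys$fixed)
  set.seed(32)
  u_ref <- numeric(sys$n_dof)
  u_ref[free] <- rnorm(length(free), sd = 0.1)
  f <- as.numeric(sys$K %*% u_ref)
  f[sys$fixed] <- 0
  U <- solve_static(sys, f)
  expect_equal(attr(U, "dof_vector")[free], u_ref[free], tolerance = 1e-8)

  P <- 3; L <- 100; E <- 1000; I <- 2000
  u <- solve_static(sys, data.frame(node = 11, dof = 2, value = P))
  expect_equal(u[11, 2], P * L^3 / (3 * E * I), tolerance = 1e-3)
  expect_gte(strain_energy(sys, u), 0)

  loose <- assemble_global_stiffness(hex_column_mesh(2))
  expect_error(solve_static(loose, data.frame(node = 1, dof = 3, value = 1)),
               "singular|rigid-body|constraints")
})

test_that("mesh refinement converges monotonically on a hex cantilever", {
  # slender solid cantilever bent by a tip load, compared to the
  # Euler-Bernoulli tip deflection P L^3 / (3 E I)
  mat <- override_materials(default_material_library(),
                            list(trabecular = list(nu = 0.3)))
  E <- mat$E[mat$region == "trabecular"]
  L <- 16; P <- 0.001
  exact <- P * L^3 / (3 * E * (1 * 1^3) / 12)
  errs <- sapply(c(4, 8, 16), function(n) {
    mesh <- hex_column_mesh(n)
    mesh$nodes[, 3] <- mesh$nodes[, 3] * L / n   # stretch to length L
    sys <- assemble_global_stiffness(mesh, mat)
    base <- which(abs(mesh$nodes[, 3]) < 1e-9)
    sys <- apply_boundary_conditions(sys, bc_set(fixed = expand.grid(node = base, dof = 1:3)))
    tip <- which(abs(mesh$nodes[, 3] - L) < 1e-9)
    u <- solve_static(sys, data.frame(node = tip, dof = 1, value = P / 4))
    abs(mean(u[tip, 1]) - exact) / exact
  })
  expect_true(all(diff(errs) < 0))
})

test_that("rigid translation of an unconstrained mesh stores no energy", {
  mesh <- hex_column_mesh(3)
  sys <- assemble_global_stiffness(mesh)
  u <- numeric(sys$n_dof)
  u[as.vector(t(sys$dof_map[, 1]))] <- 2.5    # uniform x translation
  expect_lt(as.numeric(u %*% (sys$K %*% u)), 1e-8)
})

test_that("tension-only springs deactivate in compression", {
  # vertical rod of two hexes with a parallel tension-only spring
  mesh <- hex_column_mesh(2)
  top <- which(abs(mesh$nodes[, 3] - 2) < 1e-9)
  mesh$springs <- data.frame(n1 = which(abs(mesh$nodes[, 1]) < 1e-9 &
                                        abs(mesh$nodes[, 2]) < 1e-9 &
                                        abs(mesh$nodes[, 3]) < 1e-9)[1],
                             n2 = top[1], k = 50, tension_only = TRUE,
                             region = "ligament_all")
  sys <- assemble_global_stiffness(mesh)
  sys <- apply_boundary_conditions(sys, column_uniaxial_bcs(mesh))

  # pull up: spring in tension, identical to one plain linear solve
  f_up <- data.frame(node = top, dof = 3, value = 0.25)
  U1 <- resolve_tension_only(sys, f_up)
  expect_true(all(attr(U1, "active_set")))
  expect_equal(attr(U1, "iterations"), 1L)
  expect_equal(unclass(U1), unclass(solve_static(sys, f_up)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # push down: spring must deactivate; solution equals the spring-free model
  f_dn <- data.frame(node = top, dof = 3, value = -0.25)
  U2 <- resolve_tension_only(sys, f_dn)
  expect_false(any(attr(U2, "active_set")))
  mesh0 <- mesh; mesh0$springs <- NULL
  sys0 <- assemble_global_stiffness(mesh0)
  sys0 <- apply_boundary_conditions(sys0, column_uniaxial_bcs(mesh0))
  U0 <- solve_static(sys0, f_dn)
  expect_equal(unclass(U2), unclass(U0), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(resolve_tension_only(sys, f_dn, max_iter = 0), "did not stabilize")
})
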