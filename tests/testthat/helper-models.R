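# shared fixtures, built in code

# a straight hexahedral column of `n` unit cubes stacked along z
hex_column_mesh <- function(n, region = "trabecular") {
  nodes <- NULL
  conn <- NULL
  reg <- new.env(parent = emptyenv())
  coords <- list(); cnt <- 0L
  addn <- function(p) {
    k <- paste(round(p, 9), collapse = ",")
    if (is.null(reg[[k]])) {
      cnt <<- cnt + 1L
      coords[[cnt]] <<- p
      reg[[k]] <- cnt
    }
    reg[[k]]
  }
  for (k in seq_len(n) - 1L) {
    c8 <- rbind(c(0, 0, k), c(1, 0, k), c(1, 1, k), c(0, 1, k),
                c(0, 0, k + 1), c(1, 0, k + 1), c(1, 1, k + 1), c(0, 1, k + 1))
    conn <- rbind(conn, apply(c8, 1, addn))
  }
  spine_mesh(do.call(rbind, coords), hex_conn = conn,
             hex_region = rep(region, n), hex_structure = rep("column", n))
}

# symmetry boundary conditions for uniaxial z loading of hex_column_mesh
column_uniaxial_bcs <- function(mesh) {
  nd <- mesh$nodes
  bc_set(fixed = rbind(
    data.frame(node = which(abs(nd[, 3]) < 1e-9), dof = 3),
    data.frame(node = which(abs(nd[, 1]) < 1e-9), dof = 1),
    data.frame(node = which(abs(nd[, 2]) < 1e-9), dof = 2)))
}

# a cantilever chain of `n` identical beam elements along x
beam_cantilever_system <- function(n, L = 100, E = 1000, A = 50, I = 2000,
                                   G = 400, J = 4000) {
  x <- seq(0, L, length.out = n + 1)
  nodes <- cbind(x, 0, 0)
  beams <- data.frame(n1 = seq_len(n), n2 = seq_len(n) + 1L,
                      E = E, G = G, A = A, Iy = I, Iz = I, J = J,
                      ox = 0, oy = 0, oz = 1, region = "beam")
  mesh <- spine_mesh(nodes, beams = beams)
  sys <- assemble_global_stiffness(mesh)
  apply_boundary_conditions(sys, bc_set(fixed = data.frame(node = 1, dof = 1:6)))
}

# random symmetric 3x3 stress tensor in Voigt order (xx yy zz xy yz zx)
random_voigt <- function() stats::rnorm(6, sd = 5)

voigt_to_matrix <- function(s) {
  matrix(c(s[1], s[4], s[6],
           s[4], s[2], s[5],
           s[6], s[5], s[3]), 3, 3)
}

# a random orthonormal right-handed frame
random_frame <- function() {
  repeat {
    M <- matrix(stats::rnorm(9), 3, 3)
    q <- qr(M)
    R <- qr.Q(q)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    if (abs(det(R) - 1) < 1e-9) break
  }
  structure(list(origin = c(0, 0, 0),
                 axes = rbind(xp = R[1, ], yp = R[2, ], zp = R[3, ])),
            class = "plate_frame")
}

# small standing model: template geometry -> coarse mesh -> constrained system
small_standing_model <- function(targets = list(PI = 61, SS = 52, slip_pct = 30),
                                 nx = 6, ny = 6) {
  geom <- generate_template_geometry(targets = targets, include_ribs = FALSE)
  mesh <- build_detailed_mesh(geom, resolution = mesh_resolution(nx, ny, 3, 2, 3))
  sys <- assemble_global_stiffness(mesh)
  sys <- apply_boundary_conditions(sys, standing_boundary_conditions(sys))
  list(geom = geom, mesh = mesh, sys = sys,
       dist = body_weight_distribution(45.5))
}

# the default campaign is expensive; run it once per test session
.campaign_cache <- new.env(parent = emptyenv())
cached_default_campaign <- function() {
  if (is.null(.campaign_cache$campaign)) {
    .campaign_cache$campaign <- run_simulation_campaign(seed = 1L)
  }
  .campaign_cache$campaign
}
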