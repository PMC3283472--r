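#' Hybrid finite-element mesh container
#'
#' Holds the node table and the three element families used by the spine
#' model: 8-node hexahedra (volumetric L4-pelvis segment), two-node beams
#' (thoracic spine, rib cage, pelvis struts) and axial springs (ligaments,
#' facet contact). Named node groups carry the anatomical attachment points
#' (acetabula, T1, segmental centroid chain, growth-plate surfaces).
#'
#' @param nodes n x 3 numeric matrix of node positions (mm); row i is node i.
#' @param hex_conn h x 8 integer matrix of hexahedral connectivity
#'   (VTK corner ordering), or NULL.
#' @param hex_region length-h character vector of material region labels.
#' @param hex_structure length-h character vector of anatomical structure
#'   labels (e.g. "s1_growth_plate", "disc_l5s1").
#' @param beams data frame with columns n1, n2, E, G, A, Iy, Iz, J,
#'   ox, oy, oz, region (or NULL).
#' @param springs data frame with columns n1, n2, k, tension_only, region
#'   (or NULL).
#' @param node_groups named list of integer node-id vectors.
#' @return a `spine_mesh` object.
#' @export
spine_mesh <- function(nodes, hex_conn = NULL, hex_region = character(),
                       hex_structure = character(), beams = NULL,
                       springs = NULL, node_groups = list()) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, all(is.finite(nodes)))
  n <- nrow(nodes)
  refs <- c(as.integer(hex_conn), beams$n1, beams$n2, springs$n1, springs$n2)
  if (length(refs) && (min(refs) < 1 || max(refs) > n)) {
    stop("element connectivity references nonexistent nodes")
  }
  if (!is.null(hex_conn)) {
    hex_conn <- matrix(as.integer(hex_conn), ncol = 8)
    stopifnot(length(hex_region) == nrow(hex_conn),
              length(hex_structure) == nrow(hex_conn))
  }
  structure(list(nodes = nodes, hex_conn = hex_conn,
                 hex_region = hex_region, hex_structure = hex_structure,
                 beams = beams, springs = springs,
                 node_groups = node_groups),
            class = "spine_mesh")
}

#' @export
print.spine_mesh <- function(x, ...) {
  cat(sprintf(
    "<spine_mesh> %d nodes | %d hex, %d beam, %d spring elements\n",
    nrow(x$nodes),
    if (is.null(x$hex_conn)) 0L else nrow(x$hex_conn),
    if (is.null(x$beams)) 0L else nrow(x$beams),
    if (is.null(x$springs)) 0L else nrow(x$springs)))
  invisible(x)
}

#' Total element count of a mesh
#' @param mesh a `spine_mesh`.
#' @return number of hex + beam + spring elements.
#' @export
n_elements <- function(mesh) {
  (if (is.null(mesh$hex_conn)) 0L else nrow(mesh$hex_conn)) +
    (if (is.null(mesh$beams)) 0L else nrow(mesh$beams)) +
    (if (is.null(mesh$springs)) 0L else nrow(mesh$springs))
}

# DOF map: 6 potential DOF per node (ux uy uz rx ry rz); translations are
# active everywhere, rotations only at nodes carrying beam elements.
.build_dof_map <- function(mesh) {
  n <- nrow(mesh$nodes)
  rot_nodes <- unique(c(mesh$beams$n1, mesh$beams$n2))
  active <- matrix(FALSE, n, 6)
  active[, 1:3] <- TRUE
  active[rot_nodes, 4:6] <- TRUE
  dof <- matrix(0L, n, 6)
  dof[active] <- seq_len(sum(active))
  dof
}

#' Assemble the global stiffness matrix
#'
#' Assembles all hexahedra, beams and springs into one symmetric sparse
#' stiffness matrix. Tension-only springs are assembled in their active
#' (tension-carrying) state; their individual contributions are retained so
#' the active-set iteration can deactivate them.
#'
#' @param mesh a [spine_mesh()].
#' @param materials a material library (see [default_material_library()])
#'   resolving every hex region label to E and nu.
#' @return a `fem_system`: fields `K` (sparse dsCMatrix), `dof_map`,
#'   `mesh`, `materials`, `n_dof`, `fixed` (none yet), `bc_springs`.
#' @export
assemble_global_stiffness <- function(mesh,
                                      materials = default_material_library()) {
  dof <- .build_dof_map(mesh)
  ndof <- max(dof)
  ti <- list(); tj <- list(); tx <- list(); p <- 0L
  push <- function(idx, ke) {
    p <<- p + 1L
    ij <- expand.grid(a = idx, b = idx)
    ti[[p]] <<- ij$a; tj[[p]] <<- ij$b; tx[[p]] <<- as.vector(ke)
  }

  if (!is.null(mesh$hex_conn) && nrow(mesh$hex_conn)) {
    mat <- material_lookup(materials, mesh$hex_region)
    for (e in seq_len(nrow(mesh$hex_conn))) {
      nd <- mesh$hex_conn[e, ]
      ke <- tryCatch(
        hex_element_stiffness(
          hex_element(nd, mat$E[e], mat$nu[e], mesh$hex_region[e]),
          mesh$nodes[nd, , drop = FALSE]),
        error = function(err) {
          stop(sprintf("hex element %d (%s): %s", e, mesh$hex_region[e],
                       conditionMessage(err)))
        })
      push(as.vector(t(dof[nd, 1:3])), ke)
    }
  }
  if (!is.null(mesh$beams) && nrow(mesh$beams)) {
    for (e in seq_len(nrow(mesh$beams))) {
      b <- mesh$beams[e, ]
      el <- beam_element(b$n1, b$n2, b$E, b$G, b$A, b$Iy, b$Iz, b$J,
                         orientation = c(b$ox, b$oy, b$oz), region = b$region)
      ke <- beam_element_stiffness(el, mesh$nodes[c(b$n1, b$n2), ])
      push(as.vector(t(dof[c(b$n1, b$n2), ])), ke)
    }
  }
  spring_triplets <- list()
  if (!is.null(mesh$springs) && nrow(mesh$springs)) {
    for (e in seq_len(nrow(mesh$springs))) {
      s <- mesh$springs[e, ]
      el <- spring_element(s$n1, s$n2, s$k, s$tension_only, s$region)
      ke <- spring_element_stiffness(el, mesh$nodes[c(s$n1, s$n2), ])
      idx <- as.vector(t(dof[c(s$n1, s$n2), 1:3]))
      push(idx, ke)
      if (isTRUE(s$tension_only)) {
        ij <- expand.grid(a = idx, b = idx)
        spring_triplets[[length(spring_triplets) + 1L]] <-
          list(spring = e, i = ij$a, j = ij$b, x = as.vector(ke))
      }
    }
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ndof, ndof))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  structure(list(K = K, dof_map = dof, mesh = mesh, materials = materials,
                 n_dof = ndof, fixed = integer(0),
                 spring_triplets = spring_triplets,
                 bc_springs = NULL),
            class = "fem_system")
}

#' Boundary-condition set constructor
#'
#' @param fixed data frame with columns `node`, `dof` (1..6: ux uy uz rx ry
#'   rz) of DOFs fixed to zero, or NULL.
#' @param springs data frame with columns `node`, `dof`, `k` of grounded
#'   point springs (e.g. acetabular torsion springs on rotational DOFs),
#'   or NULL.
#' @return a `bc_set` list.
#' @export
bc_set <- function(fixed = NULL, springs = NULL) {
  structure(list(fixed = fixed, springs = springs), class = "bc_set")
}

#' Apply boundary conditions to an assembled system
#'
#' Fixed DOFs are removed from the free set (eliminated at solve time);
#' grounded point springs add their stiffness to the matching diagonal
#' entries.
#'
#' @param system a `fem_system` from [assemble_global_stiffness()].
#' @param bcs a [bc_set()].
#' @return the constrained `fem_system`.
#' @export
apply_boundary_conditions <- function(system, bcs) {
  dof <- system$dof_map
  get_idx <- function(node, d) {
    if (any(node < 1 | node > nrow(dof))) stop("boundary condition on nonexistent node")
    idx <- dof[cbind(node, d)]
    if (any(idx == 0L)) {
      stop("boundary condition on nonexistent DOF (rotation at a node without rotational DOFs)")
    }
    idx
  }
  if (!is.null(bcs$fixed) && nrow(bcs$fixed)) {
    idx <- get_idx(bcs$fixed$node, bcs$fixed$dof)
    system$fixed <- sort(unique(c(system$fixed, idx)))
  }
  if (!is.null(bcs$springs) && nrow(bcs$springs)) {
    idx <- get_idx(bcs$springs$node, bcs$springs$dof)
    d <- numeric(system$n_dof)
    d[idx] <- d[idx] + bcs$springs$k
    system$K <- system$K + Matrix::Diagonal(system$n_dof, d)
    system$bc_springs <- rbind(system$bc_springs, bcs$springs)
  }
  system
}

# free-DOF stiffness with a given tension-only active set (logical vector
# over system$spring_triplets); inactive springs are subtracted from K
.K_active <- function(system, active = NULL) {
  K <- system$K
  if (!is.null(active) && length(system$spring_triplets)) {
    off <- which(!active)
    if (length(off)) {
      tr <- system$spring_triplets[off]
      K <- K - Matrix::forceSymmetric(Matrix::sparseMatrix(
        i = unlist(lapply(tr, `[[`, "i")),
        j = unlist(lapply(tr, `[[`, "j")),
        x = unlist(lapply(tr, `[[`, "x")),
        dims = dim(K)))
    }
  }
  K
}

.free_dofs <- function(system) setdiff(seq_len(system$n_dof), system$fixed)

#' Build a global load vector
#'
#' @param system a `fem_system`.
#' @param loads data frame with columns `node`, `dof` (1..6), `value`
#'   (N or N.mm), or a full-length numeric DOF vector.
#' @return numeric vector of length `system$n_dof`.
#' @export
load_vector <- function(system, loads) {
  if (is.numeric(loads) && length(loads) == system$n_dof) return(loads)
  f <- numeric(system$n_dof)
  idx <- system$dof_map[cbind(loads$node, loads$dof)]
  if (any(idx == 0L)) stop("load applied to an inactive DOF")
  for (r in seq_along(idx)) f[idx[r]] <- f[idx[r]] + loads$value[r]
  f
}

#' Solve the constrained linear-static system
#'
#' Sparse Cholesky factorization of the free-DOF stiffness; the relative
#' residual ||Ku - f|| / ||f|| must fall below 1e-8.
#'
#' @param system a constrained `fem_system`.
#' @param loads load specification, see [load_vector()].
#' @param factor optional pre-computed factorization (internal reuse).
#' @return a `displacement_field`: n x 6 matrix of nodal displacements
#'   (mm) and rotations (rad), with attributes `residual` and `system`.
#' @export
solve_static <- function(system, loads, factor = NULL) {
  f <- load_vector(system, loads)
  free <- .free_dofs(system)
  if (!length(free)) stop("all DOFs are fixed")
  Kff <- system$K[free, free, drop = FALSE]
  ff <- f[free]
  if (is.null(factor)) {
    factor <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                       error = function(e) NULL)
  }
  uf <- if (!is.null(factor)) {
    as.numeric(Matrix::solve(factor, ff))
  } else {
    tryCatch(as.numeric(Matrix::solve(Kff, ff)), error = function(e) {
      stop("singular stiffness matrix: the model has unconstrained rigid-body modes; add boundary conditions")
    })
  }
  if (!all(is.finite(uf))) {
    stop("singular stiffness matrix: the model has unconstrained rigid-body modes; add boundary conditions")
  }
  fn <- sqrt(sum(ff^2))
  res <- if (fn > 0) {
    sqrt(sum((as.numeric(Kff %*% uf) - ff)^2)) / fn
  } else 0
  if (res > 1e-8) {
    stop(sprintf(
      "linear solve did not reach the residual tolerance (%.2e > 1e-8); the system is ill-conditioned - check constraints", res))
  }
  u <- numeric(system$n_dof)
  u[free] <- uf
  U <- matrix(0, nrow(system$mesh$nodes), 6)
  act <- system$dof_map > 0
  U[act] <- u[system$dof_map[act]]
  structure(U, class = "displacement_field", residual = res,
            dof_vector = u)
}

#' Strain energy of a solution
#' @param system a `fem_system`.
#' @param u a `displacement_field` from [solve_static()].
#' @return 0.5 u' K u (N.mm).
#' @export
strain_energy <- function(system, u) {
  v <- attr(u, "dof_vector")
  as.numeric(0.5 * (v %*% (system$K %*% v)))
}

# axial elongation of each tension-only spring under displacement U (n x 6)
.tension_only_elongations <- function(system, U) {
  tr <- system$spring_triplets
  if (!length(tr)) return(numeric(0))
  sp <- system$mesh$springs
  vapply(tr, function(t3) {
    s <- sp[t3$spring, ]
    d <- system$mesh$nodes[s$n2, ] - system$mesh$nodes[s$n1, ]
    a <- d / sqrt(sum(d^2))
    sum((U[s$n2, 1:3] - U[s$n1, 1:3]) * a)
  }, numeric(1))
}

# generic active-set iteration over the tension-only springs; solve_fun
# maps a logical active set to a displacement field. Springs inside a small
# elongation dead band keep their state; if a proposed full update revisits
# a previous set (cycle), only the single most violated spring is flipped.
.active_set_iterate <- function(model, loads, active0, max_iter, solve_fun) {
  nt <- length(model$spring_triplets)
  if (nt == 0) {
    return(list(U = solve_fun(logical(0)), active = logical(0),
                iterations = 1L))
  }
  band <- 1e-9
  active <- if (is.null(active0)) rep(TRUE, nt) else active0
  seen <- character(0)
  iter <- 0L
  repeat {
    U <- solve_fun(active)
    iter <- iter + 1L
    e <- .tension_only_elongations(model, U)
    new_active <- active
    new_active[e < -band] <- FALSE
    new_active[e > band] <- TRUE
    if (identical(new_active, active)) {
      return(list(U = U, active = active, iterations = iter))
    }
    if (iter > max_iter) {
      stop(sprintf("tension-only iteration did not stabilize in %d iterations",
                   max_iter))
    }
    seen <- c(seen, paste(as.integer(active), collapse = ""))
    key <- paste(as.integer(new_active), collapse = "")
    if (key %in% seen) {
      viol <- ifelse(active, pmax(0, -e), pmax(0, e))
      viol[new_active == active] <- 0
      j <- which.max(viol)
      new_active <- active
      new_active[j] <- !active[j]
      if (paste(as.integer(new_active), collapse = "") %in% seen) {
        stop("tension-only active set is oscillating; no stable configuration found")
      }
    }
    active <- new_active
  }
}

#' Resolve tension-only (ligament) springs by active-set iteration
#'
#' Solves the model repeatedly, deactivating tension-only springs that end
#' up in compression and reactivating those that would be stretched, until
#' the active set is stable. At return no active tension-only spring is
#' compressed (beyond a 1e-9 mm dead band).
#'
#' @param model a constrained `fem_system`.
#' @param loads load specification (see [load_vector()]).
#' @param max_iter maximum number of active-set updates.
#' @return a `displacement_field` with attributes `active_set` (logical per
#'   tension-only spring) and `iterations`.
#' @export
resolve_tension_only <- function(model, loads, max_iter = 20) {
  res <- .active_set_iterate(model, loads, NULL, max_iter, function(active) {
    sys_a <- model
    sys_a$K <- .K_active(model, active)
    solve_static(sys_a, loads)
  })
  U <- res$U
  attr(U, "active_set") <- res$active
  attr(U, "iterations") <- res$iterations
  U
}

#' Recover element-centroid stresses in the hexahedral region
#'
#' Computes the symmetric Cauchy stress tensor per hexahedral element from a
#' solved displacement field: sigma = D B u evaluated at the 2x2x2 Gauss
#' points and averaged to the element centroid (Hooke's law, isotropic
#' material per region).
#'
#' @param mesh a [spine_mesh()].
#' @param displacements a `displacement_field`.
#' @param materials material library resolving the hex regions.
#' @return a `stress_field`: list with `S` (h x 6 matrix, Voigt order
#'   xx,yy,zz,xy,yz,zx, MPa, global frame), `centroid` (h x 3, mm),
#'   `region`, `structure`.
#' @export
recover_hex_stresses <- function(mesh, displacements,
                                 materials = default_material_library()) {
  if (is.null(mesh$hex_conn) || !nrow(mesh$hex_conn)) {
    stop("mesh has no hexahedral elements")
  }
  mat <- material_lookup(materials, mesh$hex_region)
  h <- nrow(mesh$hex_conn)
  S <- matrix(0, h, 6,
              dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  centroid <- matrix(0, h, 3)
  for (e in seq_len(h)) {
    nd <- mesh$hex_conn[e, ]
    X <- mesh$nodes[nd, , drop = FALSE]
    ue <- as.vector(t(displacements[nd, 1:3]))
    D <- .isotropic_D(mat$E[e], mat$nu[e])
    sg <- numeric(6)
    for (g in seq_len(nrow(.gauss_pts))) {
      dN <- .hex_dN(.gauss_pts[g, 1], .gauss_pts[g, 2], .gauss_pts[g, 3])
      Jm <- t(dN) %*% X
      dNx <- dN %*% t(solve(Jm))
      sg <- sg + as.numeric(D %*% (.hex_B(dNx) %*% ue))
    }
    S[e, ] <- sg / nrow(.gauss_pts)
    centroid[e, ] <- colMeans(X)
  }
  structure(list(S = S, centroid = centroid, region = mesh$hex_region,
                 structure = mesh$hex_structure),
            class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("<stress_field> %d elements, structures: %s\n", nrow(x$S),
              paste(unique(x$structure), collapse = ", ")))
  invisible(x)
}
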