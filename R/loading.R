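#' Per-vertebra body-weight load distribution
#'
#' Gravity loading of the trunk expressed as a fraction of total body
#' weight entering the spine at each vertebral body centroid (head, neck
#' and arm mass at T1, trunk slices level by level), after published
#' trunk-weight distributions. Forces act along -z (gravity).
#'
#' @param body_weight_kg total body weight (kg).
#' @param fraction_table named numeric vector of body-weight fractions per
#'   vertebra (T1..L5 or any subset); see [default_weight_fractions()].
#' @param g gravitational acceleration (m/s^2).
#' @return a `load_distribution` data frame with columns `vertebra`,
#'   `fraction`, `force_N` (magnitude, directed along -z), and attributes
#'   `body_weight_kg`, `g`.
#' @export
body_weight_distribution <- function(body_weight_kg,
                                     fraction_table = default_weight_fractions(),
                                     g = 9.81) {
  if (body_weight_kg < 0) stop("body weight must be >= 0")
  if (any(fraction_table < 0)) stop("fractions must be >= 0")
  if (sum(fraction_table) > 1 + 1e-12) {
    stop("body-weight fractions sum to more than 1")
  }
  out <- data.frame(vertebra = names(fraction_table),
                    fraction = as.numeric(fraction_table),
                    force_N = as.numeric(fraction_table) * body_weight_kg * g,
                    stringsAsFactors = FALSE)
  attr(out, "body_weight_kg") <- body_weight_kg
  attr(out, "g") <- g
  class(out) <- c("load_distribution", "data.frame")
  out
}

#' Follower load vectors tangent to the spinal curve
#'
#' Converts per-segment force magnitudes into force vectors directed along
#' the local tangent of the segmental centroid polyline (central finite
#' differences, one-sided at the ends), the discrete form of a follower
#' load that "follows" the kyphotic and lordotic curvature. Magnitudes are
#' preserved exactly; directions are unit vectors pointing caudally when
#' the chain is ordered cranio-caudally.
#'
#' @param centroid_chain n x 3 matrix of segmental centroids, ordered
#'   cranio-caudal (n >= 3).
#' @param magnitudes length-n force magnitudes (N).
#' @return a `follower_load_state`: list with `points`, `magnitudes`,
#'   `directions` (n x 3, unit rows).
#' @export
follower_load_vectors <- function(centroid_chain, magnitudes) {
  P <- as.matrix(centroid_chain)
  n <- nrow(P)
  if (n < 3) stop("at least 3 centroids are required")
  stopifnot(length(magnitudes) == n)
  seg <- P[-1, , drop = FALSE] - P[-n, , drop = FALSE]
  if (any(sqrt(rowSums(seg^2)) < 1e-9)) {
    stop("duplicate consecutive centroids in the chain")
  }
  Tg <- matrix(0, n, 3)
  Tg[1, ] <- P[2, ] - P[1, ]
  Tg[n, ] <- P[n, ] - P[n - 1, ]
  if (n > 2) Tg[2:(n - 1), ] <- P[3:n, , drop = FALSE] - P[1:(n - 2), , drop = FALSE]
  Tg <- Tg / sqrt(rowSums(Tg^2))
  structure(list(points = P, magnitudes = as.numeric(magnitudes),
                 directions = Tg),
            class = "follower_load_state")
}

#' Cumulative internal follower force along the chain
#'
#' The internal compressive force carried below each segmental centroid
#' equals the weight of all body segments entering the spine at or above
#' that level. This is the force the follower scheme redirects along the
#' spinal curve; the external load applied at each centroid is only that
#' level's weight increment (see [follower_equilibrium_iteration()]).
#'
#' @param distribution a [body_weight_distribution()].
#' @param levels vertebra labels of the chain nodes, cranio-caudal order.
#' @return numeric vector of cumulative internal force magnitudes (N).
#' @export
follower_magnitudes <- function(distribution, levels) {
  f <- distribution$force_N[match(levels, distribution$vertebra)]
  f[is.na(f)] <- 0
  cumsum(f)
}

# per-node applied force increments (N): each vertebra's own weight share
.follower_increments <- function(distribution, levels) {
  f <- distribution$force_N[match(levels, distribution$vertebra)]
  f[is.na(f)] <- 0
  f
}

#' Standing-posture boundary conditions
#'
#' Fixes the translations of both acetabular nodes, attaches grounded
#' torsion springs to their rotational DOFs, and blocks the transverse
#' (x, y) translations of T1, leaving its vertical translation free - the
#' standing-posture support of the model.
#'
#' @param model a `fem_system` whose mesh has node groups
#'   `acetabulum_left`, `acetabulum_right` and `t1`.
#' @param torsion_stiffness rotational spring stiffness (N.mm/rad) at each
#'   acetabulum.
#' @return a [bc_set()].
#' @export
standing_boundary_conditions <- function(model, torsion_stiffness = 1000) {
  ng <- model$mesh$node_groups
  need <- c("acetabulum_left", "acetabulum_right", "t1")
  miss <- setdiff(need, names(ng))
  if (length(miss)) {
    stop("mesh is missing node group(s): ", paste(miss, collapse = ", "))
  }
  ac <- c(ng$acetabulum_left, ng$acetabulum_right)
  fixed <- rbind(
    expand.grid(node = ac, dof = 1:3),
    data.frame(node = ng$t1, dof = c(1, 2)))
  springs <- expand.grid(node = ac, dof = 4:6)
  springs$k <- torsion_stiffness
  bc_set(fixed = fixed, springs = springs)
}

# solve with a given tension-only active set, caching Cholesky factors of
# the free-DOF stiffness by active-set key in `cache` (an environment)
.solve_active <- function(model, loads, active, cache = NULL) {
  key <- if (length(active)) paste(as.integer(active), collapse = "") else "1"
  factor <- if (!is.null(cache)) cache[[key]] else NULL
  sys_a <- model
  sys_a$K <- .K_active(model, active)
  if (is.null(factor)) {
    free <- .free_dofs(sys_a)
    Kff <- sys_a$K[free, free, drop = FALSE]
    factor <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                       error = function(e) NULL)
    if (!is.null(cache) && !is.null(factor)) cache[[key]] <- factor
  }
  solve_static(sys_a, loads, factor = factor)
}

# one tension-only resolution pass reusing cached factorizations
.resolve_cached <- function(model, loads, active0, cache, max_iter = 30) {
  .active_set_iterate(model, loads, active0, max_iter, function(active) {
    .solve_active(model, loads, active, cache)
  })
}

#' Follower-load equilibrium iteration
#'
#' Fixed-point iteration for the deformed-configuration follower load:
#' starting from the undeformed centroid chain, force directions are set
#' tangent to the (deformed) chain, the constrained model is solved
#' (resolving tension-only ligaments), and the directions are recomputed
#' from the displaced centroids until the largest direction change falls
#' below `tol`. With `single_pass = TRUE` the tangents of the undeformed
#' chain are used once without updating.
#'
#' @param model a constrained `fem_system` whose mesh has an ordered
#'   `centroid_chain` node group (names = vertebra levels, cranio-caudal).
#' @param distribution a [body_weight_distribution()].
#' @param tol convergence tolerance on the direction change (rad).
#' @param max_iter maximum follower updates.
#' @param single_pass apply the follower directions of the undeformed
#'   geometry once, without equilibrium update.
#' @return a `displacement_field` with attributes `follower_state` (the
#'   final [follower_load_vectors()] state), `follower_iterations`,
#'   `converged`, `active_set`.
#' @export
follower_equilibrium_iteration <- function(model, distribution, tol = 1e-3,
                                           max_iter = 25,
                                           single_pass = FALSE) {
  ng <- model$mesh$node_groups
  if (is.null(ng$centroid_chain)) {
    stop("mesh has no centroid_chain node group")
  }
  chain <- ng$centroid_chain
  levels <- names(chain)
  X <- model$mesh$nodes[chain, , drop = FALSE]
  # external load at each centroid: that level's weight share, redirected
  # along the local tangent (the muscle-stabilized follower scheme); the
  # internal force then accumulates tangentially down the column
  mags <- .follower_increments(distribution, levels)
  cache <- new.env(parent = emptyenv())
  active <- NULL
  U <- matrix(0, nrow(model$mesh$nodes), 6)
  prev_dirs <- NULL
  state <- NULL
  iterations <- 0L
  converged <- FALSE
  changes <- numeric(0)
  for (it in seq_len(max(1L, max_iter))) {
    iterations <- it
    Pdef <- X + U[chain, 1:3, drop = FALSE]
    state <- follower_load_vectors(Pdef, mags)
    if (all(mags == 0)) { converged <- TRUE; break }
    loads <- data.frame(
      node = rep(chain, each = 3),
      dof = rep(1:3, length(chain)),
      value = as.vector(t(state$directions * mags)))
    res <- .resolve_cached(model, loads, active, cache)
    U <- res$U
    active <- res$active
    if (single_pass) { converged <- TRUE; break }
    if (!is.null(prev_dirs)) {
      dots <- pmin(1, pmax(-1, rowSums(state$directions * prev_dirs)))
      changes <- c(changes, max(acos(dots)))
      if (max(acos(dots)) < tol) { converged <- TRUE; break }
    }
    prev_dirs <- state$directions
  }
  if (!converged) {
    dots <- pmin(1, pmax(-1, rowSums(state$directions * prev_dirs)))
    stop(sprintf(
      "follower load did not converge in %d iterations (last direction change %.2e rad)",
      max_iter, max(acos(dots))))
  }
  attr(U, "follower_state") <- state
  attr(U, "follower_iterations") <- iterations
  attr(U, "direction_changes") <- changes
  attr(U, "converged") <- converged
  attr(U, "active_set") <- active
  U
}
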