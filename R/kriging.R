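#' Dual-kriging free-form deformation
#'
#' Personalizes a template point cloud to a set of target control points.
#' The deformation is a vector-valued dual-kriging interpolant with a cubic
#' radial kernel \eqn{K(r) = r^3} and a linear drift \eqn{(1, x, y, z)}:
#' it interpolates the control correspondences exactly, reproduces any affine
#' map of the controls globally, and is smooth elsewhere.
#'
#' @param template_points n x 3 matrix of points to deform (mm).
#' @param source_controls m x 3 matrix of control points in template space
#'   (m >= 4, not all coplanar, no duplicates).
#' @param target_controls m x 3 matrix of corresponding target positions.
#' @return n x 3 matrix of deformed template points.
#' @examples
#' src <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,1))
#' tgt <- src + 5   # uniform translation
#' krige_deform(matrix(runif(30), 10, 3), src, tgt)
#' @export
krige_deform <- function(template_points, source_controls, target_controls) {
  template_points <- as.matrix(template_points)
  S <- as.matrix(source_controls)
  Tg <- as.matrix(target_controls)
  if (nrow(S) != nrow(Tg)) {
    stop("source and target control sets must have the same number of points")
  }
  m <- nrow(S)
  if (m < 4) stop("at least 4 control points are required")
  if (anyDuplicated(round(S, 12))) {
    stop("duplicate source control points give a singular kriging system")
  }
  K <- .cubic_kernel_matrix(S, S)
  P <- cbind(1, S)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(Tg, matrix(0, 4, 3))
  coef <- tryCatch(solve(A, rhs), error = function(e) {
    stop("singular kriging system (coplanar or duplicate control points)")
  })
  W <- coef[seq_len(m), , drop = FALSE]
  B <- coef[m + 1:4, , drop = FALSE]
  Kq <- .cubic_kernel_matrix(template_points, S)
  Kq %*% W + cbind(1, template_points) %*% B
}

# pairwise cubic radial kernel |xi - yj|^3
.cubic_kernel_matrix <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  d2^1.5
}
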