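#' Thin-plate-spline warps in 3D
#'
#' Fits the interpolating 3D thin-plate spline that maps `source` control
#' points exactly onto `target` points. The 3D biharmonic kernel
#' \eqn{U(r) = r} is used, so the warp is
#' \deqn{f(x) = A^\top [1, x] + \sum_i W_i \, |x - p_i|}
#' with the side conditions \eqn{1^\top W = 0} and \eqn{P^\top W = 0} that
#' make the non-affine part orthogonal to affine maps. Coefficients solve
#' the standard bordered system \eqn{K W + P A = target, P^\top W = 0}
#' with \eqn{K_{ij} = |p_i - p_j|}, \eqn{P = [1 \mid p]}.
#'
#' @param source k x 3 matrix of control points (k >= 4, not all coplanar,
#'   no two points within 1e-9 mm).
#' @param target k x 3 matrix of corresponding targets.
#' @return a `tps_model` with fields `control_points`, `warp_weights` (W,
#'   k x 3), `affine` (4 x 3: row 1 translation, rows 2-4 linear part).
#' @export
fit_tps <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  k <- nrow(source)
  if (k < 4L || nrow(target) != k)
    .mc_stop("need k >= 4 matched control points", class = "validation_error")
  dup <- .coincident_pairs(source, tol = 1e-9)
  if (nrow(dup))
    .mc_stop("coincident control points: %s",
             paste(sprintf("(%d,%d)", pmin(dup[, 1], dup[, 2]),
                           pmax(dup[, 1], dup[, 2])), collapse = " "),
             class = "singularity_error")
  if (.points_coplanar(source))
    .mc_stop("control points are coplanar; 3D TPS is singular",
             class = "singularity_error")
  L <- .tps_bordered_matrix(source)
  rc <- rcond(L)
  if (is.finite(rc) && rc < 1e-12)
    warning(sprintf("TPS system ill-conditioned (rcond = %.2e)", rc))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    .mc_stop("singular TPS system: %s", conditionMessage(e),
             class = "singularity_error"))
  structure(list(control_points = source,
                 warp_weights = sol[seq_len(k), , drop = FALSE],
                 affine = sol[k + 1:4, , drop = FALSE],
                 kernel = "r"),
            class = "tps_model")
}

#' Evaluate a fitted thin-plate spline
#' @param model a `tps_model` from [fit_tps()].
#' @param query m x 3 matrix of points to warp.
#' @return m x 3 matrix of warped points.
#' @export
evaluate_tps <- function(model, query) {
  q <- if (is.null(dim(query))) matrix(query, ncol = 3) else as.matrix(query)
  U <- .pairwise_dist(q, model$control_points)  # m x k kernel values
  cbind(1, q) %*% model$affine + U %*% model$warp_weights
}

#' Bending-energy matrix of a control-point set
#'
#' The k x k quadratic form B whose evaluation on target coordinates gives
#' the TPS bending energy: the upper-left k x k block of the inverse of
#' the bordered matrix `[[K, P], [P', 0]]`, negated. (With the 3D kernel
#' U(r) = r that block is negative semidefinite — r is conditionally
#' negative definite, unlike the 2D r^2 log r kernel — so the sign flip
#' makes B the positive semidefinite energy form.) B annihilates affine
#' vectors (its null space contains the constant and the three coordinate
#' columns) and has rank at most k - 4.
#'
#' @param points k x 3 control points (preconditions as [fit_tps()]).
#' @return a `bending_energy` object with fields `matrix` and
#'   `source_points`.
#' @export
bending_energy_matrix <- function(points) {
  points <- as.matrix(points)
  k <- nrow(points)
  if (k < 4L)
    .mc_stop("need k >= 4 points", class = "validation_error")
  if (.points_coplanar(points))
    .mc_stop("coplanar points give a singular bordered system",
             class = "singularity_error")
  L <- .tps_bordered_matrix(points)
  Linv <- tryCatch(solve(L), error = function(e)
    .mc_stop("singular bordered system", class = "singularity_error"))
  B <- -Linv[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  structure(list(matrix = B, source_points = points),
            class = "bending_energy")
}

#' Bending energy of a target configuration
#'
#' `trace(target' B target)`: zero iff `target` is an affine image of the
#' source points, strictly positive for any non-affine deformation.
#'
#' @param B a `bending_energy` object (or plain k x k matrix).
#' @param target k x 3 target coordinates.
#' @return non-negative scalar.
#' @export
bending_energy <- function(B, target) {
  M <- if (inherits(B, "bending_energy")) B$matrix else as.matrix(B)
  target <- as.matrix(target)
  e <- sum(target * (M %*% target))
  max(e, 0)  # clip tiny negative round-off
}

.tps_bordered_matrix <- function(points) {
  k <- nrow(points)
  K <- .pairwise_dist(points, points)
  P <- cbind(1, points)
  rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
}

.pairwise_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.coincident_pairs <- function(points, tol = 1e-9) {
  d <- .pairwise_dist(points, points)
  d[upper.tri(d, diag = TRUE)] <- Inf
  which(d < tol, arr.ind = TRUE)
}

.points_coplanar <- function(points, tol = 1e-8) {
  ctr <- sweep(points, 2, colMeans(points))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  sv[3] <= tol * max(sv[1], 1e-300)
}
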