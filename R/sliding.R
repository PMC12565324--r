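#' Transfer template semi-landmarks onto a specimen mesh
#'
#' Fits a TPS on the ten fixed-landmark pairs (template -> specimen),
#' warps the 200 template semi-landmarks with it, and projects each warped
#' point onto the closest point of the specimen surface. Patch ids are
#' carried over from the template. The result is the initial (pre-slide)
#' configuration for [slide_semilandmarks()].
#'
#' @param template a `template_definition` from [generate_template()] (or
#'   any list with `mesh`, `fixed_landmarks`, `semilandmarks`,
#'   `patch_ids`).
#' @param target_mesh the specimen [triangle_mesh()].
#' @param target_fixed 10 x 3 matrix of the specimen's digitized fixed
#'   landmarks; each must lie within `surface_tol` of the surface.
#' @param specimen_id identifier for the output configuration.
#' @param surface_tol validation tolerance for the fixed landmarks (mm).
#' @return a [landmark_config()]: fixed rows first, then projected
#'   semi-landmarks in template order.
#' @export
transfer_semilandmarks <- function(template, target_mesh, target_fixed,
                                   specimen_id = "specimen",
                                   surface_tol = 0.5) {
  target_fixed <- as.matrix(target_fixed)
  if (nrow(target_fixed) != nrow(template$fixed_landmarks))
    .mc_stop("fixed landmark count mismatch", class = "validation_error")
  d <- closest_point_on_mesh(target_fixed, target_mesh)$distance
  if (any(d > surface_tol))
    .mc_stop("fixed landmark(s) %s more than %g mm off the surface",
             paste(which(d > surface_tol) - 1L, collapse = ","), surface_tol,
             class = "validation_error")
  if (nrow(.coincident_pairs(target_fixed)) || .points_coplanar(target_fixed))
    .mc_stop("degenerate (coincident or coplanar) fixed landmarks on target",
             class = "singularity_error")
  model <- fit_tps(template$fixed_landmarks, target_fixed)
  warped <- evaluate_tps(model, template$semilandmarks)
  proj <- closest_point_on_mesh(warped, target_mesh)$point
  landmark_config(rbind(target_fixed, proj),
                  c(rep(0L, nrow(target_fixed)), template$patch_ids),
                  specimen_id)
}

#' Tangent basis of the surface at a point
#'
#' Returns two orthonormal vectors spanning the tangent plane at the
#' surface point nearest `p`, plus the outward-ish surface normal.
#' Vertex and edge feet use area-weighted averages of the incident face
#' normals.
#'
#' @param p 3-vector.
#' @param mesh a [triangle_mesh()].
#' @return list with unit vectors `u`, `v`, `normal` (u x v basis of the
#'   tangent plane, both orthogonal to `normal`).
#' @export
tangent_basis <- function(p, mesh) {
  cp <- closest_point_on_mesh(p, mesh)
  n <- .surface_normal(cp$point[1, ], cp$triangle[1], mesh)
  .basis_from_normal(n)
}

.basis_from_normal <- function(n) {
  ax <- diag(3)[, which.min(abs(n))]
  u <- .cross3(n, ax)
  u <- u / sqrt(sum(u^2))
  v <- .cross3(n, u)
  list(u = u, v = v, normal = n)
}

#' Slide semi-landmarks to minimize thin-plate bending energy
#'
#' Iteratively relaxes the semi-landmarks of `initial` along the specimen
#' surface so that the bending energy of the TPS deformation from the
#' full template configuration to the specimen configuration is minimal.
#' Each iteration (i) builds the tangent plane of every semi-landmark,
#' (ii) solves the normal equations of the quadratic energy restricted to
#' tangential displacements, (iii) moves the points, re-projects them
#' onto the surface and recomputes the energy. Steps that fail to lower
#' the energy are halved (at most `max_halvings` times), so the recorded
#' energy trace is non-increasing. Fixed landmarks never move.
#'
#' @param template the template whose full configuration defines the
#'   bending-energy matrix (see [bending_energy_matrix()]).
#' @param initial on-surface starting configuration, typically from
#'   [transfer_semilandmarks()].
#' @param mesh the specimen [triangle_mesh()].
#' @param tol relative energy decrease below which iteration stops.
#' @param max_iter maximum sliding iterations.
#' @param max_halvings backtracking halvings per iteration.
#' @param B optional precomputed `bending_energy` of the template
#'   configuration (reused across specimens of a population).
#' @return a `sliding_result`: `configuration`, `energy_trace`
#'   (accepted energies, starting at the initial energy), `iterations`,
#'   `converged`.
#' @export
slide_semilandmarks <- function(template, initial, mesh, tol = 1e-6,
                                max_iter = 10L, max_halvings = 5L,
                                B = NULL) {
  if (is.null(B))
    B <- bending_energy_matrix(rbind(template$fixed_landmarks,
                                     template$semilandmarks))
  Bm <- B$matrix
  Y <- initial$coordinates
  k <- nrow(Y)
  sl <- which(initial$patch_ids > 0L)
  m <- length(sl)
  if (m == 0L)
    .mc_stop("configuration has no semi-landmarks", class = "validation_error")

  energy <- bending_energy(Bm, Y)
  trace <- energy
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    # tangent directions at the current semi-landmark feet
    cp <- closest_point_on_mesh(Y[sl, , drop = FALSE], mesh)
    D <- matrix(0, 2 * m, 3)     # direction vector of each tangential dof
    for (j in seq_len(m)) {
      b <- .basis_from_normal(.surface_normal(cp$point[j, ], cp$triangle[j],
                                              mesh))
      D[2 * j - 1, ] <- b$u
      D[2 * j, ] <- b$v
    }
    ii <- rep(sl, each = 2)      # landmark row backing each dof column
    BY <- Bm %*% Y
    g <- rowSums(D * BY[ii, , drop = FALSE])
    M <- Bm[ii, ii, drop = FALSE] * tcrossprod(D)
    lam <- 1e-10 * sum(diag(M))
    step <- tryCatch(-solve(M + diag(lam, nrow(M)), g),
                     error = function(e) -qr.solve(M + diag(lam, nrow(M)), g,
                                                   tol = 1e-14))
    if (!all(is.finite(step)))
      .mc_stop("non-finite sliding step at iteration %d (energy %.6g)",
               it, energy, class = "numerical_error")

    accepted <- FALSE
    scale <- 1
    for (h in 0:max_halvings) {
      disp <- matrix(0, m, 3)
      for (a in 1:3)
        disp[, a] <- step[c(TRUE, FALSE)] * scale * D[c(TRUE, FALSE), a] +
                     step[c(FALSE, TRUE)] * scale * D[c(FALSE, TRUE), a]
      cand <- Y
      cand[sl, ] <- closest_point_on_mesh(Y[sl, , drop = FALSE] + disp,
                                          mesh)$point
      e_new <- bending_energy(Bm, cand)
      if (!is.finite(e_new))
        .mc_stop("non-finite energy at iteration %d", it,
                 class = "numerical_error")
      if (e_new < energy) {
        Y <- cand
        drop_rel <- (energy - e_new) / max(energy, .Machine$double.eps)
        energy <- e_new
        trace <- c(trace, energy)
        accepted <- TRUE
        if (drop_rel < tol) converged <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!accepted) {             # local minimum within step precision
      converged <- TRUE
      break
    }
    if (converged) break
  }

  out <- initial
  out$coordinates <- Y
  structure(list(configuration = out, energy_trace = trace,
                 iterations = iter, converged = converged),
            class = "sliding_result")
}
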