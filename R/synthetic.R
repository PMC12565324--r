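#' Parameters of the synthetic cavity surface
#'
#' The synthetic unilateral cavity is a smooth parametric half-shell
#' S(u, v) over the unit square: u runs antero-posterior (depth), v runs
#' infero-superior. In the package coordinate convention X is
#' medio-lateral, Y antero-posterior, Z infero-superior, with the origin
#' at the anterior-inferior corner of the shell (the angle between the
#' inferior cutting plane and the cavity front):
#' \deqn{x = s\,[w_i (1-v) + (w_a (1-u) + w_p u) v]\,\sin(\pi v)}
#' \deqn{y = s\,[d\,u - c (1-u)^2 \sin(\pi v)]}
#' \deqn{z = s\,H\,v, \quad H = 40\ mm}
#' so `w_a` widens the anterior band, `w_p` the posterior-superior band,
#' `w_i` the inferior band, `d` deepens the cavity and `c` bows the
#' frontal (anterior) edge forward.
#'
#' @param w_a anterior width (mm).
#' @param w_p posterior-superior width (mm).
#' @param d antero-posterior depth (mm).
#' @param c_front frontal-edge curvature (mm of forward bowing).
#' @param w_i inferior width (mm).
#' @param s global size factor.
#' @return a `cavity_params` list.
#' @export
cavity_params <- function(w_a = 10, w_p = 12, d = 50, c_front = 6,
                          w_i = 8, s = 1) {
  p <- list(w_a = w_a, w_p = w_p, d = d, c_front = c_front, w_i = w_i, s = s)
  if (any(unlist(p[c("w_a", "w_p", "d", "w_i", "s")]) <= 0) || c_front < 0)
    .mc_stop("cavity parameters must be positive", class = "validation_error")
  structure(p, class = "cavity_params")
}

.cavity_height <- 40

# evaluate the cavity surface at parametric coordinates (vectorized)
.cavity_surface <- function(u, v, params) {
  p <- params
  W <- p$w_i * (1 - v) + (p$w_a * (1 - u) + p$w_p * u) * v
  cbind(x = p$s * W * sin(pi * v),
        y = p$s * (p$d * u - p$c_front * (1 - u)^2 * sin(pi * v)),
        z = p$s * .cavity_height * v)
}

# parametric (u, v) anchors: 10 fixed landmarks, roles approximating the
# fixed-landmark definitions; all coordinates are multiples of 0.05 so the
# anchors coincide with mesh grid vertices when the resolution is a
# multiple of 20.
.fixed_anchors <- function() {
  m <- rbind(
    anterior_origin           = c(0.00, 0.00),
    vestibule_anterior        = c(0.00, 0.15),
    valve_superior            = c(0.10, 0.80),
    olfactory_front_superior  = c(0.35, 1.00),
    olfactory_back_superior   = c(0.65, 1.00),
    choana_superior           = c(1.00, 0.90),
    septum_lowest             = c(0.50, 0.00),
    cutting_plane_posterior   = c(1.00, 0.00),
    valve_inferior            = c(0.10, 0.20),
    inferior_meatus_anterior  = c(0.20, 0.40))
  colnames(m) <- c("u", "v")
  m
}

# two 10 x 10 semi-landmark patches: anterior band (patch 1) and
# posterior band (patch 2)
.semilandmark_anchors <- function() {
  v <- seq(0.05, 0.95, by = 0.10)
  u1 <- seq(0.05, 0.50, by = 0.05)
  u2 <- seq(0.55, 1.00, by = 0.05)
  g1 <- expand.grid(u = u1, v = v)
  g2 <- expand.grid(u = u2, v = v)
  list(uv = rbind(as.matrix(g1), as.matrix(g2)),
       patch = rep(c(1L, 2L), each = 100L))
}

.cavity_mesh <- function(params, resolution) {
  r <- resolution
  uu <- seq(0, 1, length.out = r + 1)
  grid <- expand.grid(u = uu, v = uu)
  v <- .cavity_surface(grid$u, grid$v, params)
  idx <- function(i, j) (j - 1L) * (r + 1L) + i       # column-major grid
  tris <- vector("list", 2L * r * r)
  t0 <- 1L
  for (j in seq_len(r)) {
    for (i in seq_len(r)) {
      a <- idx(i, j); b <- idx(i + 1L, j)
      cc <- idx(i + 1L, j + 1L); dd <- idx(i, j + 1L)
      tris[[t0]] <- c(a, b, cc); tris[[t0 + 1L]] <- c(a, cc, dd)
      t0 <- t0 + 2L
    }
  }
  triangle_mesh(v, do.call(rbind, tris), clean = TRUE)
}

#' Generate the template cavity
#'
#' Builds the template surface at the default (or given) cavity
#' parameters, triangulated at `resolution` grid cells per side, and
#' places the 10 fixed landmarks and 200 semi-landmarks (two 10 x 10
#' patches: anterior and posterior bands) at fixed parametric anchors.
#' Landmarks are parametric, not mesh-snapped: refining the resolution
#' does not move them (anchors fall on grid vertices whenever the
#' resolution is a multiple of 20).
#'
#' @param resolution grid cells per parametric direction (multiple of 20
#'   keeps all landmarks exactly on the mesh).
#' @param params a [cavity_params()].
#' @return a `template_definition`: `mesh`, `fixed_landmarks` (10 x 3,
#'   row-named by role), `semilandmarks` (200 x 3), `patch_ids`,
#'   `fixed_anchors`, `semi_anchors`, `params`, `resolution`.
#' @export
generate_template <- function(resolution = 20L, params = cavity_params()) {
  fa <- .fixed_anchors()
  sa <- .semilandmark_anchors()
  fixed <- .cavity_surface(fa[, "u"], fa[, "v"], params)
  rownames(fixed) <- rownames(fa)
  semis <- .cavity_surface(sa$uv[, "u"], sa$uv[, "v"], params)
  structure(list(mesh = .cavity_mesh(params, resolution),
                 fixed_landmarks = fixed, semilandmarks = semis,
                 patch_ids = sa$patch, fixed_anchors = fa,
                 semi_anchors = sa$uv, params = params,
                 resolution = as.integer(resolution)),
            class = "template_definition")
}

#' Full 210-point template configuration
#' @param template a `template_definition`.
#' @return a [landmark_config()] (fixed rows first).
#' @export
template_configuration <- function(template) {
  landmark_config(rbind(template$fixed_landmarks, template$semilandmarks),
                  c(rep(0L, nrow(template$fixed_landmarks)),
                    template$patch_ids),
                  "template")
}

#' Generate one synthetic specimen
#'
#' Re-evaluates the template surface under `params`, mirrors it for
#' left-side specimens, and adds iid Gaussian digitization noise of sd
#' `sigma_dig` to the landmark coordinates (never to the mesh, which
#' stays exact for projection tests). `digitized_fixed` are the noisy
#' fixed landmarks re-projected onto the surface — what an operator
#' clicking on the rendered surface would record — and are the input the
#' pipeline hands to [transfer_semilandmarks()].
#'
#' @param params a [cavity_params()].
#' @param side `"right"` or `"left"`.
#' @param sigma_dig digitization noise sd (mm).
#' @param seed optional RNG seed.
#' @param resolution mesh resolution.
#' @param specimen_id identifier.
#' @return list with `mesh`, `landmarks` (ground-truth 210-point
#'   [landmark_config()], noise included), `digitized_fixed` (10 x 3,
#'   on-surface), `params`, `side`.
#' @export
generate_specimen <- function(params, side = "right", sigma_dig = 0,
                              seed = NULL, resolution = 20L,
                              specimen_id = "specimen") {
  if (!is.null(seed)) set.seed(seed)
  side <- match.arg(side, c("right", "left"))
  template <- generate_template(resolution, params)
  mesh <- template$mesh
  coords <- rbind(template$fixed_landmarks, template$semilandmarks)
  if (side == "left") {
    mesh <- mirror_sagittal(mesh)
    coords[, 1] <- -coords[, 1]
  }
  if (sigma_dig > 0)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, sigma_dig),
                              ncol = 3)
  digitized <- closest_point_on_mesh(coords[1:10, , drop = FALSE],
                                     mesh)$point
  list(mesh = mesh,
       landmarks = landmark_config(coords,
                                   c(rep(0L, 10L), template$patch_ids),
                                   specimen_id),
       digitized_fixed = digitized, params = params, side = side)
}

#' Specification of a synthetic population
#'
#' Defaults emulate the cohort structure the analysis expects: 45
#' patients with two sides each (90 cavities), three latent morphotypes
#' in proportions 0.25 / 0.55 / 0.20, cluster mean parameters encoding
#' the qualitative morphotype contrasts (cluster 1 widest
#' posterior-superior and anterior bands and shallowest, with the
#' flattest frontal edge; cluster 3 narrowest anterior band, deepest,
#' with the most curved frontal edge; cluster 2 intermediate with the
#' widest inferior band), within-cluster parameter sd at least 3x below
#' the between-cluster mean gaps, 0.3 mm digitization noise, and a 0.75
#' probability that a side inherits the patient's latent cluster.
#'
#' @param n_patients number of patients (two sides each).
#' @param cluster_proportions 3 proportions summing to 1.
#' @param cluster_means list of 3 [cavity_params()].
#' @param within_sd named sd per parameter.
#' @param sigma_dig landmark digitization noise sd (mm).
#' @param side_effect systematic left-side offset (mm) on the first 20
#'   semi-landmarks' Z; 0 = bilaterally symmetric population.
#' @param rho_pair probability a side keeps the patient's latent cluster.
#' @param resolution mesh resolution.
#' @param seed RNG seed (required by [generate_population()]).
#' @return a `population_spec` list.
#' @export
population_spec <- function(
    n_patients = 45L,
    cluster_proportions = c(0.25, 0.55, 0.20),
    cluster_means = list(
      cavity_params(w_a = 12, w_p = 14.0, d = 46, c_front = 4.5, w_i = 8),
      cavity_params(w_a = 10, w_p = 11.5, d = 50, c_front = 6.0, w_i = 10),
      cavity_params(w_a = 8,  w_p = 11.5, d = 54, c_front = 7.5, w_i = 8)),
    within_sd = c(w_a = 0.5, w_p = 0.5, d = 1.0, c_front = 0.5,
                  w_i = 0.5, s = 0.03),
    sigma_dig = 0.3, side_effect = 0, rho_pair = 0.75,
    resolution = 20L, seed = NULL) {
  if (abs(sum(cluster_proportions) - 1) > 1e-9)
    .mc_stop("cluster proportions must sum to 1", class = "validation_error")
  if (sigma_dig < 0 || rho_pair < 0 || rho_pair > 1)
    .mc_stop("sigma_dig >= 0 and rho_pair in [0,1] required",
             class = "validation_error")
  structure(list(n_patients = as.integer(n_patients),
                 cluster_proportions = cluster_proportions,
                 cluster_means = cluster_means, within_sd = within_sd,
                 sigma_dig = sigma_dig, side_effect = side_effect,
                 rho_pair = rho_pair, resolution = as.integer(resolution),
                 seed = seed),
            class = "population_spec")
}

#' Generate a synthetic population
#'
#' Per patient: a latent morphotype is drawn from the cluster
#' proportions; each side keeps it with probability `rho_pair` or
#' redraws; the side's cavity parameters are Gaussian around its cluster
#' means; sex and age are drawn independently of cluster. All draws are
#' governed by `spec$seed` (or the `seed` argument).
#'
#' @param spec a [population_spec()].
#' @param seed overrides `spec$seed`.
#' @return list with `specimens` (list of [generate_specimen()] results),
#'   `records` ([specimen_records()]), `cohort` (patient_id / sex / age),
#'   `labels` (named ground-truth cluster per specimen), `template`,
#'   `spec`.
#' @export
generate_population <- function(spec = population_spec(), seed = NULL) {
  seed <- seed %||% spec$seed
  if (is.null(seed)) .mc_stop("seed is required", class = "validation_error")
  set.seed(seed)
  nclus <- length(spec$cluster_means)
  draw_params <- function(cl) {
    mu <- spec$cluster_means[[cl]]
    sdv <- spec$within_sd
    cavity_params(
      w_a = max(1, stats::rnorm(1, mu$w_a, sdv[["w_a"]])),
      w_p = max(1, stats::rnorm(1, mu$w_p, sdv[["w_p"]])),
      d = max(5, stats::rnorm(1, mu$d, sdv[["d"]])),
      c_front = max(0, stats::rnorm(1, mu$c_front, sdv[["c_front"]])),
      w_i = max(1, stats::rnorm(1, mu$w_i, sdv[["w_i"]])),
      s = max(0.5, stats::rnorm(1, mu$s, sdv[["s"]])))
  }
  specimens <- list()
  labels <- integer(0)
  pid <- sprintf("P%03d", seq_len(spec$n_patients))
  rec_pid <- rec_side <- character(0)
  for (i in seq_len(spec$n_patients)) {
    latent <- sample.int(nclus, 1, prob = spec$cluster_proportions)
    for (side in c("right", "left")) {
      cl <- if (stats::runif(1) < spec$rho_pair) latent
            else sample.int(nclus, 1, prob = spec$cluster_proportions)
      sp <- generate_specimen(draw_params(cl), side = side,
                              sigma_dig = spec$sigma_dig,
                              resolution = spec$resolution,
                              specimen_id = paste(pid[i], side, sep = "_"))
      if (spec$side_effect != 0 && side == "left") {
        rows <- 10L + seq_len(20L)
        sp$landmarks$coordinates[rows, 3] <-
          sp$landmarks$coordinates[rows, 3] + spec$side_effect
      }
      specimens[[length(specimens) + 1L]] <- sp
      labels[sp$landmarks$specimen_id] <- cl
      rec_pid <- c(rec_pid, pid[i])
      rec_side <- c(rec_side, side)
    }
  }
  records <- specimen_records(rec_pid, rec_side)
  cohort <- data.frame(
    patient_id = pid,
    sex = sample(c("female", "male"), spec$n_patients, replace = TRUE,
                 prob = c(42, 35) / 77),
    age = pmin(85, pmax(15, round(stats::rnorm(spec$n_patients, 53.9, 20)))),
    stringsAsFactors = FALSE)
  list(specimens = specimens, records = records, cohort = cohort,
       labels = labels, template = generate_template(spec$resolution),
       spec = spec)
}

#' Deterministic small fixture population
#'
#' 12 patients, seed 17, default morphotype structure — the dataset the
#' test suite uses for end-to-end and determinism checks.
#' @export
fixture_population <- function() {
  generate_population(population_spec(n_patients = 12L, seed = 17L))
}
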