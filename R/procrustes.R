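#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid — the size measure removed by Procrustes superimposition.
#'
#' @param config a [landmark_config()] or k x 3 matrix.
#' @return non-negative scalar (mm). A zero size (all landmarks
#'   coincident) is returned with a warning.
#' @export
centroid_size <- function(config) {
  x <- .coords(config)
  ctr <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(ctr^2))
  if (cs < 1e-300)
    warning("degenerate configuration: centroid size is 0")
  cs
}

.coords <- function(config) {
  if (inherits(config, "landmark_config")) config$coordinates
  else as.matrix(config)
}

# center at origin and scale to unit centroid size
.normalize_config <- function(x, id = "configuration") {
  x <- sweep(x, 2, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs < 1e-300)
    .mc_stop("degenerate (zero-size) configuration: %s", id,
             class = "validation_error")
  x / cs
}

#' Optimal rotation of one configuration onto another
#'
#' Ordinary Procrustes rotation via SVD of the cross-covariance. With
#' `allow_reflection = FALSE` (the default; specimens are pre-mirrored to
#' a common side) the rotation determinant is forced to +1 by flipping
#' the smallest singular direction.
#'
#' @param mobile,reference centered, unit-size k x 3 matrices.
#' @param allow_reflection permit improper rotations.
#' @return list with `aligned` (rotated mobile), `rotation` (3 x 3) and
#'   `residual` (root summed squared difference to the reference).
#' @export
align_pair <- function(mobile, reference, allow_reflection = FALSE) {
  mobile <- .coords(mobile); reference <- .coords(reference)
  M <- crossprod(mobile, reference)        # 3 x 3 cross-covariance
  sv <- svd(M)
  if (sv$d[3] <= 1e-12 * max(sv$d[1], 1e-300))
    warning("rank-deficient cross-covariance; rotation may be unstable")
  S <- diag(3)
  if (!allow_reflection && det(sv$u %*% t(sv$v)) < 0)
    S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  aligned <- mobile %*% R
  list(aligned = aligned, rotation = R,
       residual = sqrt(sum((aligned - reference)^2)))
}

#' Generalized Procrustes Analysis
#'
#' Removes translation, scale and rotation from a sample of landmark
#' configurations: all specimens are centered and scaled to unit centroid
#' size, then iteratively rotated to the running mean shape until the
#' mean stabilizes.
#'
#' @param configs list of [landmark_config()]s or k x 3 matrices with a
#'   common landmark count.
#' @param tol convergence threshold on the root-summed-square change of
#'   the mean shape.
#' @param max_iter iteration cap.
#' @param allow_reflection passed to [align_pair()].
#' @return an `aligned_sample`: `aligned` (n x k x 3 array), `mean_shape`
#'   (k x 3, unit size), `centroid_sizes` (mm), `iterations`,
#'   `specimen_ids`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L,
                allow_reflection = FALSE) {
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  n <- length(configs)
  if (n < 1L) .mc_stop("empty sample", class = "validation_error")
  ids <- vapply(seq_len(n), function(i) {
    c0 <- configs[[i]]
    if (inherits(c0, "landmark_config")) c0$specimen_id else paste0("s", i)
  }, character(1))
  mats <- lapply(configs, .coords)
  k <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 1L) != k))
    .mc_stop("landmark counts differ across specimens",
             class = "validation_error")
  sizes <- vapply(seq_len(n), function(i) {
    x <- sweep(mats[[i]], 2, colMeans(mats[[i]]))
    sqrt(sum(x^2))
  }, numeric(1))
  if (any(sizes < 1e-300))
    .mc_stop("degenerate configuration: %s", ids[which.min(sizes)],
             class = "validation_error")
  mats <- lapply(seq_len(n), function(i) .normalize_config(mats[[i]], ids[i]))

  mean_shape <- mats[[1]]
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    mats <- lapply(mats, function(x) align_pair(x, mean_shape,
                                                allow_reflection)$aligned)
    new_mean <- Reduce(`+`, mats) / n
    new_mean <- .normalize_config(new_mean, "mean shape")
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  aligned <- array(0, dim = c(n, k, 3))
  for (i in seq_len(n)) aligned[i, , ] <- mats[[i]]
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = sizes, iterations = iterations,
                 specimen_ids = ids),
            class = "aligned_sample")
}

#' Procrustes distance between two configurations
#'
#' Root summed squared difference after centering, unit-size scaling and
#' optimal rotation (partial Procrustes distance).
#'
#' @param a,b configurations with equal landmark counts.
#' @param allow_reflection passed to [align_pair()].
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  a <- .normalize_config(.coords(a), "a")
  b <- .normalize_config(.coords(b), "b")
  align_pair(a, b, allow_reflection)$residual
}

#' Permutation Procrustes ANOVA (Goodall's F)
#'
#' Tests whether group mean shapes differ, using sums of squared
#' distances of aligned specimens to their group means versus the grand
#' mean, with a permutation p-value obtained by shuffling group labels.
#' Used for the bilateral (left/right) dimorphism test.
#'
#' @param sample an `aligned_sample` from [gpa()].
#' @param labels factor-like group labels, one per specimen (>= 2 groups,
#'   each with >= 2 members).
#' @param n_perm number of label permutations.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a `procrustes_anova` list: `ss_between`, `ss_within`, `F`,
#'   `df1`, `df2`, `p`, `n_perm`, `seed`.
#' @export
procrustes_anova <- function(sample, labels, n_perm = 999L, seed) {
  if (missing(seed)) .mc_stop("seed is required", class = "validation_error")
  labels <- as.factor(labels)
  n <- dim(sample$aligned)[1]
  if (length(labels) != n)
    .mc_stop("labels length != specimen count", class = "validation_error")
  if (nlevels(droplevels(labels)) < 2L)
    .mc_stop("need at least two groups", class = "validation_error")
  if (any(table(labels) < 2L))
    .mc_stop("each group needs >= 2 members", class = "validation_error")
  X <- matrix(sample$aligned, nrow = n)   # n x 3k flattened
  g <- nlevels(labels)

  goodall_F <- function(lab) {
    gm <- rowsum(X, lab) / as.vector(table(lab))
    ssb <- sum(as.vector(table(lab)) *
                 rowSums(sweep(gm, 2, colMeans(X))^2))
    ssw <- sum((X - gm[as.integer(lab), , drop = FALSE])^2)
    list(ssb = ssb, ssw = ssw,
         F = (ssb / (g - 1)) / (ssw / (n - g)))
  }
  obs <- goodall_F(labels)
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    Fp <- goodall_F(labels[sample.int(n)])$F
    if (Fp >= obs$F) count <- count + 1L
  }
  structure(list(ss_between = obs$ssb, ss_within = obs$ssw, F = obs$F,
                 df1 = g - 1, df2 = n - g,
                 p = (count + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "procrustes_anova")
}
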