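# superimposition, shape distances, permutation Procrustes ANOVA

test_that("centroid size: hand value, scaling, degenerate flag", {
  sq <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(2))
  expect_warning(cs <- centroid_size(matrix(1, 5, 3)), "degenerate")
  expect_equal(cs, 0)
})

test_that("align_pair recovers rotations and gates reflections", {
  set.seed(31)
  x <- morphocavity:::.normalize_config(matrix(rnorm(30), 10))
  R <- random_rotation()
  res <- align_pair(x %*% R, x)
  expect_lt(res$residual, 1e-10)
  expect_equal(det(res$rotation), 1, tolerance = 1e-12)
  # mirrored configuration: blocked by default, allowed on request
  xm <- mirror_sagittal(x)
  expect_gt(align_pair(xm, x)$residual, 0.1)
  expect_lt(align_pair(xm, x, allow_reflection = TRUE)$residual, 1e-10)
})

test_that("align_pair beats brute-force random-rotation sampling", {
  set.seed(32)
  a <- morphocavity:::.normalize_config(matrix(rnorm(30), 10))
  b <- morphocavity:::.normalize_config(matrix(rnorm(30), 10))
  opt <- align_pair(a, b)$residual
  # brute force: global random sampling, then shrinking random refinement
  resid_at <- function(R) sqrt(sum((a %*% R - b)^2))
  rots <- replicate(1e4, random_rotation(), simplify = FALSE)
  vals <- vapply(rots, resid_at, numeric(1))
  bestR <- rots[[which.min(vals)]]
  samp <- min(vals)
  small_rotation <- function(theta) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, theta)
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  for (theta in c(0.2, 0.05, 0.01, 0.002)) {
    for (i in 1:2000) {
      cand <- bestR %*% small_rotation(theta)
      v <- resid_at(cand)
      if (v < samp) { samp <- v; bestR <- cand }
    }
  }
  expect_lte(opt, samp + 1e-12)
  expect_lt(samp - opt, 1e-3)
})

test_that("gpa basics: n = 1, similarity-equivalent pair, convergence", {
  set.seed(33)
  base <- matrix(rnorm(36), 12)
  out1 <- gpa(list(base))
  expect_all_close(out1$mean_shape,
                   morphocavity:::.normalize_config(base), 1e-12)
  # two similarity-equivalent configurations collapse to zero distance
  R <- random_rotation()
  out2 <- gpa(list(base, 2.3 * base %*% R + 5))
  expect_lt(sqrt(sum((out2$aligned[1, , ] - out2$aligned[2, , ])^2)), 1e-9)
  # every aligned specimen is centered with unit size
  pop <- random_configs(10, base)
  out <- gpa(pop)
  for (i in 1:10) {
    expect_all_close(colMeans(out$aligned[i, , ]), 0, 1e-9)
    expect_equal(sqrt(sum(out$aligned[i, , ]^2)), 1, tolerance = 1e-9)
  }
  expect_equal(sqrt(sum(out$mean_shape^2)), 1, tolerance = 1e-9)
})

test_that("gpa mean is equivariant under a common rotation and input order", {
  set.seed(34)
  pop <- random_configs(20, matrix(rnorm(30), 10))
  out <- gpa(pop)
  R <- random_rotation()
  out_rot <- gpa(lapply(pop, function(x) x %*% R))
  expect_lt(procrustes_distance(out$mean_shape, out_rot$mean_shape), 1e-8)
  out_perm <- gpa(pop[c(7:20, 1:6)])
  expect_lt(procrustes_distance(out$mean_shape, out_perm$mean_shape), 1e-8)
})

test_that("gpa mean minimizes the sum of squared distances", {
  set.seed(35)
  pop <- random_configs(15, matrix(rnorm(24), 8))
  out <- gpa(pop)
  X <- matrix(out$aligned, nrow = 15)
  mu <- as.vector(out$mean_shape)
  ss <- function(m) sum(sweep(X, 2, m)^2)
  s0 <- ss(mu)
  for (i in 1:100) {
    pert <- mu + rnorm(length(mu), 0, 1e-3)
    pert <- pert - rep(colMeans(matrix(pert, 8)), each = 8)
    pert <- pert / sqrt(sum(pert^2))     # stay in the unit-size manifold
    expect_gte(ss(pert), s0 - 1e-12)
  }
})

test_that("procrustes_distance is a symmetric pre-metric with triangle inequality", {
  set.seed(36)
  base <- matrix(rnorm(21), 7)
  expect_equal(procrustes_distance(base, 2 * base %*% random_rotation()), 0,
               tolerance = 1e-9)
  for (i in 1:50) {
    a <- base + matrix(rnorm(21, 0, 0.3), 7)
    b <- base + matrix(rnorm(21, 0, 0.3), 7)
    cc <- base + matrix(rnorm(21, 0, 0.3), 7)
    dab <- procrustes_distance(a, b)
    expect_equal(dab, procrustes_distance(b, a), tolerance = 1e-12)
    expect_lte(dab, procrustes_distance(a, cc) + procrustes_distance(cc, b) +
                 1e-10)
  }
})

test_that("procrustes_anova: null by construction and injected side effect", {
  set.seed(37)
  base <- matrix(rnorm(60), 20)
  # two groups that are exact copies of each other's shapes
  copies <- c(random_configs(8, base, 0.1))
  sample0 <- gpa(c(copies, copies))
  res0 <- procrustes_anova(sample0, rep(c("a", "b"), each = 8),
                           n_perm = 499, seed = 99)
  expect_lt(res0$F, 1e-10)
  expect_gte(res0$p, 0.95)
  # strong side effect: 5 sigma offset on 20 landmarks, n = 30 per side
  sigma <- 0.3
  big <- matrix(rnorm(630), 210)
  right <- random_configs(30, big, sigma)
  left <- lapply(random_configs(30, big, sigma), function(x) {
    x[11:30, 3] <- x[11:30, 3] + 5 * sigma
    x
  })
  s <- gpa(c(right, left))
  res1 <- procrustes_anova(s, rep(c("R", "L"), each = 30),
                           n_perm = 999, seed = 100)
  expect_lte(res1$p, 0.005)
  expect_error(procrustes_anova(s, rep("R", 60), n_perm = 99, seed = 1),
               class = "validation_error")
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(38)
  ps <- vapply(1:200, function(i) {
    pop <- random_configs(16, matrix(rnorm(15), 5))
    s <- gpa(pop)
    procrustes_anova(s, rep(c("a", "b"), each = 8), n_perm = 99,
                     seed = 1000 + i)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
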