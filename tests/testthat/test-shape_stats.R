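# PCA, elbow, stability, clustering, characterization stats, CCC

make_sample <- function(X, k) {
  # wrap an n x 3k matrix as an aligned_sample (k landmarks)
  structure(list(aligned = array(X, dim = c(nrow(X), k, 3))),
            class = "aligned_sample")
}

test_that("shape_pca: rank-1 variation, spectrum, reconstruction, signs", {
  set.seed(41)
  base <- as.vector(matrix(rnorm(30), 10))
  dir <- rnorm(30); dir <- dir / sqrt(sum(dir^2))
  X <- t(sapply(rnorm(25), function(t) base + t * dir))
  p <- shape_pca(make_sample(X, 10))
  expect_gte(p$explained_ratio[1], 0.999)
  expect_equal(sum(p$explained_ratio), 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained_ratio) <= 1e-12))
  expect_all_close(colMeans(p$scores), 0, 1e-10)
  # full reconstruction
  rec <- p$scores %*% p$loadings + rep(1, 25) %o% p$center
  expect_all_close(rec, X, 1e-8)
  # sign convention: dominant loading entry positive
  for (j in seq_len(nrow(p$loadings)))
    expect_gt(p$loadings[j, which.max(abs(p$loadings[j, ]))], 0)
})

test_that("eigenvalues match a dense eigendecomposition oracle", {
  set.seed(42)
  X <- matrix(rnorm(10 * 6), 10)
  p <- shape_pca(make_sample(X, 2))
  ev_oracle <- eigen(stats::cov(X) * (9 / 10), symmetric = TRUE,
                     only.values = TRUE)$values
  expect_all_close(p$explained_ratio, ev_oracle / sum(ev_oracle), 1e-10)
})

test_that("elbow selection matches the brute-force chord oracle", {
  elbow_oracle <- function(s) {
    p <- length(s); best <- 1; bestd <- -1
    for (i in seq_len(p)) {
      num <- abs((p - 1) * (s[1] - s[i]) - (1 - i) * (s[p] - s[1]))
      d <- num / sqrt((p - 1)^2 + (s[p] - s[1])^2)
      if (d > bestd + 1e-15) { bestd <- d; best <- i }
    }
    best
  }
  # frozen oracle values: the stepped spectrum elbows at 3 (the point of
  # maximum chord distance), geometric decay at 4, flat spectra at 1
  s1 <- c(0.5, 0.3, 0.05, 0.05, 0.05, 0.05)
  expect_identical(elbow_oracle(s1), 3L)
  expect_equal(select_components_elbow(s1), 3L)
  g <- 0.5^(1:10); g <- g / sum(g)
  expect_equal(select_components_elbow(g), elbow_oracle(g))
  expect_equal(select_components_elbow(g), 4L)
  expect_equal(select_components_elbow(rep(0.1, 10)), 1L)
  set.seed(43)
  for (i in 1:20) {
    s <- sort(runif(8), decreasing = TRUE); s <- s / sum(s)
    expect_equal(select_components_elbow(s), elbow_oracle(s))
  }
})

test_that("pca stability resampling: determinism and degenerate size", {
  set.seed(44)
  X <- matrix(rnorm(30 * 12), 30)
  s <- make_sample(X, 4)
  a <- pca_stability_resampling(s, sizes = c(10, 30), reps = 5, m = 3,
                                seed = 7)
  b <- pca_stability_resampling(s, sizes = c(10, 30), reps = 5, m = 3,
                                seed = 7)
  expect_identical(a, b)
  expect_equal(a$sd_cum_explained[a$size == 30], 0)   # only one subset
  expect_error(pca_stability_resampling(s, sizes = 40, reps = 2, seed = 1),
               class = "validation_error")
})

blobs <- function(n_per, centers, sd = 0.1, seed = 45) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[i, ], `+`)))
}

test_that("ward tree recovers separated blobs; small-n and inertia checks", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  sc <- blobs(15, centers)
  truth <- rep(1:3, each = 15)
  wt <- ward_tree(sc)
  expect_equal(adjusted_rand_index(cut_ward_tree(wt, 3), truth), 1)
  # n = 2: single merge at the pairwise distance
  two <- rbind(c(0, 0), c(3, 4))
  wt2 <- ward_tree(two)
  expect_equal(wt2$tree$height, 5)
  # W(1) equals total inertia
  expect_equal(inertia_profile(wt, 1),
               sum(scale(sc, scale = FALSE)^2), tolerance = 1e-9)
  expect_true(all(diff(inertia_profile(wt, 1:6)) < 0))
})

test_that("inertia-gain rule selects the generated cluster count", {
  sel3 <- select_cluster_count(ward_tree(blobs(20, rbind(c(0, 0), c(10, 0),
                                                         c(0, 10)))))
  expect_equal(sel3$k, 3)
  expect_false(sel3$low_confidence)
  sel2 <- select_cluster_count(ward_tree(blobs(20, rbind(c(0, 0), c(8, 8)))))
  expect_equal(sel2$k, 2)
  # single Gaussian: in-range answer flagged low-confidence
  g1 <- blobs(40, rbind(c(0, 0)), sd = 1, seed = 46)
  sel1 <- select_cluster_count(ward_tree(g1), kmin = 2, kmax = 8)
  expect_true(sel1$k >= 2 && sel1$k <= 8)
  # the flag is defined as max gain ratio < 1.5 — always self-consistent,
  # and the clear 3-blob case above must never be flagged
  expect_identical(sel1$low_confidence, max(sel1$ratios) < 1.5)
})

test_that("three-index vote agrees on clear structure and rejects constants", {
  sc3 <- blobs(20, rbind(c(0, 0), c(10, 0), c(0, 10)))
  v3 <- cluster_count_vote(sc3)
  expect_equal(unname(v3$choices), c(3L, 3L, 3L))
  expect_equal(v3$k, 3)
  v2 <- cluster_count_vote(blobs(20, rbind(c(0, 0), c(9, 9))))
  expect_equal(v2$k, 2)
  expect_error(cluster_count_vote(matrix(1, 10, 2)),
               class = "validation_error")
})

test_that("per-landmark MANOVA: power, null Pillai, type-I calibration", {
  set.seed(47)
  n <- 60
  labels <- rep(1:3, each = 20)
  # identical groups -> Pillai ~ 0 on a constant landmark + noise free case
  X0 <- matrix(rep(rnorm(3), each = n), n)   # same values in every group
  # power: one landmark offset by 5 sigma between clusters
  sig <- 0.5
  Xs <- matrix(rnorm(n * 3, 0, sig), n)
  Xs[labels == 2, 1] <- Xs[labels == 2, 1] + 5 * sig
  res <- manova_per_landmark(make_sample(Xs, 1), labels)
  expect_lt(res$p[1], 1e-6)
  # type-I calibration: 500 independent null landmarks in one call
  k <- 500
  Xnull <- matrix(rnorm(n * 3 * k), n)
  cal <- manova_per_landmark(make_sample(Xnull, k), sample(labels))
  rate <- mean(cal$p < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
})

test_that("per-axis ANOVA: identical groups, t^2 identity, oracle fixture", {
  set.seed(48)
  n <- 24
  labels <- rep(1:2, each = 12)
  X <- matrix(rnorm(n * 3), n)
  res <- anova_per_axis(make_sample(X, 1), labels)
  # two groups: F equals the squared two-sample (pooled) t statistic
  for (a in 1:3) {
    tt <- stats::t.test(X[labels == 1, a], X[labels == 2, a],
                        var.equal = TRUE)$statistic
    expect_equal(res$F[res$axis == c("x", "y", "z")[a]], unname(tt^2),
                 tolerance = 1e-10)
  }
  # three-group fixture against stats::aov
  labels3 <- rep(1:3, each = 8)
  X3 <- matrix(rnorm(24 * 3), 24)
  mine <- anova_per_axis(make_sample(X3, 1), labels3)
  for (a in 1:3) {
    fit <- summary(stats::aov(X3[, a] ~ factor(labels3)))[[1]]
    expect_equal(mine$F[mine$axis == c("x", "y", "z")[a]],
                 fit$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p[mine$axis == c("x", "y", "z")[a]],
                 fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # identical groups: F ~ 0, p ~ 1
  Xc <- matrix(rep(rnorm(12), 2 * 3), n)
  resc <- anova_per_axis(make_sample(Xc, 1), labels)
  expect_all_close(resc$F, 0, 1e-16)
})

test_that("Tukey HSD matches stats::TukeyHSD and is conservative", {
  set.seed(49)
  n <- 30
  labels <- rep(1:3, each = 10)
  X <- matrix(rnorm(n * 3), n)
  X[labels == 3, 2] <- X[labels == 3, 2] + 1
  mine <- tukey_pairwise(make_sample(X, 1), labels)
  for (a in 1:3) {
    hsd <- stats::TukeyHSD(stats::aov(X[, a] ~ factor(labels)))[[1]]
    sub <- mine[mine$axis == c("x", "y", "z")[a], ]
    # rows are pairs 2-1, 3-1, 3-2 in both
    expect_all_close(sub$diff, hsd[, "diff"], 1e-10)
    expect_all_close(sub$p_adj, hsd[, "p adj"], 1e-6)
  }
  # adjusted p >= unadjusted pairwise t p on every comparison
  for (r in seq_len(nrow(mine))) {
    a <- which(c("x", "y", "z") == mine$axis[r])
    g1 <- X[labels == mine$cluster_a[r], a]
    g2 <- X[labels == mine$cluster_b[r], a]
    praw <- stats::t.test(g1, g2, var.equal = TRUE)$p.value
    expect_gte(mine$p_adj[r] + 1e-12, praw)
  }
  # sign always matches the group-mean difference
  expect_true(all(mine$sign == sign(mine$diff)))
  # balanced fixture: p from the studentized range quantile round trip
  r <- mine[1, ]
  q <- stats::qtukey(1 - r$p_adj, 3, n - 3)
  g1 <- X[labels == r$cluster_a, 1]; g2 <- X[labels == r$cluster_b, 1]
  mse <- sum(stats::resid(stats::aov(X[, 1] ~ factor(labels)))^2) / (n - 3)
  expect_equal(q, abs(mean(g1) - mean(g2)) / sqrt(mse / 10), tolerance = 1e-6)
})

test_that("Lin's CCC: identity, frozen hand value, reversal", {
  x <- c(1, 2, 3, 4)
  expect_equal(lins_ccc(x, x), 1)
  expect_equal(lins_ccc(x, c(2, 3, 4, 5)), 5 / 7, tolerance = 1e-9)
  z <- x - mean(x)
  expect_equal(lins_ccc(z, -z), -1)
})

test_that("repeatability report: identical sessions, noise monotonicity, closed form", {
  set.seed(50)
  make_session <- function(noise) {
    lapply(1:20, function(i) {
      set.seed(1000 + i)     # same specimens in every session
      base <- matrix(rnorm(45, 0, 3), 15)
      landmark_config(base + matrix(rnorm(45, 0, noise), 15),
                      c(rep(0L, 5), rep(1L, 10)), sprintf("m%02d", i))
    })
  }
  s0 <- make_session(0)
  rep0 <- repeatability_report(list(a = s0, b = s0))
  expect_equal(unlist(rep0$table), c(1, 1), ignore_attr = TRUE)
  # CCC decreases monotonically with the noise added to one session
  ccc_at <- function(noise) {
    set.seed(51)
    repeatability_report(list(a = s0, b = make_session(noise)))$table[2, 1]
  }
  vals <- vapply(c(0.1, 0.5, 1), ccc_at, numeric(1))
  expect_true(all(diff(vals) < 0))
  # closed form: x ~ (0, V), y = x + e, e ~ (0, s^2):
  # CCC -> 2V / (2V + s^2)
  V <- 9; s2 <- 0.25
  expect_equal(ccc_at(0.5), 2 * V / (2 * V + s2), tolerance = 0.02)
})

test_that("chi-square and Kruskal-Wallis agree with stats oracles", {
  tab <- rbind(c(17, 17), c(44, 45), c(12, 16))
  mine <- chi_square_test(tab)
  oracle <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(mine$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(mine$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi_square_test(rbind(c(10, 10), c(10, 10)))$p, 1)

  kw <- kruskal_wallis_test(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
  g <- list(c(1.1, 2.3, 3.2, 1.7), c(2.2, 4.1, 0.4), c(5, 2.8, 3.3, 1.9))
  ko <- stats::kruskal.test(g)
  km <- kruskal_wallis_test(g)
  expect_equal(km$H, unname(ko$statistic), tolerance = 1e-12)
  expect_equal(km$p, ko$p.value, tolerance = 1e-12)
  # ties reduce H relative to the same data without ties
  no_tie <- list(c(1, 2), c(3, 4), c(5, 6))
  tie <- list(c(1, 2), c(2, 4), c(5, 6))
  expect_lt(kruskal_wallis_test(tie)$H, kruskal_wallis_test(no_tie)$H)
  expect_equal(kruskal_wallis_test(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
})
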