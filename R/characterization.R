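#' Per-landmark MANOVA across clusters
#'
#' One-way MANOVA of each landmark's (x, y, z) coordinates against the
#' cluster labels, reported as Pillai's trace with its standard F
#' approximation. Landmarks with singular within-group covariance are
#' flagged with `p = NA`.
#'
#' @param sample an `aligned_sample` from [gpa()].
#' @param labels cluster labels (>= 2 clusters, each n >= 4).
#' @param p_adjust `"none"` (default, raw p-values) or `"BH"`.
#' @return data.frame: `landmark` (0-based id), `pillai`, `F`, `df1`,
#'   `df2`, `p`, `p_adj`.
#' @export
manova_per_landmark <- function(sample, labels, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  labels <- as.factor(labels)
  .check_groups(labels, dim(sample$aligned)[1], min_n = 4L)
  k <- dim(sample$aligned)[2]
  out <- lapply(seq_len(k), function(j) {
    Y <- sample$aligned[, j, ]
    res <- tryCatch({
      fit <- stats::manova(Y ~ labels)
      sm <- summary(fit, test = "Pillai")$stats
      data.frame(landmark = j - 1L, pillai = sm[1, "Pillai"],
                 F = sm[1, "approx F"], df1 = sm[1, "num Df"],
                 df2 = sm[1, "den Df"], p = sm[1, "Pr(>F)"])
    }, error = function(e)
      data.frame(landmark = j - 1L, pillai = NA_real_, F = NA_real_,
                 df1 = NA_real_, df2 = NA_real_, p = NA_real_))
    res
  })
  out <- do.call(rbind, out)
  out$p_adj <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out
}

.check_groups <- function(labels, n, min_n = 2L) {
  if (length(labels) != n)
    .mc_stop("labels length != specimen count", class = "validation_error")
  if (nlevels(droplevels(labels)) < 2L)
    .mc_stop("need >= 2 groups", class = "validation_error")
  if (any(table(labels) < min_n))
    .mc_stop("every group needs >= %d members", min_n,
             class = "validation_error")
}

#' Per-landmark, per-axis one-way ANOVA
#'
#' Refines the MANOVA: an F test of cluster mean differences on each
#' spatial coordinate (X, Y, Z) of each landmark, computed vectorized
#' over all 3k coordinate columns.
#'
#' @inheritParams manova_per_landmark
#' @return data.frame: `landmark`, `axis` (`"x"|"y"|"z"`), `F`, `p`,
#'   `p_adj`.
#' @export
anova_per_axis <- function(sample, labels, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  labels <- as.factor(labels)
  n <- dim(sample$aligned)[1]
  .check_groups(labels, n)
  k <- dim(sample$aligned)[2]
  X <- matrix(sample$aligned, nrow = n)   # columns: all-x, all-y, all-z
  g <- nlevels(labels)
  li <- as.integer(labels)
  ng <- as.vector(table(labels))
  gm <- rowsum(X, li) / ng
  grand <- colMeans(X)
  ssb <- colSums(ng * sweep(gm, 2, grand)^2)
  ssw <- colSums((X - gm[li, , drop = FALSE])^2)
  Fv <- (ssb / (g - 1)) / (ssw / (n - g))
  p <- stats::pf(Fv, g - 1, n - g, lower.tail = FALSE)
  out <- data.frame(landmark = rep(seq_len(k) - 1L, times = 3),
                    axis = rep(c("x", "y", "z"), each = k),
                    F = Fv, p = p, row.names = NULL)
  out$p_adj <- if (p_adjust == "BH") stats::p.adjust(out$p, "BH") else out$p
  out
}

#' Pairwise Tukey HSD per landmark and axis
#'
#' Tukey-Kramer honest significant differences between every cluster
#' pair on every coordinate column, using the studentized-range
#' distribution with the pooled within-cluster mean square. The reported
#' `sign` is the sign of `mean(A) - mean(B)`: positive means cluster A's
#' landmark lies further along that axis (further from the fixed origin)
#' than cluster B's.
#'
#' @inheritParams manova_per_landmark
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame: `landmark`, `axis`, `cluster_a`, `cluster_b`,
#'   `diff` (mean A - mean B), `p_adj`, `sign`, `significant`.
#' @export
tukey_pairwise <- function(sample, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  n <- dim(sample$aligned)[1]
  .check_groups(labels, n)
  k <- dim(sample$aligned)[2]
  X <- matrix(sample$aligned, nrow = n)
  g <- nlevels(labels)
  li <- as.integer(labels)
  ng <- as.vector(table(labels))
  gm <- rowsum(X, li) / ng
  mse <- colSums((X - gm[li, , drop = FALSE])^2) / (n - g)
  pairs <- utils::combn(g, 2)
  out <- vector("list", ncol(pairs))
  for (c2 in seq_len(ncol(pairs))) {
    i <- pairs[2, c2]; j <- pairs[1, c2]   # A = later cluster, B = earlier
    dif <- gm[i, ] - gm[j, ]
    se <- sqrt(mse / 2 * (1 / ng[i] + 1 / ng[j]))
    q <- abs(dif) / se
    p_adj <- stats::ptukey(q, nmeans = g, df = n - g, lower.tail = FALSE)
    out[[c2]] <- data.frame(
      landmark = rep(seq_len(k) - 1L, times = 3),
      axis = rep(c("x", "y", "z"), each = k),
      cluster_a = levels(labels)[i], cluster_b = levels(labels)[j],
      diff = dif, p_adj = p_adj, sign = sign(dif),
      significant = p_adj < alpha, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements against the 45-degree line:
#' \eqn{2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with 1/n
#' (biased) moments. 1 for perfect agreement, -1 for perfect reversal.
#'
#' @param x,y paired numeric vectors.
#' @return scalar between -1 and 1.
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    .mc_stop("x and y must be paired vectors of length >= 2",
             class = "validation_error")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

#' Digitization repeatability / reproducibility report
#'
#' Computes Lin's CCC between digitization sessions of the same
#' specimens, separately for fixed landmarks and sliding semi-landmarks.
#' Coordinates are pooled across specimens, landmarks and axes into one
#' paired vector per session pair (the pooled-coordinates convention);
#' a per-landmark CCC table is returned alongside.
#'
#' @param sessions named list of digitization sessions; each session is a
#'   list of [landmark_config()]s over the same specimens in the same
#'   order.
#' @param comparisons named list of session index (or name) pairs, e.g.
#'   `list(repeatability = c(1, 2), reproducibility = c(1, 3))`.
#' @return list with `table` (rows fixed/sliding, one column per
#'   comparison) and `per_landmark` (landmark x comparison CCC).
#' @export
repeatability_report <- function(sessions,
                                 comparisons = list(repeatability = c(1, 2))) {
  if (length(sessions) < 2L)
    .mc_stop("need >= 2 sessions", class = "validation_error")
  pool <- function(configs, rows) {
    do.call(rbind, lapply(configs, function(cf)
      cf$coordinates[rows, , drop = FALSE]))
  }
  patch <- sessions[[1]][[1]]$patch_ids
  fixed_rows <- which(patch == 0L)
  semi_rows <- which(patch > 0L)
  k <- length(patch)
  tab <- matrix(NA_real_, 2, length(comparisons),
                dimnames = list(c("fixed", "sliding"), names(comparisons)))
  per_lm <- matrix(NA_real_, k, length(comparisons),
                   dimnames = list(NULL, names(comparisons)))
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    s1 <- sessions[[cmp[1]]]; s2 <- sessions[[cmp[2]]]
    if (length(s1) != length(s2))
      .mc_stop("sessions differ in specimen count", class = "validation_error")
    tab["fixed", ci] <- lins_ccc(as.vector(pool(s1, fixed_rows)),
                                 as.vector(pool(s2, fixed_rows)))
    if (length(semi_rows))
      tab["sliding", ci] <- lins_ccc(as.vector(pool(s1, semi_rows)),
                                     as.vector(pool(s2, semi_rows)))
    for (j in seq_len(k)) {
      a <- do.call(rbind, lapply(s1, function(cf) cf$coordinates[j, ]))
      b <- do.call(rbind, lapply(s2, function(cf) cf$coordinates[j, ]))
      per_lm[j, ci] <- lins_ccc(as.vector(a), as.vector(b))
    }
  }
  list(table = as.data.frame(tab),
       per_landmark = data.frame(landmark = seq_len(k) - 1L, per_lm,
                                 row.names = NULL))
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`.
#'
#' @param tab r x c matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) == 0)
    .mc_stop("counts must be non-negative with positive total",
             class = "validation_error")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with the standard tie correction and
#' chi-square approximation for the p-value.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis_test <- function(groups) {
  if (length(groups) < 2L)
    .mc_stop("need >= 2 groups", class = "validation_error")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- H / tie_corr
  df <- length(groups) - 1
  list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE))
}
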