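#' Principal component analysis of aligned shapes
#'
#' PCA of the n x 3k matrix of flattened Procrustes-aligned coordinates
#' (columns ordered all-X, all-Y, all-Z landmark blocks). Performed by
#' SVD of the centered matrix; eigenvalue spectrum and loadings are
#' returned in full. Component signs follow a deterministic convention:
#' the largest-magnitude entry of every loading is positive.
#'
#' @param sample an `aligned_sample` from [gpa()] (n >= 3).
#' @return a `shape_pca`: `scores` (n x m), `loadings` (m x 3k, one row
#'   per component), `explained_ratio` (full spectrum, sums to 1),
#'   `center` (3k), `landmark_count`.
#' @export
shape_pca <- function(sample) {
  n <- dim(sample$aligned)[1]
  if (n < 3L) .mc_stop("PCA needs n >= 3 specimens", class = "validation_error")
  k <- dim(sample$aligned)[2]
  X <- matrix(sample$aligned, nrow = n)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc)
  m <- min(n - 1L, ncol(X))
  d <- sv$d[seq_len(m)]
  scores <- sv$u[, seq_len(m), drop = FALSE] %*% diag(d, m)
  loadings <- t(sv$v[, seq_len(m), drop = FALSE])
  # sign convention: dominant entry of each loading positive
  for (j in seq_len(m)) {
    s <- sign(loadings[j, which.max(abs(loadings[j, ]))])
    if (s < 0) {
      loadings[j, ] <- -loadings[j, ]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- d^2
  structure(list(scores = scores, loadings = loadings,
                 explained_ratio = ev / sum(ev), center = center,
                 landmark_count = k),
            class = "shape_pca")
}

#' Elbow selection of the number of principal components
#'
#' Geometric elbow rule: on the scree plot (component index versus
#' explained-variance ratio), pick the point with the maximum
#' perpendicular distance to the chord joining the first and last scree
#' points. Ties (including a completely flat spectrum, where every
#' distance is zero) resolve to the smallest index.
#'
#' @param spectrum explained-variance ratios, non-increasing.
#' @return integer number of components to retain.
#' @export
select_components_elbow <- function(spectrum) {
  p <- length(spectrum)
  if (p == 1L) return(1L)
  x <- seq_len(p)
  dx <- p - 1
  dy <- spectrum[p] - spectrum[1]
  # |cross product| of (point - first) with the chord direction
  d <- abs((x - 1) * dy - (spectrum - spectrum[1]) * dx)
  which.max(d)  # which.max takes the first (= smallest index) on ties
}

#' PCA stability under resampling
#'
#' Repeatedly subsamples the aligned specimens without replacement at
#' each size, recomputes the PCA, and records the cumulative explained
#' variance of the first `m` components — the curve used to judge
#' whether the sample size gives stable PCA outcomes.
#'
#' @param sample an `aligned_sample`.
#' @param sizes subset sizes to scan (all <= n).
#' @param reps replicates per size.
#' @param m number of leading components summed.
#' @param seed RNG seed.
#' @return data.frame with columns `size`, `mean_cum_explained`,
#'   `sd_cum_explained`.
#' @export
pca_stability_resampling <- function(sample, sizes = seq(20, 150, by = 10),
                                     reps = 100L, m = 5L, seed) {
  if (missing(seed)) .mc_stop("seed is required", class = "validation_error")
  n <- dim(sample$aligned)[1]
  if (max(sizes) > n)
    .mc_stop("subset size %d exceeds sample size %d", max(sizes), n,
             class = "validation_error")
  set.seed(seed)
  rows <- lapply(sizes, function(sz) {
    cum <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, sz)
      sub <- list(aligned = sample$aligned[idx, , , drop = FALSE])
      ex <- shape_pca(structure(sub, class = "aligned_sample"))$explained_ratio
      sum(ex[seq_len(min(m, length(ex)))])
    }, numeric(1))
    data.frame(size = sz, mean_cum_explained = mean(cum),
               sd_cum_explained = stats::sd(cum))
  })
  do.call(rbind, rows)
}

#' Ward hierarchical clustering of PC scores
#'
#' Agglomerative clustering with the Ward.D2 criterion (squared-Euclidean
#' increase in within-cluster inertia, distances not pre-squared) on the
#' retained principal-component scores.
#'
#' @param scores n x m score matrix.
#' @return a `ward_tree`: the `stats::hclust` tree plus the score matrix
#'   it was built from.
#' @export
ward_tree <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) .mc_stop("need n >= 2", class = "validation_error")
  tree <- stats::hclust(stats::dist(scores), method = "ward.D2")
  structure(list(tree = tree, scores = scores), class = "ward_tree")
}

#' Cluster labels from a Ward tree
#' @param wt a [ward_tree()].
#' @param k number of clusters.
#' @export
cut_ward_tree <- function(wt, k) {
  as.integer(stats::cutree(wt$tree, k = k))
}

# total within-cluster sum of squares of a labelled partition
within_inertia <- function(scores, labels) {
  labels <- as.integer(as.factor(labels))
  gm <- rowsum(scores, labels) / as.vector(table(labels))
  sum((scores - gm[labels, , drop = FALSE])^2)
}

#' Within-inertia profile of a Ward tree
#' @param wt a [ward_tree()].
#' @param ks cluster counts to evaluate.
#' @return numeric W(k) for each k.
#' @export
inertia_profile <- function(wt, ks) {
  vapply(ks, function(k) within_inertia(wt$scores, cut_ward_tree(wt, k)),
         numeric(1))
}

#' Automatic cluster count from inertia gains
#'
#' Mimics the inertia-gain rule of hierarchical clustering on principal
#' components: with \eqn{\Delta W(k) = W(k-1) - W(k)} the drop in within
#' inertia when moving to k clusters, the selected k maximizes the ratio
#' \eqn{\Delta W(k) / \Delta W(k+1)} over the scan range — the partition
#' after which further splitting gains little. Ties resolve to the
#' smaller k; a maximum ratio below 1.5 flags the selection as
#' low-confidence (no clear cluster structure).
#'
#' @param wt a [ward_tree()].
#' @param kmin,kmax scan range (kmax is clipped to n - 1).
#' @return list with `k`, `ratios`, `W` (named by k), `low_confidence`.
#' @export
select_cluster_count <- function(wt, kmin = 2L, kmax = 10L) {
  n <- nrow(wt$scores)
  kmax <- min(kmax, n - 1L)
  if (kmax < kmin)
    .mc_stop("invalid scan range [%d, %d]", kmin, kmax,
             class = "validation_error")
  ks <- (kmin - 1L):(kmax + 1L)
  W <- inertia_profile(wt, ks)
  names(W) <- ks
  dW <- -diff(W)                      # dW[i] = W(k-1) - W(k) at k = ks[i+1]
  ratios <- dW[-length(dW)] / pmax(dW[-1], .Machine$double.eps)
  names(ratios) <- ks[2:(length(ks) - 1L)]
  k <- as.integer(names(ratios)[which.max(ratios)])
  list(k = k, ratios = ratios, W = W,
       low_confidence = max(ratios) < 1.5)
}

#' Reduced cluster-count index vote
#'
#' Three validity indices — Calinski-Harabasz, mean silhouette width, and
#' the inertia-gain ratio of [select_cluster_count()] — each nominate a
#' cluster count on the Ward tree; the majority wins, with ties resolved
#' in favor of the inertia-gain choice.
#'
#' @param scores n x m score matrix.
#' @param kmin,kmax scan range.
#' @return list with `choices` (named per index), `k` (majority).
#' @export
cluster_count_vote <- function(scores, kmin = 2L, kmax = 10L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  total <- within_inertia(scores, rep(1L, n))
  if (total < 1e-300)
    .mc_stop("constant data: cluster indices undefined",
             class = "validation_error")
  wt <- ward_tree(scores)
  kmax <- min(kmax, n - 1L)
  ks <- kmin:kmax
  d <- stats::dist(scores)
  ch <- sil <- setNames(numeric(length(ks)), ks)
  for (i in seq_along(ks)) {
    lab <- cut_ward_tree(wt, ks[i])
    W <- within_inertia(scores, lab)
    ch[i] <- ((total - W) / (ks[i] - 1)) / (W / (n - ks[i]))
    sil[i] <- mean(cluster::silhouette(lab, d)[, "sil_width"])
  }
  inertia_k <- select_cluster_count(wt, kmin, kmax)$k
  choices <- c(calinski_harabasz = as.integer(names(ch)[which.max(ch)]),
               silhouette = as.integer(names(sil)[which.max(sil)]),
               inertia_gain = inertia_k)
  tab <- table(choices)
  winners <- as.integer(names(tab)[tab == max(tab)])
  k <- if (length(winners) == 1L) winners else inertia_k
  list(choices = choices, k = k)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two label vectors; 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < 1e-300) return(1)
  (sum_ij - expected) / (maxi - expected)
}
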