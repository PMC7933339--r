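# Brute-force between-groups (average) linkage on squared Euclidean
# distances: recompute every cluster pair's mean pairwise distance at each
# step. Independent of the package's Lance-Williams implementation.
brute_average_linkage <- function(x) {
  d <- as.matrix(dist(x))^2
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best[1] - 1e-12) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

test_that("hca merge heights match the brute-force oracle (n <= 8)", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    tree <- hca(x)
    expect_equal(tree$height, brute_average_linkage(x), tolerance = 1e-10)
    expect_false(is.unsorted(tree$height))            # monotone linkage
    # cross-check against stats::hclust average linkage on squared d
    hc <- hclust(as.dist(as.matrix(dist(x))^2), method = "average")
    expect_equal(tree$height, hc$height, tolerance = 1e-10)
  }
})

test_that("hca handles the degenerate and well-separated cases", {
  x2 <- rbind(c(0, 0), c(3, 4))
  t2 <- hca(x2)
  expect_equal(t2$height, 25)                         # squared distance

  pairs <- rbind(c(0, 0), c(0, 0.5), c(10, 10), c(10, 10.5))
  tp <- hca(pairs)
  expect_equal(sort(cut_clusters(tp, 2)), sort(rep(1:2, each = 2)),
               ignore_attr = TRUE)
  expect_error(hca(pairs * NA), "non-finite")
  expect_error(hca(pairs[1, , drop = FALSE]), "at least 2")
})

test_that("cut_clusters honours k over its whole range", {
  set.seed(3)
  x <- matrix(rnorm(12), 6)
  tree <- hca(x)
  expect_equal(length(unique(cut_clusters(tree, 1))), 1L)
  expect_equal(length(unique(cut_clusters(tree, 6))), 6L)
  expect_error(cut_clusters(tree, 0), "k must lie")
  expect_error(cut_clusters(tree, 7), "k must lie")
})

test_that("pca matches an independent eigendecomposition up to sign", {
  set.seed(8)
  x <- matrix(rnorm(40), 8, 5)
  for (sc in c("unit_variance", "center")) {
    m <- pca(x, scaling = sc)
    ref <- prcomp(x, center = TRUE, scale. = sc == "unit_variance")
    k <- ncol(m$loadings)
    for (j in seq_len(k)) {
      s <- sign(sum(m$loadings[, j] * ref$rotation[, j]))
      expect_equal(m$loadings[, j], s * ref$rotation[, j], tolerance = 1e-8)
      expect_equal(m$scores[, j], s * ref$x[, j], tolerance = 1e-8)
    }
    expect_equal(crossprod(m$loadings), diag(k), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(m$all_explained_variance), 1, tolerance = 1e-10)
    expect_false(is.unsorted(rev(m$explained_variance)))
  }
})

test_that("pca flags collinear and degenerate inputs correctly", {
  line <- cbind(1:6, 2 * (1:6))
  m <- pca(line, scaling = "center")
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-10)

  const <- cbind(1:6, rep(2, 6))
  expect_error(pca(const), "zero-variance")
  expect_error(pca(matrix(rnorm(12), 6), n_components = 5), "n_components")
})

test_that("oplsda separates predictive from orthogonal variation", {
  set.seed(9)
  labels <- rep(c("A", "B"), each = 6)
  # group difference on variable 1 only; no other structured variance
  x <- cbind(ifelse(labels == "A", 1, -1) + rnorm(12, 0, 0.01),
             matrix(rnorm(36, 0, 0.01), 12))
  m <- oplsda(x, labels, n_orthogonal = 0, scaling = "center")
  expect_gt(abs(m$weights[1]), 0.99)
  expect_gt(m$r2y, 0.95)

  # orthogonal scores are orthogonal to the predictive score
  x2 <- matrix(rnorm(12 * 8), 12)
  x2[, 1] <- x2[, 1] + ifelse(labels == "A", 1.5, -1.5)
  m2 <- oplsda(x2, labels, n_orthogonal = 2)
  for (to in m2$orthogonal_scores)
    expect_lt(abs(sum(m2$scores * to)) /
                (sqrt(sum(m2$scores^2)) * sqrt(sum(to^2))), 1e-8)

  expect_error(oplsda(x2, rep("A", 12)), "two groups")
  expect_error(oplsda(x2[1:3, ], c("A", "A", "B")), "at least 2 samples")
})

test_that("zero orthogonal components reduce to one-step PLS", {
  set.seed(10)
  labels <- rep(c("A", "B"), times = c(5, 7))
  x <- matrix(rnorm(12 * 6), 12)
  m <- oplsda(x, labels, n_orthogonal = 0)
  # direct NIPALS formula, written out independently
  xs <- scale(x)
  y <- ifelse(labels == "A", 1, -1); y <- y - mean(y)
  w <- crossprod(xs, y); w <- w / sqrt(sum(w^2))
  t_ <- xs %*% w
  expect_equal(abs(m$weights), abs(as.numeric(w)), tolerance = 1e-8)
  expect_equal(abs(m$scores), abs(as.numeric(t_)), tolerance = 1e-8)
})

test_that("opls scores are sample-order equivariant", {
  set.seed(12)
  labels <- rep(c("A", "B"), each = 5)
  x <- matrix(rnorm(10 * 6), 10)
  x[, 2] <- x[, 2] + ifelse(labels == "A", 1, -1)
  m <- oplsda(x, labels)
  perm <- sample(10)
  mp <- oplsda(x[perm, ], labels[perm])
  expect_equal(abs(mp$scores), abs(m$scores[perm]), tolerance = 1e-8)
  expect_equal(mp$vip, m$vip, tolerance = 1e-8)
})

test_that("vip is scaled so mean squared VIP equals one", {
  set.seed(13)
  labels <- rep(c("A", "B"), each = 6)
  x <- matrix(rnorm(12 * 9), 12)
  x[, 4] <- x[, 4] + ifelse(labels == "A", 2, -2)
  m <- oplsda(x, labels)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-8)
  expect_equal(which.max(m$vip), 4L)

  # equal weights give VIP = 1 for every variable
  flat <- structure(list(weights = rep(0.5, 4), variable_names = NULL),
                    class = "mwfp_opls")
  expect_equal(unname(vip(flat)), rep(1, 4))
  expect_error(vip(list()), "fitted")
})

test_that("misassignment counts are label-permutation safe", {
  expect_equal(cluster_misassignment(c(1, 1, 2, 2), c("A", "A", "B", "B")), 0L)
  expect_equal(cluster_misassignment(c(2, 2, 1, 1), c("A", "A", "B", "B")), 0L)
  expect_equal(cluster_misassignment(c(1, 2, 2, 2), c("A", "A", "B", "B")), 1L)
})
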