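as_data_matrix <- function(x) {
  if (inherits(x, "fingerprint_matrix")) x$areas
  else as.matrix(x)
}

#' Total-area normalisation of a fingerprint matrix
#'
#' Divides every sample's peak areas by that sample's total area, removing
#' overall "strength" differences (injection amount, extraction yield)
#' before pattern-based multivariate analysis.
#'
#' @param x A [fingerprint_matrix()] or numeric matrix.
#' @return A numeric matrix whose rows each sum to 1.
#' @export
normalize_total <- function(x) {
  m <- as_data_matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("sample with non-positive total area")
  sweep(m, 1, tot, `/`)
}

#' Column scaling for multivariate analysis
#'
#' @param x Matrix-like input.
#' @param scaling `"unit_variance"` (centre and scale to unit variance, the
#'   default) or `"center"` (centre only).
#' @return Scaled matrix with attributes `center` and `scale`.
#' @export
scale_columns <- function(x, scaling = c("unit_variance", "center")) {
  scaling <- match.arg(scaling)
  m <- as_data_matrix(x)
  if (any(!is.finite(m))) stop("non-finite values in data matrix")
  ctr <- colMeans(m)
  if (scaling == "unit_variance") {
    s <- apply(m, 2, stats::sd)
    zero <- which(s <= .Machine$double.eps * max(abs(ctr), 1))
    if (length(zero))
      stop("zero-variance column under unit-variance scaling: ",
           paste(colnames(m)[zero] %||% zero, collapse = ", "))
  } else s <- rep(1, ncol(m))
  out <- sweep(sweep(m, 2, ctr, `-`), 2, s, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- s
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Agglomerative clustering with between-groups linkage on squared
#' Euclidean distances
#'
#' Starting from singletons, the two clusters with the smallest
#' between-groups distance - the mean of all pairwise squared Euclidean
#' distances between their members - are merged until one cluster remains.
#' Ties are broken deterministically by the smallest pair of cluster
#' indices. The result is representable as an `hclust` tree (between-groups
#' linkage is monotone), so [stats::cutree()] and `plot()` work on it.
#'
#' @param x Sample matrix (rows = samples) or [fingerprint_matrix()].
#' @param metric Distance; only `"squared_euclidean"` is provided.
#' @param linkage Only `"between_groups_average"` is provided.
#' @return An object of classes `mwfp_hca` and `hclust` with `merge`,
#'   `height`, `order` and `labels`.
#' @export
hca <- function(x, metric = "squared_euclidean",
                linkage = "between_groups_average") {
  metric <- match.arg(metric, "squared_euclidean")
  linkage <- match.arg(linkage, "between_groups_average")
  m <- as_data_matrix(x)
  if (any(!is.finite(m))) stop("non-finite values in data matrix")
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows to cluster")
  labels <- rownames(m) %||% as.character(seq_len(n))
  d <- as.matrix(stats::dist(m))^2
  diag(d) <- Inf
  active <- seq_len(n)          # current cluster ids (index into bookkeeping)
  size <- rep(1L, n)
  node <- -seq_len(n)           # hclust encoding of each active cluster
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  ord_list <- as.list(seq_len(n))
  for (s in seq_len(n - 1L)) {
    sub <- d[active, active, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    # smallest-index pair tie-break, scanning (i, j) with i < j
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    pick <- best[order(best[, 1L], best[, 2L])[1L], ]
    i <- active[pick[1L]]; j <- active[pick[2L]]
    height[s] <- d[i, j]
    merge[s, ] <- sort(c(node[i], node[j]))
    # Lance-Williams update for average linkage: weighted mean of distances
    rest <- setdiff(active, c(i, j))
    d[i, rest] <- d[rest, i] <-
      (size[i] * d[i, rest] + size[j] * d[j, rest]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    node[i] <- s
    members[[i]] <- c(members[[i]], members[[j]])
    ord_list[[i]] <- c(ord_list[[i]], ord_list[[j]])
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height,
                 order = ord_list[[active]], labels = labels,
                 method = "between_groups_average",
                 dist.method = "squared_euclidean",
                 call = match.call()),
            class = c("mwfp_hca", "hclust"))
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges of the tree.
#'
#' @param dendro An [hca()] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer cluster labels named by sample.
#' @export
cut_clusters <- function(dendro, k) {
  stopifnot(inherits(dendro, "hclust"))
  n <- length(dendro$labels)
  if (k < 1L || k > n) stop("k must lie in 1..", n)
  stats::cutree(dendro, k = k)
}

#' Misassignment count of a 2-group clustering against known labels
#'
#' Counts disagreements under the better of the two possible
#' cluster-to-group identifications.
#'
#' @param clusters Cluster labels (two clusters).
#' @param labels True two-group labels.
#' @return Integer number of misassigned samples.
#' @export
cluster_misassignment <- function(clusters, labels) {
  stopifnot(length(clusters) == length(labels))
  cl <- as.integer(factor(clusters))
  lb <- as.integer(factor(labels))
  direct <- sum(cl != lb)
  min(direct, length(cl) - direct)
}

#' Principal component analysis by singular value decomposition
#'
#' Columns are centred (and by default scaled to unit variance); the scores
#' and orthonormal loadings come from the SVD of the scaled matrix, with
#' components ordered by explained variance.
#'
#' @param x Sample matrix or [fingerprint_matrix()].
#' @param n_components Number of components to keep (default: all, i.e.
#'   `min(n - 1, p)`).
#' @param scaling See [scale_columns()].
#' @return Object of class `mwfp_pca`: `center`, `scale`, `loadings`
#'   (p x k, orthonormal), `scores` (n x k), `explained_variance`
#'   (fractions for the kept components; all fractions sum to 1).
#' @export
pca <- function(x, n_components = NULL,
                scaling = c("unit_variance", "center")) {
  m <- scale_columns(x, scaling)
  n <- nrow(m); p <- ncol(m)
  kmax <- min(n - 1L, p)
  k <- n_components %||% kmax
  if (k < 1L || k > kmax)
    stop("n_components must lie in 1..min(n_samples - 1, n_peaks) = ", kmax)
  sv <- svd(m)
  ev <- sv$d^2
  frac <- ev / sum(ev)
  structure(list(center = attr(m, "center"), scale = attr(m, "scale"),
                 loadings = sv$v[, seq_len(k), drop = FALSE],
                 scores = (sv$u %*% diag(sv$d, length(sv$d)))[, seq_len(k),
                                                              drop = FALSE],
                 explained_variance = frac[seq_len(k)],
                 all_explained_variance = frac[seq_len(kmax)]),
            class = "mwfp_pca")
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' Two-class OPLS-DA: the response is the centred +/-1 class encoding. Each
#' orthogonal round computes the PLS weight `w` from the current matrix,
#' extracts from the loading `p` its part orthogonal to `w`
#' (`w_orth = p - (w'p) w`, normalised), and deflates the matrix by the
#' corresponding orthogonal component. The predictive component is then a
#' single PLS component of the deflated matrix. With `n_orthogonal = 0` this
#' reduces to one-component PLS-DA.
#'
#' @param x Sample matrix or [fingerprint_matrix()].
#' @param labels Two-group class labels, each group with >= 2 samples.
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @param scaling See [scale_columns()].
#' @return Object of class `mwfp_opls`: predictive `weights` (unit norm),
#'   `scores`, `loadings`; lists `orthogonal_weights`, `orthogonal_scores`,
#'   `orthogonal_loadings`; `y` (centred encoding), `groups`, `r2y`, and
#'   `vip` (see [vip()]).
#' @export
oplsda <- function(x, labels, n_orthogonal = 1,
                   scaling = c("unit_variance", "center")) {
  m <- scale_columns(x, scaling)
  labels <- as.character(labels)
  if (length(labels) != nrow(m)) stop("labels and rows differ in length")
  groups <- unique(labels)
  if (length(groups) != 2L) stop("OPLS-DA needs exactly two groups")
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")
  y <- ifelse(labels == groups[1L], 1, -1)
  y <- y - mean(y)
  X <- m
  wo_l <- to_l <- po_l <- list()
  pls_weight <- function(X, y) {
    w <- drop(crossprod(X, y))
    w / sqrt(sum(w^2))
  }
  for (o in seq_len(n_orthogonal)) {
    w <- pls_weight(X, y)
    t_ <- drop(X %*% w)
    p_ <- drop(crossprod(X, t_)) / sum(t_^2)
    wo <- p_ - sum(w * p_) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break       # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(X %*% wo)
    po <- drop(crossprod(X, to)) / sum(to^2)
    X <- X - tcrossprod(to, po)
    wo_l[[length(wo_l) + 1L]] <- wo
    to_l[[length(to_l) + 1L]] <- to
    po_l[[length(po_l) + 1L]] <- po
  }
  w <- pls_weight(X, y)
  t_ <- drop(X %*% w)
  p_ <- drop(crossprod(X, t_)) / sum(t_^2)
  c_ <- sum(t_ * y) / sum(t_^2)
  r2y <- 1 - sum((y - c_ * t_)^2) / sum(y^2)
  model <- structure(
    list(weights = w, scores = t_, loadings = p_,
         orthogonal_weights = wo_l, orthogonal_scores = to_l,
         orthogonal_loadings = po_l,
         y = y, groups = groups, r2y = r2y,
         center = attr(m, "center"), scale = attr(m, "scale"),
         variable_names = colnames(as_data_matrix(x))),
    class = "mwfp_opls")
  model$vip <- vip(model)
  model
}

#' Variable influence on projection
#'
#' VIP over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a SSY_a (w_aj / ||w_a||)^2 / sum_a SSY_a)`.
#' With the single predictive component used here this reduces to
#' `sqrt(p) * |w_j|`, so the mean squared VIP is exactly 1 and variables
#' with VIP > 1 carry above-average class-predictive weight.
#'
#' @param model A fitted `mwfp_opls` model.
#' @return Numeric VIP vector over variables.
#' @export
vip <- function(model) {
  if (!inherits(model, "mwfp_opls")) stop("vip() needs a fitted OPLS-DA model")
  w <- model$weights
  out <- sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
  names(out) <- model$variable_names %||% names(w)
  out
}

#' @export
print.mwfp_opls <- function(x, ...) {
  cat("<OPLS-DA>", length(x$scores), "samples,", length(x$weights),
      "variables,", length(x$orthogonal_scores), "orthogonal component(s)\n",
      " groups:", paste(x$groups, collapse = " vs "),
      sprintf("  R2Y = %.3f\n", x$r2y))
  cat("  variables with VIP > 1:", sum(x$vip > 1), "\n")
  invisible(x)
}
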