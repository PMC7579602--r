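#' Correlation-based distance between covariates
#'
#' Distance `1 - |r|` between covariate columns, where `r` is the Pearson
#' correlation. Covariates are compared on the correlation scale because
#' their units are incommensurable (kg, kcal, dimensionless ratios), and
#' the absolute value makes the distance sign-blind: a strongly negative
#' correlate is just as redundant for dimension reduction as a positive
#' one.
#'
#' @param x A `covariate_panel` (its nutritional columns are used by
#'   default), or a numeric matrix/data frame of covariate columns.
#' @param cols Optional character vector selecting columns when `x` is a
#'   panel.
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
covariate_distance <- function(x, cols = NULL) {
  X <- covariate_matrix(x, cols)
  if (nrow(X) < 3L) stopf("at least 3 observations are required")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    stopf("zero-variance covariate(s): %s",
          paste(colnames(X)[sds <= 0 | !is.finite(sds)], collapse = ", "))
  }
  d <- 1 - abs(stats::cor(X))
  diag(d) <- 0
  d
}

covariate_matrix <- function(x, cols = NULL) {
  if (inherits(x, "covariate_panel")) {
    cols <- cols %||% attr(x, "nutritional_cols")
    X <- as.matrix(as.data.frame(x)[cols])
  } else {
    X <- as.matrix(x)
    if (!is.null(cols)) X <- X[, cols, drop = FALSE]
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' Kelley index for choosing the number of clusters
#'
#' For each candidate cut `k` of a hierarchical tree, the average
#' within-cluster spread (mean over clusters with at least two members of
#' their mean pairwise distance) is min-max normalized across the
#' candidate cuts onto `[1, n - 1]` and penalized by adding `k`; the `k`
#' minimizing the index balances tight clusters against cluster count
#' (lower is better). When the spread is identical at every candidate cut
#' the normalization degenerates, the index reduces to the cluster-count
#' penalty and the smallest `k` wins. The index is invariant to rescaling
#' all distances by a constant.
#'
#' Because the min-max normalization is scale-free, the criterion locates
#' an elbow in the spread profile; on data whose spread declines smoothly
#' with `k` and never flattens (e.g. a handful of equally tight clusters
#' with no internal structure) it drifts toward the largest candidate `k`.
#' Restrict `k_range` when such data are clustered deliberately.
#'
#' @param tree An [stats::hclust()] tree.
#' @param d The distance matrix the tree was built from (matrix or `dist`).
#' @param k_range Candidate cluster counts (default `2:(n-1)`).
#' @return Tibble with columns `k`, `spread`, `normalized_spread`, `index`.
#' @export
kelley_index <- function(tree, d, k_range = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  k_range <- k_range %||% seq(2L, n - 1L)
  if (any(k_range < 2L | k_range > n - 1L)) {
    stopf("k_range must lie within [2, n-1]")
  }
  spread_at <- function(k) {
    member <- stats::cutree(tree, k = k)
    per_cluster <- vapply(split(seq_len(n), member), function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      sub <- d[idx, idx, drop = FALSE]
      mean(sub[lower.tri(sub)])
    }, numeric(1))
    if (all(is.na(per_cluster))) {
      warnf("all clusters are singletons at k = %d; spread set to 0", k)
      return(0)
    }
    mean(per_cluster, na.rm = TRUE)
  }
  spread <- vapply(k_range, spread_at, numeric(1))
  rng <- range(spread)
  normalized <- if (diff(rng) > 0) {
    (n - 2) * (spread - rng[1L]) / diff(rng) + 1
  } else {
    rep(1, length(spread))
  }
  tibble(k = as.integer(k_range), spread = spread,
         normalized_spread = normalized, index = normalized + k_range)
}

#' Cluster covariates from their correlation structure
#'
#' Agglomerative hierarchical clustering (average linkage / UPGMA by
#' default) of the `1 - |r|` covariate distances, cut at the number of
#' clusters minimizing the [kelley_index()]; ties are broken toward fewer
#' clusters.
#'
#' @param d Distance matrix from [covariate_distance()] (or any symmetric
#'   distance matrix with named dimensions).
#' @param k_range Candidate cluster counts (default `2:(n-1)`).
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An object of class `cluster_partition`: list with `membership`
#'   (named integer vector), `k`, `tree`, and the `kelley` score table.
#' @export
cluster_covariates <- function(d, k_range = NULL, linkage = "average") {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stopf("need at least 3 covariates to cluster")
  off <- d[lower.tri(d)]
  if (all(off == 0)) stopf("degenerate distance matrix: all distances are zero")
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  scores <- kelley_index(tree, d, k_range)
  k <- scores$k[which.min(scores$index)]   # first minimum = smallest k
  membership <- stats::cutree(tree, k = k)
  structure(
    list(membership = membership, k = as.integer(k), tree = tree,
         kelley = scores),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("Covariate partition: %d covariates in %d clusters (Kelley criterion)\n",
              length(x$membership), x$k))
  sizes <- table(x$membership)
  cat("cluster sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster principal components of the covariate panel
#'
#' Standardizes the covariates and, within each cluster of the partition,
#' performs a principal component analysis, retaining the eigenvectors with
#' the largest eigenvalues (at most `n_eig`, fewer when the cluster is
#' smaller). The concatenated factor scores are the regressors for the
#' selection stage, and the retained loadings are kept so factor
#' coefficients can be mapped back to the original covariates. A warning is
#' issued if any cluster's retained variance fraction falls below 90%.
#' Eigenvector signs are fixed by making each vector's largest-magnitude
#' loading positive.
#'
#' @param panel A `covariate_panel`, matrix or data frame containing the
#'   partitioned covariates.
#' @param partition A `cluster_partition` from [cluster_covariates()].
#' @param n_eig Number of eigenvectors retained per cluster (default 3).
#' @return An object of class `factor_set`: list with `loadings` (full
#'   covariates x factors matrix, zero outside a covariate's own cluster),
#'   `scores` (countries x factors), `eigenvalues` and `variance_fraction`
#'   per cluster, `membership`, `center`, `scale`.
#' @export
extract_factors <- function(panel, partition, n_eig = 3L) {
  if (!inherits(partition, "cluster_partition")) {
    stopf("'partition' must come from cluster_covariates()")
  }
  X <- covariate_matrix(panel, names(partition$membership))
  if (nrow(X) < 2L) stopf("at least 2 observations are required")
  std <- standardize_matrix(X)
  Xs <- std$x
  member <- partition$membership
  clusters <- sort(unique(member))

  factor_names <- character(0)
  loadings <- matrix(0, ncol(Xs), 0, dimnames = list(colnames(Xs), NULL))
  scores <- matrix(0, nrow(Xs), 0)
  eigenvalues <- vector("list", length(clusters))
  var_frac <- numeric(length(clusters))
  names(eigenvalues) <- names(var_frac) <- paste0("C", clusters)

  for (i in seq_along(clusters)) {
    idx <- which(member == clusters[i])
    sub <- Xs[, idx, drop = FALSE]
    eig <- eigen(stats::cor(sub), symmetric = TRUE)
    r <- min(n_eig, length(idx))
    vec <- eig$vectors[, seq_len(r), drop = FALSE]
    # reproducible sign: largest-|loading| entry positive
    for (j in seq_len(r)) {
      piv <- which.max(abs(vec[, j]))
      if (vec[piv, j] < 0) vec[, j] <- -vec[, j]
    }
    eigenvalues[[i]] <- eig$values
    var_frac[i] <- sum(eig$values[seq_len(r)]) / length(idx)
    fn <- sprintf("C%d_PC%d", clusters[i], seq_len(r))
    factor_names <- c(factor_names, fn)
    block <- matrix(0, ncol(Xs), r, dimnames = list(colnames(Xs), fn))
    block[idx, ] <- vec
    loadings <- cbind(loadings, block)
    scores <- cbind(scores, sub %*% vec)
  }
  colnames(scores) <- factor_names
  if (any(var_frac < 0.90)) {
    warnf("retained variance fraction below 90%% in cluster(s): %s",
          paste(names(var_frac)[var_frac < 0.90], collapse = ", "))
  }
  structure(
    list(loadings = loadings, scores = scores, eigenvalues = eigenvalues,
         variance_fraction = var_frac, membership = member,
         center = std$center, scale = std$scale, n_eig = as.integer(n_eig)),
    class = "factor_set"
  )
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("Factor set: %d covariates -> %d factors across %d clusters\n",
              nrow(x$loadings), ncol(x$loadings), length(x$variance_fraction)))
  cat("retained variance fractions:",
      paste(sprintf("%s=%.3f", names(x$variance_fraction), x$variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is the coefficient of
#' determination from regressing column `j` on all other columns (with
#' intercept). Exactly collinear columns are reported as `Inf` with a
#' warning.
#'
#' @param X Numeric matrix or data frame with at least two columns and more
#'   rows than columns.
#' @return Named numeric vector of VIFs.
#' @export
#' @examples
#' compute_vif(matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b"))))
compute_vif <- function(X) {
  X <- covariate_matrix(X)
  if (ncol(X) < 2L) stopf("VIF needs at least 2 columns")
  if (nrow(X) <= ncol(X)) stopf("VIF needs more rows than columns")
  if (any(!is.finite(X))) stopf("non-finite values in design matrix")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    y <- X[, j]
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  if (any(is.infinite(vif))) {
    warnf("exactly collinear column(s), VIF infinite: %s",
          paste(colnames(X)[is.infinite(vif)], collapse = ", "))
  }
  setNames(vif, colnames(X))
}
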