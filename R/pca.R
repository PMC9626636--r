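#' PCA of the harmonized CBC matrix
#'
#' Principal components of the (optionally unit-variance standardized)
#' feature matrix.  CBC units are incommensurable, so standardization is the
#' default.  The sign of each component is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param matrix a `feature_matrix` from [assemble_matrix()], or a plain
#'   numeric matrix.
#' @param standardize scale features to unit variance before PCA.
#' @param k number of components to keep (default: all with positive
#'   variance; rank-deficient input reduces k with a warning).
#' @return a `pca_result` list: `loadings` (p x k, orthonormal columns),
#'   `scores` (n x k), `variance_fraction` (length k, non-increasing).
#' @export
fit_pca <- function(matrix, standardize = TRUE, k = NULL) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else as.matrix(matrix)
  if (nrow(X) <= ncol(X))
    stop("need more records than features for a meaningful PCA")
  sds <- apply(X, 2L, stats::sd)
  if (standardize && any(sds == 0)) {
    warning("zero-variance features left unscaled: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  scale_vec <- if (standardize) ifelse(sds == 0, 1, sds) else FALSE
  pc <- stats::prcomp(X, center = TRUE, scale. = scale_vec)
  tot <- sum(pc$sdev^2)
  pos <- pc$sdev^2 > tot * 1e-12
  kmax <- sum(pos)
  if (is.null(k)) k <- kmax
  if (k > kmax) {
    warning(sprintf("rank-deficient input: reducing k from %d to %d", k, kmax))
    k <- kmax
  }
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) { # sign convention: largest-|loading| entry positive
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  structure(list(loadings = load, scores = scores,
                 variance_fraction = pc$sdev[seq_len(k)]^2 / tot,
                 standardized = standardize),
            class = "pca_result")
}

#' Age statistics of the PC scores
#'
#' Per component: Pearson correlation with age (two-sided test).  Per age
#' group: score variance, plus the Spearman trend of variance against group
#' age -- growing score variance with age is the signature of a stochastic
#' (diffusive) latent process.
#'
#' @param result a `pca_result`.
#' @param ages ages (weeks) aligned with the score rows.
#' @param age_groups bin edges for the variance-by-age summary.
#' @return list with `age_correlation` (data frame: pc, r, p; `NA` r for a
#'   constant score) and `variance_trend` (per pc: data frame of group
#'   variances, and the Spearman rho of variance vs group age).
#' @export
pc_age_stats <- function(result, ages,
                         age_groups = seq(min(ages), max(ages), length.out = 5)) {
  stopifnot(inherits(result, "pca_result"),
            length(ages) == nrow(result$scores))
  k <- ncol(result$scores)
  cor_df <- do.call(rbind, lapply(seq_len(k), function(j) {
    s <- result$scores[, j]
    if (stats::sd(s) == 0)
      return(data.frame(pc = j, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(s, ages)
    data.frame(pc = j, r = unname(ct$estimate), p = ct$p.value)
  }))
  bins <- cut(ages, breaks = unique(c(-Inf, age_groups, Inf)), right = TRUE)
  trend <- lapply(seq_len(k), function(j) {
    v <- tapply(result$scores[, j], bins, stats::var)
    mid <- tapply(ages, bins, mean)
    ok <- !is.na(v)
    rho <- if (sum(ok) >= 3)
      suppressWarnings(stats::cor(mid[ok], v[ok], method = "spearman"))
    else NA_real_
    list(by_group = data.frame(age_mean = unname(mid[ok]),
                               variance = unname(v[ok])),
         spearman_rho = rho)
  })
  names(trend) <- paste0("PC", seq_len(k))
  list(age_correlation = cor_df, variance_trend = trend)
}

#' Hierarchical clustering of CBC features
#'
#' Agglomerative (average-linkage) clustering with distance
#' `1 - |Pearson r|`; perfectly correlated or anti-correlated features merge
#' at height 0, independent noise merges last.  Zero-variance features are
#' excluded with a warning.  Optional extra columns (e.g. PC scores) can be
#' clustered alongside the features.
#'
#' @param matrix a `feature_matrix` or numeric matrix.
#' @param scores optional numeric matrix of extra columns (aligned rows).
#' @return an `hclust` object (merge list with heights).
#' @export
cluster_features <- function(matrix, scores = NULL) {
  X <- if (inherits(matrix, "feature_matrix")) matrix$values else as.matrix(matrix)
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (is.null(colnames(scores)))
      colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
    X <- cbind(X, scores)
  }
  if (ncol(X) < 2) stop("need at least two features to cluster")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance features: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  d <- stats::as.dist(1 - abs(stats::cor(X)))
  stats::hclust(d, method = "average")
}

#' Export a feature dendrogram as a merge-list CSV
#'
#' One row per agglomeration step: negative entries reference original
#' features (by position in `labels`), positive entries reference earlier
#' merge rows, following the `hclust` merge convention.
#'
#' @param hc an `hclust` object from [cluster_features()].
#' @param path optional CSV path.
#' @return data frame with `merge1`, `merge2`, `height`, `label1`, `label2`
#'   (labels filled for original-feature entries).
#' @export
dendrogram_to_csv <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  lab <- function(i) {
    out <- rep(NA_character_, length(i))
    neg <- i < 0
    out[neg] <- hc$labels[-i[neg]]
    out
  }
  df <- data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                   height = hc$height,
                   label1 = lab(hc$merge[, 1]), label2 = lab(hc$merge[, 2]))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Tidy export of PCA diagnostics
#'
#' @param result a `pca_result`.
#' @param path optional CSV path.
#' @return data frame of per-component variance fractions (written to
#'   `path` when given).
#' @export
pca_summary_csv <- function(result, path = NULL) {
  stopifnot(inherits(result, "pca_result"))
  df <- data.frame(pc = seq_along(result$variance_fraction),
                   variance_fraction = result$variance_fraction)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
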