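#' K-means clustering of species by stem-length profile
#'
#' Species (rows of the stem-length table) are clustered on their
#' realized stem lengths.  Unknown cells are imputed with the stem's
#' modal length for clustering only.  The best of `restarts` seeded
#' runs by within-cluster sum of squares is kept; results are
#' deterministic given `seed`.
#'
#' @param table a `stem_length_table`.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of random starts (default 10).
#' @return object of class `cluster_assignment`: `cluster` (named
#'   integer vector), `k`, `wcss` (total within-cluster sum of
#'   squares), `centers`, `wcss_by_k` is `NULL` here (see
#'   [wcss_profile]).
#' @export
kmeans_stems <- function(table, k, seed = 1, restarts = 10) {
  x <- .imputed_lengths(table)
  if (k > nrow(x))
    stop("k (", k, ") exceeds the number of species (", nrow(x), ")")
  if (k > nrow(unique(x)))
    stop("k (", k, ") exceeds the number of distinct stem-length ",
         "profiles (", nrow(unique(x)), ")")
  set.seed(seed)
  fit <- kmeans(x, centers = k, nstart = restarts)
  structure(list(cluster = fit$cluster, k = k,
                 wcss = fit$tot.withinss, centers = fit$centers),
            class = "cluster_assignment")
}

.imputed_lengths <- function(table) {
  stopifnot(inherits(table, "stem_length_table"))
  x <- table$lengths
  for (s in seq_len(ncol(x))) {
    u <- is.na(x[, s])
    if (any(u)) x[u, s] <- table$modal[s]
  }
  storage.mode(x) <- "double"
  x
}

#' Within-cluster sum of squares across a range of k
#'
#' Side report supporting the choice of k by comparing clustering
#' results for different values of k.
#'
#' @param table a `stem_length_table`.
#' @param k_range integer vector of k values (default 2:8, truncated to
#'   the number of species).
#' @inheritParams kmeans_stems
#' @return data frame with columns `k` and `wcss`.
#' @export
wcss_profile <- function(table, k_range = 2:8, seed = 1, restarts = 10) {
  n_distinct <- nrow(unique(.imputed_lengths(table)))
  k_range <- k_range[k_range <= n_distinct]
  if (!length(k_range))
    return(data.frame(k = integer(0), wcss = numeric(0)))
  data.frame(k = k_range, wcss = vapply(k_range, function(k)
    kmeans_stems(table, k, seed, restarts)$wcss, numeric(1)))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means:", x$k, "clusters, WCSS", format(x$wcss), "\n")
  invisible(x)
}

#' Principal component analysis of stem lengths
#'
#' Eigen-decomposition of the covariance of the centered (by default
#' not scaled) species-by-stem length matrix.  Partial sequences (rows
#' with any unknown cell, i.e. overlapping `~`) are excluded when
#' `exclude_partial` is `TRUE` (the default); remaining rows with
#' unknown cells are dropped (PCA never imputes).
#'
#' @param table a `stem_length_table`.
#' @param exclude_partial drop species with any unknown cell.
#' @param scale. autoscale variables (correlation PCA) instead of the
#'   default covariance PCA.
#' @return object of class `pca_result`: `scores`, `loadings`,
#'   `variance_share` (per component, sums to 1), `cumvar2`
#'   (cumulative share of the first two components), `top_stems`
#'   (highest-|loading| stem per component), `sdev`.
#' @export
pca_stems <- function(table, exclude_partial = TRUE, scale. = FALSE) {
  x <- table$lengths
  keep <- complete.cases(x)
  if (!exclude_partial && !all(keep))
    warning("rows with unknown cells are dropped from PCA")
  x <- x[keep, , drop = FALSE]
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 species with complete profiles")
  if (ncol(x) < 2) stop("need at least 2 stems")
  if (nrow(x) <= ncol(x))
    message("note: number of sequences (", nrow(x),
            ") does not exceed number of stems (", ncol(x), ")")
  if (all(apply(x, 2, stats::var) == 0)) stop("degenerate table: rank 0")
  if (scale.) {
    const <- apply(x, 2, stats::var) == 0
    if (any(const)) x <- x[, !const, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = scale.)
  vshare <- fit$sdev^2 / sum(fit$sdev^2)
  top <- apply(fit$rotation, 2, function(v)
    rownames(fit$rotation)[which.max(abs(v))])
  structure(list(scores = fit$x, loadings = fit$rotation,
                 variance_share = vshare,
                 cumvar2 = sum(vshare[seq_len(min(2, length(vshare)))]),
                 top_stems = top, sdev = fit$sdev,
                 center = fit$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of stem lengths:", nrow(x$scores), "species,",
      nrow(x$loadings), "stems\n")
  cat(sprintf("First two components explain %.1f%% of the variance\n",
              100 * x$cumvar2))
  cat("Top-loading stems:",
      paste(names(x$top_stems)[1:min(2, length(x$top_stems))],
            x$top_stems[1:min(2, length(x$top_stems))],
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Drawing-neutral biplot payload
#'
#' Species scores on the first two components with cluster classes,
#' stem loading vectors, and an outlier list: species whose
#' standardized score radius sqrt((s1/sd1)^2 + (s2/sd2)^2) exceeds
#' `radius`.
#'
#' @param pca a `pca_result`.
#' @param clusters optional `cluster_assignment` over (a superset of)
#'   the same species.
#' @param radius outlier radius in standard-deviation units
#'   (default 2.5).
#' @return list with `points` (data frame: species, pc1, pc2, cluster,
#'   outlier), `arrows` (data frame: stem, pc1, pc2), `radius`.
#' @export
biplot_data <- function(pca, clusters = NULL, radius = 2.5) {
  sp <- rownames(pca$scores)
  cl <- rep(NA_integer_, length(sp))
  if (!is.null(clusters)) {
    if (!all(sp %in% names(clusters$cluster)))
      stop("cluster assignment is missing species: ",
           paste(setdiff(sp, names(clusters$cluster)), collapse = ", "))
    cl <- unname(clusters$cluster[sp])
  }
  s1 <- pca$scores[, 1] / pca$sdev[1]
  s2 <- if (ncol(pca$scores) >= 2) pca$scores[, 2] / pca$sdev[2] else 0
  r <- sqrt(s1^2 + s2^2)
  points <- data.frame(species = sp, pc1 = pca$scores[, 1],
                       pc2 = if (ncol(pca$scores) >= 2)
                         pca$scores[, 2] else 0,
                       cluster = cl, outlier = r > radius,
                       stringsAsFactors = FALSE)
  arrows <- data.frame(stem = rownames(pca$loadings),
                       pc1 = pca$loadings[, 1],
                       pc2 = if (ncol(pca$loadings) >= 2)
                         pca$loadings[, 2] else 0,
                       stringsAsFactors = FALSE)
  list(points = points, arrows = arrows, radius = radius)
}
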