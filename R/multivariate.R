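#' Spearman correlation distance between samples
#'
#' `d(i, j) = 1 - rho(i, j)` with Spearman rank correlation (average ranks
#' on ties), computed between columns of a complete (imputed) matrix.
#' Because the correlation only sees ranks, the distance is invariant under
#' any strictly monotone transform of a column.
#'
#' @param x Numeric matrix (features x samples) without missing values, or
#'   a [protein_matrix()].
#' @return Symmetric distance matrix with zero diagonal and attribute
#'   `metric = "spearman"`.
#' @export
spearman_distance <- function(x) {
  if (inherits(x, "protein_matrix")) x <- x$values
  if (anyNA(x)) stopf("matrix has missing values; impute before clustering")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(x, method = "spearman")
  d[abs(d) < 1e-15] <- 0
  diag(d) <- 0
  attr(d, "metric") <- "spearman"
  d
}

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Standard agglomerative clustering (via [stats::hclust()]) under the
#' chosen linkage. Average linkage is the default.
#'
#' @param dist_mat Symmetric distance matrix (e.g. [spearman_distance()]).
#' @param linkage `"average"` (default), `"complete"`, or `"ward.D2"`.
#' @return An [stats::hclust] dendrogram.
#' @export
hierarchical_cluster <- function(dist_mat,
                                 linkage = c("average", "complete", "ward.D2")) {
  linkage <- match.arg(linkage)
  if (!isTRUE(all.equal(dist_mat, t(dist_mat), tolerance = 1e-12)))
    stopf("distance matrix is not symmetric")
  if (nrow(as.matrix(dist_mat)) == 1L) {
    # degenerate single-sample tree: no merges
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          height = numeric(0), order = 1L,
                          labels = rownames(as.matrix(dist_mat)),
                          method = linkage),
                     class = "hclust"))
  }
  stats::hclust(stats::as.dist(dist_mat), method = linkage)
}

#' Cut a dendrogram into k clusters
#'
#' @param dend An [stats::hclust] object.
#' @param k Number of clusters (1 <= k <= leaves).
#' @return Named integer vector sample -> cluster label.
#' @export
cut_clusters <- function(dend, k) {
  if (!is_count(k)) stopf("`k` must be a count >= 1")
  n_leaves <- length(dend$order)
  if (k > n_leaves) stopf("k = %d exceeds %d leaves", k, n_leaves)
  if (n_leaves == 1L) return(stats::setNames(1L, dend$labels))
  stats::cutree(dend, k = k)
}

#' Principal component analysis of samples
#'
#' Samples are observations, proteins (centred across samples) are
#' variables; components come from the singular value decomposition of the
#' centred matrix and explained-variance fractions from the squared
#' singular values. The sign of each component is fixed so its
#' largest-magnitude loading is positive, making outputs reproducible.
#'
#' @param x Complete numeric matrix (proteins x samples) or
#'   [protein_matrix()].
#' @param scale. Scale proteins to unit variance before the decomposition
#'   (default `FALSE`).
#' @return List with `scores` (samples x components), `loadings`
#'   (proteins x components, orthonormal) and `explained` (fractions,
#'   nonincreasing).
#' @export
pca_samples <- function(x, scale. = FALSE) {
  if (inherits(x, "protein_matrix")) x <- x$values
  if (anyNA(x)) stopf("matrix has missing values; impute before PCA")
  if (ncol(x) < 2) stopf("PCA needs at least 2 samples")
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale.)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings, explained = explained)
}
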