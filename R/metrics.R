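#' k-NN label agreement of an embedding
#'
#' Fraction of cells whose majority cluster label among their k nearest
#' Euclidean neighbors (self excluded) equals their own label — a local
#' structure-preservation score in `[0, 1]`. Neighbor ties at the k-th
#' distance are broken toward the smaller row index; majority ties are broken
#' toward the label appearing first among the ordered neighbors.
#'
#' @param z Embedding: numeric matrix or data frame of coordinates (any
#'   non-numeric columns such as `cell_id` are dropped).
#' @param labels Cluster labels, length `nrow(z)`.
#' @param k Number of neighbors (default 10); must be `< n`.
#' @return Scalar in `[0, 1]`.
#' @export
knn_label_agreement <- function(z, labels, k = 10) {
  z <- as_coord_matrix(z)
  lab <- as.character(as_cluster_labels(labels))
  n <- nrow(z)
  if (length(lab) != n) stop("`labels` must have one entry per row of `z`.", call. = FALSE)
  if (k >= n) stop("`k` must be smaller than the number of cells.", call. = FALSE)
  D <- as.matrix(stats::dist(z))
  hits <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    idx <- order(d, seq_along(d))[seq_len(k)]    # smaller index wins distance ties
    nb <- lab[-i][idx]
    counts <- table(factor(nb, levels = unique(nb)))  # first-appearance tie-break
    maj <- names(counts)[which.max(counts)]
    maj == lab[i]
  }, logical(1))
  mean(hits)
}

#' Centroid-distance rank correlation
#'
#' Global structure-preservation score: the Spearman rank correlation between
#' the c(c-1)/2 pairwise cluster-centroid distances in the embedding and in a
#' reference space (typically the original, noiseless data). 1 means the
#' relative placement of clusters is perfectly preserved in rank.
#'
#' @inheritParams knn_label_agreement
#' @param reference Reference coordinates: either an `n x p` matrix aligned
#'   row-wise with `z` (centroids are computed per cluster), or a `c x p`
#'   matrix of per-cluster centroids ordered by first appearance of the
#'   labels.
#' @return Scalar in `[-1, 1]`. Requires at least 3 clusters.
#' @export
centroid_distance_correlation <- function(z, labels, reference) {
  z <- as_coord_matrix(z)
  lab <- as.character(as_cluster_labels(labels))
  classes <- unique(lab)
  c <- length(classes)
  if (c < 3) stop("Centroid-distance correlation needs at least 3 clusters.", call. = FALSE)
  reference <- as_coord_matrix(reference)
  cz <- centroids_by(z, lab, classes)
  cr <- if (nrow(reference) == nrow(z)) {
    centroids_by(reference, lab, classes)
  } else if (nrow(reference) == c) {
    reference
  } else {
    stop("`reference` must have either one row per cell or one row per cluster.",
         call. = FALSE)
  }
  stats::cor(as.numeric(stats::dist(cz)), as.numeric(stats::dist(cr)),
             method = "spearman")
}

centroids_by <- function(x, lab, classes) {
  t(vapply(classes, function(cl) colMeans(x[lab == cl, , drop = FALSE]),
           numeric(ncol(x))))
}

#' Mean silhouette width of an embedding
#'
#' Standard mean silhouette over cells with Euclidean distances, in
#' `[-1, 1]`. Degenerate cells for which both the within- and
#' between-cluster mean distances are zero (e.g., all points identical) score
#' 0 by convention.
#'
#' @inheritParams knn_label_agreement
#' @return Scalar in `[-1, 1]`. Requires `2 <= c < n` clusters.
#' @export
silhouette_score <- function(z, labels) {
  z <- as_coord_matrix(z)
  lab <- as.character(as_cluster_labels(labels))
  c <- length(unique(lab))
  if (c < 2 || c >= nrow(z)) {
    stop("Silhouette needs 2 <= number of clusters < n.", call. = FALSE)
  }
  sil <- cluster::silhouette(as.integer(factor(lab, levels = unique(lab))),
                             dist = stats::dist(z))
  widths <- sil[, "sil_width"]
  widths[!is.finite(widths)] <- 0
  mean(widths)
}

#' Structure-preservation report for an embedding
#'
#' Bundles the package's three structure metrics: [knn_label_agreement()]
#' (local), [silhouette_score()] (local/separation), and — when a reference
#' is supplied — [centroid_distance_correlation()] (global).
#'
#' @inheritParams centroid_distance_correlation
#' @param reference Optional reference coordinates for the global metric.
#' @param k Neighbors for the k-NN metric (default 10).
#' @return A one-row tibble with `knn_agreement`, `silhouette`,
#'   `centroid_dist_corr` (NA when no reference given), and `k_used`.
#' @export
structure_report <- function(z, labels, reference = NULL, k = 10) {
  tibble::tibble(
    knn_agreement = knn_label_agreement(z, labels, k = k),
    silhouette = silhouette_score(z, labels),
    centroid_dist_corr = if (is.null(reference)) NA_real_ else
      centroid_distance_correlation(z, labels, reference),
    k_used = as.integer(k)
  )
}

as_coord_matrix <- function(z) {
  if (inherits(z, "sspca")) return(z$embedding)
  if (is.data.frame(z)) {
    num <- vapply(z, is.numeric, logical(1))
    z <- as.matrix(z[, num, drop = FALSE])
  }
  if (!is.matrix(z) || !is.numeric(z)) {
    stop("Coordinates must be a numeric matrix or data frame.", call. = FALSE)
  }
  z
}
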