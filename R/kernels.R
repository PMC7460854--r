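#' Centering matrix
#'
#' Returns the n x n centering matrix H = I - (1/n) 11', the symmetric
#' idempotent projector that removes the mean of a vector (H 1 = 0). It is the
#' H appearing in the empirical HSIC estimator and in the ssPCA objective.
#' Internally the package applies H implicitly (by subtracting row/column
#' means) for large matrices; this function materializes the exact matrix.
#'
#' @param n Positive integer, the dimension.
#' @return An `n x n` numeric matrix.
#' @examples
#' centering_matrix(2)
#' @export
centering_matrix <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a single positive integer.", call. = FALSE)
  }
  n <- as.integer(n)
  diag(n) - matrix(1 / n, n, n)
}

#' Multiply by the centering matrix implicitly
#'
#' `center_cols(A)` computes `H %*% A` (subtract column means);
#' `center_rows(A)` computes `A %*% H` (subtract row means);
#' `double_center(A)` computes `H %*% A %*% H`. All are O(n^2) and agree with
#' the explicit matrix products to machine precision.
#'
#' @param A Numeric matrix.
#' @return Matrix of the same dimension.
#' @keywords internal
#' @noRd
center_cols <- function(A) sweep(A, 2L, colMeans(A), "-")

#' @noRd
center_rows <- function(A) sweep(A, 1L, rowMeans(A), "-")

#' @noRd
double_center <- function(A) {
  A <- sweep(A, 2L, colMeans(A), "-")
  sweep(A, 1L, rowMeans(A), "-")
}

# Shared validation for expression input: numeric matrix, n >= 2 rows, finite.
as_expression_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    idcol <- which(vapply(x, function(col) is.character(col) || is.factor(col), logical(1)))
    ids <- NULL
    if (length(idcol)) {
      ids <- as.character(x[[idcol[1L]]])
      x <- x[, -idcol, drop = FALSE]
    }
    x <- as.matrix(x)
    if (!is.null(ids)) rownames(x) <- ids
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame (cells x genes).", arg),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains missing or non-finite values; impute or filter upstream.", arg),
         call. = FALSE)
  }
  x
}

#' Linear kernel
#'
#' Computes the Gram matrix of inner products `K[i, j] = <x_i, x_j>` between
#' cell expression profiles (rows of `x`). The result is symmetric and
#' positive semidefinite.
#'
#' @param x Numeric matrix or data frame, cells in rows and genes in columns.
#'   A single character/factor column, if present, is used as cell identifiers.
#' @return An `n x n` symmetric kernel matrix with cell identifiers as
#'   dimnames when available.
#' @seealso [polynomial_kernel()], [rbf_kernel()]
#' @examples
#' linear_kernel(matrix(c(1, 3, 2, 4), 2))
#' @export
linear_kernel <- function(x) {
  x <- as_expression_matrix(x)
  K <- tcrossprod(x)
  (K + t(K)) / 2
}

#' Polynomial kernel
#'
#' Computes `K[i, j] = (c <x_i, x_j> + 1)^d` between cell expression profiles.
#'
#' @inheritParams linear_kernel
#' @param c Nonnegative scale on the inner product (default 1).
#' @param d Positive integer degree (default 2).
#' @return An `n x n` symmetric kernel matrix.
#' @examples
#' polynomial_kernel(matrix(c(1, 2), 2), c = 1, d = 1)
#' @export
polynomial_kernel <- function(x, c = 1, d = 2) {
  if (length(d) != 1L || !is.finite(d) || d < 1 || d != round(d)) {
    stop("`d` must be a positive integer.", call. = FALSE)
  }
  if (length(c) != 1L || !is.finite(c) || c < 0) {
    stop("`c` must be a single nonnegative number.", call. = FALSE)
  }
  x <- as_expression_matrix(x)
  K <- (c * tcrossprod(x) + 1)^d
  (K + t(K)) / 2
}

#' Radial basis function (Gaussian) kernel
#'
#' Computes `K[i, j] = exp(-||x_i - x_j||^2 / sigma^2)`. Note the bandwidth
#' convention: the squared distance is divided by `sigma^2`, with no factor
#' of 2. The diagonal is exactly 1 and all entries lie in (0, 1].
#'
#' @inheritParams linear_kernel
#' @param sigma Positive bandwidth, or the string `"median"` (default) to use
#'   the median heuristic of [median_bandwidth()].
#' @return An `n x n` symmetric kernel matrix with unit diagonal and an
#'   attribute `sigma` recording the bandwidth used.
#' @examples
#' rbf_kernel(matrix(c(0, 2), 2), sigma = 2)
#' @export
rbf_kernel <- function(x, sigma = "median") {
  x <- as_expression_matrix(x)
  if (identical(sigma, "median")) {
    sigma <- median_bandwidth(x)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number or \"median\".", call. = FALSE)
  }
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / sigma^2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  attr(K, "sigma") <- sigma
  K
}

#' Median-heuristic bandwidth
#'
#' Returns the median of the nonzero pairwise Euclidean distances between
#' rows of `x` — the standard deterministic, scale-adaptive choice for the
#' RBF bandwidth when none is supplied.
#'
#' @inheritParams linear_kernel
#' @return A positive scalar.
#' @examples
#' median_bandwidth(matrix(c(0, 1, 3), 3))
#' @export
median_bandwidth <- function(x) {
  x <- as_expression_matrix(x)
  d <- as.numeric(stats::dist(x))
  d <- d[d > 0]
  if (!length(d)) {
    stop("All rows of `x` are identical; the median pairwise distance is zero. ",
         "Supply `sigma` explicitly.", call. = FALSE)
  }
  stats::median(d)
}

# Normalize a label input (vector, factor, or two-column data frame) to a
# character vector plus first-appearance class order.
as_cluster_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L) stop("Label data frames need columns (cell_id, cluster).", call. = FALSE)
    lab <- as.character(labels[[2L]])
    names(lab) <- as.character(labels[[1L]])
  } else {
    lab <- as.character(labels)
    names(lab) <- names(labels)
  }
  if (!length(lab)) stop("Empty label vector.", call. = FALSE)
  if (anyNA(lab)) stop("Labels contain missing values.", call. = FALSE)
  structure(lab, classes = unique(lab))
}

#' One-hot encode cluster labels
#'
#' Recodes an n-vector of cluster labels into the binary indicator matrix
#' `Y` with `Y[i, j] = 1` iff cell i belongs to cluster j. Columns follow the
#' order of first appearance of each class, recorded in the `"classes"`
#' attribute (and as column names) for reproducibility.
#'
#' @param labels Vector or factor of cluster identifiers, or a two-column
#'   data frame `(cell_id, cluster)`.
#' @return An `n x c` binary matrix; each row sums to 1.
#' @examples
#' encode_one_hot(c("A", "B", "A", "C"))
#' @export
encode_one_hot <- function(labels) {
  lab <- as_cluster_labels(labels)
  classes <- attr(lab, "classes")
  Y <- matrix(0, length(lab), length(classes),
              dimnames = list(names(lab), classes))
  Y[cbind(seq_along(lab), match(lab, classes))] <- 1
  attr(Y, "classes") <- classes
  Y
}

#' Label kernel
#'
#' Builds the block label kernel `K_Y = Y Y'` from one-hot encoded labels:
#' entry (i, j) is 1 iff cells i and j share a cluster, 0 otherwise. The
#' result is invariant to renaming the cluster identifiers.
#'
#' @param labels Cluster labels as in [encode_one_hot()], or an already
#'   one-hot encoded binary matrix.
#' @return An `n x n` binary symmetric matrix with unit diagonal.
#' @examples
#' label_kernel(c("A", "A", "B"))
#' @export
label_kernel <- function(labels) {
  Y <- if (is.matrix(labels) && is.numeric(labels)) labels else encode_one_hot(labels)
  if (any(abs(rowSums(Y) - 1) > 1e-12) || any(Y != 0 & Y != 1)) {
    stop("`labels` is not a valid one-hot matrix (rows must have a single 1).",
         call. = FALSE)
  }
  tcrossprod(Y)
}

#' Empirical HSIC dependence between two kernels
#'
#' Computes the empirical Hilbert-Schmidt Independence Criterion between two
#' kernel matrices on the same n cells,
#' `HSIC = tr(K_X H K_Y H) / (n - 1)^2`, where `H` is the centering matrix.
#' It is nonnegative when both kernels are positive semidefinite, zero when
#' either kernel is constant, and symmetric in its arguments.
#'
#' @param kx,ky Symmetric `n x n` kernel matrices (n >= 2).
#' @return A scalar dependence value.
#' @examples
#' hsic(diag(2), diag(2)) # = 1
#' @export
hsic <- function(kx, ky) {
  if (!is.matrix(kx) || !is.matrix(ky) || nrow(kx) != ncol(kx) ||
      nrow(ky) != ncol(ky)) {
    stop("`kx` and `ky` must be square matrices.", call. = FALSE)
  }
  n <- nrow(kx)
  if (nrow(ky) != n) stop("`kx` and `ky` must have the same dimension.", call. = FALSE)
  if (n < 2) stop("HSIC requires n >= 2.", call. = FALSE)
  if (max(abs(kx - t(kx))) > 1e-8 || max(abs(ky - t(ky))) > 1e-8) {
    stop("`kx` and `ky` must be symmetric.", call. = FALSE)
  }
  # tr(Kx H Ky H) = sum((H Kx H) * Ky) for symmetric Ky
  sum(double_center(kx) * ky) / (n - 1)^2
}

#' Ingest an external similarity matrix as a kernel
#'
#' Validates a precomputed cell-cell similarity matrix (e.g., from single-cell
#' clustering software) for use as the data kernel. Asymmetric input is
#' symmetrized as `(K + K') / 2`, with a warning when the maximal asymmetry
#' exceeds `1e-6`. Non-positive-semidefinite matrices are accepted — the
#' eigensolver only requires symmetry — with a warning reporting the most
#' negative eigenvalue (checked for n <= 2000; skipped above for cost).
#'
#' @param k Square numeric similarity matrix.
#' @param check_psd Check (and warn about) negative eigenvalues (default TRUE
#'   for n <= 2000).
#' @return The symmetrized matrix, with attribute `symmetrized` flagging
#'   whether symmetrization changed it beyond `1e-6`.
#' @export
as_kernel <- function(k, check_psd = nrow(k) <= 2000) {
  if (is.data.frame(k)) k <- as_expression_matrix(k, "k")
  if (!is.matrix(k) || !is.numeric(k) || nrow(k) != ncol(k)) {
    stop("`k` must be a square numeric matrix.", call. = FALSE)
  }
  if (anyNA(k) || any(!is.finite(k))) {
    stop("`k` contains missing or non-finite values.", call. = FALSE)
  }
  asym <- max(abs(k - t(k)))
  if (asym > 1e-6) {
    warning(sprintf("Similarity matrix asymmetry %.3g exceeds 1e-6; symmetrized as (K + K')/2.",
                    asym), call. = FALSE)
  }
  ks <- (k + t(k)) / 2
  if (isTRUE(check_psd)) {
    ev <- eigen(ks, symmetric = TRUE, only.values = TRUE)$values
    lam_min <- min(ev)
    if (lam_min < -1e-8 * max(abs(ev), 1)) {
      warning(sprintf("Similarity matrix is not positive semidefinite (most negative eigenvalue %.3g); proceeding, the eigensolver only needs symmetry.",
                      lam_min), call. = FALSE)
    }
  }
  attr(ks, "symmetrized") <- asym > 1e-6
  ks
}
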