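#' Build the ssPCA objective matrix
#'
#' Forms the symmetric matrix whose top-k eigenvectors solve the ssPCA trace
#' maximization:
#' \deqn{M = (1 - \lambda) K_X H K_X + \lambda K_X H K_Y H K_X,}
#' where `H` is the centering matrix. At `lambda = 0` this is the kernel-PCA
#' objective `K_X H K_X`; at `lambda = 1` it is the purely supervised HSIC
#' term. The result is symmetrized as `(M + M')/2` to absorb floating-point
#' asymmetry and is positive semidefinite whenever `K_X` is.
#'
#' For n > 500 the centering is applied implicitly (mean subtraction) rather
#' than by multiplying with an explicit `H`; the two paths agree to machine
#' precision.
#'
#' @param kx Symmetric `n x n` data kernel.
#' @param ky Symmetric `n x n` label kernel (see [label_kernel()]).
#' @param lambda Trade-off in `[0, 1]` between total variance (0) and cluster
#'   dependence (1).
#' @param explicit_h Use the explicit centering-matrix product. Defaults to
#'   TRUE for n <= 500.
#' @return An `n x n` symmetric matrix.
#' @export
build_objective_matrix <- function(kx, ky, lambda, explicit_h = nrow(kx) <= 500) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single number in [0, 1].", call. = FALSE)
  }
  if (!is.matrix(kx) || nrow(kx) != ncol(kx)) stop("`kx` must be square.", call. = FALSE)
  if (!is.matrix(ky) || any(dim(ky) != dim(kx))) {
    stop("`ky` must be a square matrix of the same dimension as `kx`.", call. = FALSE)
  }
  n <- nrow(kx)
  if (explicit_h) {
    H <- centering_matrix(n)
    M <- (1 - lambda) * (kx %*% H %*% kx) +
      lambda * (kx %*% H %*% ky %*% H %*% kx)
  } else {
    C <- center_cols(kx)                      # C = H Kx, so t(C) = Kx H
    M <- (1 - lambda) * (t(C) %*% kx) + lambda * (t(C) %*% ky %*% C)
  }
  (M + t(M)) / 2
}

#' Top-k eigenpairs of a symmetric matrix
#'
#' Returns orthonormal eigenvectors for the k algebraically largest
#' eigenvalues of a symmetric matrix, eigenvalues in descending order. The
#' sign of each eigenvector is fixed so that its largest-magnitude entry is
#' positive (first such entry on ties), making results reproducible across
#' linear-algebra backends. A dense decomposition is used for
#' `n <= dense_limit`; above that, blocked subspace iteration with
#' Rayleigh-Ritz extraction computes only the leading eigenpairs.
#'
#' When the k-th and (k+1)-th eigenvalues are tied (within `1e-10 * ||M||`),
#' the retained subspace is unique only up to rotation; a warning says so.
#'
#' @param m Symmetric numeric matrix.
#' @param k Number of leading eigenpairs, `1 <= k <= n - 1`.
#' @param dense_limit Switch point between the dense and iterative paths
#'   (default 3000).
#' @return List with `vectors` (`n x k`, orthonormal columns) and `values`
#'   (length-k, descending).
#' @export
solve_eigen <- function(m, k, dense_limit = 3000) {
  n <- nrow(m)
  if (!is.matrix(m) || ncol(m) != n) stop("`m` must be square.", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("`m` must be symmetric.", call. = FALSE)
  }
  if (length(k) != 1L || k < 1 || k != round(k)) stop("`k` must be a positive integer.", call. = FALSE)
  if (k >= n) stop("`k` must be at most n - 1.", call. = FALSE)
  k <- as.integer(k)

  if (n <= dense_limit) {
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    values <- e$values
    vectors <- e$vectors
  } else {
    sub <- subspace_eigen(m, k)
    values <- sub$values
    vectors <- sub$vectors
  }

  scale_m <- max(abs(values), 1e-300)
  if (length(values) > k && abs(values[k] - values[k + 1]) <= 1e-10 * scale_m) {
    warning("The k-th and (k+1)-th eigenvalues are numerically tied; the embedding is unique only up to rotation within the tied subspace.",
            call. = FALSE)
  }

  W <- vectors[, seq_len(k), drop = FALSE]
  W <- fix_signs(W)
  list(vectors = W, values = values[seq_len(k)])
}

# Deterministic sign convention: largest-magnitude entry of each column made
# positive; first such entry wins on exact ties.
fix_signs <- function(W) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  W
}

# Blocked subspace (orthogonal) iteration with Rayleigh-Ritz extraction for
# the leading eigenpairs of a symmetric matrix. Used above the dense cutoff;
# deterministic (fixed internal seed for the start block).
subspace_eigen <- function(m, k, tol = 1e-10, max_iter = 1000L) {
  n <- nrow(m)
  b <- min(n, k + max(10L, k))          # oversampled block for reliable convergence
  Q <- withr::with_seed(1L, matrix(stats::rnorm(n * b), n, b))
  Q <- qr.Q(qr(Q))
  # shift so the target (algebraically largest) eigenvalues are largest in
  # magnitude even if m is indefinite; Gershgorin bound on the spectral radius
  shift <- max(rowSums(abs(m)))
  for (it in seq_len(max_iter)) {
    Z <- m %*% Q + shift * Q
    Q <- qr.Q(qr(Z))
    MQ <- m %*% Q
    B <- crossprod(Q, MQ)
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    V <- Q %*% e$vectors[, seq_len(k), drop = FALSE]
    # eigenpair residual on the k target vectors decides convergence
    R <- m %*% V - V %*% diag(e$values[seq_len(k)], k)
    if (max(abs(R)) <= tol * max(1, max(abs(e$values)))) {
      return(list(values = e$values, vectors = Q %*% e$vectors))
    }
  }
  warning("Subspace iteration reached max_iter without full convergence.", call. = FALSE)
  list(values = e$values, vectors = Q %*% e$vectors)
}

#' Fit semisupervised PCA
#'
#' Fits ssPCA to a cell-cell kernel (similarity) matrix and cluster labels.
#' The projection coefficients `W` are the eigenvectors of
#' `(1 - lambda) K_X H K_X + lambda K_X H K_Y H K_X` for the k largest
#' eigenvalues, and the embedding is `Z = K_X W`. `lambda = 0` recovers
#' unsupervised kernel PCA; `lambda = 1` is fully supervised (cluster
#' dependence only). The default `lambda = 0.75` follows common practice for
#' cluster visualization; values in 0.25–0.75 behave similarly on well-behaved
#' data.
#'
#' `x` may be a precomputed kernel (`kernel = "precomputed"`, e.g. a
#' similarity matrix from clustering software, ingested via [as_kernel()]) or
#' an expression matrix from which a kernel is built (`"linear"`, `"poly"`,
#' `"rbf"`).
#'
#' @param x Square kernel matrix, or a cells-by-genes expression matrix /
#'   data frame when `kernel` is not `"precomputed"`.
#' @param labels Cluster labels: vector/factor of length n, or a two-column
#'   data frame `(cell_id, cluster)` joined to the matrix's row names.
#' @param lambda Trade-off in `[0, 1]`; default 0.75.
#' @param k Embedding dimension (2 or 3 for visualization; any
#'   `1 <= k <= n - 1` accepted). Default 2.
#' @param kernel One of `"precomputed"`, `"linear"`, `"poly"`, `"rbf"`.
#' @param sigma RBF bandwidth (positive number or `"median"`).
#' @param poly_c,poly_d Polynomial kernel parameters.
#' @param eig_tol Threshold below which retained eigenvalues are reported as
#'   degenerate (default 1e-10).
#' @return An object of class `"sspca"` with elements `W` (n x k projection
#'   coefficients, orthonormal columns), `eigenvalues`, `embedding` (n x k
#'   matrix `Z = K_X W`), `lambda`, `k`, `cell_ids`, `labels`, `class_order`.
#'   Use [augment.sspca()] for a tidy embedding, [tidy.sspca()] /
#'   [glance.sspca()] for summaries, and `autoplot()` to plot.
#' @examples
#' sim <- simulate_tree(n_branches = 3, n_dim = 5, n_per_branch = 10, seed = 1)
#' fit <- sspca(rbf_kernel(sim$X), sim$branch, lambda = 0.75, k = 2)
#' glance(fit)
#' @export
sspca <- function(x, labels, lambda = 0.75, k = 2,
                  kernel = c("precomputed", "linear", "poly", "rbf"),
                  sigma = "median", poly_c = 1, poly_d = 2,
                  eig_tol = 1e-10) {
  kernel <- match.arg(kernel)
  kx <- switch(kernel,
    precomputed = as_kernel(as_matrix_input(x)),
    linear = linear_kernel(x),
    poly = polynomial_kernel(x, c = poly_c, d = poly_d),
    rbf = rbf_kernel(x, sigma = sigma)
  )
  n <- nrow(kx)
  lab <- align_labels(labels, rownames(kx), n)
  classes <- attr(lab, "classes")
  if (n != length(lab)) {
    stop(sprintf("Kernel has %d cells but %d labels were given.", n, length(lab)),
         call. = FALSE)
  }
  if (n < k + 1) stop("Need at least k + 1 cells.", call. = FALSE)
  if (length(classes) == 1L && lambda == 1) {
    stop("Degenerate objective: lambda = 1 with a single cluster makes the objective matrix zero (every projection is 'optimal'). Use lambda < 1.",
         call. = FALSE)
  }

  ky <- label_kernel(encode_one_hot(lab))
  M <- build_objective_matrix(kx, ky, lambda)
  sol <- solve_eigen(M, k)

  n_degen <- sum(sol$values < eig_tol)
  if (n_degen > 0) {
    warning(sprintf("%d of %d retained eigenvalues are below eig_tol = %g (degenerate directions).",
                    n_degen, k, eig_tol), call. = FALSE)
  }

  cell_ids <- rownames(kx) %||% paste0("cell", seq_len(n))
  Z <- kx %*% sol$vectors
  dimnames(Z) <- list(cell_ids, paste0("dim", seq_len(k)))
  rownames(sol$vectors) <- cell_ids

  structure(list(
    W = sol$vectors,
    eigenvalues = sol$values,
    embedding = Z,
    lambda = lambda,
    k = k,
    n = n,
    cell_ids = cell_ids,
    labels = as.character(lab),
    class_order = classes,
    kernel = kernel,
    sigma = attr(kx, "sigma"),
    eig_tol = eig_tol,
    n_degenerate = n_degen
  ), class = "sspca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_matrix_input <- function(x) {
  if (is.data.frame(x)) as_expression_matrix(x) else x
}

# Align a label input to the kernel's cell ids (id join for data frames /
# named vectors; positional otherwise).
align_labels <- function(labels, cell_ids, n) {
  lab <- as_cluster_labels(labels)
  ids <- names(lab)
  if (!is.null(ids) && !is.null(cell_ids) && !anyNA(ids) && all(nzchar(ids))) {
    if (anyDuplicated(ids)) {
      stop(sprintf("Duplicate cell ids in labels: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
    }
    missing_ids <- setdiff(cell_ids, ids)
    unknown <- setdiff(ids, cell_ids)
    if (length(missing_ids) || length(unknown)) {
      msg <- c(
        if (length(missing_ids)) sprintf("cells without labels: %s", paste(utils::head(missing_ids, 5), collapse = ", ")),
        if (length(unknown)) sprintf("label ids not in the matrix: %s", paste(utils::head(unknown, 5), collapse = ", "))
      )
      stop(paste("Label/matrix id mismatch —", paste(msg, collapse = "; ")), call. = FALSE)
    }
    lab <- lab[match(cell_ids, ids)]
    # class order must follow appearance in matrix order for reproducibility
    attr(lab, "classes") <- unique(as.character(lab))
  }
  lab
}

#' Project a kernel through a fitted ssPCA model
#'
#' Computes the embedding `Z = K_X W` from a fitted model and the training
#' kernel. This is the in-sample projection: ssPCA defines `Z` only for the
#' kernel used in fitting (external similarity matrices carry no kernel
#' function, so out-of-sample extension is not offered).
#'
#' @param object Fitted `"sspca"` model.
#' @param kx The kernel matrix used in fitting.
#' @param ... Unused.
#' @return An `n x k` embedding matrix.
#' @export
predict.sspca <- function(object, kx, ...) {
  if (missing(kx)) return(object$embedding)
  if (!is.matrix(kx) || ncol(kx) != nrow(object$W)) {
    stop("`kx` must be the n x n kernel used in fitting.", call. = FALSE)
  }
  Z <- kx %*% object$W
  colnames(Z) <- paste0("dim", seq_len(ncol(Z)))
  Z
}

#' ssPCA objective value of a fitted model
#'
#' Evaluates `(1 - lambda) tr(W' K_X H K_X W) + lambda tr(W' K_X H K_Y H K_X W)`
#' at the fitted `W`. For an exact solution this equals the sum of the model's
#' k eigenvalues.
#'
#' @param model Fitted `"sspca"` object.
#' @param kx Data kernel used in fitting.
#' @param ky Label kernel; defaults to the one rebuilt from the model's labels.
#' @param w Projection matrix to evaluate (defaults to the fitted `W`); any
#'   `n x k` matrix may be scored, e.g. for optimality checks.
#' @return Scalar objective value.
#' @export
objective_value <- function(model, kx, ky = NULL, w = model$W) {
  if (is.null(ky)) ky <- label_kernel(encode_one_hot(model$labels))
  comp <- objective_components(kx, ky, w)
  (1 - model$lambda) * comp$variance + model$lambda * comp$hsic
}

# The two trace terms of the objective for a given projection.
objective_components <- function(kx, ky, w) {
  C <- center_cols(kx)        # H Kx
  KW <- kx %*% w
  CW <- C %*% w               # H Kx W
  list(
    variance = sum(CW * KW),                  # tr(W' Kx H Kx W)
    hsic = sum(CW * (ky %*% CW))              # tr(W' Kx H Ky H Kx W)
  )
}

#' @export
print.sspca <- function(x, ...) {
  cat(sprintf("Semisupervised PCA fit (n = %d cells, %d clusters)\n",
              x$n, length(x$class_order)))
  cat(sprintf("  lambda = %g, k = %d, kernel = %s%s\n", x$lambda, x$k, x$kernel,
              if (!is.null(x$sigma)) sprintf(" (sigma = %.4g)", x$sigma) else ""))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 5), collapse = ", "), "\n")
  invisible(x)
}
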