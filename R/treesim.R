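#' Simulate high-dimensional branching-tree data
#'
#' Generates piecewise-linear branching-tree data in high dimension with
#' ground-truth branch labels, the standard benchmark for whether an
#' embedding preserves both local (within-branch) and global (between-branch)
#' structure. Branch 0 starts at the origin along a random unit direction;
#' every later branch attaches at the endpoint of a parent drawn uniformly
#' among the earlier branches and extends `branch_length` along a fresh
#' random unit direction. Each branch contributes `n_per_branch` points at
#' positions uniform on its segment, and i.i.d. Gaussian noise `N(0, sigma^2)`
#' is added to every coordinate.
#'
#' Defaults give the 10-branch, 60-dimensional, 1440-sample tree; the
#' `branch_length = 50` scale makes `sigma = 3` a low-noise and `sigma = 12`
#' a high-noise regime relative to branch extent.
#'
#' @param n_branches Number of branches (default 10).
#' @param n_dim Ambient dimension (default 60).
#' @param n_per_branch Points per branch (default 144, so 1440 total).
#' @param sigma Noise standard deviation per coordinate (default 0).
#' @param branch_length Length of every branch segment (default 50).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return An object of class `"tree_sim"`: list with `X` (noisy data matrix,
#'   rows named cell1..cellN), `X0` (noiseless matrix), `branch` (integer
#'   branch label per row, 1-based), `topology` (tibble with `branch`,
#'   `parent`; parent `NA` for the root), `start`/`end` (n_branches x n_dim
#'   endpoint matrices), and the generating parameters.
#' @examples
#' sim <- simulate_tree(n_branches = 3, n_dim = 4, n_per_branch = 5, seed = 1)
#' dim(sim$X)
#' @export
simulate_tree <- function(n_branches = 10, n_dim = 60, n_per_branch = 144,
                          sigma = 0, branch_length = 50, seed = NULL) {
  stopifnot(n_branches >= 1, n_dim >= 1, n_per_branch >= 2,
            sigma >= 0, branch_length > 0)
  gen <- function() {
    start <- matrix(0, n_branches, n_dim)
    end <- matrix(0, n_branches, n_dim)
    parent <- rep(NA_integer_, n_branches)
    for (b in seq_len(n_branches)) {
      if (b > 1L) {
        parent[b] <- sample.int(b - 1L, 1L)
        start[b, ] <- end[parent[b], ]
      }
      u <- stats::rnorm(n_dim)
      u <- u / sqrt(sum(u^2))
      end[b, ] <- start[b, ] + branch_length * u
    }
    n <- n_branches * n_per_branch
    t_pos <- stats::runif(n)
    branch <- rep(seq_len(n_branches), each = n_per_branch)
    X0 <- start[branch, , drop = FALSE] +
      t_pos * (end[branch, , drop = FALSE] - start[branch, , drop = FALSE])
    X <- X0
    if (sigma > 0) X <- X0 + matrix(stats::rnorm(n * n_dim, sd = sigma), n, n_dim)
    rownames(X) <- rownames(X0) <- paste0("cell", seq_len(n))
    list(X = X, X0 = X0, branch = branch, parent = parent,
         start = start, end = end)
  }
  res <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  structure(list(
    X = res$X, X0 = res$X0, branch = res$branch,
    topology = tibble::tibble(branch = seq_len(n_branches), parent = res$parent),
    start = res$start, end = res$end,
    n_branches = n_branches, n_dim = n_dim, n_per_branch = n_per_branch,
    sigma = sigma, branch_length = branch_length, seed = seed
  ), class = "tree_sim")
}

#' @export
print.tree_sim <- function(x, ...) {
  cat(sprintf("Simulated branching tree: %d branches x %d points = %d cells in %d dimensions (sigma = %g)\n",
              x$n_branches, x$n_per_branch, nrow(x$X), x$n_dim, x$sigma))
  invisible(x)
}

.fixture_cache <- new.env(parent = emptyenv())

#' Canonical tree fixtures
#'
#' Two fixed, seeded tree configurations used throughout the tests and
#' examples: `"default"` — 10 branches, 60 dimensions, 144 points per branch
#' (1440 cells); `"highdim"` — 8 branches, 5000 dimensions, 150 points per
#' branch (1200 cells). Both use seed 20200812 and are memoised per session.
#'
#' @param name `"default"` or `"highdim"`.
#' @param sigma Noise level added on top of the fixture geometry (default 0).
#' @return A `"tree_sim"` object.
#' @export
tree_fixture <- function(name = c("default", "highdim"), sigma = 0) {
  name <- match.arg(name)
  key <- paste(name, sigma, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- switch(name,
    default = simulate_tree(n_branches = 10, n_dim = 60, n_per_branch = 144,
                            sigma = sigma, seed = 20200812),
    highdim = simulate_tree(n_branches = 8, n_dim = 5000, n_per_branch = 150,
                            sigma = sigma, seed = 20200812)
  )
  .fixture_cache[[key]] <- fx
  fx
}

#' Distance from tree points to their generating segments
#'
#' For each row of `X`, the Euclidean distance to the segment of its labelled
#' branch. Zero (to numerical precision) for noiseless data; used to verify
#' the simulator's geometry.
#'
#' @param sim A `"tree_sim"` object.
#' @param X Matrix of points to test (default the simulation's noiseless `X0`).
#' @return Numeric vector of distances, one per row.
#' @export
point_segment_distances <- function(sim, X = sim$X0) {
  vapply(seq_len(nrow(X)), function(i) {
    b <- sim$branch[i]
    a <- sim$start[b, ]
    d <- sim$end[b, ] - a
    t_hat <- sum((X[i, ] - a) * d) / sum(d^2)
    t_hat <- min(max(t_hat, 0), 1)
    sqrt(sum((X[i, ] - (a + t_hat * d))^2))
  }, numeric(1))
}
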