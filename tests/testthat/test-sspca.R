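test_that("objective matrix matches the naive explicit-H product", {
  set.seed(101)
  kx <- random_psd(6)
  ky <- label_kernel(as.character(random_labels(6, 2)))
  for (lam in c(0, 0.5, 0.75, 1)) {
    M <- build_objective_matrix(kx, ky, lam)
    expect_lt(max(abs(M - oracle_objective_matrix(kx, ky, lam))),
              1e-9 * max(1, max(abs(M))))
  }
  # implicit-centering path agrees with the explicit one bit-tightly
  M_imp <- build_objective_matrix(kx, ky, 0.5, explicit_h = FALSE)
  M_exp <- build_objective_matrix(kx, ky, 0.5, explicit_h = TRUE)
  expect_lt(max(abs(M_imp - M_exp)), 1e-12 * max(1, max(abs(M_exp))))
})

test_that("objective matrix limits: kernel PCA at lambda = 0, zero at lambda = 1 with one cluster", {
  set.seed(102)
  kx <- random_psd(5)
  H <- explicit_H(5)
  ky1 <- matrix(1, 5, 5)  # single cluster: K_Y = 11'
  expect_lt(max(abs(build_objective_matrix(kx, ky1, 0) - kx %*% H %*% kx)), 1e-10)
  expect_lt(max(abs(build_objective_matrix(kx, ky1, 1))), 1e-10)
  expect_error(build_objective_matrix(kx, ky1, 1.2), "lambda")
  expect_error(build_objective_matrix(kx, matrix(1, 4, 4), 0.5), "dimension")
})

test_that("objective matrix is invariant to constant shifts of the label kernel", {
  set.seed(103)
  kx <- random_psd(7)
  ky <- label_kernel(as.character(random_labels(7, 3)))
  M1 <- build_objective_matrix(kx, ky, 0.6)
  M2 <- build_objective_matrix(kx, ky + 4.2, 0.6)
  expect_lt(max(abs(M1 - M2)), 1e-10 * max(1, max(abs(M1))))
})

test_that("solve_eigen returns descending orthonormal eigenpairs with fixed signs", {
  sol <- solve_eigen(diag(c(3, 2, 1)), 2)
  expect_equal(sol$values, c(3, 2))
  expect_equal(abs(sol$vectors), cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_true(all(apply(sol$vectors, 2, function(v) v[which.max(abs(v))]) > 0))

  set.seed(111)
  M <- matrix(rnorm(64), 8); M <- M + t(M)
  sol <- solve_eigen(M, 3)
  expect_lt(max(abs(crossprod(sol$vectors) - diag(3))), 1e-10)
  expect_true(all(diff(sol$values) <= 1e-12))
  res <- M %*% sol$vectors - sol$vectors %*% diag(sol$values)
  expect_lt(max(abs(res)), 1e-8 * max(abs(M)))
  expect_error(solve_eigen(M, 8), "at most")
  expect_error(solve_eigen(matrix(rnorm(64), 8), 2), "symmetric")
})

test_that("eigendecomposition beats random orthonormal candidates for the trace objective", {
  set.seed(112)
  for (rep in 1:5) {
    n <- 8
    M <- matrix(rnorm(n * n), n); M <- M + t(M)
    k <- sample(2:3, 1)
    sol <- solve_eigen(M, k)
    best <- sum(sol$values)
    cand <- replicate(500, {
      W <- random_orthonormal(n, k)
      sum(diag(crossprod(W, M %*% W)))
    })
    expect_true(all(best >= cand - 1e-6))
  }
})

test_that("iterative top-k path agrees with the dense path at n = 500", {
  set.seed(113)
  sim <- simulate_tree(n_branches = 5, n_dim = 20, n_per_branch = 100,
                       sigma = 2, seed = 9)
  K <- rbf_kernel(sim$X)
  ky <- label_kernel(as.character(sim$branch))
  M <- build_objective_matrix(K, ky, 0.75)
  dense <- solve_eigen(M, 2, dense_limit = 3000)
  iter <- solve_eigen(M, 2, dense_limit = 100)  # force the iterative path
  expect_lt(max(abs(dense$values - iter$values)),
            1e-6 * max(abs(dense$values)))
  expect_lt(principal_angle(dense$vectors, iter$vectors), 1e-6)
})

test_that("fitted projections are orthonormal and certified optimal across random instances", {
  set.seed(121)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    c <- sample(2:3, 1)
    k <- sample(1:3, 1)
    lam <- runif(1)
    kx <- random_psd(n)
    y <- as.character(random_labels(n, c))
    fit <- suppressWarnings(sspca(kx, y, lambda = lam, k = k))
    expect_lt(max(abs(crossprod(fit$W) - diag(k))), 1e-8)
    # objective value = sum of top-k eigenvalues, via an independent dense eigensolve
    obj <- objective_value(fit, kx)
    ev <- eigen(oracle_objective_matrix(kx, label_kernel(y), lam),
                symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(obj - sum(ev[seq_len(k)])), 1e-8 * max(1, abs(obj)))
    # beats random orthonormal candidates
    cand <- replicate(100, {
      W <- random_orthonormal(n, k)
      objective_value(fit, kx, w = W)
    })
    expect_true(all(obj >= cand - 1e-6 * max(1, abs(obj))))
  }
})

test_that("lambda = 0 on a pre-centered kernel reproduces the kernel-PCA eigenspace", {
  set.seed(131)
  for (rep in 1:5) {
    n <- 20
    K0 <- random_psd(n)
    H <- explicit_H(n)
    Kc <- H %*% K0 %*% H          # pre-centered: Kc 1 = 0, so M = Kc^2
    Kc <- (Kc + t(Kc)) / 2
    ev <- eigen(Kc, symmetric = TRUE)
    k <- 2
    if (ev$values[k] - ev$values[k + 1] < 1e-6) next
    fit <- suppressWarnings(sspca(Kc, rep(c("a", "b"), n / 2), lambda = 0, k = k))
    expect_lt(principal_angle(fit$W, ev$vectors[, 1:k]), 1e-6)
  }
})

test_that("the HSIC term is non-decreasing and the variance term non-increasing in lambda", {
  set.seed(141)
  for (rep in 1:20) {
    n <- 10
    kx <- random_psd(n)
    y <- as.character(random_labels(n, 3))
    ky <- label_kernel(y)
    grid <- c(0, 0.25, 0.5, 0.75, 1)
    comps <- sapply(grid, function(lam) {
      fit <- suppressWarnings(sspca(kx, y, lambda = lam, k = 2))
      comp <- sspca:::objective_components(kx, ky, fit$W)
      c(comp$hsic, comp$variance)
    })
    expect_true(all(diff(comps[1, ]) >= -1e-7 * max(1, max(abs(comps[1, ])))))
    expect_true(all(diff(comps[2, ]) <= 1e-7 * max(1, max(abs(comps[2, ])))))
  }
})

test_that("degenerate cases error or warn as documented", {
  set.seed(151)
  kx <- random_psd(6)
  expect_error(sspca(kx, rep("only", 6), lambda = 1), "Degenerate objective")
  # lambda < 1 with one cluster is allowed (pure kernel PCA content remains)
  expect_no_error(suppressWarnings(sspca(kx, rep("only", 6), lambda = 0.5)))
  # near-zero eigenvalues warn
  w <- testthat::capture_warnings(sspca(matrix(0, 6, 6) + diag(1e-14, 6),
                                        rep(c("a", "b"), 3), lambda = 0.5, k = 2))
  expect_true(any(grepl("degenerate directions", w)))
  expect_error(sspca(kx, c("a", "b"), lambda = 0.5), "labels")
})

test_that("embeddings are equivariant to cell permutation and invariant to relabeling", {
  set.seed(161)
  n <- 15
  kx <- random_psd(n)
  rownames(kx) <- colnames(kx) <- paste0("c", seq_len(n))
  y <- as.character(random_labels(n, 3))
  fit <- sspca(kx, y, lambda = 0.6, k = 2)
  # relabeling invariance: bit-identical embedding
  map <- setNames(c("Q", "R", "S"), unique(y))
  fit2 <- sspca(kx, unname(map[y]), lambda = 0.6, k = 2)
  expect_identical(fit$embedding[, ], fit2$embedding[, ])
  # permutation equivariance up to column sign
  p <- sample.int(n)
  kxp <- kx[p, p]
  fitp <- sspca(kxp, y[p], lambda = 0.6, k = 2)
  for (j in 1:2) {
    d1 <- max(abs(fitp$embedding[, j] - fit$embedding[p, j]))
    d2 <- max(abs(fitp$embedding[, j] + fit$embedding[p, j]))
    expect_lt(min(d1, d2), 1e-6 * max(1, max(abs(fit$embedding))))
  }
})

test_that("predict reproduces the stored embedding and zero W maps to zero", {
  set.seed(171)
  kx <- random_psd(10)
  y <- as.character(random_labels(10, 2))
  fit <- sspca(kx, y, k = 2)
  expect_lt(max(abs(predict(fit, kx) - fit$embedding)), 1e-12)
  fit0 <- fit
  fit0$W[] <- 0
  expect_equal(unname(predict(fit0, kx)), matrix(0, 10, 2))
})

test_that("tidiers and autoplot return well-formed objects", {
  set.seed(181)
  sim <- simulate_tree(n_branches = 3, n_dim = 6, n_per_branch = 8, sigma = 1, seed = 3)
  fit <- sspca(rbf_kernel(sim$X), sim$branch, k = 2)
  td <- tidy(fit)
  expect_identical(names(td), c("component", "eigenvalue", "degenerate"))
  expect_identical(nrow(td), 2L)
  gl <- glance(fit)
  expect_identical(gl$n, 24L)
  expect_identical(gl$n_clusters, 3L)
  expect_equal(gl$objective, sum(fit$eigenvalues))
  au <- augment(fit)
  expect_identical(names(au), c("cell_id", "dim1", "dim2", "cluster"))
  expect_identical(nrow(au), 24L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
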