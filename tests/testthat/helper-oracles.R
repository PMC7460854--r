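# Independent brute-force oracles, deliberately naive: explicit loops and
# explicit dense centering matrices, never the package's own fast paths.

naive_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(b))) {
      s <- 0
      for (l in seq_len(ncol(a))) s <- s + a[i, l] * b[l, j]
      out[i, j] <- s
    }
  }
  out
}

explicit_H <- function(n) diag(n) - matrix(1 / n, n, n)

oracle_linear_kernel <- function(x) {
  n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- sum(x[i, ] * x[j, ])
  }
  K
}

oracle_poly_kernel <- function(x, c, d) {
  n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- (c * sum(x[i, ] * x[j, ]) + 1)^d
  }
  K
}

oracle_rbf_kernel <- function(x, sigma) {
  n <- nrow(x)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    K[i, j] <- exp(-sum((x[i, ] - x[j, ])^2) / sigma^2)
  }
  K
}

# HSIC by naive four-matrix product with an explicit H.
oracle_hsic <- function(kx, ky) {
  n <- nrow(kx)
  H <- explicit_H(n)
  prod4 <- naive_matmul(naive_matmul(naive_matmul(kx, H), ky), H)
  sum(diag(prod4)) / (n - 1)^2
}

oracle_objective_matrix <- function(kx, ky, lambda) {
  H <- explicit_H(nrow(kx))
  (1 - lambda) * (kx %*% H %*% kx) + lambda * (kx %*% H %*% ky %*% H %*% kx)
}

random_psd <- function(n, rank = n) {
  a <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(a)
}

random_orthonormal <- function(n, k) qr.Q(qr(matrix(rnorm(n * k), n, k)))

random_labels <- function(n, c) {
  # guarantee every class appears
  sample(c(seq_len(c), sample.int(c, n - c, replace = TRUE)))
}

# largest principal angle (radians) between the column spaces of two
# orthonormal bases
principal_angle <- function(a, b) {
  s <- svd(crossprod(a, b))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s))
}
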