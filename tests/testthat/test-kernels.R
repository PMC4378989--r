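test_that("linear kernel equals the brute-force inner-product oracle", {
  K <- linearKernel(diag(3), standardize = FALSE, normalize = FALSE)
  expect_equal(unname(kernelMatrix(K)), diag(3))
  K1 <- linearKernel(matrix(1, 4, 1), standardize = FALSE,
                     normalize = FALSE)
  expect_equal(unname(kernelMatrix(K1)), matrix(1, 4, 4))
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  K2 <- kernelMatrix(linearKernel(X, standardize = FALSE,
                                  normalize = FALSE))
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) oracle[i, j] <- sum(X[i, ] * X[j, ])
  expect_equal(unname(K2), oracle)
})

test_that("topology kernel is X T X' and reduces to linear for T = I", {
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(
    kernelMatrix(topologyKernel(X, diag(3), standardize = FALSE,
                                normalize = FALSE)),
    kernelMatrix(linearKernel(X, standardize = FALSE, normalize = FALSE)),
    tolerance = 1e-12)
  ## single node: outer product of the only column
  x1 <- matrix(rnorm(5), 5, 1)
  expect_equal(unname(kernelMatrix(topologyKernel(x1, matrix(1, 1, 1),
                                                  standardize = FALSE,
                                                  normalize = FALSE))),
               x1 %*% t(x1), tolerance = 1e-12)
  ## path-graph TOM against the dense matrix-product oracle (on the
  ## PSD-clipped T, which is what the kernel is defined on)
  Tp <- tomMatrix(topologicalOverlap(pathNet()))
  ev <- eigen(Tp, symmetric = TRUE)
  Tplus <- ev$vectors %*% (pmax(ev$values, 0) * t(ev$vectors))
  K <- kernelMatrix(suppressWarnings(
    topologyKernel(X, Tp, standardize = FALSE, normalize = FALSE)))
  expect_equal(unname(K), unname(X %*% Tplus %*% t(X)), tolerance = 1e-10)
  expect_error(topologyKernel(matrix(rnorm(10), 5, 2), Tp,
                              standardize = FALSE), "match")
})

test_that("all-ones TOM collapses the topology kernel to row sums", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4)
  K <- kernelMatrix(topologyKernel(X, matrix(1, 4, 4), standardize = FALSE,
                                   normalize = FALSE))
  rs <- rowSums(X)
  expect_equal(unname(K), rs %*% t(rs), tolerance = 1e-10)
  expect_equal(qr(K)$rank, 1L)
})

test_that("connectivity kernel is the linear kernel on sqrt(w)-scaled columns", {
  set.seed(4)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(
    kernelMatrix(connectivityKernel(X, diag(4), standardize = FALSE,
                                    normalize = FALSE)),
    kernelMatrix(linearKernel(X, standardize = FALSE, normalize = FALSE)),
    tolerance = 1e-12)
  expect_equal(unname(kernelMatrix(connectivityKernel(
    X, matrix(0, 4, 4), standardize = FALSE, normalize = FALSE))),
    matrix(0, 5, 5))
  w <- connectivityWeights(topologicalOverlap(starNet(3)))
  expect_equal(
    kernelMatrix(connectivityKernel(X, w, standardize = FALSE,
                                    normalize = FALSE)),
    kernelMatrix(linearKernel(sweep(X, 2, sqrt(nodeWeights(w)), "*"),
                              standardize = FALSE, normalize = FALSE)),
    tolerance = 1e-12)
  expect_error(connectivityKernel(X, diag(-1, 4), standardize = FALSE),
               "non-negative")
})

test_that("interaction kernel is the Hadamard product and stays PSD", {
  set.seed(5)
  n <- 4
  ones <- linearKernel(matrix(1, n, 1), standardize = FALSE,
                       normalize = FALSE)
  A <- linearKernel(matrix(rnorm(n * 3), n), standardize = FALSE,
                    normalize = FALSE)
  expect_equal(kernelMatrix(interactionKernel(A, ones, normalize = FALSE)),
               kernelMatrix(A), tolerance = 1e-12)
  ## a zero row in K1 zeroes the same interaction row
  X <- matrix(rnorm(n * 2), n); X[2, ] <- 0
  K1 <- linearKernel(X, standardize = FALSE, normalize = FALSE)
  K12 <- interactionKernel(K1, A, normalize = FALSE)
  expect_equal(unname(kernelMatrix(K12)[2, ]), rep(0, n))
  ## element-wise oracle + eigenvalue floor
  B <- linearKernel(matrix(rnorm(n * 3), n), standardize = FALSE,
                    normalize = FALSE)
  H <- interactionKernel(A, B, normalize = FALSE)
  expect_equal(kernelMatrix(H), kernelMatrix(A) * kernelMatrix(B),
               tolerance = 1e-12)
  expect_gt(min(eigen(kernelMatrix(H), symmetric = TRUE,
                      only.values = TRUE)$values), -1e-10)
  ## the Khatri-Rao factor reproduces the Hadamard product exactly
  expect_equal(tcrossprod(kernelFactor(H)), unname(kernelMatrix(H)),
               tolerance = 1e-10)
  expect_error(interactionKernel(A, linearKernel(matrix(rnorm(10), 5))),
               "dimension")
})

test_that("kernel factor, trace normalization and standardization behave", {
  set.seed(6)
  X <- moduleData(matrix(rnorm(50), 10, 5))
  tom <- topologicalOverlap(randomNet(5, 0.5))
  for (K in list(linearKernel(X), topologyKernel(X, tom),
                 connectivityKernel(X, connectivityWeights(tom)))) {
    expect_equal(sum(diag(kernelMatrix(K))), 10, tolerance = 1e-8)
    expect_equal(tcrossprod(kernelFactor(K)), unname(kernelMatrix(K)),
                 tolerance = 1e-8)
    ev <- eigen(kernelMatrix(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    expect_equal(kernelMatrix(K), t(kernelMatrix(K)))
  }
})

test_that("kernels commute with subject permutation", {
  set.seed(7)
  X <- matrix(rnorm(36), 9, 4)
  tom <- topologicalOverlap(randomNet(4, 0.5))
  perm <- sample(9)
  K <- kernelMatrix(suppressWarnings(topologyKernel(X, tom)))
  KP <- kernelMatrix(suppressWarnings(topologyKernel(X[perm, ], tom)))
  expect_equal(KP, K[perm, perm], tolerance = 1e-10)
})

test_that("optional polynomial and Gaussian kernels are valid kernels", {
  set.seed(8)
  X <- matrix(rnorm(24), 8, 3)
  for (K in list(polynomialKernel(X), gaussianKernel(X))) {
    M <- kernelMatrix(K)
    expect_equal(M, t(M))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(abs(ev)))
  }
  ## constant term removed: the polynomial kernel of zero data is zero
  K0 <- polynomialKernel(matrix(0, 4, 2), standardize = FALSE,
                         normalize = FALSE)
  expect_equal(unname(kernelMatrix(K0)), matrix(0, 4, 4))
})

test_that("standardization warns on constant columns and centers data", {
  X <- cbind(rnorm(10), rep(2, 10))
  expect_warning(S <- standardizeColumns(X), "constant")
  expect_equal(colMeans(S), c(0, 0), tolerance = 1e-12)
  expect_equal(sd(S[, 1]), 1, tolerance = 1e-12)
})
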