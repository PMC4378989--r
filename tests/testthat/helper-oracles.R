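## Independent oracles and small fixtures used across the test files.

## Brute-force TOM by explicit neighbour counting: for each pair (l, l')
## count shared neighbours u (u != l, l') with a loop, take the degree as
## the number of direct neighbours, and apply the ratio directly.
bruteTOM <- function(A) {
  L <- nrow(A)
  T <- diag(L)
  for (l in seq_len(L)) for (lp in seq_len(L)) {
    if (l == lp) next
    shared <- 0
    for (u in seq_len(L)) {
      if (u == l || u == lp) next
      if (A[l, u] == 1 && A[lp, u] == 1) shared <- shared + 1
    }
    kl <- sum(A[l, ]); klp <- sum(A[lp, ])
    T[l, lp] <- (shared + A[l, lp]) / (min(kl, klp) - A[l, lp] + 1)
  }
  T
}

## enumerate the adjacency matrices of all simple graphs on L nodes
allGraphs <- function(L) {
  pairs <- which(upper.tri(diag(L)), arr.ind = TRUE)
  nE <- nrow(pairs)
  lapply(0:(2^nE - 1), function(mask) {
    A <- matrix(0, L, L)
    on <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nE) - 1L)) != 0L)
    for (e in on) {
      A[pairs[e, 1], pairs[e, 2]] <- 1
      A[pairs[e, 2], pairs[e, 1]] <- 1
    }
    A
  })
}

adjFromEdges <- function(L, edges) {
  A <- matrix(0, L, L)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  A
}

triangleNet <- function() moduleNetwork(adjFromEdges(3, list(c(1, 2),
                                                             c(1, 3),
                                                             c(2, 3))))
pathNet <- function() moduleNetwork(adjFromEdges(3, list(c(1, 2),
                                                         c(2, 3))))
starNet <- function(leaves = 3)
  moduleNetwork(adjFromEdges(leaves + 1,
                             lapply(1 + seq_len(leaves),
                                    function(j) c(1, j))))
emptyNet <- function(L) moduleNetwork(matrix(0, L, L))

randomNet <- function(L, p = 0.3) {
  A <- matrix(0, L, L)
  A[upper.tri(A)] <- rbinom(L * (L - 1) / 2, 1, p)
  moduleNetwork(A + t(A))
}

## dense from-scratch projection: P = V^-1 - V^-1 Z (Z'V^-1Z)^-1 Z'V^-1
## assembled with base solve() only, from the fit's variance components
oracleProjection <- function(fit, Z, kernels) {
  taus <- varianceComponents(fit)
  n <- fit@n
  V <- diag(taus[["sigma"]], n)
  if (taus[["tau1"]] > 0) V <- V + taus[["tau1"]] * kernelMatrix(kernels$K1)
  if (taus[["tau2"]] > 0) V <- V + taus[["tau2"]] * kernelMatrix(kernels$K2)
  Vi <- solve(V)
  Vi - Vi %*% Z %*% solve(t(Z) %*% Vi %*% Z) %*% t(Z) %*% Vi
}

## a small two-module dataset on fixed scale-free networks
smallDataset <- function(n = 40, L = 8, seed = 123) {
  withr::with_seed(seed, {
    net1 <- generateScaleFreeModule(L)
    net2 <- generateScaleFreeModule(L)
    X1 <- simulateModuleData(net1, n, quiet = TRUE)
    X2 <- simulateModuleData(net2, n, quiet = TRUE)
    list(net1 = net1, net2 = net2, X1 = X1, X2 = X2,
         tom1 = topologicalOverlap(net1), tom2 = topologicalOverlap(net2),
         y = rnorm(n))
  })
}

## strip the low-rank factor so the dense fitting path is exercised
denseKernel <- function(K) {
  new("KernelMatrix", kernel = kernelMatrix(K), kind = kernelKind(K),
      factor = matrix(0, nrow(kernelMatrix(K)), 0), psdRepaired = FALSE)
}

expect_monotone_loglik <- function(fit, tol = 1e-7) {
  expect_true(all(diff(fit@logLik) >= -tol * (1 + abs(fit@logLik[-1]))))
}
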