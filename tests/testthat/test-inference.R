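makeModel <- function(ds, kind = "topology") {
  K1 <- switch(kind,
    topology = suppressWarnings(topologyKernel(ds$X1, ds$tom1)),
    linear = linearKernel(ds$X1))
  K2 <- switch(kind,
    topology = suppressWarnings(topologyKernel(ds$X2, ds$tom2)),
    linear = linearKernel(ds$X2))
  kmModel(ds$y, K1, K2)
}

test_that("low-rank and dense fitting paths agree to high precision", {
  ds <- smallDataset(n = 35, L = 6, seed = 11)
  m <- makeModel(ds)
  md <- kmModel(ds$y, denseKernel(m@K1), denseKernel(m@K2),
                K12 = denseKernel(m@K12))
  for (nullType in c("interaction", "module1", "module2")) {
    f1 <- suppressWarnings(fitNullREML(m, nullType))
    f2 <- suppressWarnings(fitNullREML(md, nullType))
    expect_equal(varianceComponents(f1), varianceComponents(f2),
                 tolerance = 1e-8)
    target <- switch(nullType, interaction = m@K12, module1 = m@K1,
                     module2 = m@K2)
    targetD <- switch(nullType, interaction = md@K12, module1 = md@K1,
                      module2 = md@K2)
    expect_equal(scoreStatistic(f1, target), scoreStatistic(f2, targetD),
                 tolerance = 1e-8)
    expect_equal(pValueWeightedChisq(f1, target)$pValue,
                 pValueWeightedChisq(f2, targetD)$pValue,
                 tolerance = 1e-8)
  }
})

test_that("projection annihilates covariates and satisfies PVP = P", {
  ds <- smallDataset(n = 30, L = 6, seed = 12)
  set.seed(13)
  covar <- cbind(rnorm(30), rbinom(30, 1, 0.5))
  K1 <- suppressWarnings(topologyKernel(ds$X1, ds$tom1))
  K2 <- suppressWarnings(topologyKernel(ds$X2, ds$tom2))
  m <- kmModel(ds$y, K1, K2, covariates = covar)
  for (nullType in c("interaction", "module1", "module2")) {
    fit <- suppressWarnings(fitNullREML(m, nullType))
    P <- projectionMatrix(fit)
    V <- nullCovariance(fit)
    expect_lt(max(abs(P %*% m@Z)), 1e-8)
    expect_lt(max(abs(P %*% V %*% P - P)), 1e-8 * max(abs(P)))
    expect_monotone_loglik(fit)
    expect_true(all(varianceComponents(fit)[1:3] >= 0))
    expect_gt(varianceComponents(fit)[["sigma"]], 0)
  }
})

test_that("score statistic matches the dense quadratic-form oracle", {
  for (n in c(6, 12, 20)) {
    ds <- smallDataset(n = n, L = 5, seed = 100 + n)
    m <- makeModel(ds)
    fit <- suppressWarnings(fitNullREML(m, "interaction"))
    P <- oracleProjection(fit, m@Z, list(K1 = m@K1, K2 = m@K2))
    oracle <- drop(t(ds$y) %*% P %*% kernelMatrix(m@K12) %*% P %*% ds$y) / 2
    expect_equal(scoreStatistic(fit, m@K12), oracle,
                 tolerance = 1e-10 * max(1, abs(oracle)))
    fitC <- suppressWarnings(fitNullREML(m, "module1"))
    PC <- oracleProjection(fitC, m@Z, list(K1 = m@K1, K2 = m@K2))
    oracleC <- drop(t(ds$y) %*% PC %*% kernelMatrix(m@K1) %*% PC %*%
                      ds$y) / 2
    expect_equal(scoreStatistic(fitC, m@K1), oracleC,
                 tolerance = 1e-10 * max(1, abs(oracleC)))
  }
})

test_that("the quadratic form vanishes on the covariate span", {
  ds <- smallDataset(n = 25, L = 5, seed = 14)
  m <- makeModel(ds)
  fit <- suppressWarnings(fitNullREML(m, "interaction"))
  P <- projectionMatrix(fit)
  K12 <- kernelMatrix(m@K12)
  quadForm <- function(v) drop(t(v) %*% P %*% K12 %*% P %*% v) / 2
  ## y = 0 and any y in span(Z) give a zero statistic
  expect_equal(quadForm(rep(0, 25)), 0)
  expect_lt(abs(quadForm(m@Z %*% 3.7)), 1e-16)
  ## shifting y along Z leaves the statistic unchanged
  expect_equal(quadForm(ds$y + drop(m@Z %*% 2.5)), quadForm(ds$y),
               tolerance = 1e-8)
})

test_that("an intercept shift leaves the whole REML test invariant", {
  ds <- smallDataset(n = 30, L = 6, seed = 15)
  m1 <- makeModel(ds)
  ds2 <- ds; ds2$y <- ds$y + 7
  m2 <- kmModel(ds2$y, m1@K1, m1@K2, K12 = m1@K12)
  r1 <- suppressWarnings(testInteraction(m1))
  r2 <- suppressWarnings(testInteraction(m2))
  expect_equal(testStatistic(r1), testStatistic(r2), tolerance = 1e-8)
  expect_equal(pValue(r1), pValue(r2), tolerance = 1e-8)
})

test_that("tests are deterministic given identical inputs", {
  ds <- smallDataset(n = 30, L = 6, seed = 16)
  m <- makeModel(ds)
  r1 <- suppressWarnings(testInteraction(m))
  r2 <- suppressWarnings(testInteraction(m))
  expect_identical(pValue(r1), pValue(r2))
  expect_identical(testStatistic(r1), testStatistic(r2))
})

test_that("swapping module roles mirrors the conditional test exactly", {
  ds <- smallDataset(n = 30, L = 6, seed = 17)
  m <- makeModel(ds)
  mSwap <- kmModel(ds$y, m@K2, m@K1, K12 = m@K12)
  r1 <- suppressWarnings(testConditional(m, 1))
  r2 <- suppressWarnings(testConditional(mSwap, 2))
  expect_equal(testStatistic(r1), testStatistic(r2), tolerance = 1e-10)
  expect_equal(pValue(r1), pValue(r2), tolerance = 1e-10)
})

test_that("moment matching is exact for a single-eigenvalue target", {
  ds <- smallDataset(n = 40, L = 6, seed = 18)
  m <- makeModel(ds)
  fit <- suppressWarnings(fitNullREML(m, "module1"))
  ## rank-1 target kernel c c'
  set.seed(19)
  cvec <- matrix(rnorm(40), 40, 1)
  K <- new("KernelMatrix", kernel = tcrossprod(cvec), kind = "linear",
           factor = cvec, psdRepaired = FALSE)
  res <- pValueWeightedChisq(fit, K)
  expect_equal(res$df, 1, tolerance = 1e-8)
  ## closed form: T = (c'Py)^2/2 ~ (c'Pc/2) chi^2_1
  P <- projectionMatrix(fit)
  s <- drop(t(cvec) %*% P %*% cvec)
  pExact <- pchisq(2 * res$statistic / s, df = 1, lower.tail = FALSE)
  expect_equal(res$pValue, pExact, tolerance = 1e-6)
})

test_that("degenerate targets and zero statistics give p = 1", {
  ds <- smallDataset(n = 20, L = 5, seed = 20)
  m <- makeModel(ds)
  fit <- suppressWarnings(fitNullREML(m, "module1"))
  expect_equal(pValueWeightedChisq(fit, m@K1, statistic = 0)$pValue, 1)
  K0 <- new("KernelMatrix", kernel = matrix(0, 20, 20), kind = "linear",
            factor = matrix(0, 20, 0), psdRepaired = FALSE)
  expect_warning(res <- pValueWeightedChisq(fit, K0), "degenerate")
  expect_equal(res$pValue, 1)
})

test_that("pure-noise conditional fits hit the zero boundary, never below", {
  set.seed(30)
  net <- generateScaleFreeModule(10)
  tom <- topologicalOverlap(net)
  atZero <- 0
  for (i in 1:15) {
    X1 <- simulateModuleData(net, 80, quiet = TRUE)
    X2 <- simulateModuleData(net, 80, quiet = TRUE)
    m <- kmModel(rnorm(80),
                 suppressWarnings(topologyKernel(X1, tom)),
                 suppressWarnings(topologyKernel(X2, tom)))
    fit <- suppressWarnings(fitNullREML(m, "module1"))
    vc <- varianceComponents(fit)
    expect_true(all(vc[1:3] >= 0))
    if (vc[["tau2"]] == 0) atZero <- atZero + 1
  }
  expect_gt(atZero, 7)  # majority at the boundary under pure noise
})

test_that("identity-kernel with intercept-only design reports a flat ridge", {
  set.seed(31)
  n <- 25
  I1 <- new("KernelMatrix", kernel = diag(n), kind = "linear",
            factor = matrix(0, n, 0), psdRepaired = FALSE)
  m <- kmModel(rnorm(n), I1, I1, K12 = I1)
  expect_warning(fit <- fitNullREML(m, "module1"), "ridge")
  ## the total variance is still identifiable even though the split is not
  vc <- varianceComponents(fit)
  expect_equal(vc[["tau2"]] + vc[["sigma"]], var(m@y), tolerance = 0.3)
})

test_that("REML/EM recovers known variance components", {
  ## single-kernel model: y = h + e, h ~ N(0, tau K2), tau = 2, sigma = 1
  set.seed(32)
  net <- generateScaleFreeModule(12)
  tom <- topologicalOverlap(net)
  n <- 200
  est <- t(replicate(8, {
    X2 <- simulateModuleData(net, n, quiet = TRUE)
    K2 <- suppressWarnings(topologyKernel(X2, tom))
    X1 <- simulateModuleData(net, n, quiet = TRUE)
    K1 <- suppressWarnings(topologyKernel(X1, tom))
    ev <- eigen(kernelMatrix(K2), symmetric = TRUE)
    h <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0) * 2) * rnorm(n)))
    y <- h + rnorm(n)
    fit <- suppressWarnings(fitNullREML(kmModel(y, K1, K2), "module1"))
    expect_monotone_loglik(fit)
    varianceComponents(fit)[c("tau2", "sigma")]
  }))
  expect_equal(mean(est[, "tau2"]), 2,
               tolerance = 3 * sd(est[, "tau2"]) / sqrt(8) / 2 + 0.25)
  expect_equal(mean(est[, "sigma"]), 1,
               tolerance = 3 * sd(est[, "sigma"]) / sqrt(8) + 0.25)
})

test_that("results serialize to a tidy row", {
  ds <- smallDataset(n = 25, L = 5, seed = 33)
  m <- makeModel(ds)
  row <- resultAsData(suppressWarnings(testConditional(m, 2)))
  expect_equal(row$test, "module2")
  expect_true(row$p.value > 0 && row$p.value <= 1)
  expect_true(all(c("tau1", "tau2", "tau12", "sigma", "converged",
                    "n.iter") %in% names(row)))
})
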