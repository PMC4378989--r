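test_that("scale-free module generation yields connected trees", {
  net <- generateScaleFreeModule(20, seed = 1)
  expect_equal(sum(adjacencyMatrix(net)) / 2, 19)
  expect_true(igraph::is_connected(asIgraph(net)))
  net2 <- generateScaleFreeModule(2, seed = 2)
  expect_equal(sum(adjacencyMatrix(net2)) / 2, 1)
  expect_error(generateScaleFreeModule(1), ">= 2")
  ## heavy-tailed degrees: hubs dominate the median node
  ratios <- vapply(1:200, function(s) {
    k <- nodeDegrees(generateScaleFreeModule(20, seed = s))
    max(k) / max(stats::median(k), 1)
  }, 0)
  expect_gte(mean(ratios), 3)
})

test_that("non-scale-free modules split a parent by degree", {
  mods <- generateNonScaleFreeModules(100, 20, seed = 3)
  expect_equal(length(nodeLabels(mods$module1)), 20)
  expect_equal(length(nodeLabels(mods$module2)), 20)
  kParent <- nodeDegrees(mods$parent)
  k1 <- kParent[nodeLabels(mods$module1)]
  k2 <- kParent[nodeLabels(mods$module2)]
  expect_gte(min(k1), max(k2))
  ## module 1 densely, module 2 loosely (but not un-) connected
  expect_gt(sum(adjacencyMatrix(mods$module1)),
            sum(adjacencyMatrix(mods$module2)))
  expect_gt(sum(adjacencyMatrix(mods$module2)), 0)
  ## induced subgraph property: every module edge exists in the parent
  for (mod in mods[c("module1", "module2")]) {
    A <- adjacencyMatrix(mod)
    Ap <- adjacencyMatrix(mods$parent)[nodeLabels(mod), nodeLabels(mod)]
    expect_true(all(A <= Ap))
    expect_equal(A, Ap)  # induced: all parent edges among the nodes kept
  }
  expect_error(generateNonScaleFreeModules(30, 20), "exceed")
})

test_that("module data reproduces the network-implied correlations", {
  ## empty network: independent unit-variance nodes
  X <- dataMatrix(simulateModuleData(emptyNet(4), 5000, seed = 4))
  C <- cor(X)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
  expect_true(all(abs(apply(X, 2, var) - 1) < 0.1))
  ## single edge: correlation 1/2 for the connected pair only
  net <- moduleNetwork(adjFromEdges(3, list(c(1, 2))))
  X2 <- dataMatrix(simulateModuleData(net, 5000, seed = 5))
  C2 <- cor(X2)
  expect_lt(abs(C2[1, 2] - 0.5), 0.05)
  expect_lt(abs(C2[1, 3]), 0.05)
  ## indefinite star correlation is repaired and reported
  expect_message(simulateModuleData(starNet(8), 10, seed = 6),
                 "not positive definite")
})

test_that("causal node selection honours mode, ties and determinism", {
  st <- starNet(5)
  expect_equal(selectCausalNodes(st, "hub", 1), 1L)  # the centre
  expect_equal(selectCausalNodes(st, "hub", 6), 1:6)
  expect_equal(selectCausalNodes(st, "random", 6, seed = 7), 1:6)
  s1 <- selectCausalNodes(st, "random", 3, seed = 8)
  s2 <- selectCausalNodes(st, "random", 3, seed = 8)
  expect_identical(s1, s2)
  expect_error(selectCausalNodes(st, "hub", 99), "exceed")
  ## hub ties broken by node index
  tri <- triangleNet()
  expect_equal(selectCausalNodes(tri, "hub", 2), c(1L, 2L))
})

test_that("response generation meets its design identities", {
  net <- generateScaleFreeModule(10, seed = 9)
  X1 <- simulateModuleData(net, 5000, seed = 10, quiet = TRUE)
  X2 <- simulateModuleData(net, 5000, seed = 11, quiet = TRUE)
  ## global null: y independent of every module column
  r0 <- simulateResponse(X1, X2, 1:4, 1:4, c(0, 0, 0), 0.02, seed = 12)
  expect_equal(r0$zeta, 1)
  expect_equal(r0$mu, rep(0, 5000))
  cors <- abs(c(cor(r0$y, dataMatrix(X1)), cor(r0$y, dataMatrix(X2))))
  expect_lt(max(cors), 0.05)
  ## effect sizes live on [-0.2,-0.05] U [0.05,0.2]
  r1 <- simulateResponse(X1, X2, 1:4, 2:5, c(1, 1, 1), 0.02, seed = 13)
  betas <- abs(c(r1$beta1, r1$beta2, r1$beta12))
  expect_true(all(betas >= 0.05 & betas <= 0.2))
  expect_equal(length(r1$beta12), 16)
  ## the noise variance hits the targeted R^2 exactly by construction
  v <- var(r1$mu)
  expect_equal(v / (v + r1$zeta), 0.02, tolerance = 1e-12)
  expect_error(simulateResponse(X1, X2, 1:2, 1:2, c(1, 0, 0), 1.5),
               "r2")
})

test_that("experiment runners are reproducible and well-formed", {
  d <- simulationDesign(nSubjects = 60, moduleSize = 8, nReplicates = 4,
                        seed = 14)
  out1 <- suppressWarnings(runType1Experiment(d, kernels = c("topology",
                                                             "linear")))
  out2 <- suppressWarnings(runType1Experiment(d, kernels = c("topology",
                                                             "linear")))
  expect_identical(attr(out1, "pValues"), attr(out2, "pValues"))
  expect_equal(nrow(out1), 6)  # 2 kernels x 3 tests
  expect_true(all(out1$rate >= 0 & out1$rate <= 1))
  expect_true(all(out1$nReplicates == 4))
  pv <- attr(out1, "pValues")
  expect_equal(dim(pv), c(4, 2, 3))
  expect_true(all(pv > 0 & pv <= 1))
  expect_error(runType1Experiment(simulationDesign(gamma = c(0, 0, 1))),
               "gamma")
})

test_that("power runner targets the test matching the signal", {
  d <- simulationDesign(nSubjects = 80, moduleSize = 8, nReplicates = 3,
                        gamma = c(0, 0, 1), causalMode = "hub",
                        nCausal = 2, seed = 15)
  out <- suppressWarnings(runPowerExperiment(d, kernels = "topology",
                                             r2Levels = c(mid = 0.1)))
  expect_equal(unique(out$test), "interaction")
  expect_equal(nrow(out), 1)
  expect_true(all(out$power >= 0 & out$power <= 1))
  d2 <- simulationDesign(nSubjects = 80, moduleSize = 8, nReplicates = 3,
                         gamma = c(1, 0, 0), seed = 16)
  out2 <- suppressWarnings(runPowerExperiment(d2, kernels = "linear",
                                              r2Levels = c(mid = 0.1)))
  expect_equal(unique(out2$test), "module1")
  expect_error(runPowerExperiment(simulationDesign(gamma = c(0, 0, 0))),
               "exactly one")
})

test_that("simulation designs validate their fields", {
  expect_error(simulationDesign(nCausal = 30, moduleSize = 20), "nCausal")
  expect_error(simulationDesign(gamma = c(0, 2, 0)), "gamma")
  expect_error(simulationDesign(r2 = c(low = 1.2)), "r2")
  expect_error(simulationDesign(alpha = 0), "alpha")
  d <- simulationDesign()
  expect_equal(d@nSubjects, 1000L)
  expect_equal(d@moduleSize, 20L)
  expect_equal(unname(d@r2), c(0.01, 0.02, 0.04))
})
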