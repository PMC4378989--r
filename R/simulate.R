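#' @include scoreTest.R
NULL

## evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' SimulationDesign: parameterization of a type-I error / power experiment
#'
#' Defaults mirror the study conditions of the simulation designs this
#' package replicates: 1000 subjects per replicate, 20-node modules,
#' effect sizes uniform on [-0.2, -0.05] U [0.05, 0.2], 1000 replicates
#' for type-I error (250 for power), alpha 0.05. The numeric values of the
#' low/median/high signal levels (R-squared of the mean against the
#' trait) are 0.01 / 0.02 / 0.04.
#'
#' @slot nSubjects subjects per replicate.
#' @slot moduleSize nodes per module.
#' @slot structure "scale_free" (each module an independent
#'   preferential-attachment graph) or "non_scale_free" (top/bottom-degree
#'   induced subgraphs of a 100-node scale-free parent).
#' @slot causalMode "hub" (highest-degree nodes) or "random".
#' @slot nCausal number of causal nodes per module (C).
#' @slot gamma length-3 0/1 vector (gamma1, gamma2, gamma12) switching on
#'   module 1, module 2 and interaction signal.
#' @slot r2 named numeric vector of R-squared levels in (0, 1).
#' @slot nReplicates,alpha,seed replication count, test level, RNG seed.
#' @export
setClass("SimulationDesign",
  slots = c(nSubjects = "integer", moduleSize = "integer",
            structure = "character", causalMode = "character",
            nCausal = "integer", gamma = "numeric", r2 = "numeric",
            nReplicates = "integer", alpha = "numeric", seed = "integer"),
  validity = function(object) {
    if (!(object@structure %in% c("scale_free", "non_scale_free")))
      return("structure must be scale_free or non_scale_free")
    if (!(object@causalMode %in% c("hub", "random")))
      return("causalMode must be hub or random")
    if (object@nCausal < 1 || object@nCausal > object@moduleSize)
      return("nCausal must lie in [1, moduleSize]")
    if (length(object@gamma) != 3 || !all(object@gamma %in% c(0, 1)))
      return("gamma must be three 0/1 values")
    if (any(object@r2 <= 0) || any(object@r2 >= 1))
      return("r2 levels must lie in (0, 1)")
    if (object@nReplicates < 1) return("nReplicates must be >= 1")
    if (object@alpha <= 0 || object@alpha >= 1)
      return("alpha must lie in (0, 1)")
    TRUE
  }
)

#' @rdname SimulationDesign-class
#' @param nSubjects,moduleSize,structure,causalMode,nCausal,gamma,r2
#'   see the class slots.
#' @param nReplicates,alpha,seed see the class slots.
#' @export
simulationDesign <- function(nSubjects = 1000, moduleSize = 20,
                             structure = c("scale_free", "non_scale_free"),
                             causalMode = c("hub", "random"), nCausal = 4,
                             gamma = c(0, 0, 0),
                             r2 = c(low = 0.01, median = 0.02, high = 0.04),
                             nReplicates = 1000, alpha = 0.05, seed = 1) {
  new("SimulationDesign", nSubjects = as.integer(nSubjects),
      moduleSize = as.integer(moduleSize),
      structure = match.arg(structure), causalMode = match.arg(causalMode),
      nCausal = as.integer(nCausal), gamma = as.numeric(gamma), r2 = r2,
      nReplicates = as.integer(nReplicates), alpha = alpha,
      seed = as.integer(seed))
}

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: %s, %d subjects x %d replicates, modules of %d\n",
    object@structure, object@nSubjects, object@nReplicates,
    object@moduleSize))
  cat(sprintf("  causal: %s C = %d; gamma = (%s); alpha = %g; seed = %d\n",
              object@causalMode, object@nCausal,
              paste(object@gamma, collapse = ","), object@alpha,
              object@seed))
})

#' Generate a scale-free module network
#'
#' Barabasi-Albert preferential attachment adding one edge per new node,
#' which yields a connected tree on L nodes whose degree distribution
#' follows a power law (a few hubs, many leaves).
#'
#' @param L number of nodes (>= 2).
#' @param seed optional seed (caller's RNG state is restored).
#' @return a \linkS4class{ModuleNetwork}.
#' @export
generateScaleFreeModule <- function(L, seed = NULL) {
  if (L < 2) stop("L must be >= 2")
  .withSeed(seed, {
    g <- igraph::sample_pa(L, power = 1, m = 1, directed = FALSE)
    moduleNetworkFromIgraph(g)
  })
}

#' Generate non-scale-free modules from a scale-free parent
#'
#' Draws a scale-free parent network, then takes the induced subgraph of
#' its \code{moduleSize} highest-degree nodes as module 1 and of its
#' \code{moduleSize} lowest-degree nodes as module 2 (degree ties broken
#' by node index). Module 1 is densely connected, module 2 loosely --
#' neither is scale-free.
#'
#' The parent is a static power-law (fitness) graph: edges are placed
#' with probability proportional to the product of power-law node
#' fitnesses (exponent \code{exponent}, \code{parentSize *
#' parentMeanDegree / 2} edges), which is scale-free in degree while
#' still allowing its low-degree nodes to be adjacent. A
#' preferential-attachment parent cannot serve here: in such a graph
#' every edge has an endpoint of degree above the attachment count, and
#' the lowest-degree class is larger than a module, so the bottom-degree
#' induced subgraph is always edgeless -- its connectivity weights would
#' be identically zero rather than "loosely connected". Because a single
#' fitness draw can still leave the bottom module edgeless, the parent is
#' redrawn (bounded retries) until module 2 has at least one edge.
#'
#' @param parentSize parent network size (must exceed 2 * moduleSize).
#' @param moduleSize nodes per module.
#' @param parentMeanDegree mean degree of the parent graph.
#' @param exponent power-law exponent of the parent degree distribution.
#' @param seed optional seed.
#' @return list with elements \code{module1}, \code{module2}
#'   (\linkS4class{ModuleNetwork}) and \code{parent}.
#' @export
generateNonScaleFreeModules <- function(parentSize = 100, moduleSize = 20,
                                        parentMeanDegree = 4,
                                        exponent = 2.5, seed = NULL) {
  if (parentSize <= 2 * moduleSize)
    stop("parentSize must exceed 2 * moduleSize")
  .withSeed(seed, {
    for (try in 1:100) {
      parent <- moduleNetworkFromIgraph(igraph::sample_fitness_pl(
        parentSize, round(parentSize * parentMeanDegree / 2), exponent))
      k <- nodeDegrees(parent)
      idx <- seq_along(k)
      top <- idx[order(-k, idx)][seq_len(moduleSize)]
      bottom <- idx[order(k, idx)][seq_len(moduleSize)]
      if (sum(parent@adjacency[bottom, bottom]) > 0) break
    }
    if (sum(parent@adjacency[bottom, bottom]) == 0)
      warning("bottom-degree module has no edges after 100 draws")
    sub <- function(sel) {
      A <- parent@adjacency[sel, sel, drop = FALSE]
      moduleNetwork(A, nodeLabels = parent@nodeLabels[sel])
    }
    list(module1 = sub(top), module2 = sub(bottom), parent = parent)
  })
}

## correlation matrix implied by the network: unit diagonal, 1/2 for
## directly connected pairs; eigenvalue-floored and rescaled to unit
## diagonal when indefinite (star-like subgraphs make the raw matrix so)
.networkCorrelation <- function(net, quiet = FALSE) {
  S <- diag(nrow(net@adjacency)) + net@adjacency / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-6) {
    if (!quiet)
      message("network correlation matrix is not positive definite ",
              "(min eigenvalue ", format(min(e$values), digits = 3),
              "); floored and rescaled to unit diagonal")
    lam <- pmax(e$values, 1e-6)
    S <- e$vectors %*% (lam * t(e$vectors))
    S <- stats::cov2cor(S)
  }
  S
}

#' Simulate module data from a network-implied Gaussian model
#'
#' Subjects are i.i.d. multivariate normal with unit variances and
#' pairwise correlation 1/2 between directly connected nodes (zero
#' otherwise). If the implied correlation matrix is indefinite its
#' eigenvalues are floored at 1e-6 and it is rescaled to unit diagonal
#' (reported via a message).
#'
#' @param net a \linkS4class{ModuleNetwork}.
#' @param n number of subjects.
#' @param seed optional seed.
#' @param quiet suppress the repair message.
#' @return a \linkS4class{ModuleData}.
#' @export
simulateModuleData <- function(net, n, seed = NULL, quiet = FALSE) {
  R <- chol(.networkCorrelation(net, quiet = quiet))
  .withSeed(seed, {
    X <- matrix(stats::rnorm(n * nrow(R)), n) %*% R
    moduleData(X, nodeLabels = net@nodeLabels)
  })
}

#' Select causal nodes in a module
#'
#' @param net a \linkS4class{ModuleNetwork}.
#' @param mode "hub" picks the C highest-degree nodes (ties broken by node
#'   index); "random" samples C nodes uniformly without replacement.
#' @param C number of causal nodes (<= module size).
#' @param seed optional seed (random mode).
#' @return sorted integer vector of node indices.
#' @export
selectCausalNodes <- function(net, mode = c("hub", "random"), C,
                              seed = NULL) {
  mode <- match.arg(mode)
  L <- length(net@nodeLabels)
  if (C > L) stop("C must not exceed the module size")
  if (mode == "hub") {
    k <- nodeDegrees(net)
    sort(order(-k, seq_len(L))[seq_len(C)])
  } else {
    .withSeed(seed, sort(sample.int(L, C)))
  }
}

## all pairwise products between causal columns of the two modules
.interactionDesign <- function(X1c, X2c) {
  n <- nrow(X1c)
  out <- matrix(0, n, ncol(X1c) * ncol(X2c))
  col <- 0L
  for (j in seq_len(ncol(X2c))) for (i in seq_len(ncol(X1c))) {
    col <- col + 1L
    out[, col] <- X1c[, i] * X2c[, j]
  }
  out
}

.drawBeta <- function(p) {
  stats::runif(p, 0.05, 0.2) * sample(c(-1, 1), p, replace = TRUE)
}

#' Simulate a trait from module signals
#'
#' The subject mean is
#' \eqn{\mu_i = \gamma_1 \tilde X_{1i}'\beta_1 + \gamma_2
#' \tilde X_{2i}'\beta_2 + \gamma_{12} \tilde X_{12,i}'\beta_{12}}, where
#' the tilde matrices hold the causal columns (and, for the interaction
#' term, all pairwise products of causal columns across modules). Effect
#' sizes are drawn uniformly from [-0.2, -0.05] U [0.05, 0.2]. The noise
#' variance is set to \eqn{\zeta = \widehat{Var}(\mu)(1 - R^2)/R^2} so the
#' targeted signal fraction is met exactly; under the global null
#' (\eqn{\gamma = 0}) \eqn{\mu = 0} and \eqn{\zeta = 1}.
#'
#' @param X1,X2 \linkS4class{ModuleData} for the two modules.
#' @param causal1,causal2 causal node index sets.
#' @param gamma length-3 0/1 vector (gamma1, gamma2, gamma12).
#' @param r2 target R-squared in (0, 1).
#' @param seed optional seed.
#' @return list with \code{y}, \code{mu}, \code{zeta}, \code{beta1},
#'   \code{beta2}, \code{beta12}.
#' @export
simulateResponse <- function(X1, X2, causal1, causal2, gamma, r2,
                             seed = NULL) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  stopifnot(length(gamma) == 3)
  M1 <- dataMatrix(X1)[, causal1, drop = FALSE]
  M2 <- dataMatrix(X2)[, causal2, drop = FALSE]
  n <- nrow(M1)
  .withSeed(seed, {
    beta1 <- .drawBeta(ncol(M1))
    beta2 <- .drawBeta(ncol(M2))
    X12 <- .interactionDesign(M1, M2)
    beta12 <- .drawBeta(ncol(X12))
    mu <- gamma[1] * drop(M1 %*% beta1) + gamma[2] * drop(M2 %*% beta2) +
      gamma[3] * drop(X12 %*% beta12)
    if (all(gamma == 0)) {
      mu <- rep(0, n)
      zeta <- 1
    } else {
      zeta <- stats::var(mu) * (1 - r2) / r2
    }
    list(y = mu + stats::rnorm(n, sd = sqrt(zeta)), mu = mu, zeta = zeta,
         beta1 = beta1, beta2 = beta2, beta12 = beta12)
  })
}

## ---- experiment runners ---------------------------------------------------

## fixed per-experiment kernel machinery: for each kernel kind, a closure
## mapping a raw module data matrix to a KernelMatrix (standardization and
## trace normalization on; the TOM PSD clip happens once, here)
.kernelBuilders <- function(net, kinds) {
  tom <- topologicalOverlap(net)
  builders <- list()
  for (kind in kinds) {
    builders[[kind]] <- switch(kind,
      linear = function(X) linearKernel(X),
      topology = local({
        e <- eigen(tom@tom, symmetric = TRUE)
        half <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
        repaired <- any(e$values < 0)
        function(X) .newKernel("topology",
                               factor = standardizeColumns(dataMatrix(X)) %*%
                                 half,
                               psdRepaired = repaired)
      }),
      connectivity = local({
        sw <- sqrt(nodeWeights(connectivityWeights(tom)))
        function(X) .newKernel("connectivity",
                               factor = sweep(standardizeColumns(
                                 dataMatrix(X)), 2L, sw, "*"))
      }),
      stop("unknown kernel kind: ", kind))
  }
  builders
}

.experimentNetworks <- function(design) {
  if (design@structure == "scale_free") {
    list(module1 = generateScaleFreeModule(design@moduleSize),
         module2 = generateScaleFreeModule(design@moduleSize))
  } else {
    generateNonScaleFreeModules(100, design@moduleSize)[c("module1",
                                                          "module2")]
  }
}

.runTests <- function(y, K1, K2, tests, control) {
  out <- numeric(length(tests))
  names(out) <- tests
  model <- kmModel(y, K1, K2)
  for (tst in tests) {
    res <- switch(tst,
      interaction = testInteraction(model, control),
      module1 = testConditional(model, 1, control),
      module2 = testConditional(model, 2, control))
    out[tst] <- pValue(res)
  }
  out
}

#' Type-I error experiment under the global null
#'
#' Fixes the two module networks once from the design seed, then per
#' replicate redraws the module data and an independent standard-normal
#' trait, and runs the interaction test and both conditional tests with
#' each requested kernel kind. The whole run is reproducible bit-for-bit
#' from the design.
#'
#' @param design a \linkS4class{SimulationDesign} with
#'   \code{gamma = c(0, 0, 0)}.
#' @param kernels kernel kinds to evaluate.
#' @param tests which tests to run per replicate.
#' @param control fitter control, see \code{\link{kmControl}}.
#' @return data.frame with one row per (kernel, test): rejection count,
#'   rate and binomial standard error at the design alpha. The per-replicate
#'   p-values are attached as attribute \code{"pValues"} (replicates x
#'   kernel x test array).
#' @export
runType1Experiment <- function(design,
                               kernels = c("topology", "connectivity",
                                           "linear"),
                               tests = c("interaction", "module1",
                                         "module2"),
                               control = kmControl()) {
  stopifnot(is(design, "SimulationDesign"))
  if (any(design@gamma != 0))
    stop("type-I error experiment requires gamma = (0, 0, 0)")
  set.seed(design@seed)
  nets <- .experimentNetworks(design)
  b1 <- .kernelBuilders(nets$module1, kernels)
  b2 <- .kernelBuilders(nets$module2, kernels)
  chol1 <- chol(.networkCorrelation(nets$module1, quiet = TRUE))
  chol2 <- chol(.networkCorrelation(nets$module2, quiet = TRUE))
  n <- design@nSubjects
  pv <- array(NA_real_,
              dim = c(design@nReplicates, length(kernels), length(tests)),
              dimnames = list(NULL, kernels, tests))
  for (rep in seq_len(design@nReplicates)) {
    X1 <- moduleData(matrix(stats::rnorm(n * ncol(chol1)), n) %*% chol1,
                     nets$module1@nodeLabels)
    X2 <- moduleData(matrix(stats::rnorm(n * ncol(chol2)), n) %*% chol2,
                     nets$module2@nodeLabels)
    y <- stats::rnorm(n)
    for (kk in kernels) {
      pv[rep, kk, ] <- .runTests(y, b1[[kk]](X1), b2[[kk]](X2), tests,
                                 control)
    }
  }
  .summarizeRejections(pv, design, kernels, tests)
}

.summarizeRejections <- function(pv, design, kernels, tests,
                                 extra = NULL) {
  rows <- expand.grid(kernel = kernels, test = tests,
                      stringsAsFactors = FALSE)
  nr <- dim(pv)[1]
  rows$rejections <- mapply(function(k, t) sum(pv[, k, t] < design@alpha),
                            rows$kernel, rows$test)
  rows$nReplicates <- nr
  rows$rate <- rows$rejections / nr
  rows$se <- sqrt(rows$rate * (1 - rows$rate) / nr)
  rows$alpha <- design@alpha
  if (!is.null(extra)) rows <- cbind(rows, extra)
  attr(rows, "pValues") <- pv
  attr(rows, "design") <- design
  rows
}

#' Power experiment
#'
#' Fixes networks and the causal node sets once from the design seed (hub
#' mode picks the highest-degree nodes deterministically; random mode
#' samples once), then per replicate redraws module data, effect sizes
#' and the trait, and runs the single test matching the design's gamma
#' ((0,0,1): interaction; (1,0,0): module 1 given 2; (0,1,0): module 2
#' given 1) with each kernel kind, at every requested R-squared level.
#'
#' @inheritParams runType1Experiment
#' @param r2Levels named numeric vector of signal levels; defaults to the
#'   design's.
#' @return data.frame with one row per (kernel, r2 level): power and
#'   binomial SE, with p-values in attribute \code{"pValues"} (a list of
#'   arrays, one per level).
#' @export
runPowerExperiment <- function(design,
                               kernels = c("topology", "connectivity",
                                           "linear"),
                               r2Levels = design@r2,
                               control = kmControl()) {
  stopifnot(is(design, "SimulationDesign"))
  if (sum(design@gamma == 1) != 1 || any(!design@gamma %in% c(0, 1)))
    stop("power experiment requires exactly one gamma component = 1")
  test <- c("module1", "module2", "interaction")[design@gamma == 1]
  set.seed(design@seed)
  nets <- .experimentNetworks(design)
  b1 <- .kernelBuilders(nets$module1, kernels)
  b2 <- .kernelBuilders(nets$module2, kernels)
  chol1 <- chol(.networkCorrelation(nets$module1, quiet = TRUE))
  chol2 <- chol(.networkCorrelation(nets$module2, quiet = TRUE))
  causal1 <- selectCausalNodes(nets$module1, design@causalMode,
                               design@nCausal)
  causal2 <- selectCausalNodes(nets$module2, design@causalMode,
                               design@nCausal)
  n <- design@nSubjects
  out <- NULL
  pvList <- list()
  for (lev in seq_along(r2Levels)) {
    pv <- array(NA_real_, dim = c(design@nReplicates, length(kernels), 1L),
                dimnames = list(NULL, kernels, test))
    for (rep in seq_len(design@nReplicates)) {
      X1 <- moduleData(matrix(stats::rnorm(n * ncol(chol1)), n) %*% chol1,
                       nets$module1@nodeLabels)
      X2 <- moduleData(matrix(stats::rnorm(n * ncol(chol2)), n) %*% chol2,
                       nets$module2@nodeLabels)
      resp <- simulateResponse(X1, X2, causal1, causal2, design@gamma,
                               r2Levels[lev])
      for (kk in kernels)
        pv[rep, kk, 1L] <- .runTests(resp$y, b1[[kk]](X1), b2[[kk]](X2),
                                     test, control)
    }
    lvName <- if (!is.null(names(r2Levels))) names(r2Levels)[lev]
              else as.character(r2Levels[lev])
    smry <- .summarizeRejections(pv, design, kernels, test,
                                 extra = data.frame(
                                   r2Level = lvName,
                                   r2 = unname(r2Levels[lev])))
    pvList[[lvName]] <- pv
    attr(smry, "pValues") <- NULL
    out <- rbind(out, smry)
  }
  names(out)[names(out) == "rate"] <- "power"
  attr(out, "pValues") <- pvList
  attr(out, "design") <- design
  out
}
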