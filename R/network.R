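#' @include AllGenerics.R
NULL

#' Construct a module network from an adjacency matrix
#'
#' @param adjacency square binary symmetric matrix with zero diagonal.
#'   Dimnames, if present, provide the node labels.
#' @param nodeLabels optional character vector of node labels; defaults to
#'   the matrix dimnames or \code{"n1", "n2", ...}.
#' @return a \linkS4class{ModuleNetwork}.
#' @examples
#' A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)  # path 1-2-3
#' net <- moduleNetwork(A)
#' nodeDegrees(net)
#' @export
moduleNetwork <- function(adjacency, nodeLabels = NULL) {
  adjacency <- as.matrix(adjacency)
  if (is.null(nodeLabels)) {
    nodeLabels <- rownames(adjacency)
    if (is.null(nodeLabels))
      nodeLabels <- paste0("n", seq_len(nrow(adjacency)))
  }
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- list(nodeLabels, nodeLabels)
  new("ModuleNetwork", nodeLabels = nodeLabels, adjacency = adjacency)
}

#' Threshold a correlation matrix into a binary adjacency
#'
#' Hard thresholding: nodes l and l' are connected iff
#' \eqn{|R_{ll'}| \ge} \code{threshold} (and l differs from l'). Used when
#' no prior network is available and the network must be built from the
#' data's pairwise correlations.
#'
#' @param R symmetric correlation matrix with unit diagonal, entries in
#'   [-1, 1].
#' @param threshold scalar in (0, 1); default 0.5.
#' @return a \linkS4class{ModuleNetwork}.
#' @export
adjacencyFromCorrelation <- function(R, threshold = 0.5) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop("R must be a symmetric square matrix")
  if (min(R) < -1 - 1e-8 || max(R) > 1 + 1e-8)
    stop("correlation entries must lie in [-1, 1]")
  if (max(abs(diag(R) - 1)) > 1e-8)
    stop("R must have unit diagonal")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a scalar in (0, 1)")
  A <- (abs(R) >= threshold) + 0
  diag(A) <- 0
  moduleNetwork(A, nodeLabels = rownames(R))
}

#' Topological overlap matrix of a network
#'
#' For distinct nodes l and l',
#' \deqn{T_{ll'} = \frac{L_{ll'} + A_{ll'}}{\min(k_l, k_{l'}) - A_{ll'} + 1}}
#' where \eqn{L_{ll'} = \sum_{u \ne l, l'} A_{lu} A_{l'u}} counts shared
#' neighbours and \eqn{k_l} is the degree of node l; the diagonal is 1.
#' The denominator normalizes T into [0, 1] since
#' \eqn{L_{ll'} \le \min(k_l, k_{l'}) - A_{ll'}}. Isolated nodes give
#' zero off-diagonal overlap (the denominator is then 1, never 0).
#'
#' @param net a \linkS4class{ModuleNetwork}.
#' @return a \linkS4class{TopologicalOverlap}.
#' @export
topologicalOverlap <- function(net) {
  stopifnot(is(net, "ModuleNetwork"))
  A <- net@adjacency
  k <- rowSums(A)
  ## A %*% A counts walks of length 2; its off-diagonal (l,l') entry is the
  ## number of common neighbours since the diagonal of A is zero.
  Lmat <- A %*% A
  diag(Lmat) <- 0
  minK <- outer(k, k, pmin)
  T <- (Lmat + A) / (minK - A + 1)
  diag(T) <- 1
  dimnames(T) <- dimnames(A)
  dimnames(Lmat) <- dimnames(A)
  new("TopologicalOverlap", tom = T, sharedNeighbors = Lmat,
      nodeLabels = net@nodeLabels)
}

#' Connectivity weights from a topological overlap matrix
#'
#' The weight of node l is its total topological overlap with the rest of
#' the module, \eqn{w_l = \sum_{l' \ne l} T_{ll'}} (the row sum of T minus
#' the unit diagonal). Hub nodes receive large weights.
#'
#' @param tom a \linkS4class{TopologicalOverlap}.
#' @return a \linkS4class{ConnectivityWeights}.
#' @export
connectivityWeights <- function(tom) {
  stopifnot(is(tom, "TopologicalOverlap"))
  w <- rowSums(tom@tom) - 1
  w[w < 0] <- 0  # guard numerical dust
  names(w) <- tom@nodeLabels
  new("ConnectivityWeights", weights = w, nodeLabels = tom@nodeLabels)
}

## -- igraph bridge ----------------------------------------------------------

#' Convert between ModuleNetwork and igraph
#'
#' @param g an \code{igraph} graph (undirected; multi-edges collapse).
#' @param x a \linkS4class{ModuleNetwork}.
#' @return \code{moduleNetworkFromIgraph} returns a
#'   \linkS4class{ModuleNetwork}; \code{asIgraph} an igraph object.
#' @export
moduleNetworkFromIgraph <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 1] <- 1
  A <- pmax(A, t(A))  # force symmetric in case of directed input
  diag(A) <- 0
  lab <- igraph::vertex_attr(g, "name")
  if (is.null(lab)) lab <- paste0("n", seq_len(nrow(A)))
  moduleNetwork(A, nodeLabels = lab)
}

#' @rdname moduleNetworkFromIgraph
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "ModuleNetwork"))
  igraph::graph_from_adjacency_matrix(x@adjacency, mode = "undirected")
}

## -- accessors & show -------------------------------------------------------

#' @rdname accessors
setMethod("nodeLabels", "ModuleNetwork", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("nodeLabels", "TopologicalOverlap", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("nodeLabels", "ConnectivityWeights", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("nodeLabels", "ModuleData", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("adjacencyMatrix", "ModuleNetwork", function(x) x@adjacency)
#' @rdname accessors
setMethod("nodeDegrees", "ModuleNetwork",
          function(x) rowSums(x@adjacency))
#' @rdname accessors
setMethod("tomMatrix", "TopologicalOverlap", function(x) x@tom)
#' @rdname accessors
setMethod("sharedNeighbors", "TopologicalOverlap",
          function(x) x@sharedNeighbors)
#' @rdname accessors
setMethod("nodeWeights", "ConnectivityWeights", function(x) x@weights)
#' @rdname accessors
setMethod("weightMatrix", "ConnectivityWeights", function(x) {
  W <- diag(x@weights, nrow = length(x@weights))
  dimnames(W) <- list(x@nodeLabels, x@nodeLabels)
  W
})

setMethod("show", "ModuleNetwork", function(object) {
  k <- rowSums(object@adjacency)
  cat(sprintf("ModuleNetwork: %d nodes, %d edges\n",
              length(object@nodeLabels), sum(object@adjacency) / 2))
  cat(sprintf("  degrees: min %d / median %g / max %d\n",
              min(k), stats::median(k), max(k)))
})

setMethod("show", "TopologicalOverlap", function(object) {
  off <- object@tom[upper.tri(object@tom)]
  cat(sprintf("TopologicalOverlap: %d nodes\n", nrow(object@tom)))
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.3f, %.3f]\n",
                min(off), max(off)))
})

setMethod("show", "ConnectivityWeights", function(object) {
  cat(sprintf("ConnectivityWeights: %d nodes, total overlap in [%.3f, %.3f]\n",
              length(object@weights), min(object@weights),
              max(object@weights)))
})
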