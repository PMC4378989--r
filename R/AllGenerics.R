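#' @include AllClasses.R
NULL

#' Accessors for netKM objects
#'
#' Small generic accessors: \code{nodeLabels} returns node identifiers,
#' \code{adjacencyMatrix} the binary adjacency, \code{nodeDegrees} the row
#' sums of the adjacency, \code{tomMatrix} the topological overlap matrix,
#' \code{sharedNeighbors} the shared-neighbour counts, \code{nodeWeights}
#' the per-node total topological overlap, \code{weightMatrix} the same as
#' a diagonal matrix, \code{dataMatrix} the subject-by-node values,
#' \code{kernelMatrix}/\code{kernelKind}/\code{kernelFactor} the pieces of
#' a \linkS4class{KernelMatrix}, \code{varianceComponents} the named
#' (tau1, tau2, tau12, sigma) estimates of a fit, \code{testStatistic} and
#' \code{pValue} the pieces of a test result.
#'
#' @param x,object a netKM object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))
#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))
#' @rdname accessors
#' @export
setGeneric("sharedNeighbors", function(x) standardGeneric("sharedNeighbors"))
#' @rdname accessors
#' @export
setGeneric("nodeWeights", function(x) standardGeneric("nodeWeights"))
#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setGeneric("dataMatrix", function(x) standardGeneric("dataMatrix"))
#' @rdname accessors
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))
#' @rdname accessors
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))
#' @rdname accessors
#' @export
setGeneric("kernelFactor", function(x) standardGeneric("kernelFactor"))
#' @rdname accessors
#' @export
setGeneric("varianceComponents",
           function(x) standardGeneric("varianceComponents"))
#' @rdname accessors
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Null covariance and projection of a fitted null model
#'
#' \code{nullCovariance} materializes the n x n covariance
#' \eqn{V = \sum_k \tau_k K_k + \sigma I} implied by the fit;
#' \code{projectionMatrix} materializes
#' \eqn{P = V^{-1} - V^{-1} Z (Z' V^{-1} Z)^{-1} Z' V^{-1}}, which
#' annihilates the covariates (\eqn{PZ = 0}) and satisfies
#' \eqn{P V P = P}. Both are O(n^2) in memory; the fitter itself never
#' forms them when the kernels carry low-rank factors.
#'
#' @param fit a \linkS4class{NullFit}.
#' @return an n x n matrix.
#' @export
setGeneric("nullCovariance", function(fit) standardGeneric("nullCovariance"))
#' @rdname nullCovariance
#' @export
setGeneric("projectionMatrix",
           function(fit) standardGeneric("projectionMatrix"))
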