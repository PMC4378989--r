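#' @import methods
NULL

.isSymmetricTol <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) &&
    max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

#' ModuleNetwork: binary network over the bio-elements of a module
#'
#' Stores an undirected, unweighted network as a binary symmetric adjacency
#' matrix with zero diagonal over labeled nodes. Node degrees are the row
#' sums of the adjacency matrix.
#'
#' @slot nodeLabels ordered character vector of node identifiers.
#' @slot adjacency L x L binary symmetric matrix, zero diagonal, dimnames
#'   equal to \code{nodeLabels}.
#' @export
setClass("ModuleNetwork",
  slots = c(nodeLabels = "character", adjacency = "matrix"),
  validity = function(object) {
    A <- object@adjacency
    lab <- object@nodeLabels
    if (!is.numeric(A) || nrow(A) != ncol(A))
      return("adjacency must be a square numeric matrix")
    if (length(lab) != nrow(A))
      return("nodeLabels length must equal adjacency dimension")
    if (anyDuplicated(lab))
      return("nodeLabels must be unique")
    if (!all(A %in% c(0, 1)))
      return("adjacency entries must be 0 or 1")
    if (any(diag(A) != 0))
      return("adjacency diagonal must be zero")
    if (!isTRUE(all.equal(A, t(A))))
      return("adjacency must be symmetric")
    if (!identical(rownames(A), lab) || !identical(colnames(A), lab))
      return("adjacency dimnames must equal nodeLabels")
    TRUE
  }
)

#' TopologicalOverlap: TOM of a module network
#'
#' The topological overlap matrix T combines direct connection and shared
#' neighbourhood: for distinct nodes l, l',
#' \deqn{T_{ll'} = (L_{ll'} + A_{ll'}) / (\min(k_l, k_{l'}) - A_{ll'} + 1)}
#' with unit diagonal, where \eqn{L_{ll'}} counts shared neighbours and
#' \eqn{k_l} is the degree. All entries lie in [0, 1].
#'
#' @slot tom L x L symmetric matrix with unit diagonal, entries in [0, 1].
#' @slot sharedNeighbors L x L integer-valued matrix of shared-neighbour
#'   counts used in the construction.
#' @slot nodeLabels node identifiers, aligned with the matrix rows.
#' @export
setClass("TopologicalOverlap",
  slots = c(tom = "matrix", sharedNeighbors = "matrix",
            nodeLabels = "character"),
  validity = function(object) {
    T <- object@tom
    if (!.isSymmetricTol(T)) return("tom must be symmetric")
    if (max(abs(diag(T) - 1)) > 1e-12) return("tom diagonal must be 1")
    if (min(T) < -1e-12 || max(T) > 1 + 1e-12)
      return("tom entries must lie in [0, 1]")
    if (length(object@nodeLabels) != nrow(T))
      return("nodeLabels length must equal tom dimension")
    TRUE
  }
)

#' ConnectivityWeights: per-node total topological overlap
#'
#' Diagonal weights \eqn{w_l = \sum_{l' \ne l} T_{ll'}} used by the
#' connectivity kernel to up-weight hub nodes.
#'
#' @slot weights named non-negative numeric vector, one entry per node.
#' @slot nodeLabels node identifiers.
#' @export
setClass("ConnectivityWeights",
  slots = c(weights = "numeric", nodeLabels = "character"),
  validity = function(object) {
    if (length(object@weights) != length(object@nodeLabels))
      return("weights and nodeLabels must have equal length")
    if (any(object@weights < -1e-12))
      return("weights must be non-negative")
    TRUE
  }
)

#' ModuleData: subject-by-node data matrix for one module
#'
#' @slot values n x L numeric matrix (subjects in rows, bio-elements in
#'   columns); column names are the node labels, optional row names are
#'   subject identifiers. No missing values.
#' @slot nodeLabels node identifiers in column order.
#' @export
setClass("ModuleData",
  slots = c(values = "matrix", nodeLabels = "character"),
  validity = function(object) {
    X <- object@values
    if (!is.numeric(X)) return("values must be numeric")
    if (anyNA(X) || any(!is.finite(X)))
      return("values must be finite with no missing entries")
    if (nrow(X) < 2) return("at least 2 subjects are required")
    if (length(object@nodeLabels) != ncol(X))
      return("nodeLabels length must equal number of columns")
    if (!is.null(colnames(X)) &&
        !identical(colnames(X), object@nodeLabels))
      return("column names must equal nodeLabels")
    TRUE
  }
)

#' KernelMatrix: subject-by-subject similarity kernel
#'
#' A symmetric positive semidefinite n x n matrix. Kernels built from a
#' module data matrix X and a node-space structure matrix M (TOM, diagonal
#' connectivity weights, or identity) have the form X M X' and carry a
#' low-rank factor C with K = C C', which the REML/EM fitter exploits.
#'
#' @slot kernel n x n symmetric matrix.
#' @slot kind one of "topology", "connectivity", "linear", "interaction",
#'   "polynomial", "gaussian".
#' @slot factor n x r matrix with \code{kernel == factor \%*\% t(factor)},
#'   or a 0-column matrix when no factorization is available.
#' @slot psdRepaired TRUE when negative eigenvalues of the node-space
#'   structure matrix were clipped to zero during construction.
#' @export
setClass("KernelMatrix",
  slots = c(kernel = "matrix", kind = "character", factor = "matrix",
            psdRepaired = "logical"),
  validity = function(object) {
    K <- object@kernel
    if (!.isSymmetricTol(K, 1e-6)) return("kernel must be symmetric")
    kinds <- c("topology", "connectivity", "linear", "interaction",
               "polynomial", "gaussian")
    if (length(object@kind) != 1L || !(object@kind %in% kinds))
      return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
    if (ncol(object@factor) > 0 && nrow(object@factor) != nrow(K))
      return("factor must have as many rows as the kernel")
    TRUE
  }
)

#' KmModel: inputs of the two-module kernel machine regression
#'
#' Holds the trait vector Y, the fixed-effect design Z (with intercept),
#' and the three kernels K1, K2 and K12 of the mixed-model representation
#' \eqn{Y = Z\beta + h_1 + h_2 + h_{12} + \epsilon} with
#' \eqn{h_\ell \sim N(0, \tau_\ell K_\ell)},
#' \eqn{h_{12} \sim N(0, \tau_{12} K_{12})}.
#'
#' @slot y numeric trait vector of length n.
#' @slot Z n x Q covariate matrix including the intercept column.
#' @slot K1,K2,K12 \linkS4class{KernelMatrix} objects of dimension n.
#' @export
setClass("KmModel",
  slots = c(y = "numeric", Z = "matrix", K1 = "KernelMatrix",
            K2 = "KernelMatrix", K12 = "KernelMatrix"),
  validity = function(object) {
    n <- length(object@y)
    if (anyNA(object@y) || any(!is.finite(object@y)))
      return("y must be finite")
    if (nrow(object@Z) != n) return("Z must have length(y) rows")
    if (qr(object@Z)$rank < ncol(object@Z))
      return("Z must have full column rank")
    for (nm in c("K1", "K2", "K12")) {
      if (nrow(slot(object, nm)@kernel) != n)
        return(paste(nm, "dimension must match length(y)"))
    }
    TRUE
  }
)

#' NullFit: REML/EM fit of the mixed model under a specified null
#'
#' @slot whichNull "interaction" (tau12 = 0; tau1, tau2, sigma estimated),
#'   "module1" (conditional null for testing module 1: tau1 = tau12 = 0),
#'   or "module2" (tau2 = tau12 = 0).
#' @slot tau named numeric vector (tau1, tau2, tau12); components fixed at
#'   zero by the null are zero.
#' @slot sigma residual variance estimate.
#' @slot logLik trajectory of the restricted log-likelihood over EM
#'   iterations (non-decreasing).
#' @slot converged TRUE when the relative parameter change fell below the
#'   tolerance within the iteration cap.
#' @slot nIter number of EM iterations performed.
#' @slot n number of subjects.
#' @slot solver internal state used to apply the projection P and compute
#'   score moments without materializing n x n matrices.
#' @export
setClass("NullFit",
  slots = c(whichNull = "character", tau = "numeric", sigma = "numeric",
            logLik = "numeric", converged = "logical", nIter = "integer",
            n = "integer", solver = "list"),
  validity = function(object) {
    if (!(object@whichNull %in% c("interaction", "module1", "module2")))
      return("whichNull must be interaction, module1 or module2")
    if (any(object@tau < 0)) return("variance components must be >= 0")
    if (object@sigma <= 0) return("sigma must be > 0")
    TRUE
  }
)

#' KmTestResult: a score test with its moment-matched p-value
#'
#' The score statistic \eqn{T = Y' P K P Y / 2} is referred to a scaled
#' chi-squared distribution \eqn{\kappa \chi^2_\nu} whose first two moments
#' match the null mean and variance of the quadratic form.
#'
#' @slot test "interaction", "module1" (module 1 given module 2) or
#'   "module2".
#' @slot statistic non-negative score statistic.
#' @slot pValue p-value in (0, 1].
#' @slot kappa,df scale and degrees of freedom of the matched chi-square.
#' @slot fit the \linkS4class{NullFit} used.
#' @export
setClass("KmTestResult",
  slots = c(test = "character", statistic = "numeric", pValue = "numeric",
            kappa = "numeric", df = "numeric", fit = "NullFit"),
  validity = function(object) {
    if (object@statistic < -1e-10) return("statistic must be >= 0")
    if (object@pValue <= 0 || object@pValue > 1)
      return("pValue must lie in (0, 1]")
    TRUE
  }
)
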