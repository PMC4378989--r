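#' @include network.R
NULL

#' Construct a ModuleData object
#'
#' @param X numeric matrix, subjects in rows and bio-elements in columns.
#' @param nodeLabels node labels in column order; defaults to the column
#'   names of \code{X}.
#' @return a \linkS4class{ModuleData}.
#' @export
moduleData <- function(X, nodeLabels = NULL) {
  X <- as.matrix(X)
  if (is.null(nodeLabels)) {
    nodeLabels <- colnames(X)
    if (is.null(nodeLabels)) nodeLabels <- paste0("n", seq_len(ncol(X)))
  }
  colnames(X) <- nodeLabels
  storage.mode(X) <- "double"
  new("ModuleData", values = X, nodeLabels = nodeLabels)
}

#' @rdname accessors
setMethod("dataMatrix", "ModuleData", function(x) x@values)

#' Standardize module columns
#'
#' Centers each column and scales it to unit sample variance. Constant
#' columns are centered but left unscaled, with a warning.
#'
#' @param X a \linkS4class{ModuleData} or numeric matrix.
#' @return object of the same type with standardized columns.
#' @export
standardizeColumns <- function(X) {
  isMD <- is(X, "ModuleData")
  M <- if (isMD) X@values else as.matrix(X)
  s <- apply(M, 2L, stats::sd)
  bad <- s < 1e-12
  if (any(bad)) {
    warning(sum(bad), " constant column(s) left unscaled")
    s[bad] <- 1
  }
  M <- scale(M, center = TRUE, scale = s)
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  if (isMD) moduleData(M, X@nodeLabels) else M
}

## Internal kernel builder.  When `factor` is given, the dense kernel is
## tcrossprod(factor); trace normalization rescales K to trace n so that the
## variance components of different kernel kinds live on a comparable scale.
.newKernel <- function(kind, factor = NULL, kernel = NULL,
                       normalize = TRUE, psdRepaired = FALSE) {
  if (is.null(kernel)) kernel <- tcrossprod(factor)
  n <- nrow(kernel)
  if (normalize) {
    tr <- sum(diag(kernel))
    if (tr > 1e-300) {
      kernel <- kernel * (n / tr)
      if (!is.null(factor)) factor <- factor * sqrt(n / tr)
    }
  }
  if (is.null(factor)) factor <- matrix(0, n, 0)
  kernel <- (kernel + t(kernel)) / 2
  new("KernelMatrix", kernel = kernel, kind = kind, factor = factor,
      psdRepaired = psdRepaired)
}

.moduleMatrix <- function(X, standardize) {
  M <- if (is(X, "ModuleData")) X@values else as.matrix(X)
  if (standardize) M <- standardizeColumns(M)
  if (is(M, "ModuleData")) M <- M@values
  M
}

#' Kernels on module data
#'
#' \code{linearKernel} is the unstructured kernel
#' \eqn{K(X_i, X_{i'}) = X_i' X_{i'}}. \code{topologyKernel} is
#' \eqn{X_i' T X_{i'}} with T the topological overlap matrix, which
#' smooths effects across network-adjacent nodes. \code{connectivityKernel}
#' is \eqn{X_i' W X_{i'}} with diagonal W of per-node total topological
#' overlap, which up-weights hubs; it equals the linear kernel on columns
#' scaled by \eqn{\sqrt{w_l}}. \code{interactionKernel} is the element-wise
#' (Hadamard) product of two main-effect kernels and is positive
#' semidefinite by the Schur product theorem.
#'
#' Columns are standardized (mean 0, unit variance) before the product by
#' default, and kernels are trace-normalized to trace n by default; both
#' can be switched off. If T is not positive semidefinite its negative
#' eigenvalues are clipped to zero before use (flagged on the result, with
#' a warning when the clip exceeds 1e-8 relatively).
#'
#' @param X a \linkS4class{ModuleData} or numeric matrix (subjects x
#'   nodes).
#' @param tom a \linkS4class{TopologicalOverlap} aligned with the columns
#'   of \code{X}.
#' @param weights a \linkS4class{ConnectivityWeights} aligned with the
#'   columns of \code{X}.
#' @param K1,K2 \linkS4class{KernelMatrix} objects of equal dimension.
#' @param standardize standardize columns first (default TRUE).
#' @param normalize trace-normalize the kernel (default TRUE).
#' @return a \linkS4class{KernelMatrix}.
#' @examples
#' X <- moduleData(matrix(rnorm(20), 5, 4))
#' K <- linearKernel(X)
#' @export
linearKernel <- function(X, standardize = TRUE, normalize = TRUE) {
  M <- .moduleMatrix(X, standardize)
  .newKernel("linear", factor = M, normalize = normalize)
}

#' @rdname linearKernel
#' @export
topologyKernel <- function(X, tom, standardize = TRUE, normalize = TRUE) {
  M <- .moduleMatrix(X, standardize)
  T <- if (is(tom, "TopologicalOverlap")) tom@tom else as.matrix(tom)
  if (ncol(M) != nrow(T))
    stop("number of module columns (", ncol(M),
         ") does not match TOM dimension (", nrow(T), ")")
  if (is(tom, "TopologicalOverlap") && !is.null(colnames(M)) &&
      !identical(colnames(M), tom@nodeLabels))
    stop("module column labels do not match TOM node labels")
  e <- eigen(T, symmetric = TRUE)
  repaired <- any(e$values < 0)
  if (any(e$values < -1e-8 * max(abs(e$values))))
    warning("TOM had negative eigenvalues (min ",
            format(min(e$values), digits = 3),
            "); clipped to 0 for a valid covariance")
  lam <- pmax(e$values, 0)
  half <- e$vectors %*% (sqrt(lam) * t(e$vectors))  # symmetric sqrt of T+
  .newKernel("topology", factor = M %*% half, normalize = normalize,
             psdRepaired = repaired)
}

#' @rdname linearKernel
#' @export
connectivityKernel <- function(X, weights, standardize = TRUE,
                               normalize = TRUE) {
  M <- .moduleMatrix(X, standardize)
  w <- if (is(weights, "ConnectivityWeights")) weights@weights
       else diag(as.matrix(weights))
  if (any(w < 0)) stop("connectivity weights must be non-negative")
  if (ncol(M) != length(w))
    stop("number of module columns does not match weight vector length")
  .newKernel("connectivity",
             factor = sweep(M, 2L, sqrt(w), "*"),
             normalize = normalize)
}

#' @rdname linearKernel
#' @export
interactionKernel <- function(K1, K2, normalize = TRUE) {
  stopifnot(is(K1, "KernelMatrix"), is(K2, "KernelMatrix"))
  if (nrow(K1@kernel) != nrow(K2@kernel))
    stop("K1 and K2 must have the same dimension")
  K <- K1@kernel * K2@kernel
  fac <- NULL
  r1 <- ncol(K1@factor); r2 <- ncol(K2@factor)
  if (r1 > 0 && r2 > 0 && r1 * r2 <= 8192) {
    ## row-wise Khatri-Rao product: (C1 C1') o (C2 C2') = C12 C12'
    n <- nrow(K)
    fac <- matrix(0, n, r1 * r2)
    for (j in seq_len(r2))
      fac[, ((j - 1L) * r1 + 1L):(j * r1)] <- K1@factor * K2@factor[, j]
  }
  .newKernel("interaction", factor = fac, kernel = K,
             normalize = normalize,
             psdRepaired = K1@psdRepaired || K2@psdRepaired)
}

#' Polynomial and Gaussian kernels
#'
#' Optional unstructured alternatives. The second-order polynomial kernel
#' is \eqn{(1 + X_i' X_{i'})^2}; with \code{dropConstant = TRUE} (the
#' default) the constant term is removed, i.e.
#' \eqn{(1 + X_i' X_{i'})^2 - 1}, so the kernel is safe to use inside the
#' Hadamard interaction kernel. The Gaussian kernel is
#' \eqn{\exp(-\|X_i - X_{i'}\|^2 / d)} with tuning parameter \code{d}
#' defaulting to the number of nodes; its constant term (the value at
#' coincident points) is likewise removed for interaction use.
#'
#' @inheritParams linearKernel
#' @param dropConstant remove the constant offset (default TRUE).
#' @param d Gaussian bandwidth; default \code{ncol(X)}.
#' @return a \linkS4class{KernelMatrix} (no low-rank factor).
#' @export
polynomialKernel <- function(X, standardize = TRUE, normalize = TRUE,
                             dropConstant = TRUE) {
  M <- .moduleMatrix(X, standardize)
  K <- (1 + tcrossprod(M))^2
  if (dropConstant) K <- K - 1
  .newKernel("polynomial", kernel = K, normalize = normalize)
}

#' @rdname polynomialKernel
#' @export
gaussianKernel <- function(X, d = NULL, standardize = TRUE,
                           normalize = TRUE, dropConstant = TRUE) {
  M <- .moduleMatrix(X, standardize)
  if (is.null(d)) d <- ncol(M)
  sq <- rowSums(M^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(M)
  D2[D2 < 0] <- 0
  K <- exp(-D2 / d)
  if (dropConstant) K <- K - min(K)
  .newKernel("gaussian", kernel = K, normalize = normalize)
}

#' @rdname accessors
setMethod("kernelMatrix", "KernelMatrix", function(x) x@kernel)
#' @rdname accessors
setMethod("kernelKind", "KernelMatrix", function(x) x@kind)
#' @rdname accessors
setMethod("kernelFactor", "KernelMatrix", function(x) x@factor)

setMethod("show", "KernelMatrix", function(object) {
  cat(sprintf("KernelMatrix (%s): %d x %d%s%s\n", object@kind,
              nrow(object@kernel), ncol(object@kernel),
              if (ncol(object@factor)) sprintf(", rank <= %d",
                                               ncol(object@factor)) else "",
              if (object@psdRepaired) ", PSD-repaired" else ""))
})
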