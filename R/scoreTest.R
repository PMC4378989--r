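#' @include reml.R
NULL

## stat, mean e and variance v of T = Y'P K P Y / 2 under the fitted null,
## using the low-rank route when both the fit and the target carry factors
.scorePieces <- function(fit, kernel) {
  stopifnot(is(fit, "NullFit"), is(kernel, "KernelMatrix"))
  if (nrow(kernel@kernel) != fit@n)
    stop("target kernel dimension does not match the fit")
  ctx <- fit@solver$ctx
  if (ctx$path == "lowrank" && ncol(kernel@factor) > 0)
    return(.lrScore(ctx, fit@solver$core, kernel@factor))
  if (ctx$path == "dense")
    return(.denseScore(ctx, fit@solver$core, kernel@kernel))
  ## low-rank fit, factor-less target: materialize P once
  P <- projectionMatrix(fit)
  y <- ctx$y
  Py <- drop(P %*% y)
  PK <- P %*% kernel@kernel
  PK2 <- PK %*% PK
  list(stat = sum(Py * drop(kernel@kernel %*% Py)) / 2,
       e = sum(diag(PK)) / 2, v = sum(PK * t(PK)) / 2,
       q3 = sum(PK2 * t(PK)), q4 = sum(PK2 * t(PK2)),
       P = P, Kt = kernel@kernel)
}

## eigenvalues of the half-form: the null of T = Y'PKPY/2 is
## sum_i lam_i chi^2_1 with lam the non-zero eigenvalues of K P / 2
.scoreLambda <- function(sp) {
  if (!is.null(sp$S))
    return(eigen((sp$S + t(sp$S)) / 2, symmetric = TRUE,
                 only.values = TRUE)$values / 2)
  ## dense: non-zero eigenvalues of K P equal those of K^{1/2} P K^{1/2}
  ek <- eigen((sp$Kt + t(sp$Kt)) / 2, symmetric = TRUE)
  lam <- pmax(ek$values, 0)
  half <- ek$vectors %*% (sqrt(lam) * t(ek$vectors))
  M <- half %*% sp$P %*% half
  eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values / 2
}

## Imhof's integral for the upper tail of a weighted sum of chi-squares
.imhofTail <- function(x, lam) {
  lam <- lam[abs(lam) > 1e-12 * max(abs(lam), 1e-300)]
  if (!length(lam)) return(NA_real_)
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * x * u
    rho <- exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                     subdivisions = 1000L)$value,
    error = function(e) NA_real_)
  if (!is.finite(val)) return(NA_real_)
  p <- 0.5 + val / pi
  if (p < 1e-9 || p > 1) return(NA_real_)  # integration resolution limit
  p
}

#' Score statistic for a target kernel under a fitted null
#'
#' Computes \eqn{T = Y' P K P Y / 2}, where P is the REML projection of
#' the null fit and K the kernel of the effect being tested (K12 for the
#' interaction test, K1 or K2 for a conditional test). Non-negative
#' whenever K is positive semidefinite, and invariant to replacing Y by
#' Y + Zc (P annihilates the covariates).
#'
#' @param fit a \linkS4class{NullFit}.
#' @param kernel the target \linkS4class{KernelMatrix}.
#' @return the scalar statistic.
#' @export
scoreStatistic <- function(fit, kernel) {
  .scorePieces(fit, kernel)$stat
}

## four-moment (Liu-style) match of the quadratic form to a shifted,
## scaled, possibly noncentral chi-square; c_k = tr((KP)^k)/2^k
.liuParams <- function(sp) {
  c1 <- sp$e; c2 <- sp$v / 2; c3 <- sp$q3 / 8; c4 <- sp$q4 / 16
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    ncp <- 0
    df <- 1 / s2
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), df = df, ncp = ncp,
       muX = df + ncp, sigmaX = sqrt(2 * (df + 2 * ncp)))
}

.liuPValue <- function(statistic, lp) {
  q <- (statistic - lp$muQ) / lp$sigmaQ * lp$sigmaX + lp$muX
  stats::pchisq(q, df = lp$df, ncp = lp$ncp, lower.tail = FALSE)
}

#' Weighted chi-squared p-value for the score statistic
#'
#' Under the fitted null, \eqn{T = Y'PKPY/2} is a weighted sum of
#' chi-squares with weights given by the spectrum of \eqn{KP/2}. The
#' default \code{method = "exact"} evaluates that distribution's upper
#' tail directly by numerical integration over the fitted spectrum
#' (Imhof's formula), falling back to the four-moment match when the
#' integral cannot be resolved (e.g. p-values beyond the integration
#' resolution). \code{method = "liu"} matches mean, variance, skewness
#' and kurtosis to a shifted, scaled (possibly noncentral) chi-square;
#' \code{method = "satterthwaite"} is the classical two-moment match to
#' \eqn{\kappa\chi^2_\nu} with \eqn{\nu = 2e^2/v}, \eqn{\kappa = v/(2e)},
#' \eqn{e = tr(PK)/2}, \eqn{v = tr((PK)^2)/2}. When K has a single
#' non-zero eigenvalue all three reduce to the exact scaled
#' \eqn{\chi^2_1}. The returned \code{kappa} and \code{df} are the
#' matched-moment parameters regardless of method, for reporting.
#'
#' @param fit a \linkS4class{NullFit}.
#' @param kernel the target \linkS4class{KernelMatrix}.
#' @param statistic optional pre-computed statistic; computed when NULL.
#' @param method see above.
#' @return list with \code{statistic}, \code{pValue}, matched scale
#'   \code{kappa}, degrees of freedom \code{df}, noncentrality \code{ncp},
#'   and the \code{method} that produced the p-value.
#' @export
pValueWeightedChisq <- function(fit, kernel, statistic = NULL,
                                method = c("exact", "liu",
                                           "satterthwaite")) {
  method <- match.arg(method)
  sp <- .scorePieces(fit, kernel)
  if (is.null(statistic)) statistic <- sp$stat
  if (sp$e <= 0 || sp$v <= 0) {
    warning("degenerate target kernel under the null (e = ",
            format(sp$e, digits = 3), ", v = ",
            format(sp$v, digits = 3), "); p-value set to 1")
    return(list(statistic = statistic, pValue = 1, kappa = NA_real_,
                df = NA_real_, ncp = NA_real_, method = method))
  }
  lp <- .liuParams(sp)
  kappa <- lp$sigmaQ / lp$sigmaX
  if (statistic <= 0)  # T = 0 is the lower support point
    return(list(statistic = statistic, pValue = 1, kappa = kappa,
                df = lp$df, ncp = lp$ncp, method = method))
  if (method == "satterthwaite") {
    df <- 2 * sp$e^2 / sp$v
    k2 <- sp$v / (2 * sp$e)
    p <- stats::pchisq(statistic / k2, df = df, lower.tail = FALSE)
    return(list(statistic = statistic,
                pValue = max(p, .Machine$double.xmin), kappa = k2,
                df = df, ncp = 0, method = method))
  }
  p <- NA_real_
  used <- method
  if (method == "exact") {
    p <- .imhofTail(statistic, .scoreLambda(sp))
    if (is.na(p)) used <- "liu"
  }
  if (is.na(p)) p <- .liuPValue(statistic, lp)
  list(statistic = statistic, pValue = max(p, .Machine$double.xmin),
       kappa = kappa, df = lp$df, ncp = lp$ncp, method = used)
}

.makeResult <- function(test, fit, kernel) {
  pv <- pValueWeightedChisq(fit, kernel)
  new("KmTestResult", test = test, statistic = pv$statistic,
      pValue = pv$pValue, kappa = pv$kappa, df = pv$df, fit = fit)
}

#' Module-module interaction and conditional module tests
#'
#' \code{testInteraction} tests \eqn{H_0: h_{12}(\cdot) = 0}: the null
#' model estimates \eqn{(\tau_1, \tau_2, \sigma)} with
#' \eqn{\tau_{12} = 0}, and the score statistic uses the interaction
#' kernel K12. \code{testConditional} tests one module's effect while
#' adjusting for the other without constraining it, with the interaction
#' fixed at zero throughout: for module 1, \eqn{H_0: h_1(\cdot) = 0} with
#' \eqn{V_1 = \tau_2 K_2 + \sigma I} and target kernel K1.
#'
#' @param model a \linkS4class{KmModel}.
#' @param module which module's conditional effect to test (1 or 2).
#' @param control see \code{\link{kmControl}}.
#' @return a \linkS4class{KmTestResult}.
#' @examples
#' set.seed(1)
#' net <- generateScaleFreeModule(8)
#' X1 <- simulateModuleData(net, 60)
#' X2 <- simulateModuleData(net, 60)
#' tom <- topologicalOverlap(net)
#' K1 <- topologyKernel(X1, tom); K2 <- topologyKernel(X2, tom)
#' m <- kmModel(rnorm(60), K1, K2)
#' testInteraction(m)
#' @export
testInteraction <- function(model, control = kmControl()) {
  fit <- fitNullREML(model, "interaction", control)
  .makeResult("interaction", fit, model@K12)
}

#' @rdname testInteraction
#' @export
testConditional <- function(model, module = 1, control = kmControl()) {
  stopifnot(module %in% c(1, 2))
  if (module == 1) {
    fit <- fitNullREML(model, "module1", control)
    .makeResult("module1", fit, model@K1)
  } else {
    fit <- fitNullREML(model, "module2", control)
    .makeResult("module2", fit, model@K2)
  }
}

#' @rdname accessors
setMethod("testStatistic", "KmTestResult", function(x) x@statistic)
#' @rdname accessors
setMethod("pValue", "KmTestResult", function(x) x@pValue)

setMethod("show", "KmTestResult", function(object) {
  lab <- switch(object@test,
                interaction = "interaction (H0: h12 = 0)",
                module1 = "module 1 given module 2 (H0: h1 = 0)",
                module2 = "module 2 given module 1 (H0: h2 = 0)")
  cat("Kernel machine score test:", lab, "\n")
  cat(sprintf("  T = %.4f, matched kappa*chi2(df): kappa = %.4g, df = %.3f\n",
              object@statistic, object@kappa, object@df))
  cat(sprintf("  p-value = %.4g\n", object@pValue))
  vc <- varianceComponents(object@fit)
  cat("  null fit: ",
      paste(sprintf("%s = %.3g", names(vc), vc), collapse = ", "),
      if (object@fit@converged) "" else "  [not converged]", "\n", sep = "")
})

#' Tidy a test result into a one-row data.frame
#'
#' @param result a \linkS4class{KmTestResult}.
#' @return data.frame with test, statistic, df, kappa, p-value, variance
#'   components and convergence metadata.
#' @export
resultAsData <- function(result) {
  stopifnot(is(result, "KmTestResult"))
  vc <- varianceComponents(result@fit)
  data.frame(test = result@test, statistic = result@statistic,
             df = result@df, kappa = result@kappa, p.value = result@pValue,
             tau1 = vc[["tau1"]], tau2 = vc[["tau2"]],
             tau12 = vc[["tau12"]], sigma = vc[["sigma"]],
             converged = result@fit@converged, n.iter = result@fit@nIter,
             stringsAsFactors = FALSE)
}
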