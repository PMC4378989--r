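#' @include kernels.R
NULL

#' Assemble the inputs of the two-module kernel machine regression
#'
#' @param y numeric continuous trait vector.
#' @param covariates optional n x q matrix or data.frame of covariates
#'   (no intercept column; one is added).
#' @param K1,K2 main-effect \linkS4class{KernelMatrix} objects for the two
#'   modules.
#' @param K12 interaction kernel; defaults to
#'   \code{interactionKernel(K1, K2)}.
#' @return a \linkS4class{KmModel}.
#' @export
kmModel <- function(y, K1, K2, covariates = NULL,
                    K12 = interactionKernel(K1, K2)) {
  y <- as.numeric(y)
  n <- length(y)
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (is.null(colnames(C))) colnames(C) <- paste0("z", seq_len(ncol(C)))
    Z <- cbind(Z, C)
  }
  new("KmModel", y = y, Z = Z, K1 = K1, K2 = K2, K12 = K12)
}

#' Control parameters for the REML/EM fitter
#'
#' @param tol relative parameter-change convergence tolerance.
#' @param maxIter iteration cap; hitting it flags the fit as
#'   non-converged (warning, not an error).
#' @param accelerate extrapolate along the EM direction with doubling step
#'   sizes, accepting only candidates that do not decrease the restricted
#'   log-likelihood. Plain EM decays boundary components only harmonically;
#'   acceleration keeps the monotonicity guarantee while converging fast.
#' @param floorFrac variance components are floored at
#'   \code{floorFrac * var(y)} during iteration; a component ending at the
#'   floor is reported as 0.
#' @param maxDoublings cap on step doublings per iteration.
#' @return a list of control values.
#' @export
kmControl <- function(tol = 1e-6, maxIter = 500L, accelerate = TRUE,
                      floorFrac = 1e-8, maxDoublings = 40L) {
  list(tol = tol, maxIter = as.integer(maxIter), accelerate = accelerate,
       floorFrac = floorFrac, maxDoublings = as.integer(maxDoublings))
}

## --- low-rank (Gram) solver ------------------------------------------------
## All active kernels have K_k = C_k C_k'.  With B = [sqrt(tau_k) C_k] and
## M = sigma I_r + B'B, Woodbury gives V^-1 = (I - B M^-1 B')/sigma, and every
## quantity the EM step and the score moments need reduces to r- and
## q-dimensional Gram algebra; n enters only in a one-time precompute.

.lrContext <- function(y, Z, factors) {
  Call <- do.call(cbind, factors)
  r <- ncol(Call)
  ends <- cumsum(vapply(factors, ncol, 1L))
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- Map(function(s, e) seq.int(s, e), starts, ends)
  list(path = "lowrank", y = y, Z = Z, n = length(y), q = ncol(Z),
       Call = Call, r = r, blocks = blocks,
       G = crossprod(Call), CtZ = crossprod(Call, Z),
       Cty = drop(crossprod(Call, y)),
       ZtZ = crossprod(Z), Zty = drop(crossprod(Z, y)), yty = sum(y * y))
}

.lrCore <- function(ctx, taus, sigma) {
  svec <- rep(sqrt(taus), times = vapply(ctx$blocks, length, 1L))
  BtB <- outer(svec, svec) * ctx$G
  M <- BtB
  diag(M) <- diag(M) + sigma
  cM <- chol(M)
  Mi <- chol2inv(cM)
  BtZ <- svec * ctx$CtZ
  Bty <- svec * ctx$Cty
  MiBty <- drop(Mi %*% Bty)
  MiBtZ <- Mi %*% BtZ
  ZtViZ <- (ctx$ZtZ - crossprod(BtZ, MiBtZ)) / sigma
  ZtViy <- (ctx$Zty - drop(crossprod(BtZ, MiBty))) / sigma
  yViy <- (ctx$yty - sum(Bty * MiBty)) / sigma
  cZ <- chol((ZtViZ + t(ZtViZ)) / 2)
  a <- backsolve(cZ, backsolve(cZ, ZtViy, transpose = TRUE))
  yPy <- yViy - sum(ZtViy * a)
  logdetV <- (ctx$n - ctx$r) * log(sigma) + 2 * sum(log(diag(cM)))
  logdetZ <- 2 * sum(log(diag(cZ)))
  list(taus = taus, sigma = sigma, svec = svec, Mi = Mi, BtZ = BtZ,
       Bty = Bty, MiBty = MiBty, MiBtZ = MiBtZ, ZtViZ = ZtViZ, cZ = cZ,
       a = a, yPy = yPy,
       loglik = -0.5 * (logdetV + logdetZ + yPy))
}

.lrMoments <- function(ctx, co) {
  sigma <- co$sigma
  GS <- sweep(ctx$G, 2L, co$svec, "*")           # C'B
  CtViy <- (ctx$Cty - drop(GS %*% co$MiBty)) / sigma
  CtViZ <- (ctx$CtZ - GS %*% co$MiBtZ) / sigma
  CtPy <- CtViy - drop(CtViZ %*% co$a)
  CtViC <- (ctx$G - GS %*% co$Mi %*% t(GS)) / sigma
  H <- backsolve(co$cZ, t(CtViZ), transpose = TRUE)  # cZ'^-1 (CtViZ)'
  CtPCdiag <- diag(CtViC) - colSums(H^2)
  quad <- vapply(ctx$blocks, function(b) sum(CtPy[b]^2), 0)
  trPK <- vapply(ctx$blocks, function(b) sum(CtPCdiag[b]), 0)
  ## tr(P) and y'P^2y via V^-2 Gram identities
  trVi <- (ctx$n - ctx$r + sigma * sum(diag(co$Mi))) / sigma
  Mi2BtZ <- co$Mi %*% co$MiBtZ
  ZtVi2Z <- (ctx$ZtZ - crossprod(co$BtZ, co$MiBtZ) -
               sigma * crossprod(co$BtZ, Mi2BtZ)) / sigma^2
  trP <- trVi - sum(diag(backsolve(co$cZ, backsolve(co$cZ, ZtVi2Z,
                                                    transpose = TRUE))))
  Mi2Bty <- drop(co$Mi %*% co$MiBty)
  yVi2y <- (ctx$yty - sum(co$Bty * co$MiBty) -
              sigma * sum(co$Bty * Mi2Bty)) / sigma^2
  ZtVi2y <- (ctx$Zty - drop(crossprod(co$BtZ, co$MiBty)) -
               sigma * drop(crossprod(co$BtZ, Mi2Bty))) / sigma^2
  yPPy <- yVi2y - 2 * sum(co$a * ZtVi2y) +
    sum(co$a * drop(ZtVi2Z %*% co$a))
  list(quad = quad, trPK = trPK, trP = trP, yPPy = yPPy)
}

## score statistic and spectral moments q_k = tr((K P)^k), k = 1..4, of
## Y'P K P Y / 2 for a factored target; with K = CC', tr((KP)^k) = tr(S^k)
## for the small matrix S = C'PC
.lrScore <- function(ctx, co, Ct) {
  sigma <- co$sigma
  CtC <- crossprod(Ct, ctx$Call)
  CtB <- sweep(CtC, 2L, co$svec, "*")
  CtZ <- crossprod(Ct, ctx$Z)
  Cty <- drop(crossprod(Ct, ctx$y))
  CtViy <- (Cty - drop(CtB %*% co$MiBty)) / sigma
  CtViZ <- (CtZ - CtB %*% co$MiBtZ) / sigma
  CtPy <- CtViy - drop(CtViZ %*% co$a)
  CtViCt <- (crossprod(Ct) - CtB %*% co$Mi %*% t(CtB)) / sigma
  H <- backsolve(co$cZ, t(CtViZ), transpose = TRUE)
  S <- CtViCt - crossprod(H)
  S2 <- S %*% S
  list(stat = sum(CtPy^2) / 2, e = sum(diag(S)) / 2, v = sum(S * S) / 2,
       q3 = sum(S2 * S), q4 = sum(S2 * S2), S = S)
}

## --- dense solver ----------------------------------------------------------

.denseContext <- function(y, Z, Ks) {
  list(path = "dense", y = y, Z = Z, n = length(y), q = ncol(Z), Ks = Ks)
}

.denseCore <- function(ctx, taus, sigma) {
  V <- diag(sigma, ctx$n)
  for (k in seq_along(ctx$Ks)) V <- V + taus[k] * ctx$Ks[[k]]
  cV <- chol(V)
  Vi <- chol2inv(cV)
  ViZ <- Vi %*% ctx$Z
  ZtViZ <- crossprod(ctx$Z, ViZ)
  cZ <- chol((ZtViZ + t(ZtViZ)) / 2)
  P <- Vi - ViZ %*% chol2inv(cZ) %*% t(ViZ)
  P <- (P + t(P)) / 2
  Py <- drop(P %*% ctx$y)
  yPy <- sum(ctx$y * Py)
  list(taus = taus, sigma = sigma, P = P, Py = Py, yPy = yPy, V = V,
       loglik = -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cZ))) +
                          yPy))
}

.denseMoments <- function(ctx, co) {
  quad <- vapply(ctx$Ks, function(K) sum(co$Py * drop(K %*% co$Py)), 0)
  trPK <- vapply(ctx$Ks, function(K) sum(co$P * K), 0)
  list(quad = quad, trPK = trPK, trP = sum(diag(co$P)),
       yPPy = sum(co$Py^2))
}

.denseScore <- function(ctx, co, Kt) {
  PK <- co$P %*% Kt
  PK2 <- PK %*% PK
  list(stat = sum(co$Py * drop(Kt %*% co$Py)) / 2,
       e = sum(diag(PK)) / 2, v = sum(PK * t(PK)) / 2,
       q3 = sum(PK2 * t(PK)), q4 = sum(PK2 * t(PK2)),
       P = co$P, Kt = Kt)
}

.solveCore <- function(ctx, taus, sigma) {
  if (ctx$path == "lowrank") .lrCore(ctx, taus, sigma)
  else .denseCore(ctx, taus, sigma)
}

.solveMoments <- function(ctx, co) {
  if (ctx$path == "lowrank") .lrMoments(ctx, co)
  else .denseMoments(ctx, co)
}

## flat-ridge diagnostic: a kernel numerically proportional to the identity
## with an intercept-only design leaves only tau + sigma identifiable
.checkRidge <- function(Z, kernels) {
  interceptOnly <- ncol(Z) == 1L && max(abs(Z - Z[1])) < 1e-12
  if (!interceptOnly) return(invisible(FALSE))
  for (K in kernels) {
    Kd <- K@kernel
    c0 <- mean(diag(Kd))
    if (max(abs(Kd - diag(c0, nrow(Kd)))) < 1e-8 * max(c0, 1)) {
      warning("kernel '", K@kind, "' is numerically proportional to the ",
              "identity with an intercept-only design: only the total ",
              "variance is identifiable (flat likelihood ridge)")
      return(invisible(TRUE))
    }
  }
  invisible(FALSE)
}

#' Fit the mixed model under a specified null by REML/EM
#'
#' Under the interaction null, \eqn{\tau_{12} = 0} and
#' \eqn{(\tau_1, \tau_2, \sigma)} are estimated with
#' \eqn{V_{12} = \tau_1 K_1 + \tau_2 K_2 + \sigma I}. Under the
#' conditional null for module 1, \eqn{\tau_1 = \tau_{12} = 0} and
#' \eqn{(\tau_2, \sigma)} are estimated with
#' \eqn{V_1 = \tau_2 K_2 + \sigma I}; symmetrically for module 2.
#'
#' The EM step for each free component is
#' \eqn{\tau' = \tau + \tau^2 (y'PKPy - tr(PK))/n} (and the analogue with
#' \eqn{K = I} for \eqn{\sigma}), where P is the REML projection of the
#' current iterate. The restricted log-likelihood is non-decreasing over
#' iterations. When every active kernel carries a low-rank factor the fit
#' runs entirely on Gram matrices (cost O(r^3) per iteration after a
#' one-time O(n r^2) precompute); otherwise a dense path is used.
#'
#' @param model a \linkS4class{KmModel}.
#' @param whichNull "interaction", "module1" (null for testing module 1
#'   given module 2) or "module2".
#' @param control see \code{\link{kmControl}}.
#' @return a \linkS4class{NullFit}.
#' @export
fitNullREML <- function(model,
                        whichNull = c("interaction", "module1", "module2"),
                        control = kmControl()) {
  stopifnot(is(model, "KmModel"))
  whichNull <- match.arg(whichNull)
  active <- switch(whichNull,
    interaction = list(tau1 = model@K1, tau2 = model@K2),
    module1 = list(tau2 = model@K2),
    module2 = list(tau1 = model@K1))
  y <- model@y; Z <- model@Z; n <- length(y)
  .checkRidge(Z, active)

  useLR <- all(vapply(active, function(K) ncol(K@factor) > 0, TRUE)) &&
    sum(vapply(active, function(K) ncol(K@factor), 1L)) < n
  ctx <- if (useLR) .lrContext(y, Z, lapply(active, slot, "factor"))
         else .denseContext(y, Z, lapply(active, slot, "kernel"))

  varY <- stats::var(y)
  floorVal <- control$floorFrac * varY
  nA <- length(active)
  theta <- rep(varY / (nA + 1), nA + 1L)  # (taus, sigma)

  emStep <- function(theta, mom) {
    taus <- theta[seq_len(nA)]; sigma <- theta[nA + 1L]
    newTaus <- taus + taus^2 * (mom$quad - mom$trPK) / n
    newSigma <- sigma + sigma^2 * (mom$yPPy - mom$trP) / n
    pmax(c(newTaus, newSigma), floorVal)
  }

  core <- .solveCore(ctx, theta[seq_len(nA)], theta[nA + 1L])
  traj <- core$loglik
  converged <- FALSE
  iter <- 0L
  stagnant <- 0L
  while (iter < control$maxIter) {
    iter <- iter + 1L
    mom <- .solveMoments(ctx, core)
    prop <- emStep(theta, mom)
    dir <- prop - theta
    best <- list(theta = prop,
                 core = .solveCore(ctx, prop[seq_len(nA)], prop[nA + 1L]))
    if (control$accelerate && any(dir != 0)) {
      alpha <- 2
      prev <- best$core$loglik
      for (d in seq_len(control$maxDoublings)) {
        cand <- pmax(theta + alpha * dir, floorVal)
        candCore <- try(.solveCore(ctx, cand[seq_len(nA)],
                                   cand[nA + 1L]), silent = TRUE)
        if (inherits(candCore, "try-error")) break
        if (candCore$loglik < prev - 1e-12 * (1 + abs(prev))) break
        if (candCore$loglik >= best$core$loglik)
          best <- list(theta = cand, core = candCore)
        prev <- candCore$loglik
        if (all(cand == pmax(theta + 2 * alpha * dir, floorVal))) break
        alpha <- 2 * alpha
      }
    }
    ## guard: never accept a decrease (plain EM is monotone in theory;
    ## this protects against numerical dust)
    if (best$core$loglik < core$loglik) best <- list(theta = theta,
                                                     core = core)
    rel <- abs(best$theta - theta) / pmax(abs(theta), floorVal)
    gain <- best$core$loglik - core$loglik
    theta <- best$theta
    core <- best$core
    traj <- c(traj, core$loglik)
    if (max(rel) < control$tol) { converged <- TRUE; break }
    ## secondary stop: the restricted likelihood has stopped improving to
    ## numerical resolution (flat ridge or boundary); treat as converged
    stagnant <- if (gain < 1e-8 * (1 + abs(core$loglik))) stagnant + 1L
                else 0L
    if (stagnant >= 2L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML/EM did not converge in ", control$maxIter,
            " iterations (", whichNull, " null); result is flagged")

  ## snap floored components to zero and refit the final state
  taus <- theta[seq_len(nA)]; sigma <- theta[nA + 1L]
  taus[taus <= 10 * floorVal] <- 0  # ended at (or vanishingly near) the floor
  core <- .solveCore(ctx, taus, sigma)

  tau <- c(tau1 = 0, tau2 = 0, tau12 = 0)
  tau[names(active)] <- taus
  new("NullFit", whichNull = whichNull, tau = tau, sigma = sigma,
      logLik = traj, converged = converged, nIter = iter, n = as.integer(n),
      solver = list(ctx = ctx, core = core, active = active))
}

## --- accessors & materializers --------------------------------------------

#' @rdname accessors
setMethod("varianceComponents", "NullFit",
          function(x) c(x@tau, sigma = x@sigma))

setMethod("nullCovariance", "NullFit", function(fit) {
  n <- fit@n
  V <- diag(fit@sigma, n)
  taus <- fit@tau[names(fit@solver$active)]
  for (k in seq_along(fit@solver$active))
    V <- V + taus[k] * fit@solver$active[[k]]@kernel
  V
})

setMethod("projectionMatrix", "NullFit", function(fit) {
  ctx <- fit@solver$ctx
  if (ctx$path == "dense") return(fit@solver$core$P)
  co <- fit@solver$core
  B <- sweep(ctx$Call, 2L, co$svec, "*")
  Vi <- (diag(ctx$n) - B %*% co$Mi %*% t(B)) / co$sigma
  ViZ <- Vi %*% ctx$Z
  P <- Vi - ViZ %*% chol2inv(co$cZ) %*% t(ViZ)
  (P + t(P)) / 2
})

setMethod("show", "NullFit", function(object) {
  cat(sprintf("NullFit (%s null): n = %d, %sconverged in %d iterations\n",
              object@whichNull, object@n,
              if (object@converged) "" else "NOT ", object@nIter))
  vc <- varianceComponents(object)
  cat("  ", paste(sprintf("%s = %.4g", names(vc), vc), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  restricted logLik: %.4f\n", tail(object@logLik, 1L)))
})
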