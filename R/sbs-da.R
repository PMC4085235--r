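# Degree-of-advancement variant: per-step moment ODEs for the reaction
# counts under first-order closure, dual Neville tables (mean + variance),
# hybrid Poisson/Gaussian sampling; plus the unbiased tau-leap comparator.

#' Right-hand side of the per-step reaction-count moment ODEs
#'
#' First-order-closure evolution of the mean \eqn{\mu_j} and variance
#' \eqn{V_j} of the number of firings of each reaction over one step, with
#' coefficients frozen at the step-start state \eqn{X_n}:
#' \deqn{d\mu_j/ds = \sum_{j'} f_{jj'}(X_n)\,\mu_{j'} + a_j(X_n), \qquad
#'   dV_j/ds = 2 f_{jj}(X_n) V_j + d\mu_j/ds,}
#' with \eqn{\mu_j(0) = V_j(0) = 0}.  Exact for linear propensities; for
#' non-linear ones the propensities are Taylor-expanded and truncated at
#' first order.
#'
#' @param sys a \linkS4class{ReactionSystem}.
#' @param xn step-start state (frozen).
#' @param mu,var current moment vectors (length M).
#' @return list with \code{dmu} and \code{dvar}.
#' @export
momentRhs <- function(sys, xn, mu, var) {
  f <- reactionCouplingMatrix(sys, xn)
  a <- propensities(sys, xn)
  dmu <- drop(f %*% mu) + a
  dvar <- 2 * diag(f) * var + dmu
  list(dmu = dmu, dvar = dvar)
}

# internal: integrate the frozen-coefficient moment ODEs with the MMP,
# returning the stacked (mu, var) endpoint; no admissibility check (the
# state here is a moment vector, not a population)
.momentIntegral <- function(sys, xn, tau, nSub, frozen = NULL) {
  M <- nReactions(sys)
  if (tau == 0) return(list(ok = TRUE, value = numeric(2L * M), nEvals = 0L))
  if (is.null(frozen)) frozen <- .freezeMoments(sys, xn)
  f <- frozen$f; a <- frozen$a; fDiag <- frozen$fDiag
  iMu <- seq_len(M); iV <- M + iMu
  rhs <- function(y) {
    dmu <- drop(f %*% y[iMu]) + a
    c(dmu, 2 * fDiag * y[iV] + dmu)
  }
  # the shared start-state value rhs(0) = (a, a) costs nothing to restate
  res <- .mmp(rhs, numeric(2L * M), tau, as.integer(nSub),
              checkNonneg = FALSE, drift0 = c(a, a))
  list(ok = res$ok, value = res$smoothed, nEvals = res$nEvals)
}

# coupling matrix and propensities frozen at the step-start state
.freezeMoments <- function(sys, xn) {
  f <- reactionCouplingMatrix(sys, xn)
  list(f = f, a = propensities(sys, xn), fDiag = diag(f))
}

#' Integrate the per-step moment ODEs
#'
#' Solves the frozen-coefficient system of \code{\link{momentRhs}} over
#' \eqn{[0, \tau]} with the modified midpoint method (\code{nSub}
#' substeps, Gragg-smoothed endpoint), initial conditions
#' \eqn{\mu = V = 0}.  The variance is clamped at zero on output.
#'
#' @inheritParams momentRhs
#' @param tau step length (>= 0).
#' @param nSub even substep count.
#' @return list with \code{mu} and \code{var} (length-M numeric vectors).
#' @export
integrateMoments <- function(sys, xn, tau, nSub) {
  stopifnot(tau >= 0)
  res <- .momentIntegral(sys, xn, tau, nSub)
  if (!res$ok) stop("modified midpoint failure in moment integration")
  M <- nReactions(sys)
  list(mu = res$value[seq_len(M)], var = pmax(res$value[M + seq_len(M)], 0))
}

#' Hybrid Poisson/Gaussian reaction-count sampling
#'
#' Per reaction channel: \eqn{K_j \sim} Poisson\eqn{(\mu_j)} when
#' \eqn{\mu_j < 10}; otherwise \eqn{K_j} is a Normal\eqn{(\mu_j, V_j)}
#' draw rounded to the nearest integer (half-up) and clamped at zero.  The
#' threshold ten is the conventional point above which a Poisson sample is
#' well represented by a matched Gaussian.
#'
#' @param mu non-negative means (length M).
#' @param var non-negative variances (length M).
#' @return integer vector of M non-negative counts.
#' @export
hybridSample <- function(mu, var) {
  stopifnot(length(mu) == length(var), all(mu >= 0), all(var >= 0))
  K <- numeric(length(mu))
  pois <- mu < 10
  if (any(pois)) K[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    z <- rnorm(sum(!pois), mu[!pois], sqrt(var[!pois]))
    K[!pois] <- pmax(floor(z + 0.5), 0)
  }
  K
}

#' Single adaptive SBS-DA step
#'
#' Control flow identical to \code{\link{sbsStep}}, but the Neville
#' machinery extrapolates the per-step mean/variance pairs of the reaction
#' counts (two tables, built jointly; convergence is gated on the scaled
#' error of the mean table, and the variance inherits the accepted
#' column), and \code{\link{hybridSample}} replaces the pure Poisson draw.
#' A negative extrapolated mean is clamped to zero with a warning.
#'
#' @inheritParams sbsStep
#' @return as \code{\link{sbsStep}}.
#' @export
sbsDaStep <- function(sys, x, tau, settings = solverSettings(),
                      kTarget = NA_integer_) {
  stopifnot(tau > 0)
  M <- nReactions(sys)
  if (.allQuiet(sys, x)) {
    return(list(state = x, tauUsed = tau, kConverged = 1L, rejections = 0L,
                work = 0L, extrapolated = numeric(2L * M),
                counts = integer(M), kNext = 2L, tauNext = tau))
  }
  frozen <- .freezeMoments(sys, x)
  .adaptiveStep(sys, x, tau, settings, kTarget, Inf, baseWork = 1L,
    firstColumnFn = function(tt, nSub) .momentIntegral(sys, x, tt, nSub,
                                                       frozen),
    errFn = function(table, q) .muColumnError(table, q, M, settings@atol,
                                              settings@rtol),
    sampleFn = function(extr, q) {
      mu <- extr[seq_len(M)]
      if (any(mu < -1e-8 * max(1, max(abs(mu)))))
        warning("negative extrapolated mean clamped to zero")
      mu <- pmax(mu, 0)
      v <- pmax(extr[M + seq_len(M)], 0)
      list(counts = hybridSample(mu, v))
    })
}

# column error restricted to the mean block of the stacked (mu, var) entries
.muColumnError <- function(table, q, M, atol, rtol) {
  top <- table$entries[[q]][[q]][seq_len(M)]
  second <- table$entries[[q]][[q - 1L]][seq_len(M)]
  sqrt(sum((top - second)^2)) / (atol + rtol * sqrt(sum(top^2)))
}

#' Adaptive SBS-DA simulation
#'
#' Degree-of-advancement run to exactly \code{T}; see
#' \code{\link{sbsDaStep}} for the per-step mechanics and
#' \code{\link{sbsSimulate}} for the shared adaptive control.
#'
#' @inheritParams sbsSimulate
#' @return a \linkS4class{Trajectory}.
#' @export
sbsDaSimulate <- function(sys, x0, T, settings = solverSettings(),
                          t0 = 0, saveTrajectory = TRUE,
                          engine = c("R", "compiled")) {
  engine <- match.arg(engine)
  if (engine == "compiled")
    return(.sbsTrajectory(sys, x0, T, settings, t0, saveTrajectory, TRUE))
  .adaptiveSimulate(sys, x0, T, settings, t0,
                    function(x, tau, kTarget)
                      sbsDaStep(sys, x, tau, settings, kTarget),
                    "sbsda", saveTrajectory)
}

#' Fixed-stepsize, fixed-column SBS-DA
#'
#' Order-study variant of the SBS-DA: every step integrates the moment
#' ODEs at columns 1..\code{k}, extrapolates, and applies the hybrid
#' update with stepsize exactly \code{tau}.
#'
#' @inheritParams sbsFixed
#' @return a \linkS4class{Trajectory}.
#' @export
sbsDaFixed <- function(sys, x0, T, tau, k = 1L, t0 = 0,
                       saveTrajectory = TRUE) {
  nSteps <- (T - t0) / tau
  stopifnot(abs(nSteps - round(nSteps)) < 1e-9, k >= 1L)
  nSteps <- round(nSteps)
  x <- as.numeric(x0); t <- t0
  times <- t; states <- list(x)
  nuEff <- effectiveNetChange(sys)
  M <- nReactions(sys)
  for (s in seq_len(nSteps)) {
    mom <- .sbsDaFixedMoments(sys, x, tau, k)
    K <- hybridSample(mom$mu, mom$var)
    x <- x + drop(nuEff %*% K)
    if (any(x < 0))
      stop("negative population in fixed-step SBS-DA realisation")
    t <- t0 + s * tau
    if (saveTrajectory) { times <- c(times, t); states <- c(states, list(x)) }
  }
  if (!saveTrajectory) { times <- c(times, T); states <- c(states, list(x)) }
  newTrajectory(times, do.call(rbind, states), "sbsda_fixed")
}

# deterministic extrapolated (mu, var) of one fixed-step SBS-DA step
.sbsDaFixedMoments <- function(sys, x, tau, k) {
  M <- nReactions(sys)
  frozen <- .freezeMoments(sys, x)
  table <- nevilleTable()
  for (q in seq_len(k)) {
    fc <- .momentIntegral(sys, x, tau, 2L * q, frozen)
    if (!fc$ok) stop("modified midpoint failure in fixed-step SBS-DA")
    table <- nevilleExtend(table, fc$value, 2L * q)
  }
  extr <- nevilleTop(table, k)
  list(mu = pmax(extr[seq_len(M)], 0), var = pmax(extr[M + seq_len(M)], 0))
}

#' Unbiased tau-leap simulation
#'
#' Comparator that combines the tau-leap's leap-condition stepsize
#' selection with accurate per-step reaction-count moments: at each step
#' \eqn{\tau} comes from \code{\link{tauSelect}}, the moment ODEs are
#' integrated at high fixed resolution (8 and 16 substeps with one
#' extrapolation), and the state is updated with
#' \code{\link{hybridSample}}.
#'
#' @inheritParams tauLeapSimulate
#' @param epsilon leap-condition bound (often larger than for the Euler
#'   tau-leap, since the moments are much more accurate).
#' @return a \linkS4class{Trajectory}.
#' @export
ubtlSimulate <- function(sys, x0, T, epsilon = 1, t0 = 0,
                         saveTrajectory = TRUE,
                         engine = c("R", "compiled")) {
  stopifnot(T > t0, all(x0 >= 0))
  engine <- match.arg(engine)
  if (engine == "compiled")
    return(.leapTrajectory(sys, x0, T, epsilon, TRUE, t0, saveTrajectory,
                           "ubtl"))
  x <- as.numeric(x0); t <- t0
  times <- t; states <- list(x)
  taus <- numeric(0)
  nuEff <- effectiveNetChange(sys)
  M <- nReactions(sys)
  floorTau <- 1e-12 * (T - t0)
  while (t < T) {
    tau <- tauSelect(sys, x, epsilon, tRemaining = T - t)
    frozen <- .freezeMoments(sys, x)
    repeat {
      table <- nevilleTable()
      for (nSub in c(8L, 16L)) {
        fc <- .momentIntegral(sys, x, tau, nSub, frozen)
        if (!fc$ok) stop("modified midpoint failure in UBTL step")
        table <- nevilleExtend(table, fc$value, nSub)
      }
      extr <- nevilleTop(table, 2L)
      mu <- pmax(extr[seq_len(M)], 0)
      v <- pmax(extr[M + seq_len(M)], 0)
      K <- hybridSample(mu, v)
      xNew <- x + drop(nuEff %*% K)
      if (all(xNew >= 0)) break
      tau <- tau / 2
      if (tau < floorTau)
        stop("UBTL stepsize underflow at t=", signif(t, 6))
    }
    x <- xNew
    t <- if (T - t - tau < floorTau) T else t + tau
    taus <- c(taus, tau)
    if (saveTrajectory) { times <- c(times, t); states <- c(states, list(x)) }
  }
  if (!saveTrajectory) { times <- c(times, T); states <- c(states, list(x)) }
  newTrajectory(times, do.call(rbind, states), "ubtl",
                data.frame(tau = taus))
}
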