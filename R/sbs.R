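# The Stochastic Bulirsch-Stoer stepper: Romberg tables of per-step
# propensity integrals, adaptive order/stepsize control, acceptance and
# rejection, Poisson state updates.

#' Candidate next stepsize for a Romberg column
#'
#' \deqn{\tau_k = \tau\, S_1 (S_2/err_k)^{1/(2(k-1)+1)},}
#' the hypothetical stepsize that would have made column \code{k}'s scaled
#' error exactly one (times safety factors).  When \code{errK} is tiny the
#' result is capped at \code{tau * s1 * maxGrowth}.
#'
#' @param tau current stepsize.
#' @param errK scaled column error (>= 0).
#' @param k Romberg column (>= 2).
#' @param s1,s2 safety factors in (0,1).
#' @param maxGrowth growth cap.
#' @return candidate stepsize.
#' @export
candidateStepsize <- function(tau, errK, k, s1, s2, maxGrowth = 4) {
  stopifnot(tau > 0, errK >= 0, k >= 2)
  if (errK < 1e-300) return(tau * s1 * maxGrowth)
  min(tau * s1 * (s2 / errK)^(1 / (2 * (k - 1) + 1)), tau * maxGrowth)
}

#' Cumulative drift-evaluation work per Romberg row
#'
#' The modified midpoint pass for row \eqn{q} costs \eqn{n_q + 1} drift
#' evaluations with \eqn{n_q = 2q}, so building rows 1..q costs
#' \eqn{A_1 = 3}, \eqn{A_{q+1} = A_q + n_{q+1}}.
#'
#' @param k deepest row.
#' @return integer vector \eqn{A_1 \ldots A_k}.
#' @export
workSequence <- function(k) {
  stopifnot(k >= 1)
  cumsum(c(3L, 2L * (seq_len(k - 1L) + 1L)))
}

#' Efficiency-optimal column selection
#'
#' Picks the candidate minimising the work per unit step \eqn{W_q =
#' A_q/\tau_q}; exact ties break toward the smaller column.
#'
#' @param candidates data.frame (or list of rows) with columns \code{k},
#'   \code{tau}, \code{work}.
#' @return list with \code{k} and \code{tau} of the winner.
#' @export
selectColumn <- function(candidates) {
  cand <- as.data.frame(candidates)
  if (nrow(cand) == 0L) stop("no candidate columns")
  W <- cand$work / cand$tau
  best <- which(W <= min(W) + 0)       # exact comparison; ties possible
  best <- best[which.min(cand$k[best])]
  list(k = cand$k[best], tau = cand$tau[best])
}

# One adaptive SBS (or SBS-DA) step.
#
# firstColumnFn(tau, nSub) -> list(ok, value, nEvals): the quantity being
#   extrapolated (propensity integrals for SBS, stacked moment pairs for
#   SBS-DA).
# errFn(table, q) -> scaled column error (gates convergence).
# sampleFn(extr, q) -> list(counts, update): draws K and the state increment.
.adaptiveStep <- function(sys, x, tau, settings, kTarget, tRemaining,
                          firstColumnFn, errFn, sampleFn, baseWork = 0L) {
  floorTau <- attr(tRemaining, "floorTau")
  if (is.null(floorTau)) floorTau <- 0
  rejections <- 0L
  work <- baseWork
  nuEff <- effectiveNetChange(sys)
  repeat {
    first <- is.na(kTarget)
    window <- if (first) 2:settings@kMax
              else intersect((kTarget - 1L):(kTarget + 1L), 2:settings@kMax)
    qMax <- max(window)
    table <- nevilleTable()
    errs <- rep(NA_real_, qMax)
    accepted <- NA_integer_
    failed <- FALSE
    for (q in seq_len(qMax)) {
      fc <- firstColumnFn(tau, 2L * q)
      if (!fc$ok) { failed <- TRUE; break }
      work <- work + fc$nEvals
      table <- nevilleExtend(table, fc$value, 2L * q)
      if (q >= 2L) {
        errs[q] <- errFn(table, q)
        if (q %in% window && errs[q] <= 1) { accepted <- q; break }
      }
    }
    if (failed || is.na(accepted)) {
      tau <- tau / 2
      rejections <- rejections + 1L
      if (tau < floorTau)
        stop("SBS stepsize underflow (no convergence)")
      next
    }
    extr <- nevilleTop(table, accepted)
    smp <- sampleFn(extr, accepted)
    xNew <- x + drop(nuEff %*% smp$counts)
    if (any(xNew < 0)) {
      tau <- tau / 2
      rejections <- rejections + 1L
      if (tau < floorTau)
        stop("SBS stepsize underflow (negative populations)")
      next
    }
    # efficiency-optimal next (k, tau) from the columns actually built
    # (same rule as selectColumn(), inlined on the hot path)
    built <- which(!is.na(errs))
    A <- workSequence(qMax)
    tauCand <- numeric(length(built))
    for (u in seq_along(built))
      tauCand[u] <- candidateStepsize(tau, errs[built[u]], built[u],
                                      settings@s1, settings@s2,
                                      settings@maxGrowth)
    W <- A[built] / tauCand
    best <- which(W == min(W))[1L]       # built is increasing: ties -> lower k
    return(list(state = xNew, tauUsed = tau, kConverged = accepted,
                rejections = rejections, work = work,
                extrapolated = extr, counts = smp$counts,
                kNext = built[best], tauNext = tauCand[best]))
  }
}

# zero-propensity shortcut shared by the adaptive steppers
.allQuiet <- function(sys, x) all(propensities(sys, x) == 0)

#' Single adaptive Stochastic Bulirsch-Stoer step
#'
#' Builds first-column propensity integrals \eqn{\Delta a^{\hat\tau_q}} for
#' substep counts \eqn{n_q = 2q}, extends the Neville table, and accepts at
#' the first column of the allowed window whose scaled error is at most
#' one.  Reaction counts are then sampled as \eqn{K_j \sim}
#' Poisson\eqn{(\Delta a_j^{extr})} and the state updated by
#' \eqn{X' = X + \sum_j \nu_j K_j}.  No convergence within the window, or a
#' negative population after the update, rejects the step and retries with
#' \eqn{\tau/2}.  The efficiency-optimal next column and stepsize are
#' returned.
#'
#' @param sys a \linkS4class{ReactionSystem}.
#' @param x current counts.
#' @param tau stepsize to attempt.
#' @param settings a \linkS4class{SolverSettings}.
#' @param kTarget working column from the previous step (window
#'   \code{kTarget} +/- 1), or \code{NA} on the first step (columns are
#'   built upward until convergence or \code{kMax}).
#' @param ev precompiled evaluators from an internal cache; leave
#'   \code{NULL}.
#' @return list with \code{state}, \code{tauUsed}, \code{kConverged},
#'   \code{rejections}, \code{work}, \code{extrapolated}, \code{counts},
#'   \code{kNext}, \code{tauNext}.
#' @export
sbsStep <- function(sys, x, tau, settings = solverSettings(),
                    kTarget = NA_integer_, ev = NULL) {
  stopifnot(tau > 0)
  if (is.null(ev)) ev <- .makeEvaluators(sys)
  if (all(ev$prop(x) == 0)) {
    M <- nReactions(sys)
    return(list(state = x, tauUsed = tau, kConverged = 1L, rejections = 0L,
                work = 0L, extrapolated = numeric(M),
                counts = integer(M), kNext = 2L, tauNext = tau))
  }
  drift0 <- ev$drift(x)     # shared first stage across all Romberg rows
  .adaptiveStep(sys, x, tau, settings, kTarget, Inf, baseWork = 1L,
    firstColumnFn = function(tt, nSub) .propIntegral(sys, x, tt, nSub, ev,
                                                     drift0),
    errFn = function(table, q) columnError(table, q, settings@atol,
                                           settings@rtol),
    sampleFn = function(extr, q) {
      lambda <- extr
      if (any(lambda < -1e-8 * max(1, max(abs(lambda)))))
        stop("negative extrapolated Poisson parameter")
      lambda <- pmax(lambda, 0)
      list(counts = rpois(length(lambda), lambda))
    })
}

# shared adaptive driver for SBS and SBS-DA
.adaptiveSimulate <- function(sys, x0, T, settings, t0, stepFn, method,
                              saveTrajectory = TRUE) {
  stopifnot(T > t0, all(x0 >= 0))
  x <- as.numeric(x0); t <- t0
  a0 <- sum(propensities(sys, x))
  tau <- if (!is.na(settings@tau0)) settings@tau0
         else if (a0 > 0) settings@tau0Multiple / a0
         else T - t0
  kTarget <- NA_integer_
  times <- t; states <- list(x)
  iT <- iTau <- numeric(0); iK <- iRej <- iWork <- integer(0)
  floorTau <- 1e-12 * (T - t0)
  while (t < T) {
    tauTry <- min(max(tau, floorTau), T - t)
    rec <- stepFn(x, tauTry, kTarget)
    if (rec$tauUsed < floorTau)
      stop("adaptive stepper stalled: stepsize underflow at t=",
           signif(t, 6))
    x <- rec$state
    tPrev <- t
    t <- if (T - t - rec$tauUsed < floorTau) T else t + rec$tauUsed
    iT <- c(iT, tPrev); iTau <- c(iTau, rec$tauUsed)
    iK <- c(iK, rec$kConverged); iRej <- c(iRej, rec$rejections)
    iWork <- c(iWork, rec$work)
    tau <- min(rec$tauNext, if (T - t > 0) T - t else rec$tauNext)
    kTarget <- rec$kNext
    if (saveTrajectory) { times <- c(times, t); states <- c(states, list(x)) }
  }
  if (!saveTrajectory) { times <- c(times, T); states <- c(states, list(x)) }
  newTrajectory(times, do.call(rbind, states), method,
                data.frame(t = iT, tau = iTau, k = iK, rejections = iRej,
                           work = iWork))
}

#' Adaptive Stochastic Bulirsch-Stoer simulation
#'
#' Full adaptive run to exactly \code{T}.  The first step builds Romberg
#' columns upward from \eqn{q = 1} until the scaled error drops below one
#' (or \code{kMax} is reached); subsequent steps test only the window
#' \eqn{k-1, k, k+1} around the current working column.  Per-step
#' diagnostics (stepsize, accepted column, rejections, work) are recorded
#' in \code{stepInfo}.
#'
#' @inheritParams tauLeapSimulate
#' @return a \linkS4class{Trajectory}.
#' @export
sbsSimulate <- function(sys, x0, T, settings = solverSettings(),
                        t0 = 0, saveTrajectory = TRUE,
                        engine = c("R", "compiled")) {
  engine <- match.arg(engine)
  if (engine == "compiled")
    return(.sbsTrajectory(sys, x0, T, settings, t0, saveTrajectory, FALSE))
  ev <- .makeEvaluators(sys)
  .adaptiveSimulate(sys, x0, T, settings, t0,
                    function(x, tau, kTarget)
                      sbsStep(sys, x, tau, settings, kTarget, ev),
                    "sbs", saveTrajectory)
}

# wrapper for the compiled adaptive engines (SBS and SBS-DA)
.sbsTrajectory <- function(sys, x0, T, settings, t0, saveTrajectory, da) {
  res <- .sbs_cpp(sys@reactantOrders, effectiveNetChange(sys),
                  sys@rateConstants, as.numeric(x0), t0, T,
                  settings@s1, settings@s2, settings@atol, settings@rtol,
                  settings@kMax, settings@tau0, settings@tau0Multiple,
                  settings@maxGrowth, da, saveTrajectory)
  newTrajectory(res$times, res$states, if (da) "sbsda" else "sbs",
                data.frame(t = res$t, tau = res$tau, k = res$k,
                           rejections = res$rejections, work = res$work))
}

#' Fixed-stepsize, fixed-column SBS
#'
#' The restricted variant used for order studies: every step uses exactly
#' stepsize \code{tau} and Romberg columns 1..\code{k} (\code{k = 1} means
#' a single modified-midpoint pass with two substeps and no extrapolation),
#' with the usual Poisson update.  No adaptivity and no rejection: a step
#' that would drive populations negative fails the whole realisation
#' (order studies are run in regimes where this cannot occur).
#'
#' @inheritParams sbsSimulate
#' @param tau fixed stepsize; \code{T/tau} must be an integer.
#' @param k fixed Romberg column (>= 1).
#' @return a \linkS4class{Trajectory}.
#' @export
sbsFixed <- function(sys, x0, T, tau, k = 1L, t0 = 0,
                     saveTrajectory = TRUE) {
  nSteps <- (T - t0) / tau
  stopifnot(abs(nSteps - round(nSteps)) < 1e-9, k >= 1L)
  nSteps <- round(nSteps)
  x <- as.numeric(x0); t <- t0
  times <- t; states <- list(x)
  nuEff <- effectiveNetChange(sys)
  for (s in seq_len(nSteps)) {
    lambda <- .sbsFixedLambda(sys, x, tau, k)
    K <- rpois(length(lambda), lambda)
    x <- x + drop(nuEff %*% K)
    if (any(x < 0)) stop("negative population in fixed-step SBS realisation")
    t <- t0 + s * tau
    if (saveTrajectory) { times <- c(times, t); states <- c(states, list(x)) }
  }
  if (!saveTrajectory) { times <- c(times, T); states <- c(states, list(x)) }
  newTrajectory(times, do.call(rbind, states), "sbs_fixed")
}

# extrapolated Poisson parameter of one fixed-step SBS step (deterministic)
.sbsFixedLambda <- function(sys, x, tau, k) {
  table <- nevilleTable()
  for (q in seq_len(k)) {
    fc <- .propIntegral(sys, x, tau, 2L * q)
    if (!fc$ok) stop("modified midpoint failure in fixed-step SBS")
    table <- nevilleExtend(table, fc$value, 2L * q)
  }
  pmax(nevilleTop(table, k), 0)
}
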