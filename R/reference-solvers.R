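# Baseline stochastic solvers: the exact SSA (compiled core) and the
# adaptive Euler tau-leap.

newTrajectory <- function(times, states, method, stepInfo = NULL) {
  if (is.null(stepInfo)) stepInfo <- data.frame()
  new("Trajectory", times = as.numeric(times),
      states = as.matrix(states), method = method, stepInfo = stepInfo)
}

#' Exact stochastic simulation algorithm (Gillespie direct method)
#'
#' Generates one statistically exact realisation: exponentially distributed
#' waiting times with rate \eqn{a_0(x)} and reaction \eqn{j'} selected with
#' probability \eqn{a_{j'}/a_0}.  When all propensities vanish the state is
#' frozen up to \code{T}.
#'
#' @param sys a \linkS4class{ReactionSystem}.
#' @param x0 initial copy numbers.
#' @param T simulation horizon (final time).
#' @param t0 start time.
#' @param saveTrajectory if \code{FALSE} only the initial and final states
#'   are recorded (much lighter for ensembles).
#' @param maxEvents safety cap on the number of reaction events.
#' @return a \linkS4class{Trajectory} ending exactly at \code{T}.
#' @export
ssaSimulate <- function(sys, x0, T, t0 = 0, saveTrajectory = TRUE,
                        maxEvents = 1e8) {
  stopifnot(T > t0, all(x0 >= 0))
  res <- .ssa_cpp(sys@reactantOrders, effectiveNetChange(sys),
                  sys@rateConstants, as.numeric(x0), t0, T,
                  saveTrajectory, maxEvents)
  if (!saveTrajectory) {
    states <- rbind(as.numeric(x0), res$state)
    return(newTrajectory(c(t0, T), states, "ssa"))
  }
  times <- res$times
  states <- res$states
  if (times[length(times)] < T) {
    times <- c(times, T)
    states <- rbind(states, res$finalState)
  }
  newTrajectory(times, states, "ssa")
}

#' Leap-condition stepsize selection for the tau-leap
#'
#' Bound-based scheme of Cao, Gillespie and Petzold: the step bounds the
#' mean and standard deviation of the relative propensity change by
#' \code{epsilon}, via
#' \deqn{\tau = \min_i \left\{ \frac{\max(\epsilon x_i/g_i, 1)}{|\mu_i|},
#'   \frac{\max(\epsilon x_i/g_i, 1)^2}{\sigma_i^2} \right\}}
#' with \eqn{\mu_i = \sum_j \nu_{ij} a_j}, \eqn{\sigma_i^2 = \sum_j
#' \nu_{ij}^2 a_j}, taken over non-buffered reactant species; \eqn{g_i} is
#' the highest-order correction factor for species \code{i}.  The result is
#' clamped to the remaining simulation time, which is also returned when
#' all propensities vanish or are constant.
#'
#' @inheritParams ssaSimulate
#' @param x current state.
#' @param epsilon leap-condition bound (\eqn{\ll 1}).
#' @param tRemaining remaining time to the horizon.
#' @return a positive stepsize.
#' @export
tauSelect <- function(sys, x, epsilon, tRemaining = Inf) {
  stopifnot(epsilon > 0)
  a <- propensities(sys, x)
  if (all(a == 0)) return(tRemaining)
  nu <- effectiveNetChange(sys)
  mu <- drop(nu %*% a)
  sig2 <- drop((nu^2) %*% a)
  orders <- sys@reactantOrders
  tau <- Inf
  for (i in seq_len(nSpecies(sys))) {
    if (sys@fixedSpecies[i]) next
    js <- which(orders[i, ] > 0L)
    if (!length(js)) next                       # never a reactant
    oTot <- colSums(orders[, js, drop = FALSE])
    o <- max(oTot)
    m <- max(orders[i, js[oTot == o]])
    xi <- x[i]
    g <- if (o == 1L) 1
    else if (o == 2L) { if (m == 1L) 2 else 2 + 1 / (xi - 1) }
    else { # third order
      if (m == 1L) 3
      else if (m == 2L) 1.5 * (2 + 1 / (xi - 1))
      else 3 + 1 / (xi - 1) + 2 / (xi - 2)
    }
    bound <- max(epsilon * xi / g, 1)
    if (mu[i] != 0) tau <- min(tau, bound / abs(mu[i]))
    if (sig2[i] != 0) tau <- min(tau, bound^2 / sig2[i])
  }
  min(tau, tRemaining)
}

#' Single Euler tau-leap step
#'
#' Fires \eqn{K_j \sim} Poisson\eqn{(a_j(x)\tau)} reactions per channel and
#' applies the net changes (buffered species unchanged).  If the update
#' would drive any population negative the step is reported as failed so
#' the caller can retry with a halved stepsize.
#'
#' @inheritParams tauSelect
#' @param tau stepsize (\eqn{\ge 0}).
#' @return list with \code{ok} (logical), \code{state} (new counts, only
#'   when \code{ok}) and \code{counts} (the sampled \eqn{K_j}).
#' @export
tauLeapStep <- function(sys, x, tau) {
  stopifnot(tau >= 0)
  a <- propensities(sys, x)
  K <- rpois(nReactions(sys), a * tau)
  xNew <- x + drop(effectiveNetChange(sys) %*% K)
  if (any(xNew < 0)) list(ok = FALSE, counts = K)
  else list(ok = TRUE, state = xNew, counts = K)
}

#' Adaptive Euler tau-leap simulation
#'
#' Alternates \code{\link{tauSelect}} and \code{\link{tauLeapStep}} until
#' the horizon, halving the stepsize whenever a step would create negative
#' populations.  The final time is exactly \code{T}.
#'
#' @inheritParams ssaSimulate
#' @param settings a \linkS4class{SolverSettings}; only \code{epsilon} is
#'   used.
#' @param saveTrajectory if \code{FALSE} only initial and final states are
#'   kept.
#' @param engine \code{"R"} for the reference implementation,
#'   \code{"compiled"} for the statement-for-statement compiled mirror
#'   (bit-identical under the same seed; used for large ensembles).
#' @return a \linkS4class{Trajectory}.
#' @export
tauLeapSimulate <- function(sys, x0, T, settings = solverSettings(),
                            t0 = 0, saveTrajectory = TRUE,
                            engine = c("R", "compiled")) {
  stopifnot(T > t0, all(x0 >= 0))
  engine <- match.arg(engine)
  if (engine == "compiled")
    return(.leapTrajectory(sys, x0, T, settings@epsilon, FALSE, t0,
                           saveTrajectory, "tl"))
  x <- as.numeric(x0); t <- t0
  times <- t; states <- list(x)
  taus <- numeric(0)
  floorTau <- 1e-12 * (T - t0)
  while (t < T) {
    tau <- tauSelect(sys, x, settings@epsilon, tRemaining = T - t)
    repeat {
      st <- tauLeapStep(sys, x, tau)
      if (st$ok) break
      tau <- tau / 2
      if (tau < floorTau)
        stop("tau-leap stepsize underflow at t=", signif(t, 6))
    }
    x <- st$state
    t <- if (T - t - tau < floorTau) T else t + tau
    taus <- c(taus, tau)
    if (saveTrajectory) { times <- c(times, t); states <- c(states, list(x)) }
  }
  if (!saveTrajectory) { times <- c(times, T); states <- c(states, list(x)) }
  newTrajectory(times, do.call(rbind, states), "tl",
                data.frame(tau = taus))
}

# shared wrapper for the compiled tau-leap / UBTL engines
.leapTrajectory <- function(sys, x0, T, epsilon, ubtl, t0, saveTrajectory,
                            method) {
  res <- .leap_cpp(sys@reactantOrders, effectiveNetChange(sys),
                   sys@rateConstants, sys@fixedSpecies, as.numeric(x0),
                   t0, T, epsilon, ubtl, saveTrajectory)
  newTrajectory(res$times, res$states, method, data.frame(tau = res$tau))
}
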