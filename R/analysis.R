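# Analysis machinery: histograms and L1 error, the efficiency score,
# weak-order slope estimation, and exact oracles (closed-form linear
# moments, truncated chemical master equation, exact distribution
# propagation of fixed-step numerical chains).

#' Build a binned empirical PDF
#'
#' Half-open uniform bins \code{[origin + m*w, origin + (m+1)*w)};
#' probabilities are counts over \code{length(samples)}.  Supplying
#' \code{lo}/\code{hi} extends the covered range (e.g. to share bin edges
#' with another histogram, as L1 comparison requires).
#'
#' @param samples numeric vector (>= 1 sample).
#' @param binWidth positive bin width.
#' @param origin bin alignment origin.
#' @param lo,hi optional values the bin range must also cover.
#' @return a \linkS4class{Histogram}.
#' @export
buildHistogram <- function(samples, binWidth, origin = 0, lo = NULL,
                           hi = NULL) {
  if (length(samples) == 0L) stop("no samples")
  stopifnot(binWidth > 0)
  mFirst <- floor((min(samples, lo) - origin) / binWidth)
  mLast  <- floor((max(samples, hi) - origin) / binWidth)
  edges <- origin + (mFirst:(mLast + 1L)) * binWidth
  idx <- floor((samples - origin) / binWidth) - mFirst + 1L
  counts <- tabulate(idx, nbins = mLast - mFirst + 1L)
  new("Histogram", binEdges = edges, probabilities = counts / length(samples),
      nSamples = length(samples))
}

#' @rdname buildHistogram
#' @param support integer support of a discrete pmf.
#' @param prob probabilities on \code{support}.
#' @return \code{pmfHistogram}: the same binning applied to an exact pmf
#'   (used for analytic reference distributions).
#' @export
pmfHistogram <- function(support, prob, binWidth, origin = 0, lo = NULL,
                         hi = NULL) {
  stopifnot(length(support) == length(prob), binWidth > 0)
  prob <- prob / sum(prob)
  mFirst <- floor((min(support, lo) - origin) / binWidth)
  mLast  <- floor((max(support, hi) - origin) / binWidth)
  edges <- origin + (mFirst:(mLast + 1L)) * binWidth
  idx <- floor((support - origin) / binWidth) - mFirst + 1L
  p <- vapply(seq_len(mLast - mFirst + 1L),
              function(b) sum(prob[idx == b]), numeric(1))
  new("Histogram", binEdges = edges, probabilities = p,
      nSamples = length(support))
}

#' L1 distance between two histograms on identical bins
#'
#' \eqn{\sum_{bins} |p_1 - p_2|}; a value in [0, 2].  The two histograms
#' must share bin edges exactly (build them with common \code{lo}/\code{hi}
#' and the same width and origin).
#'
#' @param h1,h2 \linkS4class{Histogram} objects with identical edges.
#' @return non-negative scalar distance.
#' @export
l1Distance <- function(h1, h2) {
  if (length(h1@binEdges) != length(h2@binEdges) ||
      any(abs(h1@binEdges - h2@binEdges) > 1e-9))
    stop("histograms must share identical bins; rebin first")
  sum(abs(h1@probabilities - h2@probabilities))
}

#' Efficiency score
#'
#' \deqn{\eta = \frac{(\sum \mathrm{errors})^{-1}}{\sum \mathrm{runtimes}},}
#' the inverse of the total histogram error over all species and parameter
#' settings divided by the summed single-simulation runtimes.  Higher is
#' better; comparable only between runs that used identical bins.  A zero
#' total error is flagged as unbounded (\code{Inf}).
#'
#' @param totalErrors numeric vector of histogram errors.
#' @param runtimes numeric vector of single-simulation runtimes.
#' @return scalar efficiency (possibly \code{Inf}).
#' @export
efficiency <- function(totalErrors, runtimes) {
  if (!length(totalErrors) || !length(runtimes)) stop("empty inputs")
  tot <- sum(totalErrors)
  if (tot == 0) {
    warning("zero total error: efficiency unbounded")
    return(Inf)
  }
  (1 / tot) / sum(runtimes)
}

#' Weak-order slope by log-log regression
#'
#' Least-squares slope of \code{log(error)} against \code{log(stepsize)}.
#' Exact-zero (or round-off-level) errors must be excluded by the caller.
#'
#' @param stepsizes positive stepsizes.
#' @param errors positive errors.
#' @return the regression slope.
#' @export
weakOrderSlope <- function(stepsizes, errors) {
  stopifnot(length(stepsizes) == length(errors), length(errors) >= 2)
  if (any(errors <= 0)) stop("errors must be positive (exclude exact zeros)")
  unname(coef(lm(log(errors) ~ log(stepsizes)))[2])
}

#' Closed-form moments of the linear pure-birth (Yule) process
#'
#' For \eqn{X \to 2X} with rate constant \code{c} started at \code{x0}:
#' mean \eqn{x_0 e^{cT}}, variance \eqn{x_0 e^{cT}(e^{cT} - 1)}.
#'
#' @param c birth rate constant.
#' @param x0 initial copy number.
#' @param T time.
#' @return list with \code{mean} and \code{variance}.
#' @export
linearMomentOracle <- function(c, x0, T) {
  g <- exp(c * T)
  list(mean = x0 * g, variance = x0 * g * (g - 1))
}

# ---- rank-1 state-space reduction -----------------------------------------

# Systems whose effective stoichiometry has rank one admit an exact
# one-coordinate description: x = x0 + m*d with d a primitive integer
# direction and each reaction advancing m by an integer s_j.  The CME on
# the truncated support is solved by uniformization (Jensen's method):
# P(T) = sum_k Pois(k; Lambda*T) * (I + Q/Lambda)^k P(0), which needs only
# sparse matrix-vector products and converges to any required tolerance.
.rank1Reduction <- function(sys) {
  nu <- effectiveNetChange(sys)
  j0 <- which(colSums(abs(nu)) > 0)[1]
  if (is.na(j0)) stop("system has no state-changing reaction")
  d <- nu[, j0]
  g <- Reduce(function(a, b) if (b == 0) a else .gcd(a, abs(b)), d, 0)
  d <- d / g
  s <- numeric(ncol(nu))
  for (j in seq_len(ncol(nu))) {
    nz <- which(d != 0)
    sj <- nu[nz[1], j] / d[nz[1]]
    if (any(abs(nu[, j] - sj * d) > 1e-9) || abs(sj - round(sj)) > 1e-9)
      stop("effective stoichiometry is not rank one")
    s[j] <- round(sj)
  }
  list(d = d, s = s)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# admissible and reachable range of the free coordinate m (all species
# non-negative; only directions some reaction can actually move in),
# capped at `truncation` states in either direction
.rank1Support <- function(x0, d, s, truncation) {
  up <- Inf; dn <- Inf   # admissible extents in +m and -m direction
  for (i in seq_along(d)) {
    if (d[i] < 0) up <- min(up, floor(x0[i] / -d[i]))
    if (d[i] > 0) dn <- min(dn, floor(x0[i] / d[i]))
  }
  if (all(s <= 0)) up <- 0      # no reaction increases m
  if (all(s >= 0)) dn <- 0      # no reaction decreases m
  mHi <- if (is.finite(up)) up else truncation
  mLo <- if (is.finite(dn)) -dn else -truncation
  mHi <- min(mHi, truncation); mLo <- max(mLo, -truncation)
  mLo:mHi
}

#' Truncated chemical master equation oracle
#'
#' Exact state distribution at time \code{T} for systems whose effective
#' stoichiometry has rank one (each reaction shifts the state along one
#' integer direction), e.g. one-species systems or \eqn{X + Y \to
#' \emptyset} started with equal counts.  The truncated generator is
#' exponentiated by uniformization (Jensen's method) to round-off-level
#' series tolerance; probability leaking out of the truncation window
#' beyond \code{1e-8} is an error.
#'
#' @param sys a rank-one \linkS4class{ReactionSystem}.
#' @param x0 initial counts.
#' @param T time.
#' @param truncation cap on the number of states kept in either direction
#'   along the free coordinate.
#' @return list with \code{support} (free-coordinate values \code{m}),
#'   \code{states} (matrix of full states, one row per \code{m}),
#'   \code{prob}, and \code{mean} (per-species mean vector).
#' @export
cmeOracle <- function(sys, x0, T, truncation = 5000) {
  red <- .rank1Reduction(sys)
  m <- .rank1Support(as.numeric(x0), red$d, red$s, truncation)
  nS <- length(m)
  states <- outer(rep(1, nS), as.numeric(x0)) + outer(m, red$d)
  # per-state total outflow and per-reaction rates/targets (sparse);
  # flow to states outside the window accumulates in a leakage sink
  M <- nReactions(sys)
  rates <- matrix(0, nS, M)
  for (si in seq_len(nS)) rates[si, ] <- propensities(sys, states[si, ])
  outflow <- rowSums(rates)
  Lambda <- max(outflow)
  if (Lambda == 0) {
    prob <- as.numeric(m == 0)
    return(list(support = m, states = states, prob = prob,
                mean = unname(drop(prob %*% states))))
  }
  # one application of (I + Q/Lambda), with sink mass tracked separately
  applyP <- function(p) {
    out <- p$v * (1 - outflow / Lambda)
    sink <- p$sink
    for (j in seq_len(M)) {
      flux <- p$v * rates[, j] / Lambda
      tgt <- seq_len(nS) + red$s[j]
      ok <- tgt >= 1L & tgt <= nS
      # targets of one reaction are a uniform shift, hence unique
      out[tgt[ok]] <- out[tgt[ok]] + flux[ok]
      sink <- sink + sum(flux[!ok])
    }
    list(v = out, sink = sink)
  }
  lt <- Lambda * T
  kMax <- ceiling(lt + 12 * sqrt(lt) + 30)
  w <- dpois(0:kMax, lt)
  p <- list(v = as.numeric(m == 0), sink = 0)
  acc <- w[1] * p$v
  accSink <- w[1] * p$sink
  for (k in seq_len(kMax)) {
    p <- applyP(p)
    if (w[k + 1] > 0) {
      acc <- acc + w[k + 1] * p$v
      accSink <- accSink + w[k + 1] * p$sink
    }
  }
  if (accSink > 1e-8) stop("CME truncation leakage ", signif(accSink, 3))
  tail <- 1 - sum(w)
  if (tail > 1e-10) stop("uniformization series truncated too early")
  prob <- pmax(acc, 0)
  prob <- prob / sum(prob)
  list(support = m, states = states, prob = prob,
       mean = unname(drop(prob %*% states)))
}

# per-channel increment pmfs used by chainDistribution -----------------------

# pmf of a Poisson(lambda) truncated where the tail mass drops below tol
.poisPmf <- function(lambda, tol = 1e-14) {
  if (lambda == 0) return(c(`0` = 1))
  kMax <- max(10, ceiling(lambda + 12 * sqrt(lambda) + 20))
  p <- dpois(0:kMax, lambda)
  cut <- which(cumsum(p) > 1 - tol)[1]
  if (is.na(cut)) cut <- kMax + 1L
  p <- p[seq_len(max(cut, 2L))]
  p / sum(p)
}

# pmf of round(Normal(mu, var)) clamped at zero (half-up rounding)
.roundedGaussPmf <- function(mu, var) {
  if (var == 0) { p <- 1; names(p) <- floor(mu + 0.5); return(p) }
  sd <- sqrt(var)
  kMax <- ceiling(mu + 10 * sd + 2)
  k <- 0:kMax
  p <- pnorm((k + 0.5 - mu) / sd) - pnorm((k - 0.5 - mu) / sd)
  p[1] <- pnorm((0.5 - mu) / sd)          # all mass below 0.5 clamps to 0
  p / sum(p)
}

#' Exact distribution propagation of a fixed-step stochastic chain
#'
#' Propagates the full state distribution of a fixed-stepsize,
#' fixed-column numerical method on a rank-one system, with no sampling
#' anywhere: for each support state the one-step reaction-count law
#' (Poisson for the tau-leap and SBS; hybrid Poisson/rounded-Gaussian for
#' SBS-DA) is deterministically parameterised and convolved over the
#' current distribution.  Kernel mass that would leave the admissible
#' window is lumped at the boundary state.  This replaces Monte-Carlo
#' averaging in weak-order measurements, removing all sampling noise.
#'
#' @inheritParams cmeOracle
#' @param tau fixed stepsize; \code{T/tau} must be an integer.
#' @param method one of \code{"sbs"}, \code{"sbsda"}, \code{"tl"}.
#' @param k Romberg column for the SBS/SBS-DA chains.
#' @return as \code{\link{cmeOracle}} (distribution of the numerical chain
#'   at time \code{T}).
#' @export
chainDistribution <- function(sys, x0, tau, T, method = c("sbs", "sbsda",
                                                          "tl"),
                              k = 1L, truncation = 2000) {
  method <- match.arg(method)
  nSteps <- T / tau
  stopifnot(abs(nSteps - round(nSteps)) < 1e-9)
  nSteps <- round(nSteps)
  red <- .rank1Reduction(sys)
  m <- .rank1Support(as.numeric(x0), red$d, red$s, truncation)
  nS <- length(m)
  states <- outer(rep(1, nS), as.numeric(x0)) + outer(m, red$d)
  M <- nReactions(sys)

  kernel <- matrix(0, nS, nS)           # kernel[to, from]
  for (si in seq_len(nS)) {
    chanPmf <- vector("list", M)
    if (method == "sbs") {
      lambda <- .sbsFixedLambda(sys, states[si, ], tau, k)
      for (j in seq_len(M)) chanPmf[[j]] <- .poisPmf(lambda[j])
    } else if (method == "tl") {
      lambda <- propensities(sys, states[si, ]) * tau
      for (j in seq_len(M)) chanPmf[[j]] <- .poisPmf(lambda[j])
    } else {
      mom <- .sbsDaFixedMoments(sys, states[si, ], tau, k)
      for (j in seq_len(M)) {
        chanPmf[[j]] <- if (mom$mu[j] < 10) .poisPmf(mom$mu[j])
                        else .roundedGaussPmf(mom$mu[j], mom$var[j])
      }
    }
    # convolve channel increments onto the free coordinate
    inc <- c(`0` = 1)                   # pmf over delta-m, named by value
    for (j in seq_len(M)) {
      pj <- chanPmf[[j]]
      kj <- if (is.null(names(pj))) seq_along(pj) - 1L
            else as.integer(names(pj))
      vals <- outer(as.integer(names(inc)), kj * red$s[j], `+`)
      pr <- outer(unname(inc), unname(pj))
      inc <- tapply(as.numeric(pr), as.integer(vals), sum)
      names(inc) <- names(inc)
    }
    tgt <- si + as.integer(names(inc))
    tgt <- pmin(pmax(tgt, 1L), nS)      # lump boundary leakage
    for (u in seq_along(tgt))
      kernel[tgt[u], si] <- kernel[tgt[u], si] + inc[u]
  }

  prob <- ifelse(m == 0, 1, 0)
  for (s in seq_len(nSteps)) prob <- drop(kernel %*% prob)
  prob <- pmax(prob, 0); prob <- prob / sum(prob)
  list(support = m, states = states, prob = prob,
       mean = unname(drop(prob %*% states)))
}

# ---- exact-in-mean recursions for linear one-species systems ---------------

#' Exact mean recursion of fixed-step methods on a linear system
#'
#' For a one-species system with a single linear reaction (e.g. the Yule
#' process \eqn{X \to 2X}) the per-step Poisson parameter of each
#' fixed-step method is linear in the state, so the mean of the numerical
#' chain obeys a deterministic recursion \eqn{E[X_{n+1}] = (1 + \nu\alpha)
#' E[X_n]}.  This computes the chain mean at \code{T} exactly, with no
#' Monte Carlo anywhere.
#'
#' @param sys one-species, one-reaction linear \linkS4class{ReactionSystem}.
#' @param x0 initial count.
#' @param T horizon; \code{T/tau} must be an integer.
#' @param tau fixed stepsize.
#' @param method \code{"sbs"}, \code{"sbsda"} or \code{"tl"}.
#' @param k Romberg column for the extrapolation methods.
#' @return the exact mean of the numerical chain at \code{T}.
#' @export
linearMeanRecursion <- function(sys, x0, T, tau, method = c("sbs", "sbsda",
                                                            "tl"),
                                k = 1L) {
  method <- match.arg(method)
  stopifnot(nSpecies(sys) == 1L, nReactions(sys) == 1L,
            sys@reactantOrders[1, 1] == 1L)
  nSteps <- T / tau
  stopifnot(abs(nSteps - round(nSteps)) < 1e-9)
  nSteps <- round(nSteps)
  xRef <- as.numeric(x0)
  alpha <- switch(method,
    sbs   = .sbsFixedLambda(sys, xRef, tau, k) / xRef,
    sbsda = .sbsDaFixedMoments(sys, xRef, tau, k)$mu / xRef,
    tl    = propensities(sys, xRef) * tau / xRef)
  nuEff <- effectiveNetChange(sys)[1, 1]
  x0 * (1 + nuEff * alpha)^nSteps
}

#' Weak-order study on the linear (Yule) system
#'
#' Measures the weak order in the mean of a fixed-step method on
#' \eqn{X \to 2X} by the exact mean recursion against the closed-form mean
#' \eqn{x_0 e^{cT}}, regressing log error on log stepsize.  Errors below
#' \code{floor * mean} (round-off) are excluded from the regression.
#'
#' @inheritParams linearMeanRecursion
#' @param taus decreasing stepsizes, each dividing \code{T}.
#' @param floor relative round-off floor for exclusion.
#' @return list with \code{taus}, \code{errors}, \code{slope}.
#' @export
linearOrderStudy <- function(sys, x0, T, taus, method = "sbs", k = 1L,
                             floor = 1e-12) {
  exact <- linearMomentOracle(sys@rateConstants[1], x0, T)$mean
  errs <- vapply(taus, function(tt)
    abs(linearMeanRecursion(sys, x0, T, tt, method, k) - exact), numeric(1))
  keep <- errs > floor * exact
  list(taus = taus, errors = errs,
       slope = weakOrderSlope(taus[keep], errs[keep]))
}

#' Weak-order study on a non-linear rank-one system
#'
#' Propagates the exact distribution of the fixed-step chain
#' (\code{\link{chainDistribution}}) and compares its mean for the first
#' non-buffered species with the truncated-CME mean, regressing log error
#' on log stepsize.  Fully deterministic.
#'
#' @inheritParams chainDistribution
#' @param taus decreasing stepsizes, each dividing \code{T}.
#' @return list with \code{taus}, \code{errors}, \code{slope},
#'   \code{exactMean}.
#' @export
chainOrderStudy <- function(sys, x0, T, taus, method = "sbs", k = 1L,
                            truncation = 2000) {
  sp <- which(!sys@fixedSpecies)[1]
  exact <- cmeOracle(sys, x0, T, truncation)$mean[sp]
  errs <- vapply(taus, function(tt)
    abs(chainDistribution(sys, x0, tt, T, method, k,
                          truncation)$mean[sp] - exact), numeric(1))
  keep <- errs > 1e-11 * max(1, abs(exact))
  list(taus = taus, errors = errs, exactMean = exact,
       slope = weakOrderSlope(taus[keep], errs[keep]))
}

#' Exact marginal distributions for the chain-decay system
#'
#' For \eqn{X_1 \to X_2 \to X_3} each initial \eqn{X_1} molecule is
#' independently in state 1, 2 or 3 at time \code{T} with probabilities
#' \eqn{p_1 = e^{-c_1 T}}, \eqn{p_2} (the intermediate occupancy of a
#' two-stage relaxation) and \eqn{p_3 = 1 - p_1 - p_2}; initial \eqn{X_2}
#' molecules survive with probability \eqn{e^{-c_2 T}}.  The marginal of
#' each species is therefore an exact binomial convolution, used as the
#' analytic reference distribution for histogram errors.
#'
#' @param species which species (1, 2 or 3).
#' @param x0 initial counts (length 3).
#' @param c1,c2 decay rate constants.
#' @param T time.
#' @return list with \code{support} and \code{prob}.
#' @export
chainDecayMarginal <- function(species, x0 = c(10000, 1, 0), c1 = 1, c2 = 1,
                               T = 5) {
  p1 <- exp(-c1 * T)
  p2 <- if (abs(c1 - c2) < 1e-12) c1 * T * exp(-c1 * T)
        else c1 / (c2 - c1) * (exp(-c1 * T) - exp(-c2 * T))
  p3 <- 1 - p1 - p2
  q2 <- exp(-c2 * T)                    # survival of an initial X2 molecule
  n1 <- x0[1]; n2 <- x0[2]; n3 <- x0[3]
  convolveBinom <- function(nA, pA, nB, pB, shift = 0) {
    a <- dbinom(0:nA, nA, pA)
    b <- if (nB > 0) dbinom(0:nB, nB, pB) else 1
    pr <- if (length(b) > 1) convolve(a, rev(b), type = "open") else a
    list(support = shift + 0:(nA + nB), prob = pmax(pr, 0))
  }
  out <- switch(as.character(species),
    "1" = list(support = 0:n1, prob = dbinom(0:n1, n1, p1)),
    "2" = convolveBinom(n1, p2, n2, q2),
    "3" = convolveBinom(n1, p3, n2, 1 - q2, shift = n3),
    stop("species must be 1, 2 or 3"))
  out$prob <- out$prob / sum(out$prob)
  out
}
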