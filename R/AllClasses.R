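#' @import methods
#' @importFrom stats rpois rnorm rexp runif setNames lm coef dpois pnorm dnorm dbinom convolve
#' @importFrom utils write.table read.table
#' @useDynLib StochBS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Mass-action reaction network
#'
#' An S4 container for a chemical reaction network with \code{N} species and
#' \code{M} irreversible mass-action reactions.  Columns of
#' \code{reactantOrders} hold the left-hand-side multiplicities of each
#' reaction; columns of \code{netChange} are the stoichiometric change
#' vectors \eqn{\nu_j}.  Species flagged in \code{fixedSpecies} are buffered:
#' they enter propensities but their populations never change (their rows of
#' \eqn{\nu} are treated as zero in every state update).
#'
#' @slot speciesNames character vector of length N.
#' @slot reactantOrders N x M non-negative integer matrix.
#' @slot netChange N x M integer matrix, columns \eqn{\nu_j}.
#' @slot rateConstants positive numeric vector of length M (state-space
#'   stochastic rate constants \eqn{c_j}).
#' @slot fixedSpecies logical vector of length N.
#' @slot reactionNames character vector of length M.
#'
#' @export
setClass("ReactionSystem",
  representation(
    speciesNames   = "character",
    reactantOrders = "matrix",
    netChange      = "matrix",
    rateConstants  = "numeric",
    fixedSpecies   = "logical",
    reactionNames  = "character"
  )
)

setValidity("ReactionSystem", function(object) {
  msgs <- character(0)
  N <- length(object@speciesNames)
  M <- length(object@rateConstants)
  if (N < 1L) msgs <- c(msgs, "need at least one species")
  if (M < 1L) msgs <- c(msgs, "need at least one reaction")
  if (!identical(dim(object@reactantOrders), c(N, M)))
    msgs <- c(msgs, "reactantOrders must be N x M")
  if (!identical(dim(object@netChange), c(N, M)))
    msgs <- c(msgs, "netChange must be N x M")
  if (any(object@reactantOrders < 0) ||
      any(object@reactantOrders != round(object@reactantOrders)))
    msgs <- c(msgs, "reactantOrders must be non-negative integers")
  if (any(object@netChange != round(object@netChange)))
    msgs <- c(msgs, "netChange must be integer-valued")
  if (any(!is.finite(object@rateConstants)) || any(object@rateConstants <= 0))
    msgs <- c(msgs, "rate constants must be positive and finite")
  if (length(object@fixedSpecies) != N)
    msgs <- c(msgs, "fixedSpecies must have one flag per species")
  if (length(object@reactionNames) != M)
    msgs <- c(msgs, "reactionNames must have one name per reaction")
  if (anyDuplicated(object@reactionNames))
    msgs <- c(msgs, "duplicate reaction names")
  if (anyDuplicated(object@speciesNames))
    msgs <- c(msgs, "duplicate species names")
  # a reaction must do something, unless every species it touches is buffered
  if (M >= 1L && N >= 1L && length(object@fixedSpecies) == N &&
      identical(dim(object@netChange), c(N, M))) {
    eff <- object@netChange
    eff[object@fixedSpecies, ] <- 0L
    dead <- colSums(abs(object@netChange)) > 0 & colSums(abs(eff)) == 0
    # allowed: all change confined to fixed species
    nochange <- colSums(abs(object@netChange)) == 0
    if (any(nochange))
      msgs <- c(msgs, "reaction with zero net change")
  }
  if (length(msgs)) msgs else TRUE
})

#' Solver settings for the adaptive extrapolation methods
#'
#' Bundles the tunables of the SBS/SBS-DA steppers and of the tau-leap
#' comparators.  \code{s1} and \code{s2} are stepsize safety factors in
#' (0,1); \code{atol}/\code{rtol} scale the Romberg column error;
#' \code{kMax} is the deepest Neville column tried on the first step
#' (default 8); \code{tau0} is the initial stepsize (\code{NA} requests the
#' conservative policy \code{tau0Multiple / a0(x0)}); \code{epsilon} is the
#' tau-leap leap-condition bound; \code{maxGrowth} caps stepsize growth per
#' step.
#'
#' @export
setClass("SolverSettings",
  representation(
    s1 = "numeric", s2 = "numeric",
    atol = "numeric", rtol = "numeric",
    kMax = "integer",
    tau0 = "numeric", tau0Multiple = "numeric",
    epsilon = "numeric",
    maxGrowth = "numeric"
  )
)

setValidity("SolverSettings", function(object) {
  msgs <- character(0)
  if (object@s1 <= 0 || object@s1 >= 1) msgs <- c(msgs, "s1 must be in (0,1)")
  if (object@s2 <= 0 || object@s2 >= 1) msgs <- c(msgs, "s2 must be in (0,1)")
  if (any(object@atol < 0) || any(object@rtol < 0))
    msgs <- c(msgs, "tolerances must be non-negative")
  if (all(object@atol + object@rtol <= 0))
    msgs <- c(msgs, "atol + rtol must be positive")
  if (object@kMax < 2L) msgs <- c(msgs, "kMax must be at least 2")
  if (!is.na(object@tau0) && object@tau0 <= 0)
    msgs <- c(msgs, "tau0 must be positive")
  if (object@epsilon <= 0) msgs <- c(msgs, "epsilon must be positive")
  if (object@maxGrowth < 1) msgs <- c(msgs, "maxGrowth must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SolverSettings-class
#' @param s1,s2 safety factors in (0,1).
#' @param atol,rtol absolute/relative error tolerances (scalars).
#' @param kMax deepest Neville column on the first step.
#' @param tau0 explicit initial stepsize, or \code{NA} to use
#'   \code{tau0Multiple / a0(x0)}.
#' @param tau0Multiple multiple of the expected SSA step used when
#'   \code{tau0} is \code{NA}.
#' @param epsilon tau-leap error-control parameter.
#' @param maxGrowth cap on per-step stepsize growth.
#' @return a validated \code{SolverSettings} object.
#' @export
solverSettings <- function(s1 = 0.25, s2 = 0.25, atol = 1e-6, rtol = 1e-6,
                           kMax = 8L, tau0 = NA_real_, tau0Multiple = 10,
                           epsilon = 0.05, maxGrowth = 4) {
  new("SolverSettings", s1 = s1, s2 = s2, atol = atol, rtol = rtol,
      kMax = as.integer(kMax), tau0 = tau0, tau0Multiple = tau0Multiple,
      epsilon = epsilon, maxGrowth = maxGrowth)
}

#' Simulated trajectory of a reaction network
#'
#' Records a single realisation: strictly increasing times, the matching
#' states (one row per saved time point, one column per species), the method
#' identifier and optional per-step diagnostics (stepsize, accepted Neville
#' column, rejections, drift-evaluation work).
#'
#' @export
setClass("Trajectory",
  representation(
    times    = "numeric",
    states   = "matrix",
    method   = "character",
    stepInfo = "data.frame"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character(0)
  if (length(object@times) != nrow(object@states))
    msgs <- c(msgs, "one state row per time point required")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@states < 0))
    msgs <- c(msgs, "negative copy numbers in trajectory")
  if (length(msgs)) msgs else TRUE
})

#' Binned empirical probability mass function
#'
#' Uniform-width, half-open bins \code{[origin + m*w, origin + (m+1)*w)}
#' with probabilities summing to one.
#'
#' @export
setClass("Histogram",
  representation(
    binEdges      = "numeric",
    probabilities = "numeric",
    nSamples      = "integer"
  )
)

setValidity("Histogram", function(object) {
  msgs <- character(0)
  if (length(object@binEdges) != length(object@probabilities) + 1L)
    msgs <- c(msgs, "need one more edge than bins")
  if (any(diff(object@binEdges) <= 0))
    msgs <- c(msgs, "bin edges must increase")
  if (any(object@probabilities < 0))
    msgs <- c(msgs, "negative bin probability")
  if (abs(sum(object@probabilities) - 1) > 1e-12)
    msgs <- c(msgs, "probabilities must sum to 1")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ReactionSystem", function(object) {
  cat(sprintf("ReactionSystem: %d species, %d reactions\n",
              nSpecies(object), nReactions(object)))
  fx <- if (any(object@fixedSpecies))
    paste0(" (fixed: ", paste(object@speciesNames[object@fixedSpecies],
                              collapse = ", "), ")") else ""
  cat("  species: ", paste(object@speciesNames, collapse = ", "), fx, "\n",
      sep = "")
  for (j in seq_len(nReactions(object)))
    cat("  ", formatReaction(object, j), "\n", sep = "")
  invisible(object)
})

setMethod("show", "SolverSettings", function(object) {
  cat("SolverSettings:",
      sprintf("S1=%g S2=%g atol=%g rtol=%g kMax=%d eps=%g",
              object@s1, object@s2, object@atol, object@rtol,
              object@kMax, object@epsilon), "\n")
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory (%s): %d time points over [%g, %g], %d species\n",
              object@method, length(object@times),
              object@times[1], object@times[length(object@times)],
              ncol(object@states)))
  invisible(object)
})

setMethod("show", "Histogram", function(object) {
  cat(sprintf("Histogram: %d bins of width %g on [%g, %g), n=%d\n",
              length(object@probabilities), diff(object@binEdges)[1],
              object@binEdges[1], object@binEdges[length(object@binEdges)],
              object@nSamples))
  invisible(object)
})
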