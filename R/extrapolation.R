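# Deterministic engine shared by the stochastic steppers: modified midpoint
# (Gragg) stages, composite-trapezoid propensity integrals, polynomial
# Neville/Romberg extrapolation in the square of the substep, and the scaled
# column error.

# internal MMP: returns ok=FALSE when a stage leaves the admissible region
# (the check is skipped for non-population states such as moment vectors).
# `drift0` optionally supplies the start-state drift: all rows of a Romberg
# table start from the same state, so the stepper evaluates it once and the
# per-row cost is n_q evaluations (hence A_1 = 3 = 1 + n_1).
.mmp <- function(driftFn, x0, tau, nSub, checkNonneg = TRUE,
                 drift0 = NULL) {
  h <- tau / nSub
  N <- length(x0)
  stages <- matrix(0, nSub + 1L, N)
  stages[1L, ] <- x0
  slack <- if (checkNonneg) -1e-9 * (1 + max(abs(x0))) else -Inf
  z0 <- x0
  z1 <- z0 + h * (if (is.null(drift0)) driftFn(z0) else drift0)
  if (any(z1 < slack) || !all(is.finite(z1))) return(list(ok = FALSE))
  stages[2L, ] <- z1
  for (m in seq_len(nSub - 1L)) {
    z2 <- z0 + 2 * h * driftFn(z1)
    if (any(z2 < slack) || !all(is.finite(z2))) return(list(ok = FALSE))
    stages[m + 2L, ] <- z2
    z0 <- z1; z1 <- z2
  }
  smoothed <- 0.5 * (stages[nSub + 1L, ] + stages[nSub, ] +
                       h * driftFn(stages[nSub + 1L, ]))
  list(ok = TRUE, stages = stages, smoothed = smoothed,
       nEvals = nSub + if (is.null(drift0)) 1L else 0L)
}

#' Modified midpoint (Gragg) stages
#'
#' Integrates \code{dx/dt = driftFn(x)} over one macro step of length
#' \code{tau} using \code{nSub} substeps of the two-step midpoint scheme:
#' \eqn{z_1 = z_0 + \hat h f(z_0)}, \eqn{z_{m+1} = z_{m-1} + 2\hat h
#' f(z_m)}, with the Gragg-smoothed endpoint \eqn{\frac12(z_n + z_{n-1} +
#' \hat h f(z_n))}.  The global error has an expansion in even powers of
#' \eqn{\hat h = \tau/n}, which is what makes \eqn{\hat h^2} extrapolation
#' work.  Exactly \code{nSub + 1} drift evaluations are performed.
#'
#' @param driftFn function of the state returning the drift vector.
#' @param x0 real-valued initial state.
#' @param tau macro stepsize (> 0).
#' @param nSub even number of substeps (>= 2).
#' @return list with \code{stages} (an \code{(nSub+1) x N} matrix,
#'   \eqn{z_0 \ldots z_n}), \code{smoothed} (the Gragg endpoint) and
#'   \code{nEvals}.
#' @export
mmpStates <- function(driftFn, x0, tau, nSub) {
  stopifnot(tau > 0, nSub >= 2, nSub %% 2 == 0)
  res <- .mmp(driftFn, x0, tau, as.integer(nSub))
  if (!res$ok) stop("modified midpoint stage left the admissible region")
  res[c("stages", "smoothed", "nEvals")]
}

# internal propensity integral with failure signalling; `ev` carries
# precompiled evaluators (made once per run by .makeEvaluators)
.propIntegral <- function(sys, x0, tau, nSub, ev = NULL, drift0 = NULL) {
  if (is.null(ev)) ev <- .makeEvaluators(sys)
  if (tau == 0) return(list(ok = TRUE, value = numeric(ev$M), nEvals = 0L))
  res <- .mmp(ev$drift, as.numeric(x0), tau, as.integer(nSub),
              drift0 = drift0)
  if (!res$ok) return(list(ok = FALSE))
  h <- tau / nSub
  acc <- 0.5 * (ev$prop(res$stages[1L, ]) + ev$prop(res$stages[nSub + 1L, ]))
  for (m in 2:nSub) acc <- acc + ev$prop(res$stages[m, ])
  list(ok = TRUE, value = pmax(h * acc, 0), nEvals = res$nEvals)
}

#' Per-step propensity integrals by composite trapezoid
#'
#' Approximates \eqn{\Delta a_j = \int_t^{t+\tau} a_j(X(s))\,ds} along the
#' deterministic reaction-rate trajectory started at \code{x0}: the
#' modified midpoint stages are computed for the drift, propensities are
#' evaluated at every raw stage \eqn{z_0 \ldots z_n}, and the composite
#' trapezoidal rule with node spacing \eqn{\hat h = \tau/n} is applied.
#' This is the first-column quantity that the Romberg table extrapolates.
#'
#' @inheritParams mmpStates
#' @param sys a \linkS4class{ReactionSystem}.
#' @param x0 step-start state (counts).
#' @return numeric vector of M non-negative integral approximations.
#' @export
propensityIntegral <- function(sys, x0, tau, nSub) {
  stopifnot(tau >= 0)
  res <- .propIntegral(sys, x0, tau, nSub)
  if (!res$ok) stop("modified midpoint stage left the admissible region")
  res$value
}

#' Neville/Romberg extrapolation tables
#'
#' A Neville table accumulates first-column approximations of a vector
#' quantity computed with \code{nSub} substeps (so substep \eqn{\hat h =
#' \tau/n}) and completes each new diagonal by polynomial extrapolation in
#' \eqn{\hat h^2}, the correct variable for quantities whose error
#' expansion contains only even powers:
#' \deqn{Y_{q-r,q} = Y_{q-r+1,q} + \frac{Y_{q-r+1,q} - Y_{q-r,q-1}}
#'   {(n_q/n_{q-r})^2 - 1}.}
#'
#' @return \code{nevilleTable()}: an empty table.
#' @export
nevilleTable <- function() {
  structure(list(nSub = integer(0), entries = list(), errs = numeric(0)),
            class = "nevilleTable")
}

#' @rdname nevilleTable
#' @param table a Neville table.
#' @param value new first-column approximation (numeric vector).
#' @param nSub its substep count; must exceed the previous row's.
#' @return \code{nevilleExtend}: the table with one more completed row.
#' @export
nevilleExtend <- function(table, value, nSub) {
  q <- length(table$nSub) + 1L
  if (q > 1L && nSub <= table$nSub[q - 1L])
    stop("substep counts must strictly increase")
  table$nSub <- c(table$nSub, as.integer(nSub))
  row <- vector("list", q)
  row[[1L]] <- as.numeric(value)
  if (q > 1L) {
    prev <- table$entries[[q - 1L]]
    for (cc in 2:q) {
      ratio <- (table$nSub[q] / table$nSub[q - cc + 1L])^2
      row[[cc]] <- row[[cc - 1L]] + (row[[cc - 1L]] - prev[[cc - 1L]]) /
        (ratio - 1)
    }
  }
  table$entries[[q]] <- row
  table
}

#' @rdname nevilleTable
#' @param q column index.
#' @return \code{nevilleTop}: the most extrapolated entry of column
#'   \code{q} (the entry combining rows 1..q).
#' @export
nevilleTop <- function(table, q = length(table$nSub)) {
  stopifnot(q >= 1L, q <= length(table$nSub))
  table$entries[[q]][[q]]
}

#' Scaled internal-consistency error of a Romberg column
#'
#' \deqn{err_q = \frac{\| Y^{\hat\tau_1,\hat\tau_q} -
#'   Y^{\hat\tau_2,\hat\tau_q} \|_2}{atol + rtol \,
#'   \|Y^{\hat\tau_1,\hat\tau_q}\|_2},}
#' the L2 distance between the top two entries of column \code{q} over a
#' mixed tolerance.  Convergence is accepted when \eqn{err_q \le 1}.
#'
#' @param table a Neville table with at least \code{q} rows.
#' @param q column index (>= 2).
#' @param atol,rtol non-negative tolerances.
#' @return non-negative scalar error.
#' @export
columnError <- function(table, q, atol, rtol) {
  if (q < 2L) stop("column error is defined for q >= 2")
  stopifnot(q <= length(table$nSub))
  top <- table$entries[[q]][[q]]
  second <- table$entries[[q]][[q - 1L]]
  sqrt(sum((top - second)^2)) / (atol + rtol * sqrt(sum(top^2)))
}

#' @rdname nevilleTable
#' @param x a Neville table.
#' @param ... unused.
#' @export
print.nevilleTable <- function(x, ...) {
  q <- length(x$nSub)
  cat(sprintf("Neville table: %d row(s)\n", q))
  for (r in seq_len(q)) {
    vals <- vapply(seq_len(r), function(cc)
      paste(signif(x$entries[[r]][[cc]], 8), collapse = ","), character(1))
    cat(sprintf("  n=%2d | %s\n", x$nSub[r], paste(vals, collapse = "  ")))
  }
  invisible(x)
}
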