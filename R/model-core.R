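# Mass-action network representation and propensity algebra.
#
# Conventions: propensities use Gillespie's distinct-combination counting,
# a_j(x) = c_j * prod_i C(x_i, m_ij) where m_ij is the reactant multiplicity
# (so a homodimerisation contributes x(x-1)/2, a trimer x(x-1)(x-2)/6).  The
# same falling-factorial expression, taken over the reals, defines the
# deterministic reaction-rate drift used inside the extrapolation stages.

#' Build a mass-action reaction system
#'
#' @param species character vector of species names.
#' @param reactions list of reactions; each element is a list with
#'   \code{name}, \code{reactants} (named integer vector of multiplicities,
#'   possibly empty for zero-order input), \code{products} (named integer
#'   vector), \code{c} (forward rate constant) and optionally \code{cRev}
#'   (reverse rate constant).  A reaction with \code{cRev} is expanded into
#'   two irreversible reactions, forward first.
#' @param fixed character vector of buffered species names; these enter
#'   propensities but their populations are never changed.
#' @return a validated \linkS4class{ReactionSystem}.
#' @examples
#' sys <- reactionSystem(
#'   species = c("X1", "X2", "X3"),
#'   reactions = list(
#'     list(name = "r1", reactants = c(X1 = 1), products = c(X2 = 1), c = 1),
#'     list(name = "r2", reactants = c(X2 = 1), products = c(X3 = 1), c = 1)))
#' propensities(sys, c(10000, 1, 0))
#' @export
reactionSystem <- function(species, reactions, fixed = character(0)) {
  if (length(reactions) == 0L) stop("empty reaction list")
  if (length(species) == 0L) stop("need at least one species")
  if (!all(fixed %in% species))
    stop("unknown fixed species: ", paste(setdiff(fixed, species), collapse = ", "))
  N <- length(species)

  expanded <- list()
  for (r in reactions) {
    if (is.null(r$name)) stop("reaction without a name")
    stopifnot(is.numeric(r$c), length(r$c) == 1L)
    expanded <- c(expanded, list(list(name = r$name, reactants = r$reactants,
                                      products = r$products, c = r$c)))
    if (!is.null(r$cRev)) {
      expanded <- c(expanded, list(list(name = paste0(r$name, "_rev"),
                                        reactants = r$products,
                                        products = r$reactants, c = r$cRev)))
    }
  }
  M <- length(expanded)
  orders <- matrix(0L, N, M, dimnames = list(species, NULL))
  nu     <- matrix(0L, N, M, dimnames = list(species, NULL))
  cs <- numeric(M)
  nms <- character(M)
  for (j in seq_len(M)) {
    r <- expanded[[j]]
    nms[j] <- r$name
    if (!is.numeric(r$c) || r$c <= 0)
      stop("non-positive rate constant in reaction '", r$name, "'")
    cs[j] <- r$c
    for (side in c("reactants", "products")) {
      v <- r[[side]]
      if (length(v) == 0L) next
      if (is.null(names(v)) || any(!nzchar(names(v))))
        stop("unnamed species multiplicities in reaction '", r$name, "'")
      unknown <- setdiff(names(v), species)
      if (length(unknown))
        stop("unknown species in reaction '", r$name, "': ",
             paste(unknown, collapse = ", "))
      for (sp in names(v)) {
        m <- as.integer(v[[sp]])
        if (side == "reactants") {
          orders[sp, j] <- orders[sp, j] + m
          nu[sp, j] <- nu[sp, j] - m
        } else {
          nu[sp, j] <- nu[sp, j] + m
        }
      }
    }
  }
  new("ReactionSystem", speciesNames = species, reactantOrders = orders,
      netChange = nu, rateConstants = cs,
      fixedSpecies = species %in% fixed, reactionNames = nms)
}

# net-change matrix with buffered-species rows zeroed: the matrix actually
# applied in state updates and in the drift
effectiveNetChange <- function(sys) {
  nu <- sys@netChange
  nu[sys@fixedSpecies, ] <- 0L
  nu
}

# falling factorial x(x-1)...(x-m+1), valid for real x
fallingFactorial <- function(x, m) {
  out <- rep(1, length(x))
  for (l in seq_len(m) - 1L) out <- out * (x - l)
  out
}

# d/dx of the falling factorial: sum over factors of the product of the rest
fallingFactorialDeriv <- function(x, m) {
  if (m == 0L) return(rep(0, length(x)))
  out <- rep(0, length(x))
  for (l in seq_len(m) - 1L) {
    term <- rep(1, length(x))
    for (lp in seq_len(m) - 1L) if (lp != l) term <- term * (x - lp)
    out <- out + term
  }
  out
}

#' Mass-action propensities
#'
#' Evaluates \eqn{a_j(x) = c_j \prod_i C(x_i, m_{ij})} for every reaction.
#' For integer states this counts distinct reactant combinations; the same
#' falling-factorial expression extends to real-valued states (used inside
#' the deterministic substeps), where any negative factor is clamped to
#' zero propensity.
#'
#' @param sys a \linkS4class{ReactionSystem}.
#' @param x numeric state vector of length \code{nSpecies(sys)}.
#' @param real logical; if \code{TRUE}, \code{x} may be real-valued.
#' @return numeric vector of M non-negative propensities.
#' @export
propensities <- function(sys, x, real = FALSE) {
  if (length(x) != nSpecies(sys))
    stop("state vector has wrong length")
  if (!real && any(x < 0)) stop("negative copy number in state")
  M <- nReactions(sys)
  a <- sys@rateConstants
  orders <- sys@reactantOrders
  for (j in seq_len(M)) {
    idx <- which(orders[, j] > 0L)
    for (i in idx) {
      m <- orders[i, j]
      a[j] <- a[j] * fallingFactorial(x[i], m) / factorial(m)
    }
  }
  pmax(a, 0)
}

#' Deterministic reaction-rate drift
#'
#' Right-hand side of the reaction-rate equations,
#' \eqn{\sum_j \nu_j a_j(x)}, with buffered-species rows zeroed.  Accepts
#' real-valued states; this is the vector field integrated by the modified
#' midpoint stages.
#'
#' @inheritParams propensities
#' @return numeric vector of length N.
#' @export
rreDrift <- function(sys, x) {
  a <- propensities(sys, x, real = TRUE)
  drop(effectiveNetChange(sys) %*% a)
}

#' Reaction-coupling matrix
#'
#' The M x M matrix \eqn{f_{jj'}(x) = \sum_i \partial a_j/\partial x_i \,
#' \nu_{ij'}} governing the first-order-closure moment equations for the
#' per-step reaction counts.  Partial derivatives are those of the
#' real-valued mass-action extension; buffered species contribute nothing
#' (their \eqn{\nu} rows are zero in updates).
#'
#' @inheritParams propensities
#' @return M x M numeric matrix.
#' @export
reactionCouplingMatrix <- function(sys, x) {
  N <- nSpecies(sys); M <- nReactions(sys)
  orders <- sys@reactantOrders
  dA <- matrix(0, M, N)   # dA[j, i] = da_j / dx_i
  for (j in seq_len(M)) {
    idx <- which(orders[, j] > 0L)
    for (i in idx) {
      g <- sys@rateConstants[j]
      for (ip in idx) {
        m <- orders[ip, j]
        g <- g * (if (ip == i) fallingFactorialDeriv(x[ip], m)
                  else fallingFactorial(x[ip], m)) / factorial(m)
      }
      dA[j, i] <- g
    }
  }
  dA %*% effectiveNetChange(sys)
}

#' Left-null vectors of the effective stoichiometry
#'
#' Basis for the linear conservation laws \eqn{w^T X = const} that hold
#' along every realisation (computed on the net-change matrix with buffered
#' rows zeroed, restricted to non-buffered species).
#'
#' @param sys a \linkS4class{ReactionSystem}.
#' @return numeric matrix with one conservation vector per column (possibly
#'   zero columns).
#' @export
conservationLaws <- function(sys) {
  nu <- effectiveNetChange(sys)
  s <- svd(nu, nu = nrow(nu))
  tol <- max(dim(nu)) * max(s$d, 0) * .Machine$double.eps
  keep <- seq_len(nrow(nu)) > sum(s$d > tol)
  w <- s$u[, keep, drop = FALSE]
  # conservation laws must not involve buffered species
  w[, colSums(abs(w[sys@fixedSpecies, , drop = FALSE])) < 1e-10, drop = FALSE]
}

# Precompiled fast evaluators for the inner simulation loops.  Semantics
# identical to propensities()/rreDrift(); the (species, reaction,
# multiplicity) triplets and the effective stoichiometry are hoisted out of
# the per-call path.
.makeEvaluators <- function(sys) {
  orders <- sys@reactantOrders
  cs <- sys@rateConstants
  nz <- which(orders > 0L, arr.ind = TRUE)
  ti <- nz[, 1L]; tj <- nz[, 2L]
  tm <- orders[nz]
  tfact <- factorial(tm)
  maxm <- if (length(tm)) max(tm) else 0L
  nuEff <- effectiveNetChange(sys)
  M <- length(cs)
  prop <- function(x) {
    a <- cs
    if (length(ti)) {
      val <- rep(1, length(ti))
      for (l in seq_len(maxm) - 1L) {
        sel <- tm > l
        val[sel] <- val[sel] * (x[ti[sel]] - l)
      }
      val <- val / tfact
      for (u in seq_along(ti)) a[tj[u]] <- a[tj[u]] * val[u]
    }
    pmax(a, 0)
  }
  list(prop = prop,
       drift = function(x) drop(nuEff %*% prop(x)),
       nuEff = nuEff, M = M)
}

formatReaction <- function(sys, j) {
  side <- function(v) {
    idx <- which(v > 0L)
    if (!length(idx)) return("0")
    paste(sprintf("%s%s", ifelse(v[idx] > 1L, paste0(v[idx], " "), ""),
                  sys@speciesNames[idx]), collapse = " + ")
  }
  lhs <- sys@reactantOrders[, j]
  rhs <- sys@reactantOrders[, j] + sys@netChange[, j]
  sprintf("%s : %s -> %s ; c=%g", sys@reactionNames[j], side(lhs), side(rhs),
          sys@rateConstants[j])
}
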