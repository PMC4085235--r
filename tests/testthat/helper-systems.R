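# Shared fixtures and helpers for the test suite.  Everything is built in
# code; no stored data.

# one-species linear decay X -> 0
decaySystem <- function(c = 1) {
  reactionSystem("X", list(
    list(name = "decay", reactants = c(X = 1), products = NULL, c = c)))
}

# pairwise annihilation X + Y -> 0
annihilationSystem <- function(c = 1e-5) {
  reactionSystem(c("X", "Y"), list(
    list(name = "annihilate", reactants = c(X = 1, Y = 1), products = NULL,
         c = c)))
}

# zero-order-only source 0 -> X
sourceSystem <- function(c = 5) {
  reactionSystem("X", list(
    list(name = "in", reactants = NULL, products = c(X = 1), c = c)))
}

# check every linear conservation law of `sys` along a trajectory
expect_conserved <- function(traj, sys, tol = 1e-8) {
  w <- conservationLaws(sys)
  if (ncol(w) == 0) return(invisible(TRUE))
  vals <- trajStates(traj) %*% w
  for (j in seq_len(ncol(vals)))
    expect_lt(max(abs(vals[, j] - vals[1, j])), tol)
  invisible(TRUE)
}

# Monte-Carlo z-test helper: |mean(x) - mu| within `z` standard errors
expect_mc_mean <- function(x, mu, z = 4) {
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), z * se + 1e-12)
}

# small dense matrix power (used by the midpoint order test)
`%^%` <- function(A, k) {
  out <- diag(nrow(A))
  while (k > 0) { out <- out %*% A; k <- k - 1 }
  out
}
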