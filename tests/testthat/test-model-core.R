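# Reaction-network representation, mass-action propensities, drift and the
# reaction-coupling matrix.

test_that("built-in fixtures have the documented dimensions", {
  dims <- list(chain_decay = c(3, 2), michaelis_menten = c(4, 3),
               schlogl = c(3, 4), enzymes = c(8, 12), yule = c(1, 1),
               annihilation = c(2, 1), birth_death = c(1, 2))
  for (nm in names(dims)) {
    fx <- builtinFixture(nm)
    expect_identical(c(nSpecies(fx$sys), nReactions(fx$sys)),
                     as.integer(dims[[nm]]), info = nm)
    expect_length(fx$x0, nSpecies(fx$sys))
    expect_true(fx$T > 0)
  }
})

test_that("invalid system specifications are rejected", {
  expect_error(reactionSystem("X", list()), "empty reaction list")
  expect_error(reactionSystem("X", list(
    list(name = "r", reactants = c(Y = 1), products = NULL, c = 1))),
    "unknown species")
  expect_error(reactionSystem("X", list(
    list(name = "r", reactants = c(X = 1), products = NULL, c = -1))),
    "non-positive rate")
  expect_error(reactionSystem("X", list(
    list(name = "r", reactants = c(X = 1), products = c(X = 1), c = 1))),
    "zero net change")
})

test_that("reversible reactions expand forward-then-reverse", {
  sys <- reactionSystem(c("A", "B"), list(
    list(name = "bind", reactants = c(A = 1), products = c(B = 1),
         c = 2, cRev = 3)))
  expect_identical(nReactions(sys), 2L)
  expect_identical(reactionNames(sys), c("bind", "bind_rev"))
  expect_equal(rateConstants(sys), c(2, 3))
  expect_equal(netChange(sys)[, 1], c(A = -1, B = 1))
  expect_equal(netChange(sys)[, 2], c(A = 1, B = -1))
})

test_that("propensities follow distinct-combination mass action", {
  fx <- builtinFixture("chain_decay")
  expect_equal(propensities(fx$sys, c(10000, 1, 0)), c(10000, 1))
  # pair combinatorics: A + 2X -> 3X at A = 1e5, X = 250
  sg <- builtinFixture("schlogl")
  a <- propensities(sg$sys, c(250, 1e5, 2e5))
  expect_equal(a[1], 3e-7 * 1e5 * 250 * 249 / 2)  # 933.75
  expect_equal(a[1], 933.75)
  # triple combinatorics: 3X -> A + 2X
  expect_equal(a[2], 1e-4 * 250 * 249 * 248 / 6)
  # all-zero state kills every propensity with no zero-order input
  expect_equal(propensities(fx$sys, c(0, 0, 0)), c(0, 0))
  expect_error(propensities(fx$sys, c(-1, 0, 0)), "negative")
})

test_that("propensity vanishes when a reactant count is below its multiplicity", {
  sg <- builtinFixture("schlogl")
  expect_equal(propensities(sg$sys, c(1, 1e5, 2e5))[1], 0)  # needs 2 X
  expect_equal(propensities(sg$sys, c(2, 1e5, 2e5))[2], 0)  # needs 3 X
  # random non-negative states always give non-negative propensities
  set.seed(11)
  for (rep in 1:20) {
    x <- rpois(3, 3)
    expect_true(all(propensities(sg$sys, x) >= 0))
  }
})

test_that("drift is the nu-weighted propensity sum with fixed rows zeroed", {
  fx <- builtinFixture("chain_decay")
  expect_equal(unname(rreDrift(fx$sys, c(10000, 1, 0))),
               c(-10000, 9999, 1))
  yl <- builtinFixture("yule")
  expect_equal(unname(rreDrift(yl$sys, 1000)), 200)
  expect_equal(unname(rreDrift(fx$sys, c(0, 0, 0))), c(0, 0, 0))
  # buffered species never move
  sg <- builtinFixture("schlogl")
  d <- rreDrift(sg$sys, c(250, 1e5, 2e5))
  expect_equal(unname(d[2:3]), c(0, 0))
})

test_that("reaction-coupling matrix matches hand values and finite differences", {
  yl <- builtinFixture("yule")
  expect_equal(reactionCouplingMatrix(yl$sys, 1000), matrix(0.2, 1, 1))
  an <- annihilationSystem(1e-5)
  expect_equal(reactionCouplingMatrix(an, c(10000, 10000)),
               matrix(-0.2, 1, 1))
  # zero-order reaction has constant propensity: zero coupling
  expect_equal(reactionCouplingMatrix(sourceSystem(), 7), matrix(0, 1, 1))
  # central finite differences of a_j along nu_{j'} on all fixtures
  for (nm in c("chain_decay", "michaelis_menten", "schlogl", "enzymes")) {
    fx <- builtinFixture(nm)
    sys <- fx$sys
    x <- as.numeric(fx$x0)
    f <- reactionCouplingMatrix(sys, x)
    nuEff <- netChange(sys)
    nuEff[fixedSpecies(sys), ] <- 0L
    M <- nReactions(sys)
    fFD <- matrix(0, M, M)
    for (jp in seq_len(M)) {
      ap <- propensities(sys, x + nuEff[, jp], real = TRUE)
      am <- propensities(sys, x - nuEff[, jp], real = TRUE)
      fFD[, jp] <- (ap - am) / 2
    }
    expect_lt(max(abs(f - fFD)) / max(1, max(abs(f))), 1e-3)
  }
})

test_that("conservation laws annihilate the effective stoichiometry", {
  fx <- builtinFixture("chain_decay")
  w <- conservationLaws(fx$sys)
  expect_identical(ncol(w), 1L)               # X1 + X2 + X3
  nuEff <- netChange(fx$sys)
  expect_lt(max(abs(t(w) %*% nuEff)), 1e-10)
  mm <- builtinFixture("michaelis_menten")
  expect_identical(ncol(conservationLaws(mm$sys)), 2L)  # X2+X3, X1+X3+X4
  en <- builtinFixture("enzymes")
  expect_identical(ncol(conservationLaws(en$sys)), 2L)  # two enzyme totals
})
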