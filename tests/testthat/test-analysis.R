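# Histograms, L1 error, efficiency, weak-order regression and the exact
# oracles.

test_that("histograms bin half-open with probabilities summing to one", {
  h <- buildHistogram(c(0, 1, 2, 3), binWidth = 2)
  expect_equal(binProbabilities(h), c(0.5, 0.5))
  expect_equal(binEdges(h), c(0, 2, 4))
  h1 <- buildHistogram(rep(7, 10), binWidth = 3)
  expect_equal(binProbabilities(h1), 1)
  set.seed(2)
  for (w in c(1, 2, 5)) {
    h2 <- buildHistogram(rpois(500, 20), w)
    expect_equal(sum(binProbabilities(h2)), 1)
  }
  expect_error(buildHistogram(numeric(0), 1), "no samples")
  # pmf binning agrees with sample binning in the large-n limit structure
  hp <- pmfHistogram(0:3, rep(0.25, 4), binWidth = 2)
  expect_equal(binProbabilities(hp), c(0.5, 0.5))
})

test_that("L1 distance is a metric on shared bins", {
  mk <- function(p) new("Histogram", binEdges = seq(0, length(p)),
                        probabilities = p, nSamples = 1L)
  expect_equal(l1Distance(mk(c(1, 0)), mk(c(1, 0))), 0)
  expect_equal(l1Distance(mk(c(1, 0)), mk(c(0, 1))), 2)
  expect_equal(l1Distance(mk(c(0.5, 0.5)), mk(c(1, 0))), 1)
  # symmetry and triangle inequality on random histograms
  set.seed(4)
  for (i in 1:10) {
    p <- function() { v <- runif(4); v / sum(v) }
    a <- mk(p()); b <- mk(p()); cc <- mk(p())
    expect_equal(l1Distance(a, b), l1Distance(b, a))
    expect_lte(l1Distance(a, cc),
               l1Distance(a, b) + l1Distance(b, cc) + 1e-12)
  }
  bad <- new("Histogram", binEdges = c(0, 2, 4),
             probabilities = c(0.5, 0.5), nSamples = 1L)
  expect_error(l1Distance(mk(c(1, 0)), bad), "identical bins")
})

test_that("efficiency is inverse total error over total runtime", {
  expect_equal(efficiency(2, 4), 0.125)
  expect_equal(efficiency(c(1, 1), c(2, 2)), 0.125)
  expect_equal(efficiency(2, 8), efficiency(2, 4) / 2)  # linear in runtime
  expect_warning(eta <- efficiency(0, 1), "unbounded")
  expect_identical(eta, Inf)
  expect_error(efficiency(numeric(0), 1), "empty")
})

test_that("weak-order slope recovers exact power laws", {
  expect_equal(weakOrderSlope(c(0.2, 0.1), c(0.04, 0.01)), 2)
  expect_equal(weakOrderSlope(c(0.3, 0.1, 0.03), rep(2, 3)), 0)
  taus <- 10^seq(-1, -4, length.out = 8)
  expect_equal(weakOrderSlope(taus, 3 * taus^4), 4, tolerance = 1e-10)
  expect_error(weakOrderSlope(c(0.1, 0.01), c(0.5, 0)), "positive")
})

test_that("Yule moment oracle matches closed form and SSA", {
  expect_equal(linearMomentOracle(0.2, 1000, 0),
               list(mean = 1000, variance = 0))
  o <- linearMomentOracle(0.2, 1000, 12)
  expect_equal(o$mean, 1000 * exp(2.4))
  expect_equal(o$mean, 11023.18, tolerance = 1e-6)
  # SSA cross-validation of mean and variance at a smaller size
  yl <- builtinFixture("yule")
  ens <- simulateEnsemble(yl$sys, 100, 2, "ssa", n = 3000, seed = 13)
  o2 <- linearMomentOracle(0.2, 100, 2)
  expect_mc_mean(ens[, 1], o2$mean)
  v <- var(ens[, 1])
  seV <- o2$variance * sqrt(2 / (nrow(ens) - 1)) * 2  # rough kurtosis slack
  expect_lt(abs(v - o2$variance), 4 * seV)
})

test_that("the truncated CME oracle solves small systems exactly", {
  an <- annihilationSystem(1)
  cm <- cmeOracle(an, c(2, 2), 0.5)
  # hand-solved 3-state master equation
  expect_equal(cm$mean[1], (2 / 3) * exp(-2) + (4 / 3) * exp(-0.5),
               tolerance = 1e-9)
  expect_equal(sum(cm$prob), 1, tolerance = 1e-8)
  # T = 0: point mass at the initial state
  cm0 <- cmeOracle(an, c(2, 2), 1e-12)
  expect_equal(cm0$prob[cm0$support == 0], 1, tolerance = 1e-9)
  # zero propensities: frozen point mass
  cmF <- cmeOracle(decaySystem(1), 0, 5)
  expect_equal(cmF$mean[1], 0)
  # SSA cross-check on the birth-death toy at T = 2
  bd <- builtinFixture("birth_death")
  cmBD <- cmeOracle(bd$sys, 0, 2, truncation = 60)
  ens <- simulateEnsemble(bd$sys, 0, 2, "ssa", n = 3000, seed = 41)
  expect_mc_mean(ens[, 1], cmBD$mean[1])
})

test_that("chain distribution propagates exact kernels", {
  dec <- decaySystem(1)
  # zero propensities: point mass stays put
  cd0 <- chainDistribution(decaySystem(1), 0, tau = 1, T = 2, "tl")
  expect_equal(sum(cd0$prob), 1)
  expect_equal(cd0$mean[1], 0)
  # Euler tau-leap on a 3-state decay toy vs the analytic per-step
  # composition of clamped-Poisson kernels
  tau <- 0.25; nStep <- 2
  cd <- chainDistribution(dec, 2, tau, tau * nStep, "tl")
  pv <- c(`0` = 0, `1` = 0, `2` = 1)           # states v = 0, 1, 2
  stepOnce <- function(p) {
    q <- c(0, 0, 0)
    for (v in 0:2) {
      if (p[v + 1] == 0) next
      lam <- v * tau
      probs <- dpois(0:10, lam)
      for (k in 0:10) {
        vNew <- max(v - k, 0)
        q[vNew + 1] <- q[vNew + 1] + p[v + 1] * probs[k + 1]
      }
      q[max(v - 11, 0) + 1] <- q[max(v - 11, 0) + 1] +
        p[v + 1] * (1 - sum(probs))
    }
    q
  }
  p <- pv
  for (s in seq_len(nStep)) p <- stepOnce(p)
  # align: support is m = reactions fired, state v = 2 - m
  probByState <- rev(cd$prob)                  # v = 0,1,2
  expect_equal(probByState, p, tolerance = 1e-8)
  expect_equal(sum(cd$prob), 1, tolerance = 1e-12)
})

test_that("chain-decay marginals integrate to binomial convolutions", {
  ref1 <- chainDecayMarginal(1)
  expect_equal(sum(ref1$prob), 1)
  expect_equal(sum(ref1$support * ref1$prob), 10000 * exp(-5),
               tolerance = 1e-8)
  ref2 <- chainDecayMarginal(2)
  expect_equal(sum(ref2$support * ref2$prob),
               10000 * 5 * exp(-5) + exp(-5), tolerance = 1e-6)
  ref3 <- chainDecayMarginal(3)
  m3 <- sum(ref3$support * ref3$prob)
  expect_equal(sum(sum(ref1$support * ref1$prob),
                   sum(ref2$support * ref2$prob), m3), 10001,
               tolerance = 1e-6)
  # SSA cross-check of the X2 marginal mean
  fx <- builtinFixture("chain_decay")
  ens <- simulateEnsemble(fx$sys, fx$x0, fx$T, "ssa", n = 2000, seed = 47)
  expect_mc_mean(ens[, 2], sum(ref2$support * ref2$prob))
})
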