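# Degree-of-advancement variant: moment ODEs, hybrid sampling, UBTL.

test_that("moment right-hand side matches hand values", {
  yl <- builtinFixture("yule")
  r <- momentRhs(yl$sys, 1000, mu = 0, var = 0)
  expect_equal(r$dmu, 200)                    # f mu + a = 0 + 0.2*1000
  expect_equal(r$dvar, 200)                   # 2 f V + dmu = 0 + 200
  # all propensities zero: zero derivatives
  fx <- builtinFixture("chain_decay")
  r0 <- momentRhs(fx$sys, c(0, 0, 5), c(0, 0), c(0, 0))
  expect_equal(r0$dmu, c(0, 0))
  expect_equal(r0$dvar, c(0, 0))
  # zero-order reaction: f = 0 so dmu = dvar = a
  src <- sourceSystem(5)
  rs <- momentRhs(src, 0, 3, 7)
  expect_equal(rs$dmu, 5)
  expect_equal(rs$dvar, 5)
})

test_that("moment integration is exact for zero-order input and order two otherwise", {
  src <- sourceSystem(5)
  m <- integrateMoments(src, 0, tau = 2, nSub = 2)
  expect_equal(m$mu, 10)                      # mu = V = a tau exactly
  expect_equal(m$var, 10)
  m0 <- integrateMoments(src, 0, tau = 0, nSub = 2)
  expect_equal(c(m0$mu, m0$var), c(0, 0))
  # X -> 2X: mu(tau) -> x (e^{c tau} - 1), order 2, >= 4 extrapolated
  yl <- builtinFixture("yule")
  exact <- 1000 * (exp(0.2 * 0.5) - 1)
  ns <- c(2, 4, 8, 16)
  errs <- vapply(ns, function(n)
    abs(integrateMoments(yl$sys, 1000, 0.5, n)$mu - exact), numeric(1))
  expect_lt(abs(weakOrderSlope(0.5 / ns, errs) - 2), 0.15)
})

test_that("hybrid sampling switches between Poisson and rounded Gaussian at ten", {
  set.seed(17)
  # below the threshold: genuine Poisson draws (integer, right moments)
  k <- hybridSample(rep(5, 2e4), rep(99, 2e4))  # var ignored on this branch
  expect_true(all(k == floor(k)))
  expect_mc_mean(k, 5)
  expect_lt(abs(var(k) - 5), 0.2)
  # degenerate Gaussian: deterministic rounding
  expect_equal(hybridSample(12, 0), 12)
  expect_equal(hybridSample(12.49, 0), 12)
  expect_equal(hybridSample(12.5, 0), 13)      # half-up ties
  # matched-moment Gaussian branch (rounding adds <= 1/12 to the variance)
  k2 <- hybridSample(rep(50, 1e5), rep(50, 1e5))
  expect_mc_mean(k2, 50)
  expect_lt(abs(var(k2) - 50), 1)
  expect_true(all(k2 >= 0))
})

test_that("SBS-DA mirrors SBS on linear systems and conserves on fixtures", {
  fx <- builtinFixture("chain_decay")
  st <- solverSettings(s1 = 0.15, s2 = 0.2, atol = 1e-6, rtol = 1e-5,
                       tau0 = 1)
  set.seed(19)
  tr <- sbsDaSimulate(fx$sys, fx$x0, fx$T, st)
  expect_equal(trajTimes(tr)[length(trajTimes(tr))], fx$T)
  expect_conserved(tr, fx$sys)
  # zero propensities: unchanged
  rec <- sbsDaStep(fx$sys, c(0, 0, 9), tau = 2)
  expect_equal(unname(rec$state), c(0, 0, 9))
  # exact-in-mean on the linear fixture (Eq-level agreement with SBS)
  ens <- simulateEnsemble(fx$sys, fx$x0, fx$T, "sbsda", n = 2000, st,
                          seed = 23)
  expect_mc_mean(ens[, 1], 10000 * exp(-5))
  # the deterministic mean maps of SBS and SBS-DA coincide for linear
  # propensities (same linear ODE for the mean)
  yl <- builtinFixture("yule")
  for (tt in c(1.5, 0.5)) {
    expect_equal(linearMeanRecursion(yl$sys, 1000, 12, tt, "sbs", 2L),
                 linearMeanRecursion(yl$sys, 1000, 12, tt, "sbsda", 2L),
                 tolerance = 1e-9)
  }
})

test_that("variance table is non-negative and equals the mean for f = 0", {
  src <- sourceSystem(5)
  for (tt in c(0.1, 1, 3)) {
    m <- integrateMoments(src, 0, tt, 4)
    expect_equal(m$mu, m$var)
    expect_gte(m$var, 0)
  }
  # decaying channel: variance stays clamped at >= 0 for large steps
  dec <- decaySystem(2)
  m2 <- integrateMoments(dec, 5, 10, 8)
  expect_gte(m2$var, 0)
})

test_that("UBTL is exact in mean on chain decay and Poisson-consistent", {
  fx <- builtinFixture("chain_decay")
  ens <- simulateEnsemble(fx$sys, fx$x0, fx$T, "ubtl", n = 1500,
                          solverSettings(epsilon = 2), seed = 29)
  expect_mc_mean(ens[, 1], 10000 * exp(-5))
  # zero propensities: unchanged single step to T
  tr0 <- ubtlSimulate(fx$sys, c(0, 0, 4), fx$T)
  expect_equal(unname(finalState(tr0)), c(0, 0, 4))
  # zero-order-only system: per-step K has mu = V = a tau (Poisson law)
  src <- sourceSystem(5)
  set.seed(31)
  k <- replicate(5000, {
    tr <- ubtlSimulate(src, 0, T = 1, epsilon = 5)
    trajStates(tr)[2, 1] - trajStates(tr)[1, 1]
  })
  tau1 <- 1  # first step covers [0, min(tauSelect, T)]
  expect_mc_mean(k, 5 * tau1)
  expect_lt(abs(var(k) - 5 * tau1), 0.4)
})
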