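# Adaptive SBS stepper: stepsize/order control, acceptance, Poisson update.

test_that("candidate stepsize follows the safety-scaled error power law", {
  # err = S2: the power term is exactly one
  expect_equal(candidateStepsize(2, 0.3, 5, s1 = 0.7, s2 = 0.3), 2 * 0.7)
  # direct substitution: (S2/err)^(1/3) with S1 = S2 = 1
  expect_equal(candidateStepsize(1, 8, 2, s1 = 1 - 1e-14, s2 = 1 - 1e-14),
               0.5, tolerance = 1e-10)
  # vanishing error engages the growth guard
  expect_equal(candidateStepsize(1, 0, 3, s1 = 0.5, s2 = 0.5,
                                 maxGrowth = 4), 1 * 0.5 * 4)
})

test_that("column selection minimises work per unit step", {
  expect_equal(selectColumn(data.frame(k = c(1, 2), tau = c(0.1, 0.5),
                                       work = c(3, 7))),
               list(k = 2, tau = 0.5))          # W: 30 vs 14
  expect_equal(selectColumn(data.frame(k = 3, tau = 0.2, work = 13)),
               list(k = 3, tau = 0.2))
  # exact tie breaks toward the smaller column
  expect_equal(selectColumn(data.frame(k = c(2, 4), tau = c(1, 2),
                                       work = c(5, 10)))$k, 2)
  expect_error(selectColumn(data.frame(k = numeric(0), tau = numeric(0),
                                       work = numeric(0))), "no candidate")
})

test_that("a zero-propensity state passes through the stepper unchanged", {
  fx <- builtinFixture("chain_decay")
  rec <- sbsStep(fx$sys, c(0, 0, 50), tau = 1)
  expect_equal(unname(rec$state), c(0, 0, 50))
  expect_identical(rec$kConverged, 1L)
  expect_identical(rec$rejections, 0L)
  expect_equal(rec$extrapolated, c(0, 0))
})

test_that("steps are rejected and retried when the window cannot converge", {
  fx <- builtinFixture("chain_decay")
  # a brutal tolerance with a huge first step forces at least one halving
  st <- solverSettings(s1 = 0.5, s2 = 0.5, atol = 1e-300, rtol = 1e-14,
                       kMax = 3L, tau0 = 5)
  set.seed(8)
  tr <- sbsSimulate(fx$sys, fx$x0, fx$T, st)
  expect_gt(sum(stepInfo(tr)$rejections), 0)
})

test_that("accepted columns always satisfy the err <= 1 gate", {
  fx <- builtinFixture("chain_decay")
  st <- solverSettings(s1 = 0.5, s2 = 0.5, atol = 1e-6, rtol = 1e-6,
                       tau0 = 1)
  set.seed(9)
  x <- as.numeric(fx$x0)
  kTarget <- NA_integer_
  tau <- 1
  for (i in 1:15) {
    rec <- sbsStep(fx$sys, x, tau, st, kTarget)
    # replay the accepted table deterministically and check its gate
    tb <- nevilleTable()
    for (q in seq_len(rec$kConverged))
      tb <- nevilleExtend(tb, propensityIntegral(fx$sys, x, rec$tauUsed,
                                                 2L * q), 2L * q)
    expect_lte(columnError(tb, rec$kConverged, st@atol, st@rtol), 1)
    expect_equal(nevilleTop(tb, rec$kConverged), rec$extrapolated)
    x <- rec$state
    tau <- rec$tauNext
    kTarget <- rec$kNext
  }
})

test_that("per-step work matches the A_q accounting", {
  fx <- builtinFixture("chain_decay")
  st <- solverSettings(s1 = 0.5, s2 = 0.5, atol = 1e-6, rtol = 1e-6,
                       tau0 = 0.5)
  set.seed(10)
  tr <- sbsSimulate(fx$sys, fx$x0, fx$T, st)
  si <- stepInfo(tr)
  clean <- si[si$rejections == 0, ]
  expect_gt(nrow(clean), 0)
  expect_true(all(clean$work == workSequence(8)[clean$k]))
})

test_that("adaptive SBS reaches T exactly, conserves, and is exact in mean", {
  fx <- builtinFixture("chain_decay")
  st <- solverSettings(s1 = 0.2, s2 = 0.4, atol = 1e-6, rtol = 1e-5,
                       tau0 = 1)
  set.seed(12)
  tr <- sbsSimulate(fx$sys, fx$x0, fx$T, st)
  expect_equal(trajTimes(tr)[length(trajTimes(tr))], fx$T)
  expect_conserved(tr, fx$sys)
  ens <- simulateEnsemble(fx$sys, fx$x0, fx$T, "sbs", n = 2000, st,
                          seed = 21)
  expect_mc_mean(ens[, 1], 10000 * exp(-5))
})

test_that("single fixed steps replay the integral + extrapolation + Poisson pipeline", {
  yl <- builtinFixture("yule")
  # k = 2: manual composition with the same RNG stream must agree exactly
  set.seed(33)
  tr <- sbsFixed(yl$sys, 1000, T = 0.5, tau = 0.5, k = 2)
  set.seed(33)
  tb <- nevilleTable()
  tb <- nevilleExtend(tb, propensityIntegral(yl$sys, 1000, 0.5, 2), 2)
  tb <- nevilleExtend(tb, propensityIntegral(yl$sys, 1000, 0.5, 4), 4)
  k <- rpois(1, nevilleTop(tb, 2))
  expect_equal(unname(finalState(tr)), 1000 + k)
  # tau -> 0: single-step mean increment approaches a(x0) tau
  lam <- vapply(c(1e-3, 1e-4), function(tt)
    propensityIntegral(yl$sys, 1000, tt, 2) / tt, numeric(1))
  expect_equal(lam, c(200, 200), tolerance = 1e-4)
})

test_that("exact mean recursion shows weak orders two and four on the Yule system", {
  yl <- builtinFixture("yule")
  taus <- c(1.5, 1, 0.75, 0.5, 0.375, 0.25)
  s1 <- linearOrderStudy(yl$sys, yl$x0, yl$T, taus, "sbs", 1L)$slope
  s2 <- linearOrderStudy(yl$sys, yl$x0, yl$T, taus, "sbs", 2L)$slope
  sTl <- linearOrderStudy(yl$sys, yl$x0, yl$T, taus, "tl")$slope
  expect_lt(abs(s1 - 2), 0.2)
  expect_lt(abs(s2 - 4), 0.3)
  expect_lt(abs(sTl - 1), 0.3)
  # the recursion itself matches direct simulation in expectation
  set.seed(3)
  ens <- replicate(400, finalState(sbsFixed(yl$sys, 1000, 12, 1.5, k = 2,
                                            saveTrajectory = FALSE)))
  expect_mc_mean(ens, linearMeanRecursion(yl$sys, 1000, 12, 1.5, "sbs", 2L))
})
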