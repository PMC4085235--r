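# Modified midpoint stages, propensity integrals, Neville extrapolation
# and the scaled column error.

test_that("modified midpoint reproduces the hand-executed Gragg scheme", {
  m <- mmpStates(function(x) -x, 1, tau = 0.1, nSub = 2)
  expect_equal(drop(m$stages), c(1, 0.95, 0.905))
  expect_equal(drop(m$smoothed), 0.904875)
  expect_identical(m$nEvals, 3L)
  # zero drift: all stages equal the start
  m0 <- mmpStates(function(x) 0 * x, c(2, 3), 1, 4)
  expect_true(all(m0$stages[, 1] == 2) && all(m0$stages[, 2] == 3))
  # constant drift: exact endpoint
  mc <- mmpStates(function(x) c(2, -1), c(10, 10), 0.5, 6)
  expect_equal(mc$smoothed, c(11, 9.5))
})

test_that("modified midpoint endpoint converges with order two", {
  A <- matrix(c(-1, 1, 0, -0.5), 2, 2)     # linear system, exact = expm
  x0 <- c(1, 2)
  tau <- 1
  exact <- as.numeric(Reduce(`+`, lapply(0:60, function(k)
    (A * tau) %^% k %*% x0 / factorial(k))))
  ns <- c(8, 16, 32, 64)
  errs <- vapply(ns, function(n)
    max(abs(mmpStates(function(x) drop(A %*% x), x0, tau, n)$smoothed -
              exact)), numeric(1))
  slope <- weakOrderSlope(tau / ns, errs)
  expect_lt(abs(slope - 2), 0.1)
})

test_that("propensity integral matches the worked example and converges", {
  yl <- builtinFixture("yule")
  # hand-executed: stages 1000, 1050, 1105; trapezoid 0.25*(100+210+110.5)
  expect_equal(propensityIntegral(yl$sys, 1000, 0.5, 2), 105.125)
  expect_equal(propensityIntegral(yl$sys, 1000, 0, 4), 0)
  # constant propensity: trapezoid exact for any substep count
  src <- sourceSystem(5)
  expect_equal(propensityIntegral(src, 0, 2, 2), 10)
  expect_equal(propensityIntegral(src, 0, 2, 8), 10)
  # order 2 in the substep; >= 4 after one extrapolation
  exact <- 1000 * (exp(0.1) - 1)           # int c x dt over tau = 0.5
  ns <- c(2, 4, 8, 16)
  errs <- vapply(ns, function(n)
    abs(propensityIntegral(yl$sys, 1000, 0.5, n) - exact), numeric(1))
  expect_lt(abs(weakOrderSlope(0.5 / ns, errs) - 2), 0.1)
  errsX <- vapply(ns, function(n) {
    tb <- nevilleTable()
    tb <- nevilleExtend(tb, propensityIntegral(yl$sys, 1000, 0.5, n), n)
    tb <- nevilleExtend(tb, propensityIntegral(yl$sys, 1000, 0.5, 2 * n),
                        2 * n)
    abs(nevilleTop(tb, 2) - exact)
  }, numeric(1))
  expect_gt(weakOrderSlope(0.5 / ns, errsX), 4 - 0.2)
})

test_that("Neville extrapolation in h^2 is exact on even polynomials", {
  # f(h) = 1 + h^2 sampled at h = 0.4, 0.2: one extrapolation kills h^2
  tb <- nevilleTable()
  tb <- nevilleExtend(tb, 1 + 0.4^2, 2)    # n = 2 -> h = 0.4 (tau = 0.8)
  tb <- nevilleExtend(tb, 1 + 0.2^2, 4)
  expect_equal(nevilleTop(tb, 2), 1)
  # single entry: no extrapolation beyond column 1
  tb1 <- nevilleExtend(nevilleTable(), c(3, 4), 2)
  expect_equal(nevilleTop(tb1, 1), c(3, 4))
  # constant data: every extrapolant equals the constant
  tb2 <- nevilleTable()
  for (n in c(2, 4, 6)) tb2 <- nevilleExtend(tb2, c(7, 7), n)
  for (q in 1:3) expect_equal(nevilleTop(tb2, q), c(7, 7))
  # c0 + c2 h^2 + c4 h^4 recovered exactly with three rows
  f <- function(h) 2.5 - 3 * h^2 + 1.7 * h^4
  tb3 <- nevilleTable()
  for (n in c(2, 4, 6)) tb3 <- nevilleExtend(tb3, f(1 / n), n)
  expect_equal(nevilleTop(tb3, 3), 2.5, tolerance = 1e-12)
  # substep counts must increase
  expect_error(nevilleExtend(tb3, 1, 4), "increase")
})

test_that("column error implements the scaled top-difference", {
  tb <- nevilleTable()
  tb <- nevilleExtend(tb, 10, 2)
  tb <- nevilleExtend(tb, 10, 4)
  expect_equal(columnError(tb, 2, atol = 1, rtol = 1), 0)
  # entries chosen so column 2 holds 10 and 10.5 exactly
  mkTable <- function(top, second) {
    t0 <- nevilleTable()
    t0$nSub <- c(2L, 4L)
    t0$entries <- list(list(second), list(second, top))
    t0
  }
  tb2 <- mkTable(10, 10.5)
  expect_equal(columnError(tb2, 2, atol = 0, rtol = 0.1), 0.5 / 1)
  expect_equal(columnError(tb2, 2, atol = 1e-6, rtol = 0), 5e5)
  expect_error(columnError(tb2, 1, 1, 1), "q >= 2")
})

test_that("drift-evaluation counting matches the work recurrence", {
  expect_identical(workSequence(1), 3L)
  expect_identical(workSequence(3), c(3L, 7L, 13L))
  # a single midpoint pass costs n + 1 drift calls; all Romberg rows of a
  # step share the same start state, so rows 1..k cost 1 + sum(n_q) = A_k
  counter <- local({
    n <- 0L
    list(f = function(x) { n <<- n + 1L; -x }, get = function() n)
  })
  perRow <- integer(3)
  for (q in 1:3) {
    before <- counter$get()
    m <- mmpStates(counter$f, 1, 0.1, 2 * q)
    perRow[q] <- counter$get() - before
    expect_identical(m$nEvals, 2L * q + 1L)
  }
  shared <- 1L + sum(perRow - 1L)
  expect_identical(shared, workSequence(3)[3])
  # the adaptive stepper reports exactly this accounting
  fx <- builtinFixture("chain_decay")
  set.seed(6)
  rec <- sbsStep(fx$sys, as.numeric(fx$x0), 0.05,
                 solverSettings(s1 = 0.5, s2 = 0.5, rtol = 1e-4))
  expect_identical(rec$work, workSequence(rec$kConverged)[rec$kConverged])
})
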