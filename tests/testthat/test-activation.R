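test_that("activation dynamics residual encodes first-order coupling", {
  const <- activation_constants()
  # steady state
  expect_equal(activation_dynamics_residual(0.5, 0.5, 0, const), 0)
  # e > a with zero residual implies positive rate
  expect_gt(activation_rate(0.8, 0.2, const), 0)
  expect_lt(activation_rate(0.1, 0.7, const), 0)
  # residual is rate mismatch
  r <- activation_dynamics_residual(0.8, 0.2, 1.0, const)
  expect_equal(r, 1.0 - activation_rate(0.8, 0.2, const))
})

test_that("step-response rise time matches tau_act against an independent integrator", {
  const <- activation_constants()
  rhs <- function(t, y, p) list(activation_rate(1.0, y, const))
  sol <- deSolve::ode(y = 0.01, times = seq(0, 0.12, by = 1e-4), func = rhs,
                      parms = NULL, method = "ode45")
  a <- sol[, 2]
  target <- 0.01 + (1 - 0.01) * (1 - exp(-1))
  t63 <- sol[min(which(a >= target)), 1]
  expect_lt(abs(t63 - const$tau_act) / const$tau_act, 0.10)
  # deactivation is slower: time to fall 63% of the way from 1 to a_min
  sol2 <- deSolve::ode(y = 1, times = seq(0, 0.5, by = 1e-4), func = function(t, y, p)
    list(activation_rate(0.01, y, const)), parms = NULL, method = "ode45")
  a2 <- sol2[, 2]
  tgt2 <- 1 - (1 - 0.01) * (1 - exp(-1))
  t63d <- sol2[min(which(a2 <= tgt2)), 1]
  expect_gt(t63d, t63)
})

test_that("activation inverse recovers excitation from rate", {
  const <- activation_constants()
  for (e in c(0.05, 0.3, 0.9)) {
    for (a in c(0.02, 0.4, 0.8)) {
      rate <- activation_rate(e, a, const)
      expect_equal(activation_inverse(a, rate, const), e, tolerance = 1e-8)
    }
  }
})

test_that("analytic partials of the activation rate match finite differences", {
  const <- activation_constants()
  h <- 1e-7
  set.seed(1)
  e <- runif(20, 0.02, 1)
  a <- runif(20, 0.02, 1)
  p <- activation_rate_partials(e, a, const)
  de_num <- (activation_rate(e + h, a, const) - activation_rate(e - h, a, const)) / (2 * h)
  da_num <- (activation_rate(e, a + h, const) - activation_rate(e, a - h, const)) / (2 * h)
  expect_equal(p$de, de_num, tolerance = 1e-5)
  expect_equal(p$da, da_num, tolerance = 1e-5)
})
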