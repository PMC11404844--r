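test_that("engagement window follows the tanh construction", {
  b <- 1000
  w <- engagement_window(0.3, t_c = 0.3, t_d = 0.6, b = b)
  expect_equal(w$P_e, 0.5)  # tanh(0) = 0 exactly
  # deep inside the window: saturated
  w_mid <- engagement_window(0.45, 0.3, 0.6, b)
  expect_gt(w_mid$P_active, 0.999)
  # far before engagement: off
  w_pre <- engagement_window(0.1, 0.3, 0.6, b)
  expect_lt(w_pre$P_active, 1e-3)
  # components stay in (0, 1)
  tt <- seq(0, 1, by = 0.01)
  w_all <- engagement_window(tt, 0.3, 0.6, b)
  expect_true(all(w_all$P_e >= 0 & w_all$P_e <= 1))
  expect_true(all(w_all$P_active == w_all$P_e * w_all$P_d))
})

test_that("spring moment is a windowed restoring torque, linear in stiffness", {
  tt <- seq(0, 1, length.out = 201)
  q <- 0.2 * sin(2 * pi * tt)
  expect_equal(spring_moment(tt, q, k_r = 0, 0.2, 0.6), rep(0, 201))
  tau <- spring_moment(tt, q, k_r = 100, 0.2, 0.6)
  # near-zero displacement at engagement
  expect_lt(abs(tau[which.min(abs(tt - 0.2))]), 1e-6 * 100 + 0.2)
  expect_equal(spring_moment(tt, q, 300, 0.2, 0.6), 3 * tau, tolerance = 1e-12)
  # constant displacement inside a saturated window gives Hooke's law
  q_c <- rep(0.1, 201); q_c[tt < 0.25] <- 0  # engage at 0.3 where q = 0.1
  q_step <- ifelse(tt > 0.27 & tt < 0.9, 0.1, 0)
  tau_c <- spring_moment(tt, q_step, 50, 0.4, 0.8,
                         q_fun = stats::approxfun(tt, q_step, rule = 2))
  mid <- tt > 0.5 & tt < 0.7
  expect_equal(unname(tau_c[mid]), rep(0, sum(mid)), tolerance = 1e-6)
  # with engagement angle 0.1 and q dropping to 0, torque = k * 0.1
  tau_d <- 50 * engagement_window(tt, 0.4, 0.95, 1000)$P_active * (0.1 - 0)
  expect_equal(max(abs(tau_d)), 5, tolerance = 1e-6)
})

test_that("closure constraint value is the squared angle gap", {
  tt <- seq(0, 1, length.out = 401)
  q <- 0.3 * sin(2 * pi * tt)
  # same-phase disengagement: q(t_c) = q(t_d)
  expect_lt(spring_closure_constraint(tt, q, 0.1, 0.4), 1e-8)
  # constructed 0.2 rad gap -> 0.04 (infeasible against the 0.01 bound)
  t_c <- 0.25  # q = 0.3
  t_d <- uniroot(function(t) 0.3 * sin(2 * pi * t) - 0.1, c(0.3, 0.49))$root
  expect_equal(spring_closure_constraint(tt, q, t_c, t_d), 0.04,
               tolerance = 1e-4)
  # continuity in t_d
  vals <- sapply(seq(0.6, 0.7, by = 0.001), function(td)
    spring_closure_constraint(tt, q, 0.2, td))
  expect_lt(max(abs(diff(vals))), 0.01)
})

test_that("spring net work vanishes on closed paths and scales with leakage", {
  tt <- seq(0, 1, length.out = 801)
  q <- 0.25 * sin(2 * pi * tt)
  # k_r = 0: no work
  expect_equal(spring_net_work(rep(0, 801), tt, q), 0)
  # full-cycle window on a sinusoid: closed path, near-zero net work
  tau <- spring_moment(tt, q, 120, 0.01, 0.99, b = 1000)
  w_full <- spring_net_work(tau, tt, q)
  peak <- exoassist:::spring_peak_energy(tau, 120)
  expect_lt(abs(w_full) / peak, 0.02)
  # smoothing leakage decreases monotonically as b grows
  leak <- sapply(c(100, 1000, 10000), function(b) {
    tau_b <- spring_moment(tt, q, 120, 0.2, 0.7, b = b)
    abs(spring_net_work(tau_b, tt, q)) /
      exoassist:::spring_peak_energy(tau_b, 120)
  })
  expect_true(all(diff(leak) < 0))
})

test_that("motor constraints localize sign and bound violations", {
  spec <- motor_spec("ankle", assist_sign = -1, torque_bound = 50)
  tau <- c(-10, -20, 5, -60)
  v <- motor_constraints(tau, spec)
  expect_equal(v$sign_violation, c(0, 0, 5, 0))
  expect_equal(v$bound_violation, c(0, 0, 0, 10))
  expect_true(all(motor_constraints(rep(0, 4), spec)$sign_violation == 0))
  expect_error(motor_spec("ankle", assist_sign = 2), "assist_sign")
  expect_error(spring_spec("ankle", -1, t_c = 0.5, t_d = 0.4), "t_d")
})
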