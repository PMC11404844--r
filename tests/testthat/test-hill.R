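sol_params <- function() default_muscle_set()[1, ]  # soleus row

test_that("fiber + tendon reconstruction closes the muscle-tendon length", {
  p <- sol_params()
  l_mt <- p$l_t_slack + p$l_m_opt * cos(p$alpha_opt) * c(0.9, 1.0, 1.1)
  for (lm in c(0.7, 1.0, 1.3)) {
    g <- muscle_geometry(lm, l_mt, p)
    rebuilt <- g$fiber_along_tendon + g$lt_tilde * p$l_t_slack
    expect_equal(rebuilt, l_mt, tolerance = 1e-10)
    # fixed-height pennation: lm * sin(alpha) is constant
    expect_equal(g$lm * sqrt(1 - g$cos_alpha^2), p$l_m_opt * sin(p$alpha_opt),
                 tolerance = 1e-12)
  }
})

test_that("equilibrium solved by an independent bisection has near-zero residual", {
  p <- sol_params()
  l_mt <- p$l_t_slack + p$l_m_opt * cos(p$alpha_opt) * seq(0.85, 1.15, length.out = 7)
  for (a in c(0.05, 0.3, 1.0)) {
    # independent oracle: plain bisection over lm_tilde at fixed a, v = 0
    roots <- vapply(l_mt, function(l) {
      f <- function(lm) hill_equilibrium_residual(a, lm, 0, l, p)$residual
      lo <- 0.5; hi <- 1.8
      for (k in 1:200) {
        mid <- (lo + hi) / 2
        if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
      }
      (lo + hi) / 2
    }, numeric(1))
    res <- vapply(seq_along(l_mt), function(i)
      hill_equilibrium_residual(a, roots[i], 0, l_mt[i], p)$residual, numeric(1))
    expect_true(all(abs(res) < 1e-8))
    # package root-finder agrees with the bisection oracle
    expect_equal(hill_equilibrium_solve(a, l_mt, p), roots, tolerance = 1e-7)
  }
})

test_that("equilibrium has exactly one root on the validity range", {
  p <- sol_params()
  grid <- seq(0.48, 1.85, length.out = 300)
  for (a in c(0.05, 0.5, 1)) {
    for (lmt_scale in c(0.9, 1.0, 1.1)) {
      l_mt <- p$l_t_slack + p$l_m_opt * cos(p$alpha_opt) * lmt_scale
      r <- vapply(grid, function(lm)
        hill_equilibrium_residual(a, lm, 0, l_mt, p)$residual, numeric(1))
      expect_lt(r[1], 0); expect_gt(r[length(r)], 0)    # bracketing sign change
      expect_equal(sum(diff(sign(r)) != 0), 1)          # exactly one crossing
      # strictly increasing through the crossing (well-posed bracketing)
      near <- which(abs(grid - grid[which.min(abs(r))]) < 0.15)
      expect_true(all(diff(r[near]) > 0))
    }
  }
})

test_that("slack muscle at slack tendon has near-zero residual", {
  p <- sol_params()
  p$passive_scale <- 1
  # choose lm_tilde in the slack region and l_mt so the tendon sits at slack
  lm <- 0.7
  g_along <- sqrt((lm * p$l_m_opt)^2 - (p$l_m_opt * sin(p$alpha_opt))^2)
  l_mt <- p$l_t_slack + g_along
  out <- hill_equilibrium_residual(0, lm, 0, l_mt, p)
  expect_lt(abs(out$residual), 0.01)
})

test_that("equilibrium fiber length is invariant to f_max (normalized homogeneity)", {
  p <- sol_params()
  l_mt <- p$l_t_slack + p$l_m_opt * cos(p$alpha_opt)
  r1 <- hill_equilibrium_solve(0.4, l_mt, p)
  p2 <- p; p2$f_max <- 2 * p$f_max
  r2 <- hill_equilibrium_solve(0.4, l_mt, p2)
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("degenerate geometry raises a hard error", {
  p <- sol_params()
  expect_error(muscle_geometry(sin(p$alpha_opt) * 0.99, p$l_t_slack + 0.04, p),
               "degenerate")
})

test_that("rigid-tendon state is geometrically consistent", {
  p <- sol_params()
  l_mt <- p$l_t_slack + p$l_m_opt * cos(p$alpha_opt)
  st <- rigid_tendon_state(l_mt, 0.05, p)
  # fiber projection reproduces l_mt minus slack tendon
  expect_equal(st$lm_tilde * p$l_m_opt * st$cos_alpha, l_mt - p$l_t_slack,
               tolerance = 1e-12)
  expect_gt(st$v_tilde, 0)  # lengthening muscle-tendon => lengthening fiber
})
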