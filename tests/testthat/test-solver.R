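# Collocation solver behavior on the cheap two-muscle fixture. The heavier
# synthetic-model checks live in test-acceptance.R.

test_that("analytic AL gradients match finite differences (elastic, rigid, motor)", {
  trial <- two_muscle_trial(n = 41, passive_scale = 1)
  p <- two_muscle_params(passive_scale = 1)
  for (rigid in c(FALSE, TRUE)) {
    for (with_motor in c(FALSE, TRUE)) {
      opts <- solver_options(mesh = 15, rigid_tendon = rigid)
      dev <- if (with_motor) motor_spec("ankle", -1) else NULL
      disc <- discretize(trial, opts$mesh)
      ctx <- exoassist:::build_context(disc, p, solver_weights(), opts,
                                       device = dev)
      if (rigid) ctx$rigid_terms <- local({
        ft <- exoassist:::rigid_force_terms(ctx$disc_mid, p)
        list(gain = ft$gain, offset = ft$offset, v_tilde = ft$v_tilde,
             lm_tilde = ft$lm_tilde)
      })
      init <- exoassist:::initial_guess(ctx)
      x0 <- exoassist:::pack_x(init$a, init$lm, init$e, init$tau)
      set.seed(3)
      x0 <- x0 * (1 + 0.03 * runif(length(x0), -1, 1))
      lam_H <- matrix(0.4, ctx$N, ctx$nm)
      lam_A <- matrix(-0.2, ctx$N, ctx$nm)
      ev <- exoassist:::al_eval(x0, ctx, lam_H, lam_A, 5, 2)
      idx <- round(seq(1, length(x0), length.out = 25))
      g_num <- vapply(idx, function(k) {
        d <- 1e-6
        xp <- x0; xp[k] <- xp[k] + d
        xm <- x0; xm[k] <- xm[k] - d
        (exoassist:::al_eval(xp, ctx, lam_H, lam_A, 5, 2)$L -
           exoassist:::al_eval(xm, ctx, lam_H, lam_A, 5, 2)$L) / (2 * d)
      }, numeric(1))
      expect_lt(max(abs(ev$grad[idx] - g_num)), 1e-5)
    }
  }
})

test_that("compiled evaluator matches the reference implementation exactly", {
  trial <- two_muscle_trial(n = 41, passive_scale = 1)
  p <- two_muscle_params(passive_scale = 1)
  opts <- solver_options(mesh = 20)
  disc <- discretize(trial, opts$mesh)
  ctx <- exoassist:::build_context(disc, p, solver_weights(), opts)
  ctx$R_cube <- local({
    arr <- array(0, c(ctx$N, ctx$nm, ctx$nj))
    for (j in seq_len(ctx$nj)) arr[, , j] <- ctx$R[[j]]
    arr
  })
  init <- exoassist:::initial_guess(ctx)
  x0 <- exoassist:::pack_x(init$a, init$lm, init$e, init$tau)
  set.seed(11)
  x0 <- x0 * (1 + 0.05 * runif(length(x0), -1, 1))
  lam_H <- matrix(0.7, ctx$N, ctx$nm)
  lam_A <- matrix(0.1, ctx$N, ctx$nm)
  evR <- exoassist:::al_eval(x0, ctx, lam_H, lam_A, 9, 4)
  evC <- exoassist:::al_eval_fast(x0, ctx, lam_H, lam_A, 9, 4)
  expect_lt(abs(evC$L - evR$L) / abs(evR$L), 1e-13)
  expect_lt(max(abs(evC$grad - evR$grad)), 1e-10)
  dummy <- matrix(0, 1, 1)
  ptr <- exoassist:::alctx_new(ctx$N, ctx$nm, ctx$nj, ctx$h, FALSE,
    ctx$l_mt, ctx$tau_id, ctx$tau_exo_fixed, ctx$R_cube,
    ctx$f_max, ctx$l_opt, ctx$l_slk, ctx$k_t, ctx$p_scale, ctx$p_shift,
    ctx$height, 1, 1000, 0.001, 100, ctx$const$tau_act,
    ctx$const$tau_deact, ctx$const$blend, -1L, dummy, dummy, dummy)
  exoassist:::alctx_update(ptr, lam_H, lam_A, 9, 4, 1000)
  evP <- exoassist:::aleval_ptr(ptr, x0, TRUE)
  expect_lt(abs(evP$L - evR$L) / abs(evR$L), 1e-13)
  expect_lt(max(abs(evP$grad - evR$grad)), 1e-10)
})

test_that("zero net moments drive activations near the floor with tiny reserves", {
  trial <- two_muscle_trial(n = 41, const_moment = 0, passive_scale = 0)
  p <- two_muscle_params(passive_scale = 0)
  sol <- solve_unassisted(trial, p, options = solver_options(mesh = 40))
  # the agonist sits on the activation floor; the antagonist co-activates
  # just enough to cancel the floor-forced agonist moment
  expect_lt(max(sol$activations[, "ag"]), 0.0105)
  expect_lt(max(sol$activations), 0.05)
  expect_lt(max(abs(sol$reserves)), 1e-3)
  expect_lt(sol$objective, 0.005)
})

test_that("rigid-tendon collocation matches the brute-force per-frame oracle", {
  trial <- two_muscle_trial(n = 41, const_moment = -20, passive_scale = 0)
  p <- two_muscle_params(passive_scale = 0)
  sol <- solve_unassisted(trial, p,
                          options = solver_options(mesh = 40,
                                                   rigid_tendon = TRUE))
  oracle <- two_muscle_oracle(trial, p, mesh = 40)
  rms <- sqrt(mean((sol$activations - oracle$activations)^2))
  expect_lt(rms, 1e-2)
})

test_that("moment balance holds exactly through the reserve elimination", {
  trial <- two_muscle_trial(n = 41, passive_scale = 1)
  p <- two_muscle_params(passive_scale = 1)
  sol <- solve_unassisted(trial, p, options = solver_options(mesh = 40))
  expect_lt(sol$moment_balance_violation, 1e-9)
  expect_lt(sol$constraint_violation, 1e-5)
})

test_that("solves are deterministic (bitwise-identical objective)", {
  trial <- two_muscle_trial(n = 41, passive_scale = 1)
  p <- two_muscle_params(passive_scale = 1)
  o <- solver_options(mesh = 30)
  s1 <- solve_unassisted(trial, p, options = o)
  s2 <- solve_unassisted(trial, p, options = o)
  expect_equal(s1$objective, s2$objective, tolerance = 1e-10)
  expect_identical(s1$activations, s2$activations)
})

test_that("a motor with degenerate bounds reproduces the unassisted solution", {
  trial <- two_muscle_trial(n = 41, passive_scale = 1)
  p <- two_muscle_params(passive_scale = 1)
  o <- solver_options(mesh = 30)
  un <- solve_unassisted(trial, p, options = o)
  res <- solve_assisted(trial, p, device = motor_spec("ankle", -1,
                                                      torque_bound = 1e-10),
                        options = o)
  expect_equal(res$solution$objective, un$objective, tolerance = 1e-3)
})

test_that("an unbounded motor drives the agonist toward the floor on a toy moment", {
  # single-direction moment that the motor can fully replace
  trial <- two_muscle_trial(n = 41, const_moment = -15, passive_scale = 0)
  p <- two_muscle_params(passive_scale = 0)
  o <- solver_options(mesh = 30, maxit_inner = 3000, tol_obj = 1e-8)
  res <- solve_assisted(trial, p, device = motor_spec("ankle", -1),
                        options = o)
  # the agonist is driven to its floor; the motor supplies essentially the
  # whole moment (minus the floor-activation muscle contribution)
  expect_lt(max(res$solution$activations[, "ag"]), 0.02)
  expect_lt(max(abs(res$solution$tau_exo[, "ankle"] + 15)) / 15, 0.2)
})

test_that("unknown joints are rejected", {
  trial <- two_muscle_trial(n = 21)
  p <- two_muscle_params()
  expect_error(solve_assisted(trial, p, device = motor_spec("hip", -1)),
               "unknown joint")
})
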