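make_fiber_targets <- function(trial, params, perturb = NULL, a_ref = 0.05) {
  # targets simulated from (optionally perturbed) parameters
  p <- params
  if (!is.null(perturb)) p[[perturb$field]][perturb$row] <-
    p[[perturb$field]][perturb$row] * perturb$factor
  lapply(seq_len(nrow(p)), function(m) {
    lm <- exoassist:::quasi_static_fiber(a_ref, trial$l_mt[, m], p[m, ])
    pct <- trial$time / max(trial$time) * 100
    fiber_target(p$name[m], pct, lm)
  })
}

test_that("fiber tuning recovers the nominal parameters from self-targets", {
  trial <- two_muscle_trial(n = 41, passive_scale = 0)
  p <- two_muscle_params()
  targets <- make_fiber_targets(trial, p)
  res <- tune_fiber_parameters(trial, p, targets)
  for (f in c("l_m_opt", "l_t_slack", "k_t")) {
    expect_lt(max(abs(res$params[[f]] / p[[f]] - 1)), 0.005)
  }
  # idempotence: re-running on the tuned parameters barely moves them
  res2 <- tune_fiber_parameters(trial, res$params, targets)
  expect_lt(max(abs(res2$params$l_t_slack / res$params$l_t_slack - 1)), 0.001)
})

test_that("a +5% tendon slack length perturbation is recovered within 1%", {
  trial <- two_muscle_trial(n = 41, passive_scale = 0)
  p <- two_muscle_params()
  targets <- make_fiber_targets(trial, p,
                                perturb = list(field = "l_t_slack", row = 1,
                                               factor = 1.05))
  res <- tune_fiber_parameters(trial, p, targets)
  expect_lt(abs(res$params$l_t_slack[1] / (1.05 * p$l_t_slack[1]) - 1), 0.01)
})

test_that("infeasible fiber targets converge to a bound with a warning", {
  trial <- two_muscle_trial(n = 41, passive_scale = 0)
  p <- two_muscle_params()
  pct <- trial$time / max(trial$time) * 100
  # fiber lengths far shorter than the geometry allows
  bad <- list(fiber_target("ag", pct, rep(0.4, length(pct))))
  expect_warning(res <- tune_fiber_parameters(trial, p, bad),
                 "bound|infeasible")
  expect_gt(res$diagnostics$rmse[1], 0.02)
  expect_true(res$diagnostics$at_bound[1])
})

# reduced single-muscle-per-joint model: passive scales identifiable
reduced_spec <- function() {
  keep <- c("soleus", "tib_ant", "vasti", "hamstrings", "iliopsoas",
            "glut_med", "adductors")
  p <- default_muscle_set()
  synthetic_model_spec(muscles = p[match(keep, p$name), ])
}

passive_targets_for <- function(spec, params, factor = 1) {
  geom <- spec_geometry(spec)
  lapply(spec$joints, function(j) {
    angles <- seq(-0.4, 0.4, length.out = 15) + unname(exoassist:::.Q_REF[j])
    tau <- exoassist:::passive_joint_moment(params, geom, j, angles)
    passive_moment_target(j, angles, factor * tau)
  })
}

test_that("passive-curve tuning is a zero-change recovery on self-targets", {
  spec <- reduced_spec()
  p <- spec$muscles
  targets <- passive_targets_for(spec, p)
  res <- tune_passive_curves(p, targets, spec_geometry(spec))
  expect_lt(max(abs(res$params$passive_scale - 1)), 0.01)
})

test_that("doubled passive-moment targets double the scale (linear structure)", {
  spec <- reduced_spec()
  p <- spec$muscles
  targets <- passive_targets_for(spec, p, factor = 2)
  res <- tune_passive_curves(p, targets, spec_geometry(spec))
  expect_lt(max(abs(res$params$passive_scale / 2 - 1)), 0.02)
})

test_that("all-zero passive targets drive the scales to the lower bound", {
  spec <- reduced_spec()
  p <- spec$muscles
  targets <- passive_targets_for(spec, p, factor = 0)
  res <- tune_passive_curves(p, targets, spec_geometry(spec))
  expect_lt(max(res$params$passive_scale), 1e-3)
})
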