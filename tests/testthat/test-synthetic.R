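test_that("generated kinematics are periodic, deterministic, speed-scaled", {
  spec <- get_model_spec(1)
  kin1 <- generate_kinematics(spec, seed = 0)
  kin2 <- generate_kinematics(spec, seed = 0)
  kin3 <- generate_kinematics(spec, seed = 1)
  expect_lt(max(abs(kin1$q[1, ] - kin1$q[nrow(kin1$q), ])), 1e-12)
  expect_identical(kin1$q, kin2$q)
  expect_gt(max(abs(kin1$q - kin3$q)), 1e-4)  # seeds differ
  # peak angular velocity grows with speed
  peak_vel <- sapply(c(0.55, 1.45), function(ss) {
    sp <- get_model_spec(ss)
    k <- generate_kinematics(sp, 0)
    max(abs(diff(k$q[, "ankle"]) / diff(k$time)))
  })
  expect_gt(peak_vel[2], peak_vel[1])
  # gait-like phasing: stance dorsiflexion peak precedes the preswing
  # plantarflexion trough
  qa <- kin1$q[, "ankle"]
  s <- kin1$time / spec$cycle_T
  expect_lt(s[which.max(qa)], s[which.min(qa)])
})

test_that("muscle-tendon geometry closes exactly for constant arms", {
  spec <- get_model_spec(1)
  kin <- generate_kinematics(spec, 2)
  l_mt <- exoassist:::lmt_from_q(spec, kin$q)
  rebuilt <- matrix(rep(spec$l_mt0, each = nrow(kin$q)), nrow(kin$q)) -
    kin$q %*% t(spec$arms)
  expect_equal(unname(l_mt), unname(rebuilt), tolerance = 1e-15)
})

test_that("every joint keeps an agonist/antagonist pair", {
  expect_error(synthetic_model_spec(muscles = default_muscle_set()[-4, ]),
               "antagonist")  # dropping tib_ant breaks the ankle pair
})

test_that("unrefined truth trials are built by forward integration", {
  spec <- get_model_spec(1)
  truth <- generate_ground_truth(spec, 0, refine = FALSE, n_samples = 101)
  trial <- generate_trial_from_truth(spec, truth)
  tr <- attr(trial, "truth")
  # net moments equal the moments of the integrated tendon forces
  tau_rebuilt <- tr$tendon_forces %*% spec$arms
  expect_equal(unname(trial$tau_id), unname(tau_rebuilt), tolerance = 1e-9)
  # integrated states are periodic and inside the curve validity range
  expect_lt(max(abs(tr$lm_tilde[1, ] - tr$lm_tilde[nrow(tr$lm_tilde), ])),
            1e-9)
  expect_true(all(tr$lm_tilde > 0.3 & tr$lm_tilde < 1.85))
  expect_true(all(tr$activations >= 0.01 & tr$activations <= 1))
  expect_true(all(tr$excitations >= 0.01 & tr$excitations <= 1))
})

test_that("refined truth trials carry an exactly feasible zero-reserve truth", {
  trial <- get_synthetic_trial(1, 0)
  tr <- attr(trial, "truth")
  spec <- get_model_spec(1)
  opts <- solver_options()
  disc <- discretize(trial, 100)
  ctx <- exoassist:::build_context(disc, spec$muscles, solver_weights(), opts)
  # evaluate the stored truth states under the solver discretization
  ss <- get_synthetic_truth(1, 0)$solution_states
  x <- exoassist:::pack_x(ss$a_nodes, ss$lm_nodes, ss$e, NULL)
  ev <- exoassist:::al_eval(x, ctx, matrix(0, 100, 9), matrix(0, 100, 9),
                            0, 0, want_grad = FALSE)
  expect_lt(max(abs(ev$cH)), 1e-6)
  expect_lt(max(abs(ev$cA)), 1e-6)
  expect_lt(max(abs(ev$eR)), 1e-10)
})

test_that("the fixture suite writes deterministic, round-trippable files", {
  d <- withr::local_tempdir()
  idx <- fixture_suite(d, seeds = 0, speed_scales = 1)
  files <- list.files(d)
  expect_true("trial_normal_seed0_kinematics.sto" %in% files)
  expect_true("trial_normal_seed0_truth_activations.sto" %in% files)
  expect_true("muscle_params.tsv" %in% files)
  # bit-identical rerun
  h1 <- tools::md5sum(file.path(d, files))
  fixture_suite(d, seeds = 0, speed_scales = 1)
  h2 <- tools::md5sum(file.path(d, files))
  expect_identical(h1, h2)
  # lossless io round trip
  back <- read_gait_trial(d, "trial_normal_seed0")
  orig <- get_synthetic_trial(1, 0)
  expect_equal(back$tau_id, orig$tau_id, tolerance = 1e-12)
  expect_equal(back$l_mt, orig$l_mt, tolerance = 1e-12)
})
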