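test_that("contractile work rate follows the shortening-positive convention", {
  expect_equal(contractile_work_rate(100, 0), 0)
  expect_equal(contractile_work_rate(100, 0.1), 10)
  expect_equal(contractile_work_rate(100, -0.1), -10)
  expect_error(contractile_work_rate(-5, 0.1))
})

test_that("heat rate vanishes for a switched-off muscle", {
  expect_equal(heat_rate(a = 0, e = 0, lm_tilde = 1, f_ce = 0, f_iso = 0,
                         v_ce = 0, mass = 0.5, fast_twitch = 0.4), 0)
})

test_that("isometric heat matches an independent term-by-term evaluation", {
  # independent evaluation of the published heat components (coefficients
  # written out directly, not via the package internals)
  mass <- 0.8; ft <- 0.35; e <- 0.5; a <- 0.5; lm <- 1.0
  slow <- 1 - ft
  u_slow <- sin(pi / 2 * e); u_fast <- 1 - cos(pi / 2 * e)
  h_act_ref <- mass * (slow * 40 * u_slow + ft * 133 * u_fast)
  h_mnt_ref <- mass * active_force_length(lm) *
    (slow * 74 * u_slow + ft * 111 * u_fast)
  # isometric: shortening/lengthening term is zero
  got <- heat_rate(a, e, lm, f_ce = 300, f_iso = 300, v_ce = 0,
                   mass = mass, fast_twitch = ft)
  expect_equal(got, h_act_ref + h_mnt_ref, tolerance = 1e-8)
})

test_that("shortening and lengthening heat use the published coefficients", {
  mass <- 0.8; ft <- 0.35; e <- 0.5; a <- 0.5; lm <- 1.0
  iso <- heat_rate(a, e, lm, 300, 320, 0, mass, ft)
  # shortening at v_ce = +0.1 m/s adds (0.16 F_iso + 0.18 F_CE) * v
  sh <- heat_rate(a, e, lm, 300, 320, 0.1, mass, ft)
  expect_equal(sh - iso, (0.16 * 320 + 0.18 * 300) * 0.1, tolerance = 1e-10)
  # lengthening at v_ce = -0.1 m/s adds 0.157 F_CE * v (negative)
  ln <- heat_rate(a, e, lm, 300, 320, -0.1, mass, ft)
  expect_equal(ln - iso, 0.157 * 300 * (-0.1), tolerance = 1e-10)
})

test_that("heat rate is monotone non-decreasing in activation drive", {
  vals <- sapply(seq(0.1, 1, by = 0.1), function(a)
    heat_rate(a, a, 1.0, 200 * a, 200 * a, 0, 0.6, 0.4))
  expect_true(all(diff(vals) >= 0))
})

test_that("negative-rate adjustment clamps the metabolic rate at zero", {
  # positive branch unchanged
  adj <- adjust_negative_rate(5, 3)
  expect_equal(adj$e_dot, 8)
  expect_equal(adj$h_mod, 3)
  # negative total clamped to zero via heat correction
  adj2 <- adjust_negative_rate(-10, 3)
  expect_equal(adj2$e_dot, 0)
  expect_equal(adj2$h_mod, 10)
  # boundary case already at zero
  adj3 <- adjust_negative_rate(-3, 3)
  expect_equal(adj3$e_dot, 0)
  # the literal printed substitution leaves E = -H (audit flag)
  lit <- adjust_negative_rate(-10, 3, literal = TRUE)
  expect_equal(lit$e_dot, -3)
})

test_that("muscle mass derives from maximum force, specific tension, density", {
  p <- default_muscle_set()
  mp <- metabolic_params(p)
  expect_equal(mp$mass, p$f_max / 0.25e6 * 1059.7 * p$l_m_opt)
  expect_true(all(mp$mass > 0))
})

test_that("leg total sums pointwise and errors on mismatched grids", {
  e_dot <- cbind(a = c(5, 6), b = c(7, 1))
  lt <- leg_total(e_dot, time = c(0, 0.5), body_mass = 70)
  expect_equal(lt$e_leg, c(12, 7))
  expect_equal(leg_total(e_dot[, 1, drop = FALSE], c(0, 0.5))$e_leg, c(5, 6))
  # permuting muscles leaves the total unchanged
  expect_equal(leg_total(e_dot[, c(2, 1)], c(0, 0.5))$e_leg, lt$e_leg)
  expect_error(leg_total(e_dot, time = c(0, 0.5, 1)), "mismatched")
})

test_that("metabolic breakdown decomposes exactly and is non-negative", {
  trial <- two_muscle_trial(n = 41, passive_scale = 1)
  p <- two_muscle_params(passive_scale = 1)
  sol <- solve_unassisted(trial, p, options = solver_options(mesh = 40))
  met <- compute_metabolics(sol, p)
  expect_true(all(met$e_dot >= 0))
  expect_equal(met$e_dot - met$w_ce - met$h_mod,
               matrix(0, nrow(met$e_dot), 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(met$e_leg, rowSums(met$e_dot))
  expect_equal(met$avg_e_leg_w_per_kg, met$avg_e_leg_w / 69)
  # writing round-trips the leg total
  d <- withr::local_tempdir()
  write_metabolics(met, d, "m")
  back <- read_motion_table(file.path(d, "m_metabolics.sto"))$data
  expect_equal(back$e_leg, met$e_leg, tolerance = 1e-12)
})
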