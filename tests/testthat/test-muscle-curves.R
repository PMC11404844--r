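# Characteristic-curve behavior. Regression values were computed by direct
# evaluation of the published curve coefficients, independently of the
# package code.

test_that("active force-length peaks at optimal length and vanishes at short lengths", {
  expect_equal(active_force_length(1.0), 1.0, tolerance = 1e-3)
  expect_lt(active_force_length(0.2), 0.05)
  expect_equal(active_force_length(0.2), 0.007735841995, tolerance = 1e-9)
  # unimodal around the optimum
  expect_lt(active_force_length(1.1), active_force_length(1.0))
  expect_lt(active_force_length(0.9), active_force_length(1.0))
  expect_equal(active_force_length(1.1), 0.952586640519, tolerance = 1e-9)
})

test_that("force-velocity is monotone with the Hill endpoints", {
  expect_equal(force_velocity(0), 1.0, tolerance = 3e-3)
  expect_lt(force_velocity(-1), 0.05)
  fv1 <- force_velocity(1)
  expect_gt(fv1, 1)
  expect_lt(fv1, 2)
  expect_equal(fv1, 1.789482662815, tolerance = 1e-9)
  v <- seq(-1, 1, length.out = 201)
  expect_true(all(diff(force_velocity(v)) > 0))
  # exact analytic inverse round-trips
  expect_equal(force_velocity_inverse(force_velocity(v)), v, tolerance = 1e-10)
})

test_that("passive force-length engages above slack region and scales linearly", {
  expect_lt(abs(passive_force_length(0.8)), 0.01)
  expect_identical(passive_force_length(c(0.8, 1.2, 1.6), passive_scale = 0),
                   c(0, 0, 0))
  # strictly increasing over a dense grid
  l <- seq(0.3, 1.9, length.out = 400)
  expect_true(all(diff(passive_force_length(l)) > 0))
  expect_gt(passive_force_length(1.4), 0)
  expect_gt(passive_force_length(1.6), passive_force_length(1.4))
  expect_equal(passive_force_length(1.6), 1.0185672836, tolerance = 1e-9)
  # linear in the scale parameter
  expect_equal(passive_force_length(1.5, passive_scale = 3),
               3 * passive_force_length(1.5), tolerance = 1e-12)
  # shift moves the engagement point
  expect_equal(passive_force_length(1.55, passive_shift = 0.05),
               passive_force_length(1.5), tolerance = 1e-12)
})

test_that("tendon force-length is zero at slack, ordered by stiffness, invertible", {
  expect_lt(abs(tendon_force_length(1.0)), 0.01)
  expect_gt(tendon_force_length(1.05, k_t = 35), tendon_force_length(1.05, k_t = 20))
  expect_equal(tendon_force_length(1.05, k_t = 35), 1.1327804899, tolerance = 1e-8)
  # inverse consistency against a bisection root-finder (independent of the
  # closed-form inverse)
  for (kt in c(20, 35)) {
    for (lt in c(1.01, 1.03, 1.05)) {
      f <- tendon_force_length(lt, kt)
      root <- uniroot(function(x) tendon_force_length(x, kt) - f,
                      lower = 0.9, upper = 1.2, tol = 1e-12)$root
      expect_equal(root, lt, tolerance = 1e-8)
      expect_equal(tendon_force_length_inverse(f, kt), lt, tolerance = 1e-10)
    }
  }
})

test_that("curve evaluations are smooth (finite central-difference gradients match analytic)", {
  h <- 1e-6
  l <- seq(0.25, 1.85, length.out = 23)
  num <- (active_force_length(l + h) - active_force_length(l - h)) / (2 * h)
  expect_equal(active_force_length_deriv(l), num, tolerance = 1e-5)
  v <- seq(-0.95, 0.95, length.out = 23)
  num <- (force_velocity(v + h) - force_velocity(v - h)) / (2 * h)
  expect_equal(force_velocity_deriv(v), num, tolerance = 1e-5)
  num <- (passive_force_length(l + h) - passive_force_length(l - h)) / (2 * h)
  expect_equal(passive_force_length_deriv(l), num, tolerance = 1e-5)
  lt <- seq(0.97, 1.06, length.out = 17)
  num <- (tendon_force_length(lt + h) - tendon_force_length(lt - h)) / (2 * h)
  expect_equal(tendon_force_length_deriv(lt), num, tolerance = 1e-4)
})

test_that("NaN and non-positive inputs are rejected", {
  expect_error(active_force_length(NaN))
  expect_error(active_force_length(-0.1))
  expect_error(passive_force_length(NaN))
  expect_error(tendon_force_length(0))
})
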