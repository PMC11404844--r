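test_that("interpolation reproduces input samples at their own times", {
  trial <- two_muscle_trial(n = 41)
  disc <- discretize(trial, mesh = 40)  # nodes coincide with input grid
  expect_equal(disc$time, trial$time, tolerance = 1e-12)
  expect_equal(disc$q, trial$q, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(disc$tau_id, trial$tau_id, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(disc$l_mt, trial$l_mt, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("linear signals interpolate exactly at off-grid nodes", {
  tt <- seq(0, 1, length.out = 21)
  lin <- two_muscle_trial(n = 21)
  lin$tau_id[, 1] <- 2 + 3 * tt  # overwrite with a linear test signal
  disc <- discretize(lin, mesh = 50)
  expect_equal(disc$tau_id[, 1], 2 + 3 * disc$time, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("interpolation error on a sine decreases with denser sampling", {
  truth_fun <- function(t) -25 * (0.55 + 0.45 * sin(2 * pi * t + 1))
  err <- sapply(c(15, 29), function(n) {
    disc <- discretize(two_muscle_trial(n = n), 100)
    max(abs(disc$tau_id[, 1] - truth_fun(disc$time)))
  })
  expect_lt(err[2], err[1])
})

test_that("invalid meshes and grids are rejected", {
  trial <- two_muscle_trial(n = 21)
  expect_error(discretize(trial, mesh = 5), "at least 10")
  bad <- trial; bad$time[3] <- bad$time[5]
  expect_error(discretize(bad, 100), "non-monotone")
})

test_that("trial grids twice as fine as the mesh expose exact midpoint data", {
  trial <- two_muscle_trial(n = 81)  # 80 intervals = 2 x mesh 40
  disc <- discretize(trial, mesh = 40)
  expect_false(is.null(disc$exact_mid))
  mid_idx <- seq(2, 80, by = 2)
  expect_equal(disc$exact_mid$tau_id, trial$tau_id[mid_idx, , drop = FALSE],
               ignore_attr = TRUE)
  expect_null(discretize(trial, mesh = 50)$exact_mid)
})
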