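# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Full synthetic truth and trial (refined ground truth); expensive, cache
# per speed/seed.
get_synthetic_truth <- function(speed = 1, seed = 0) {
  cached(sprintf("truth_%s_%d", speed, seed), {
    spec <- synthetic_model_spec(speed_scale = speed)
    generate_ground_truth(spec, seed = seed)
  })
}

get_synthetic_trial <- function(speed = 1, seed = 0) {
  cached(sprintf("trial_%s_%d", speed, seed), {
    spec <- synthetic_model_spec(speed_scale = speed)
    generate_trial_from_truth(spec, get_synthetic_truth(speed, seed))
  })
}

get_model_spec <- function(speed = 1) synthetic_model_spec(speed_scale = speed)

# Cheap analytic fixture: one sagittal "ankle" degree of freedom spanned by
# an agonist/antagonist pair, passive curves switched off by default,
# gentle sinusoidal kinematics and a prescribed net moment profile.
two_muscle_params <- function(passive_scale = 0) {
  muscle_params(name = c("ag", "ant"),
                f_max = c(2000, 800),
                l_m_opt = c(0.05, 0.06),
                l_t_slack = c(0.20, 0.18),
                alpha_opt = c(0.1, 0.05),
                passive_scale = passive_scale,
                fast_twitch = c(0.4, 0.3))
}

.TWO_ARMS <- c(ag = -0.05, ant = 0.04)

two_muscle_trial <- function(n = 81, amp = 25, const_moment = NULL,
                             passive_scale = 0) {
  p <- two_muscle_params(passive_scale)
  T_cyc <- 1.0
  tt <- seq(0, T_cyc, length.out = n)
  s <- tt / T_cyc
  q <- matrix(0.05 * sin(2 * pi * s), ncol = 1,
              dimnames = list(NULL, "ankle"))
  l_mt0 <- p$l_t_slack + p$l_m_opt * cos(p$alpha_opt)
  l_mt <- cbind(l_mt0[1] - .TWO_ARMS["ag"] * q[, 1],
                l_mt0[2] - .TWO_ARMS["ant"] * q[, 1])
  colnames(l_mt) <- c("ag", "ant")
  tau <- if (is.null(const_moment))
    matrix(-amp * (0.55 + 0.45 * sin(2 * pi * s + 1)), ncol = 1)
  else matrix(const_moment, n, 1)
  colnames(tau) <- "ankle"
  arr <- array(0, c(n, 2, 1), dimnames = list(NULL, c("ag", "ant"), "ankle"))
  arr[, "ag", 1] <- .TWO_ARMS["ag"]; arr[, "ant", 1] <- .TWO_ARMS["ant"]
  gait_trial(tt, q, tau, l_mt, arr, body_mass = 69, speed_label = "normal")
}

# Brute-force per-frame static-optimization oracle for the two-muscle
# fixture with rigid tendons: dense grid search refined by Nelder-Mead,
# independent of the package's static/collocation solvers.
two_muscle_oracle <- function(trial, params, weights = solver_weights(),
                              mesh = 40, a_min = 0.01) {
  key <- sprintf("oracle_%s_%s", mesh, signif(sum(trial$tau_id), 8))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  h <- (trial$time[length(trial$time)] - trial$time[1]) / mesh
  t_mid <- trial$time[1] + (seq_len(mesh) - 1) * h + h / 2
  tau_f <- periodic_spline(trial$time, trial$tau_id[, 1])
  lmt_f <- lapply(1:2, function(m) periodic_spline(trial$time, trial$l_mt[, m]))
  a_out <- matrix(NA_real_, length(t_mid), 2)
  for (i in seq_along(t_mid)) {
    FF <- function(a, m) {
      p <- params[m, ]
      st <- rigid_tendon_state(lmt_f[[m]](t_mid[i]),
                               lmt_f[[m]](t_mid[i], deriv = 1), p)
      (a * active_force_length(st$lm_tilde) * force_velocity(st$v_tilde) +
         passive_force_length(st$lm_tilde, p$passive_scale, p$passive_shift) +
         0.01 * st$v_tilde) * st$cos_alpha * p$f_max
    }
    tau_i <- tau_f(t_mid[i])
    cost <- function(a) {
      tau_mus <- .TWO_ARMS["ag"] * FF(a[1], 1) + .TWO_ARMS["ant"] * FF(a[2], 2)
      eR <- (tau_i - tau_mus) / weights$T_R
      sum(a^2) + weights$w_r * eR^2
    }
    grid <- as.matrix(expand.grid(a1 = seq(a_min, 1, length.out = 60),
                                  a2 = seq(a_min, 1, length.out = 60)))
    vals <- apply(grid, 1, cost)
    best <- grid[which.min(vals), ]
    fit <- optim(best, function(a)
      if (any(a < a_min) || any(a > 1)) 1e9 else cost(a),
      method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 500))
    a_out[i, ] <- fit$par
  }
  colnames(a_out) <- c("ag", "ant")
  .fixture_cache[[key]] <- list(time = t_mid, activations = a_out)
  .fixture_cache[[key]]
}
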