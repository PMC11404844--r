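# Synthetic gait-trial generator. Produces desk-scale trials with the
# structure the pipeline assumes: smooth periodic joint kinematics built from
# a few harmonics with gait-like phasing, constant moment arms (so the
# muscle-tendon geometry closes exactly), and net joint moments constructed
# from known ground-truth activations by forward-integrating the muscle
# dynamics. The trials loosely mimic normative adult gait; they make no
# claim of subject fidelity - the point is a recoverable ground truth.

# Harmonic coefficients (c0, a1, b1, a2, b2, a3, b3) of the baseline joint
# angle trajectories q(s) over the cycle fraction s, fitted once to
# normative-gait waypoints (rad). Internal sign convention: positive
# dorsiflexion, knee extension, hip flexion, hip abduction.
.KIN_COEF <- list(
  ankle        = c(-0.0106, -0.0138, 0.0711, 0.0321, -0.1042, -0.0486, 0.0112),
  knee         = c(-0.3671, 0.0346, 0.3486, 0.2601, -0.1189, -0.0010, -0.0919),
  hip_sagittal = c(0.2076, 0.3394, -0.0463, -0.0399, -0.0381, -0.0067, 0.0105),
  hip_frontal  = c(-0.0107, 0.0078, -0.0879, -0.0122, -0.0115, 0.0109, 0.0087)
)

# Reference posture (rad) at which each muscle sits at optimal fiber length
# with a slack tendon; mid-range of the gait excursions.
.Q_REF <- c(ankle = 0, knee = -0.45, hip_sagittal = 0.15, hip_frontal = 0)

# Constant moment arms (m), muscle x joint, internal sign convention
# (positive arm = positive moment for positive force).
.MOMENT_ARMS <- local({
  muscles <- c("soleus", "gas_med", "gas_lat", "tib_ant", "vasti",
               "hamstrings", "iliopsoas", "glut_med", "adductors")
  joints <- c("ankle", "knee", "hip_sagittal", "hip_frontal")
  A <- matrix(0, length(muscles), length(joints),
              dimnames = list(muscles, joints))
  A["soleus", "ankle"] <- -0.050
  A["gas_med", "ankle"] <- -0.048; A["gas_med", "knee"] <- -0.018
  A["gas_lat", "ankle"] <- -0.048; A["gas_lat", "knee"] <- -0.018
  A["tib_ant", "ankle"] <- 0.040
  A["vasti", "knee"] <- 0.045
  A["hamstrings", "knee"] <- -0.035; A["hamstrings", "hip_sagittal"] <- -0.055
  A["iliopsoas", "hip_sagittal"] <- 0.045
  A["glut_med", "hip_frontal"] <- 0.055
  A["adductors", "hip_frontal"] <- -0.045
  A
})

#' Synthetic musculoskeletal model specification
#'
#' Fixes the synthetic study conditions: the joint set, the muscle set with
#' agonist and antagonist coverage at every joint, constant moment arms, the
#' reference muscle-tendon lengths (chosen so each muscle sits at optimal
#' fiber length with a slack tendon at a mid-range reference posture), body
#' mass, and the walking-speed scale. Speed scales follow the preferred-
#' walking-speed percentages of the emulated protocol: 0.55 (slow), 1.0
#' (normal) and 1.45 (fast).
#'
#' @param muscles A `muscle_params` table (default [default_muscle_set()]).
#' @param joints Joint subset (default all four).
#' @param body_mass Body mass (kg).
#' @param speed_scale Fraction of preferred walking speed (0.55, 1.0, 1.45).
#' @return A `synthetic_model_spec` object.
#' @export
synthetic_model_spec <- function(muscles = default_muscle_set(),
                                 joints = c("ankle", "knee", "hip_sagittal",
                                            "hip_frontal"),
                                 body_mass = 69, speed_scale = 1.0) {
  stopifnot(all(joints %in% colnames(.MOMENT_ARMS)),
            all(muscles$name %in% rownames(.MOMENT_ARMS)),
            body_mass > 0, speed_scale > 0)
  arms <- .MOMENT_ARMS[muscles$name, joints, drop = FALSE]
  # every joint must have an agonist and an antagonist among the muscles
  for (j in joints) {
    if (!any(arms[, j] > 0) || !any(arms[, j] < 0))
      stop("joint ", j, " lacks an agonist/antagonist pair in the muscle set")
  }
  # reference muscle-tendon length: optimal fiber + slack tendon at .Q_REF
  l_mt_ref <- muscles$l_t_slack + muscles$l_m_opt * cos(muscles$alpha_opt)
  l_mt0 <- l_mt_ref + as.vector(arms %*% .Q_REF[joints])  # value at q = 0
  cycle_T <- 1.1 * speed_scale^(-0.35)
  structure(list(muscles = muscles, joints = joints, arms = arms,
                 l_mt0 = l_mt0, body_mass = body_mass,
                 speed_scale = speed_scale, cycle_T = cycle_T,
                 speed_label = if (speed_scale < 0.8) "slow"
                               else if (speed_scale > 1.2) "fast" else "normal"),
            class = "synthetic_model_spec")
}

#' @export
print.synthetic_model_spec <- function(x, ...) {
  cat(sprintf("<synthetic_model_spec> %d muscles, joints [%s], speed %.2f PWS (T = %.3f s)\n",
              nrow(x$muscles), paste(x$joints, collapse = ", "),
              x$speed_scale, x$cycle_T))
  invisible(x)
}

#' Generate periodic gait-like joint kinematics
#'
#' Sums of 2-4 harmonics per joint with gait-like phasing (ankle
#' dorsiflexion peaking in stance before preswing plantarflexion, swing-phase
#' knee flexion, sinusoid-like hip flexion-extension). Exactly periodic and
#' C-infinity by construction. The seed jitters harmonic amplitudes and
#' phases a few percent so seeds differ; amplitudes scale mildly with the
#' speed scale.
#'
#' @param spec A [synthetic_model_spec()].
#' @param seed Integer seed.
#' @param n_samples Samples over the closed cycle (default 101).
#' @return List with `time` and matrix `q` (n_samples x joints, rad).
#' @export
generate_kinematics <- function(spec, seed = 0, n_samples = 101) {
  stopifnot(inherits(spec, "synthetic_model_spec"))
  rng <- local({ set.seed(seed + 1000L); list(amp = 1 + 0.04 * stats::rnorm(24),
                                              ph = 0.015 * stats::rnorm(24)) })
  tt <- seq(0, spec$cycle_T, length.out = n_samples)
  s <- tt / spec$cycle_T
  ampf <- 0.85 + 0.15 * spec$speed_scale
  q <- sapply(seq_along(spec$joints), function(jj) {
    cf <- .KIN_COEF[[spec$joints[jj]]]
    y <- rep(cf[1], length(s))
    for (k in 1:3) {
      A <- cf[2 * k]; B <- cf[2 * k + 1]
      amp <- rng$amp[(jj - 1) * 6 + 2 * k - 1]
      ph <- rng$ph[(jj - 1) * 6 + 2 * k]
      # rotate the harmonic by a small phase and scale its amplitude
      ang <- 2 * pi * k * s + ph
      y <- y + ampf * amp * (A * cos(ang) + B * sin(ang))
    }
    y
  })
  colnames(q) <- spec$joints
  list(time = tt, q = q)
}

# Periodic Gaussian bump on the cycle fraction (center c, width w).
periodic_bump <- function(s, c, w) {
  d <- (s - c) %% 1
  d <- ifelse(d > 0.5, d - 1, d)
  exp(-0.5 * (d / w)^2)
}

# Gait-like net joint moment targets (N m) used to shape the ground-truth
# activations; per-kg profiles scaled by body mass with a mild speed factor.
target_moments <- function(spec, s) {
  f <- 0.75 + 0.25 * spec$speed_scale
  m <- spec$body_mass
  out <- sapply(spec$joints, function(j) {
    switch(j,
      ankle = m * (-1.05 * f * periodic_bump(s, 0.47, 0.11) +
                     0.12 * periodic_bump(s, 0.05, 0.06)),
      knee = m * (0.48 * f * periodic_bump(s, 0.12, 0.08) -
                    0.22 * periodic_bump(s, 0.55, 0.08) -
                    0.10 * periodic_bump(s, 0.80, 0.08)),
      hip_sagittal = m * (-0.50 * f * periodic_bump(s, 0.08, 0.10) +
                            0.55 * f * periodic_bump(s, 0.57, 0.10) -
                            0.18 * periodic_bump(s, 0.90, 0.07)),
      hip_frontal = m * (0.52 * f * (periodic_bump(s, 0.20, 0.09) +
                                       0.9 * periodic_bump(s, 0.50, 0.09))))
  })
  colnames(out) <- spec$joints
  out
}

# Muscle-tendon lengths from joint angles (constant arms: exact closure).
lmt_from_q <- function(spec, q) {
  l <- matrix(rep(spec$l_mt0, each = nrow(q)), nrow(q), nrow(spec$muscles))
  l <- l - q %*% t(spec$arms)
  colnames(l) <- spec$muscles$name
  l
}

# Keep the first K harmonics of a periodic signal sampled on the closed grid
# (first == last sample).
fourier_smooth <- function(x, K = 5) {
  n <- length(x) - 1
  z <- stats::fft(x[1:n])
  keep <- c(1, 2:(K + 1), (n - K + 1):n)
  z[setdiff(1:n, keep)] <- 0
  y <- Re(stats::fft(z, inverse = TRUE)) / n
  c(y, y[1])
}

#' Generate the ground truth for a synthetic trial
#'
#' Builds ground-truth activations by solving a per-frame static
#' optimization against gait-like net-moment targets (so the truth is itself
#' near-optimal under the minimal-activation criterion), smoothed to a few
#' harmonics and clamped away from the bounds. Optionally embeds a known
#' spring device whose torque is added to the constructed net moments.
#'
#' @param spec A [synthetic_model_spec()].
#' @param seed Integer seed (controls the kinematics jitter).
#' @param device Optional [spring_spec()] with concrete `k_r`, `t_c`, `t_d`
#'   to embed in the trial.
#' @param refine Refine the static pattern by a full collocation solve of
#'   the provisional trial so the truth lies on the solution manifold of
#'   the elastic-tendon estimator (default `TRUE`; recovery experiments
#'   assume it).
#' @param n_samples Samples of the stored trial grid (default 201, twice
#'   the default solver mesh plus one, so a mesh-100 solve reads its
#'   collocation data without interpolation error).
#' @return A `ground_truth` list: `seed`, `activations` (closed-grid matrix),
#'   `device`, `device_torque` (node x joint matrix or NULL).
#' @export
generate_ground_truth <- function(spec, seed = 0, device = NULL,
                                  refine = TRUE, n_samples = 201) {
  kin <- generate_kinematics(spec, seed, n_samples)
  s <- kin$time / spec$cycle_T
  tau_des <- target_moments(spec, s)
  l_mt <- lmt_from_q(spec, kin$q)
  arms <- array(rep(as.vector(spec$arms), each = length(kin$time)),
                c(length(kin$time), nrow(spec$muscles), length(spec$joints)),
                dimnames = list(NULL, spec$muscles$name, spec$joints))
  trial0 <- gait_trial(kin$time, kin$q, tau_des, l_mt, arms,
                       body_mass = spec$body_mass,
                       speed_label = spec$speed_label)
  disc <- discretize(trial0, mesh = length(kin$time) - 1)
  dev_tau <- NULL
  if (!is.null(device)) {
    stopifnot(inherits(device, "spring_spec"),
              !is.na(device$k_r), !is.na(device$t_c), !is.na(device$t_d))
    dev_tau <- matrix(0, length(kin$time), length(spec$joints),
                      dimnames = list(NULL, spec$joints))
    # same unidirectional spring model the device solver fits
    q_fun <- periodic_spline(kin$time, kin$q[, device$joint])
    dev_tau[, device$joint] <- spring_profile(kin$time, q_fun, device$k_r,
                                              device$t_c, device$t_d,
                                              device$b, device$assist_sign)
  }
  # static truth against targets (device torque, if any, frees the muscles)
  st <- static_optimize(disc, spec$muscles, solver_weights(),
                        tau_exo = dev_tau)
  a <- apply(st$activations, 2, fourier_smooth, K = 6)
  a <- pmin(pmax(a, 0.02), 0.95)
  colnames(a) <- spec$muscles$name
  truth <- structure(list(seed = seed, activations = a, device = device,
                          device_torque = dev_tau, n_samples = n_samples),
                     class = "ground_truth")
  if (refine) {
    # Place the truth on the solution manifold of the estimator: the
    # rigid-tendon static pattern is feasible but not optimal for the
    # elastic-tendon dynamic problem (compliant-tendon muscles are loaded
    # differently), so a trial built from it would not be recoverable.
    # Re-solve the provisional trial with the full collocation problem and
    # adopt that activation pattern as the ground truth.
    trial0 <- generate_trial_from_truth(spec, truth)
    ref <- refine_truth_solution(spec, trial0, truth)
    truth$activations <- ref$activations
    truth$solution_states <- ref$states
  }
  truth
}

# Collocation solve of the provisional trial (device torque, if any, held
# fixed); returns the activation pattern on the full (interleaved
# node/midpoint) trial grid plus the solution state, which
# generate_trial_from_truth uses to construct net moments that are exactly
# consistent with a zero-reserve optimum.
refine_truth_solution <- function(spec, trial0, truth) {
  n_nodes <- length(trial0$time)
  opts <- solver_options(mesh = (n_nodes - 1) %/% 2)
  disc <- discretize(trial0, opts$mesh)
  dev_tau <- truth$device_torque
  if (!is.null(dev_tau) && nrow(dev_tau) != length(disc$time)) {
    dev_tau <- sapply(seq_len(ncol(dev_tau)), function(j)
      periodic_spline(trial0$time, truth$device_torque[, j])(disc$time))
    colnames(dev_tau) <- colnames(truth$device_torque)
  }
  ctx <- build_context(disc, spec$muscles, solver_weights(), opts,
                       tau_exo_fixed = dev_tau)
  core <- solve_core(ctx)
  a <- interleave_closed(core$ev$a, core$ev$a_mid)
  colnames(a) <- spec$muscles$name
  list(activations = a,
       states = list(t_mid = ctx$t_mid, t_nodes = ctx$t_nodes,
                     T_cyc = spec$cycle_T,
                     a_nodes = core$ev$a, lm_nodes = core$ev$lm,
                     a_mid = core$ev$a_mid, lm_mid = core$ev$lm_mid,
                     v_tilde = core$ev$vt, F_t = core$ev$F_t,
                     tau_mus = core$ev$tau_mus, e = core$ev$e))
}

# interleave node (N x M) and midpoint (N x M) series into the closed
# 2N+1-sample trial grid
interleave_closed <- function(Xn, Xm) {
  N <- nrow(Xn)
  out <- matrix(0, 2 * N + 1, ncol(Xn))
  out[seq(1, 2 * N - 1, by = 2), ] <- Xn
  out[seq(2, 2 * N, by = 2), ] <- Xm
  out[2 * N + 1, ] <- Xn[1, ]
  out
}

#' Build a gait trial from a known ground truth
#'
#' Forward-integrates the activation-driven contraction dynamics at the
#' ground-truth activations over repeated cycles until periodic, then
#' constructs the net joint moments as the moments the resulting tendon
#' forces produce (plus the embedded device torque, if any). The trial is
#' exactly feasible for the redundancy solver with (near-)zero reserves by
#' construction.
#'
#' @param spec A [synthetic_model_spec()].
#' @param truth A `ground_truth` from [generate_ground_truth()].
#' @return A [gait_trial()] with attribute `truth` carrying the generating
#'   activations, fiber states, excitations, tendon forces and device
#'   torque.
#' @export
generate_trial_from_truth <- function(spec, truth) {
  stopifnot(inherits(spec, "synthetic_model_spec"), inherits(truth, "ground_truth"))
  kin <- generate_kinematics(spec, truth$seed,
                             n_samples = if (is.null(truth$n_samples)) 101
                                         else truth$n_samples)
  tt <- kin$time; T_cyc <- spec$cycle_T
  nm <- nrow(spec$muscles)
  n_nodes <- length(tt)
  l_mt <- lmt_from_q(spec, kin$q)
  p <- spec$muscles

  if (!is.null(truth$solution_states)) {
    # refined truth: the stored collocation solution is the ground truth;
    # construct the net moments directly from its muscle moments so the
    # trial is exactly feasible with zero reserves at the truth
    st <- truth$solution_states
    mid_closed_t <- c(st$t_mid, st$t_mid[1] + T_cyc)
    mid_to_nodes <- function(y) {
      f <- periodic_spline(mid_closed_t, c(y, y[1]))
      f(tt %% T_cyc)
    }
    tau_id <- sapply(seq_along(spec$joints), function(j)
      mid_to_nodes(st$tau_mus[, j]))
    colnames(tau_id) <- spec$joints
    if (!is.null(truth$device_torque)) tau_id <- tau_id + truth$device_torque
    interp_cols <- function(M) {
      out <- sapply(seq_len(ncol(M)), function(m) mid_to_nodes(M[, m]))
      colnames(out) <- p$name
      out
    }
    lm_tilde <- interleave_closed(st$lm_nodes, st$lm_mid)
    colnames(lm_tilde) <- p$name
    v_tilde <- interp_cols(st$v_tilde)
    f_ten <- interp_cols(st$F_t)
    e <- pmin(pmax(interp_cols(st$e), activation_constants()$a_min), 1)
    arms <- array(rep(as.vector(spec$arms), each = length(tt)),
                  c(length(tt), nrow(p), length(spec$joints)),
                  dimnames = list(NULL, p$name, spec$joints))
    trial <- gait_trial(tt, kin$q, tau_id, l_mt, arms,
                        body_mass = spec$body_mass,
                        speed_label = spec$speed_label)
    attr(trial, "truth") <- list(activations = truth$activations,
                                 lm_tilde = lm_tilde, v_tilde = v_tilde,
                                 excitations = e, tendon_forces = f_ten,
                                 tau_mus = tau_id - if (is.null(truth$device_torque))
                                   0 else truth$device_torque,
                                 device = truth$device,
                                 device_torque = truth$device_torque,
                                 seed = truth$seed)
    return(trial)
  }

  if (any(truth$activations < 0.0199 | truth$activations > 0.951))
    stop("truth activations outside the feasible range for the generator")

  # achievable activations: derive excitations from the requested activation
  # trajectory (clamped to the excitation bounds), then re-integrate the
  # activation dynamics so the stored truth is exactly reachable
  const <- activation_constants()
  dadt_req <- apply(truth$activations, 2, function(x)
    periodic_spline(tt, x)(tt, deriv = 1))
  e <- pmin(pmax(activation_inverse(truth$activations, dadt_req, const),
                 const$a_min), 1)
  sub <- max(2, ceiling(800 / (n_nodes - 1)))  # substeps per grid interval
  dt <- (tt[2] - tt[1]) / sub
  n_sub <- (n_nodes - 1) * sub
  # precompute excitations at the substep grid and half-steps (periodic
  # splines; one cycle reused across settle cycles)
  e_sp <- lapply(seq_len(nm), function(m) periodic_spline(tt, e[, m]))
  ts_sub <- (seq_len(n_sub) - 1) * dt
  e_sub <- sapply(e_sp, function(f) f(ts_sub %% T_cyc))
  e_half <- sapply(e_sp, function(f) f((ts_sub + dt / 2) %% T_cyc))
  e_next <- sapply(e_sp, function(f) f((ts_sub + dt) %% T_cyc))
  e_sub <- pmin(pmax(e_sub, const$a_min), 1)
  e_half <- pmin(pmax(e_half, const$a_min), 1)
  e_next <- pmin(pmax(e_next, const$a_min), 1)
  rk4_cycle <- function(a_cur, record = FALSE) {
    if (record) a_rec <- matrix(0, n_nodes, nm)
    if (record) a_rec[1, ] <- a_cur
    for (i in seq_len(n_sub)) {
      k1 <- activation_rate(e_sub[i, ], a_cur, const)
      k2 <- activation_rate(e_half[i, ], a_cur + dt / 2 * k1, const)
      k3 <- activation_rate(e_half[i, ], a_cur + dt / 2 * k2, const)
      k4 <- activation_rate(e_next[i, ], a_cur + dt * k3, const)
      a_cur <- pmin(pmax(a_cur + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4),
                         const$a_min), 1)
      if (record && i %% sub == 0) a_rec[i / sub + 1, ] <- a_cur
    }
    if (record) a_rec else a_cur
  }
  a_cur <- truth$activations[1, ]
  for (cyc in 1:2) a_cur <- rk4_cycle(a_cur)  # settle to the periodic orbit
  a_truth <- rk4_cycle(a_cur, record = TRUE)
  dimnames(a_truth) <- list(NULL, p$name)
  a_truth[n_nodes, ] <- a_truth[1, ]  # periodic closure (settled orbit)

  # vectorized fiber mechanics helpers (per-muscle constant vectors)
  lopt <- p$l_m_opt; lslk <- p$l_t_slack; kt <- p$k_t
  psc <- p$passive_scale; psh <- p$passive_shift
  hgt <- p$l_m_opt * sin(p$alpha_opt)
  geom <- function(lm, lmt_now) {
    lm_abs <- lm * lopt
    along <- sqrt(lm_abs^2 - hgt^2)
    list(cosA = along / lm_abs, lt = (lmt_now - along) / lslk, along = along)
  }
  # fiber velocity from the Hill equilibrium (vectorized Newton over muscles)
  v_from_state <- function(a, lm, lmt_now) {
    g <- geom(lm, lmt_now)
    rhs <- tendon_force_length(g$lt, kt) / g$cosA -
      passive_force_length(lm, psc, psh)
    af <- a * active_force_length(lm)
    x <- force_velocity_inverse(pmin(pmax(rhs / af, 0.02), 1.75))
    x <- pmin(pmax(x, -1), 1)
    for (it in 1:10) {
      f <- af * force_velocity(x) + .FIBER_DAMPING * x - rhs
      df <- af * force_velocity_deriv(x) + .FIBER_DAMPING
      x <- pmin(pmax(x - f / df, -1.5), 1.5)
    }
    x
  }
  # d(v)/d(lm) at the equilibrium velocity (implicit function theorem)
  dv_dlm <- function(a, lm, lmt_now, v) {
    g <- geom(lm, lmt_now)
    dlt <- -lopt / (lslk * g$cosA)
    dcos <- hgt^2 / (lopt^2 * lm^3 * g$cosA)
    drhs <- (tendon_force_length_deriv(g$lt, kt) * dlt * g$cosA -
               tendon_force_length(g$lt, kt) * dcos) / g$cosA^2 -
      passive_force_length_deriv(lm, psc, psh)
    (drhs - a * active_force_length_deriv(lm) * force_velocity(v)) /
      (a * active_force_length(lm) * force_velocity_deriv(v) + .FIBER_DAMPING)
  }

  # precomputed activation / muscle-tendon length tables on the fiber
  # integration substep grid (one cycle, reused across settle cycles)
  sub_f <- max(2, ceiling(400 / (n_nodes - 1)))
  dt_f <- (tt[2] - tt[1]) / sub_f
  n_sub_f <- (n_nodes - 1) * sub_f
  ts_f <- (seq_len(n_sub_f + 1) - 1) * dt_f
  a_sp <- lapply(seq_len(nm), function(m) periodic_spline(tt, a_truth[, m]))
  a_tab <- sapply(a_sp, function(f) f(ts_f %% T_cyc))
  a_tab <- pmin(pmax(a_tab, const$a_min), 1)
  l_sp <- lapply(seq_len(nm), function(m) periodic_spline(tt, l_mt[, m]))
  l_tab <- sapply(l_sp, function(f) f(ts_f %% T_cyc))

  # trapezoidal (implicit, 2nd-order, L-stable enough at these steps)
  # integration of the stiff fiber dynamics; muscles decouple, Newton on the
  # implicit update is vectorized over muscles
  trap_step <- function(lm0, i) {
    v0 <- v_from_state(a_tab[i, ], lm0, l_tab[i, ])
    a1 <- a_tab[i + 1, ]; l1 <- l_tab[i + 1, ]
    lm1 <- pmin(pmax(lm0 + dt_f * .VEL_SCALE * v0, 0.3), 1.85)
    for (it in 1:6) {
      v1 <- v_from_state(a1, lm1, l1)
      r <- lm1 - lm0 - dt_f / 2 * .VEL_SCALE * (v0 + v1)
      dr <- 1 - dt_f / 2 * .VEL_SCALE * dv_dlm(a1, lm1, l1, v1)
      lm1 <- pmin(pmax(lm1 - r / dr, 0.3), 1.85)
    }
    lm1
  }
  integrate_cycle <- function(lm_cur, record = FALSE) {
    if (record) { lm_rec <- matrix(0, n_nodes, nm); lm_rec[1, ] <- lm_cur }
    for (i in seq_len(n_sub_f)) {
      lm_cur <- trap_step(lm_cur, i)
      if (record && i %% sub_f == 0) lm_rec[i / sub_f + 1, ] <- lm_cur
    }
    if (record) lm_rec else lm_cur
  }
  lm_cur <- vapply(seq_len(nm), function(m)
    hill_equilibrium_solve(a_truth[1, m], l_mt[1, m], p[m, ]), numeric(1))
  for (cyc in 1:3) lm_cur <- integrate_cycle(lm_cur)  # settle cycles
  lm_tilde <- integrate_cycle(lm_cur, record = TRUE)
  dimnames(lm_tilde) <- list(NULL, p$name)
  lm_tilde[n_nodes, ] <- lm_tilde[1, ]  # periodic closure (settled orbit)

  # node-wise tendon forces and velocities
  v_tilde <- f_ten <- matrix(0, n_nodes, nm, dimnames = list(NULL, p$name))
  for (i in seq_len(n_nodes)) {
    v_tilde[i, ] <- v_from_state(a_truth[i, ], lm_tilde[i, ], l_mt[i, ])
    g <- geom(lm_tilde[i, ], l_mt[i, ])
    f_ten[i, ] <- tendon_force_length(g$lt, kt) * p$f_max
  }
  tau_mus <- sapply(seq_along(spec$joints), function(j)
    as.vector(f_ten %*% spec$arms[, j]))
  colnames(tau_mus) <- spec$joints
  tau_id <- tau_mus
  if (!is.null(truth$device_torque)) tau_id <- tau_id + truth$device_torque
  truth$activations <- a_truth

  arms <- array(rep(as.vector(spec$arms), each = length(tt)),
                c(length(tt), nm, length(spec$joints)),
                dimnames = list(NULL, p$name, spec$joints))
  trial <- gait_trial(tt, kin$q, tau_id, l_mt, arms,
                      body_mass = spec$body_mass, speed_label = spec$speed_label)
  attr(trial, "truth") <- list(activations = truth$activations,
                               lm_tilde = lm_tilde, v_tilde = v_tilde,
                               excitations = e, tendon_forces = f_ten,
                               tau_mus = tau_mus,
                               device = truth$device,
                               device_torque = truth$device_torque,
                               seed = truth$seed)
  trial
}

#' Generate a complete synthetic trial
#'
#' Convenience wrapper: ground truth plus trial in one call.
#'
#' @inheritParams generate_ground_truth
#' @return A [gait_trial()] with the `truth` attribute.
#' @export
synthetic_trial <- function(spec, seed = 0, device = NULL) {
  generate_trial_from_truth(spec, generate_ground_truth(spec, seed, device))
}

#' Write the standard fixture suite
#'
#' Three speeds (0.55, 1.0, 1.45 of preferred speed) by three seeds (0, 1,
#' 2), each written as motion-storage tables plus the ground-truth
#' activation table and one shared muscle parameter table. Deterministic:
#' re-running overwrites bit-identically.
#'
#' @param out_dir Output directory.
#' @param seeds Integer seeds (default 0:2).
#' @param speed_scales Speed scales (default c(0.55, 1, 1.45)).
#' @param body_mass Body mass (kg).
#' @return Data.frame listing the trial stems, invisibly.
#' @export
fixture_suite <- function(out_dir, seeds = 0:2,
                          speed_scales = c(0.55, 1, 1.45), body_mass = 69) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  idx <- expand.grid(seed = seeds, speed = speed_scales)
  stems <- character(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    spec <- synthetic_model_spec(speed_scale = idx$speed[k],
                                 body_mass = body_mass)
    trial <- synthetic_trial(spec, seed = idx$seed[k])
    stem <- sprintf("trial_%s_seed%d", spec$speed_label, idx$seed[k])
    write_gait_trial(trial, out_dir, stem)
    tr <- attr(trial, "truth")
    write_motion_table(data.frame(time = trial$time, tr$activations,
                                  check.names = FALSE),
                       file.path(out_dir, paste0(stem, "_truth_activations.sto")),
                       name = paste0(stem, " ground-truth activations"))
    stems[k] <- stem
  }
  write_muscle_params(default_muscle_set(),
                      file.path(out_dir, "muscle_params.tsv"),
                      comment = "synthetic default lower-limb set")
  invisible(data.frame(stem = stems, seed = idx$seed, speed = idx$speed))
}
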