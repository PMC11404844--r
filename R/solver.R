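# Direct-collocation muscle redundancy solver.
#
# Transcription: uniform periodic mesh of N intervals over the gait cycle
# (node N+1 identified with node 1, which enforces state periodicity) with
# an implicit-midpoint scheme: activations and normalized fiber lengths live
# on the nodes; excitations, the scaled fiber velocity (the fiber-length
# state derivative, an implicit control) and the motor torque live on the
# interval midpoints, where the Hill equilibrium, the activation-dynamics
# defects, the moment balance and the objective quadrature are evaluated.
# The midpoint scheme is second-order, so the objective is stable under
# mesh refinement. The reserve actuators are eliminated analytically
# through the moment-balance equation, so the balance holds exactly at
# every collocation point and the heavily penalized reserve excitations
# appear only in the objective.
#
# The resulting equality-constrained NLP (bounds on activations,
# excitations and fiber lengths; Hill and activation-dynamics residuals as
# equalities) is solved with an augmented-Lagrangian method whose
# bound-constrained inner problems go to optim(method = "L-BFGS-B") with
# analytic gradients.

#' Objective weights of the redundancy problem
#'
#' Defaults reproduce the study settings: activation weight 1, reserve
#' weight 1000, fiber-velocity weight 0.001, reserve magnitude 100 N m.
#'
#' @param w_a Activation term weight.
#' @param w_r Reserve term weight.
#' @param w_v Fiber-velocity term weight.
#' @param T_R Reserve actuator magnitude (N m).
#' @return List of weights.
#' @export
solver_weights <- function(w_a = 1, w_r = 1000, w_v = 0.001, T_R = 100) {
  stopifnot(w_a >= 0, w_r >= 0, w_v >= 0, T_R > 0)
  list(w_a = w_a, w_r = w_r, w_v = w_v, T_R = T_R)
}

#' Solver options
#'
#' @param mesh Collocation intervals per cycle.
#' @param tol_con Constraint tolerance on the scaled defect residuals.
#' @param tol_obj Relative objective tolerance between outer iterations.
#' @param maxit_inner L-BFGS-B iteration cap per inner solve.
#' @param max_outer Augmented-Lagrangian outer iteration cap.
#' @param rho0 Initial penalty parameter.
#' @param rigid_tendon Use rigid tendons (fiber state follows geometry; no
#'   Hill equality constraints).
#' @param inner_factr L-BFGS-B `factr` termination factor of the inner
#'   solves (relative-progress threshold in units of machine epsilon).
#' @param a_min Lower activation/excitation bound.
#' @param verbose Print outer-iteration diagnostics.
#' @return List of options.
#' @export
solver_options <- function(mesh = 100, tol_con = 1e-7, tol_obj = 5e-6,
                           maxit_inner = 1000, max_outer = 20, rho0 = 10,
                           rigid_tendon = FALSE, inner_factr = 1e7,
                           a_min = 0.01, verbose = FALSE) {
  list(mesh = mesh, tol_con = tol_con, tol_obj = tol_obj,
       maxit_inner = maxit_inner, max_outer = max_outer, rho0 = rho0,
       rigid_tendon = rigid_tendon, inner_factr = inner_factr,
       a_min = a_min, verbose = verbose)
}

# cyclic row shifts on N x M matrices
shift_up <- function(X) X[c(nrow(X), seq_len(nrow(X) - 1)), , drop = FALSE]   # row i-1
shift_down <- function(X) X[c(seq_len(nrow(X) - 1) + 1, 1), , drop = FALSE]   # row i+1

# midpoint average / scaled difference over interval i (nodes i -> i+1)
mid_avg <- function(X) (X + shift_down(X)) / 2
mid_diff <- function(X, h) (shift_down(X) - X) / h
# distribute midpoint gradients back to the nodes
dist_avg <- function(G) (G + shift_up(G)) / 2
dist_diff <- function(G, h) (shift_up(G) - G) / h

# Problem context shared by objective/gradient evaluations. All trial
# quantities are interpolated to the interval midpoints of the periodic
# mesh; parameter vectors are replicated to N x M matrices.
build_context <- function(disc, params, weights, options, device = NULL,
                          tau_exo_fixed = NULL) {
  N <- length(disc$time) - 1
  h <- disc$h
  t_nodes <- disc$time[seq_len(N)]
  t_mid <- t_nodes + h / 2
  nm <- nrow(params); nj <- ncol(disc$tau_id)
  rep_row <- function(v) matrix(rep(v, each = N), N, nm)
  interp_mid <- function(mat) {
    out <- sapply(seq_len(ncol(mat)), function(j)
      periodic_spline(disc$time, mat[, j])(t_mid))
    colnames(out) <- colnames(mat)
    out
  }
  ctx <- list(
    N = N, nm = nm, nj = nj, h = h,
    t_nodes = t_nodes, t_mid = t_mid,
    l_mt = if (is.null(disc$exact_mid)) interp_mid(disc$l_mt) else disc$exact_mid$l_mt,
    tau_id = if (is.null(disc$exact_mid)) interp_mid(disc$tau_id) else disc$exact_mid$tau_id,
    q = if (is.null(disc$exact_mid)) interp_mid(disc$q) else disc$exact_mid$q,
    joints = colnames(disc$tau_id),
    muscles = params$name,
    f_max = rep_row(params$f_max), l_opt = rep_row(params$l_m_opt),
    l_slk = rep_row(params$l_t_slack), k_t = rep_row(params$k_t),
    p_scale = rep_row(params$passive_scale),
    p_shift = rep_row(params$passive_shift),
    height = rep_row(params$l_m_opt * sin(params$alpha_opt)),
    weights = weights, options = options, params = params,
    const = activation_constants(a_min = options$a_min),
    device = device
  )
  ctx$R <- lapply(seq_len(nj), function(j) {
    A <- sapply(seq_len(nm), function(m) {
      ya <- disc$moment_arms[, m, j]
      if (all(ya == ya[1])) rep(ya[1], N) else periodic_spline(disc$time, ya)(t_mid)
    })
    matrix(A, N, nm)
  })
  # bounds on the fiber length state (node values; use midpoint l_mt bounds
  # tightened to their neighborhood minimum)
  lm_lo <- pmax(0.21, sin(params$alpha_opt) + 0.02)
  ctx$lm_lo <- rep_row(lm_lo)
  lm_hi_mid <- sqrt(pmax((ctx$l_mt - 0.5 * ctx$l_slk)^2, 1e-8) + ctx$height^2) /
    ctx$l_opt
  ctx$lm_hi <- pmin(pmin(lm_hi_mid, shift_up(lm_hi_mid)), 1.89)
  # fixed external assistance at midpoints (given on the closed node grid)
  if (is.null(tau_exo_fixed)) {
    ctx$tau_exo_fixed <- matrix(0, N, nj)
  } else {
    ctx$tau_exo_fixed <- sapply(seq_len(nj), function(j)
      periodic_spline(disc$time, tau_exo_fixed[, j])(t_mid))
    if (is.null(dim(ctx$tau_exo_fixed)))
      ctx$tau_exo_fixed <- matrix(ctx$tau_exo_fixed, N, nj)
  }
  # midpoint-grid pseudo-discretization for the static initializer/surrogate
  ctx$disc_mid <- list(time = t_mid, h = h, w = rep(h, N),
                       q = ctx$q, tau_id = ctx$tau_id, l_mt = ctx$l_mt,
                       dl_mt = interp_mid_deriv(disc, t_mid),
                       moment_arms = local({
                         arr <- array(0, c(N, nm, nj))
                         for (j in seq_len(nj)) arr[, , j] <- ctx$R[[j]]
                         dimnames(arr) <- list(NULL, params$name, ctx$joints)
                         arr
                       }))
  ctx$motor_joint <- if (!is.null(device) && inherits(device, "motor_spec"))
    match(device$joint, ctx$joints) else NA_integer_
  ctx
}

interp_mid_deriv <- function(disc, t_mid) {
  out <- sapply(seq_len(ncol(disc$l_mt)), function(m)
    periodic_spline(disc$time, disc$l_mt[, m])(t_mid, deriv = 1))
  colnames(out) <- colnames(disc$l_mt)
  out
}

# pack/unpack decision variables: a (nodes), lm (nodes, elastic mode),
# e (midpoints), motor torque (midpoints)
pack_x <- function(a, lm, e, tau) c(a, lm, e, tau)
unpack_x <- function(x, ctx) {
  N <- ctx$N; nm <- ctx$nm
  n_mat <- N * nm
  rigid <- ctx$options$rigid_tendon
  a <- matrix(x[seq_len(n_mat)], N, nm)
  off <- n_mat
  if (!rigid) { lm <- matrix(x[off + seq_len(n_mat)], N, nm); off <- off + n_mat }
  else lm <- NULL
  e <- matrix(x[off + seq_len(n_mat)], N, nm); off <- off + n_mat
  tau <- if (!is.na(ctx$motor_joint)) x[off + seq_len(N)] else NULL
  list(a = a, lm = lm, e = e, tau = tau)
}

# Augmented-Lagrangian objective and gradient.
al_eval <- function(x, ctx, lam_H, lam_A, rho_H, rho_A, want_grad = TRUE) {
  w <- ctx$weights; h <- ctx$h; N <- ctx$N; nm <- ctx$nm
  u <- unpack_x(x, ctx)
  a <- u$a; e <- u$e
  rigid <- ctx$options$rigid_tendon
  const <- ctx$const
  VS <- .VEL_SCALE; dmp <- .FIBER_DAMPING

  am <- mid_avg(a)
  if (!rigid) {
    lm <- u$lm
    lmm <- mid_avg(lm)
    vt <- mid_diff(lm, h) / VS
    fact <- active_force_length(lmm)
    dfact <- active_force_length_deriv(lmm)
    fv <- force_velocity(vt)
    dfv <- force_velocity_deriv(vt)
    fpas <- passive_force_length(lmm, ctx$p_scale, ctx$p_shift)
    dfpas <- passive_force_length_deriv(lmm, ctx$p_scale, ctx$p_shift)
    lm_abs <- lmm * ctx$l_opt
    along <- sqrt(lm_abs^2 - ctx$height^2)
    cosA <- along / lm_abs
    dcos <- ctx$height^2 / (ctx$l_opt^2 * lmm^3 * cosA)
    lt <- (ctx$l_mt - along) / ctx$l_slk
    dlt <- -ctx$l_opt / (ctx$l_slk * cosA)
    ftn <- tendon_force_length(lt, ctx$k_t)
    dftn <- tendon_force_length_deriv(lt, ctx$k_t)
    fib <- am * fact * fv + fpas + dmp * vt
    cH <- fib * cosA - ftn
    F_t <- ctx$f_max * ftn
  } else {
    rt <- ctx$rigid_terms
    vt <- rt$v_tilde
    F_t <- rt$gain * am + rt$offset
    cH <- NULL
    lmm <- rt$lm_tilde
  }

  # moment balance -> reserves (all at midpoints)
  tau_mus <- matrix(0, N, ctx$nj)
  for (j in seq_len(ctx$nj)) tau_mus[, j] <- rowSums(ctx$R[[j]] * F_t)
  tau_exo <- ctx$tau_exo_fixed
  if (!is.na(ctx$motor_joint)) tau_exo[, ctx$motor_joint] <-
    tau_exo[, ctx$motor_joint] + u$tau
  eR <- (ctx$tau_id - tau_mus - tau_exo) / w$T_R

  # activation dynamics defect over each interval (implicit midpoint)
  g <- activation_rate(e, am, const)
  cA <- (shift_down(a) - a) - h * g

  J_a <- h * w$w_a * sum(am^2)
  J_r <- h * w$w_r * sum(eR^2)
  J_v <- h * w$w_v * sum(vt^2)
  J <- J_a + J_r + J_v

  L <- J + sum(lam_A * cA) + 0.5 * rho_A * sum(cA^2)
  if (!rigid) L <- L + sum(lam_H * cH) + 0.5 * rho_H * sum(cH^2)

  if (!want_grad)
    return(list(L = L, J = J, J_a = J_a, J_r = J_r, J_v = J_v,
                cH = cH, cA = cA, eR = eR, tau_mus = tau_mus,
                tau_exo = tau_exo, vt = vt, lm_mid = lmm, a_mid = am,
                F_t = F_t, a = a, e = e, lm = u$lm, tau = u$tau))

  sA <- lam_A + rho_A * cA
  gp <- activation_rate_partials(e, am, const)

  # sum_j eR[,j] * R_j, used by every force-route gradient
  eR_R <- matrix(0, N, nm)
  for (j in seq_len(ctx$nj)) eR_R <- eR_R + eR[, j] * ctx$R[[j]]

  # midpoint-activation routes: objective + dynamics + (elastic) Hill
  G_am <- 2 * h * w$w_a * am - h * sA * gp$da
  if (!rigid) {
    sH <- lam_H + rho_H * cH
    G_am <- G_am + sH * (fact * fv * cosA)
  } else {
    G_am <- G_am + 2 * h * w$w_r * (-1 / w$T_R) * eR_R * ctx$rigid_terms$gain
  }
  grad_a <- dist_avg(G_am) + (shift_up(sA) - sA)
  grad_e <- -h * sA * gp$de

  if (!rigid) {
    # midpoint fiber-length route
    G_lmm <- sH * ((am * dfact * fv + dfpas) * cosA + fib * dcos - dftn * dlt) +
      2 * h * w$w_r * (-1 / w$T_R) * eR_R * ctx$f_max * dftn * dlt
    # velocity route
    G_vt <- sH * (am * fact * dfv + dmp) * cosA + 2 * h * w$w_v * vt
    grad_lm <- dist_avg(G_lmm) + dist_diff(G_vt, h) / VS
  } else grad_lm <- NULL

  grad_tau <- if (!is.na(ctx$motor_joint))
    -2 * h * w$w_r * eR[, ctx$motor_joint] / w$T_R else NULL

  list(L = L, grad = c(grad_a, grad_lm, grad_e, grad_tau),
       J = J, J_a = J_a, J_r = J_r, J_v = J_v, cH = cH, cA = cA, eR = eR)
}

# Deterministic initial guess: per-frame static optimization at the
# midpoints for the activations (clamped inside the bounds), node values by
# cyclic averaging, fiber lengths from the Hill equilibrium at the median
# activation, excitations equal to the midpoint activations, motor torque
# zero.
initial_guess <- function(ctx) {
  st <- static_optimize(ctx$disc_mid, ctx$params, ctx$weights,
                        tau_exo = ctx$tau_exo_fixed, a_min = ctx$options$a_min)
  am0 <- pmin(pmax(st$activations, ctx$options$a_min + 0.005), 0.95)
  a0 <- (am0 + shift_up(am0)) / 2   # midpoint -> node estimate
  e0 <- am0
  if (!ctx$options$rigid_tendon) {
    lm0 <- matrix(0, ctx$N, ctx$nm)
    for (m in seq_len(ctx$nm)) {
      lm_mid <- hill_equilibrium_solve(stats::median(am0[, m]), ctx$l_mt[, m],
                                       ctx$params[m, ])
      lm0[, m] <- (lm_mid + lm_mid[c(ctx$N, seq_len(ctx$N - 1))]) / 2
    }
    lm0 <- pmin(pmax(lm0, ctx$lm_lo + 1e-3), ctx$lm_hi - 1e-3)
  } else lm0 <- NULL
  tau0 <- if (!is.na(ctx$motor_joint)) rep(0, ctx$N) else NULL
  list(a = a0, lm = lm0, e = e0, tau = tau0)
}

# Core augmented-Lagrangian solve. init/warm may come from a warm start.
solve_core <- function(ctx, init = NULL, warm = NULL) {
  opt <- ctx$options
  if (opt$rigid_tendon)
    ctx$rigid_terms <- local({
      ft <- rigid_force_terms(ctx$disc_mid, ctx$params)
      list(gain = ft$gain, offset = ft$offset, v_tilde = ft$v_tilde,
           lm_tilde = ft$lm_tilde)
    })
  if (is.null(init)) init <- initial_guess(ctx)
  ctx$R_cube <- local({
    arr <- array(0, c(ctx$N, ctx$nm, ctx$nj))
    for (j in seq_len(ctx$nj)) arr[, , j] <- ctx$R[[j]]
    arr
  })
  dummy <- matrix(0, 1, 1)
  ctx$cpp_ptr <- alctx_new(ctx$N, ctx$nm, ctx$nj, ctx$h,
    opt$rigid_tendon, ctx$l_mt, ctx$tau_id, ctx$tau_exo_fixed, ctx$R_cube,
    ctx$f_max, ctx$l_opt, ctx$l_slk, ctx$k_t, ctx$p_scale, ctx$p_shift,
    ctx$height, ctx$weights$w_a, ctx$weights$w_r, ctx$weights$w_v,
    ctx$weights$T_R, ctx$const$tau_act, ctx$const$tau_deact,
    ctx$const$blend,
    if (is.na(ctx$motor_joint)) -1L else ctx$motor_joint - 1L,
    if (opt$rigid_tendon) ctx$rigid_terms$gain else dummy,
    if (opt$rigid_tendon) ctx$rigid_terms$offset else dummy,
    if (opt$rigid_tendon) ctx$rigid_terms$v_tilde else dummy)
  x <- pack_x(init$a, init$lm, init$e, init$tau)

  N <- ctx$N; nm <- ctx$nm
  n_mat <- N * nm
  a_lo <- rep(opt$a_min, n_mat); a_hi <- rep(1, n_mat)
  lo <- a_lo; hi <- a_hi
  if (!opt$rigid_tendon) { lo <- c(lo, ctx$lm_lo); hi <- c(hi, ctx$lm_hi) }
  lo <- c(lo, a_lo); hi <- c(hi, a_hi)
  if (!is.na(ctx$motor_joint)) {
    dev <- ctx$device
    t_lo <- if (dev$assist_sign > 0) rep(0, N) else rep(-dev$torque_bound, N)
    t_hi <- if (dev$assist_sign > 0) rep(dev$torque_bound, N) else rep(0, N)
    t_lo[!is.finite(t_lo)] <- -1e4; t_hi[!is.finite(t_hi)] <- 1e4
    lo <- c(lo, t_lo); hi <- c(hi, t_hi)
  }
  x <- pmin(pmax(x, lo), hi)

  lam_H <- if (!opt$rigid_tendon) matrix(0, N, nm) else NULL
  lam_A <- matrix(0, N, nm)
  if (!is.null(warm)) { lam_H <- warm$lam_H; lam_A <- warm$lam_A }
  rho_H <- rho_A <- opt$rho0
  if (!is.null(warm) && !is.null(warm$rho)) { rho_H <- warm$rho[1]; rho_A <- warm$rho[2] }

  # variable scaling for the inner solver: fiber-length gradients are two
  # orders of magnitude stiffer than activation gradients (tendon-stiffness
  # amplification), motor torques live on a ~100 N m scale
  scl <- rep(1, n_mat)                       # a
  if (!opt$rigid_tendon) scl <- c(scl, rep(1 / 60, n_mat))  # lm
  scl <- c(scl, rep(1, n_mat))               # e
  if (!is.na(ctx$motor_joint)) scl <- c(scl, rep(25, N))    # motor torque

  # Continuation on the reserve weight: the problem is non-convex and plain
  # descent tends to land in a basin that leans on the reserve actuators
  # near rapid force decays. A first pass with the reserve term boosted
  # pulls the iterate into the low-reserve basin; the final pass optimizes
  # the true objective from there. The reported solution and objective are
  # always evaluated at the study weights.
  phases <- if (is.null(warm))
    list(list(w_r_mult = 10, outers = 4, tol_mult = 100,
              maxit = opt$maxit_inner),
         list(w_r_mult = 1, outers = opt$max_outer, tol_mult = 1,
              maxit = opt$maxit_inner))
  else list(list(w_r_mult = 1, outers = opt$max_outer, tol_mult = 1,
                 maxit = opt$maxit_inner))

  status <- "max_outer_reached"
  true_w_r <- ctx$weights$w_r
  for (phase in phases) {
    ctx$weights$w_r <- true_w_r * phase$w_r_mult
    prev_viol <- Inf; prev_J <- Inf
    for (outer in seq_len(phase$outers)) {
      alctx_update(ctx$cpp_ptr,
                   if (opt$rigid_tendon) matrix(0, 1, 1) else lam_H,
                   lam_A, rho_H, rho_A, ctx$weights$w_r)
      fit <- al_inner_solve(ctx$cpp_ptr, x, lo, hi, scl,
                            phase$maxit, opt$inner_factr, 0,
                            if (is.null(opt$lmm)) 8 else opt$lmm)
      x <- fit$par
      ev <- al_eval(x, ctx, lam_H, lam_A, rho_H, rho_A, want_grad = FALSE)
      viol <- max(abs(ev$cA), if (!opt$rigid_tendon) abs(ev$cH) else 0)
      if (opt$verbose)
        message(sprintf("  [w_r x%g] outer %d: J = %.6g, viol = %.3g, rho = %g, evals = %d",
                        phase$w_r_mult, outer, ev$J, viol, rho_H, fit$fncount))
      if (viol < opt$tol_con * phase$tol_mult &&
          abs(ev$J - prev_J) <= opt$tol_obj * max(1, abs(ev$J))) {
        status <- "converged"; break
      }
      lam_A <- lam_A + rho_A * ev$cA
      if (!opt$rigid_tendon) lam_H <- lam_H + rho_H * ev$cH
      # escalate the penalty when violations stagnate, but cap it: beyond
      # ~1e8 the inner problem conditioning degrades and multiplier updates
      # alone drive feasibility
      if (viol > 0.25 * prev_viol) {
        rho_H <- min(rho_H * 10, 1e8); rho_A <- min(rho_A * 10, 1e8)
      }
      prev_viol <- viol; prev_J <- ev$J
    }
  }
  ctx$weights$w_r <- true_w_r
  ev <- al_eval(x, ctx, lam_H, lam_A, rho_H, rho_A, want_grad = FALSE)
  # feasible at the outer budget: report convergence (objective progress
  # simply exhausted the iteration allowance)
  final_viol <- max(abs(ev$cA), if (!opt$rigid_tendon) abs(ev$cH) else 0)
  if (status != "converged" && final_viol < opt$tol_con) status <- "converged"
  list(x = x, ev = ev, status = status,
       viol = max(abs(ev$cA), if (!opt$rigid_tendon) abs(ev$cH) else 0),
       warm = list(lam_H = lam_H, lam_A = lam_A, rho = c(rho_H, rho_A)))
}

# Assemble the user-facing solution object from a core solve. All
# mechanical/energetic time series are reported on the midpoint grid where
# the collocation conditions hold. The core iterate and multipliers are
# attached so related solves (assisted conditions on the same trial/mesh)
# can warm-start.
as_solution <- function(core, ctx, trial) {
  ev <- core$ev
  a <- ev$a_mid; e <- ev$e; lm <- ev$lm_mid; vt <- ev$vt; F_t <- ev$F_t
  eR <- ev$eR; tau_mus <- ev$tau_mus; tau_exo <- ev$tau_exo
  colnames(a) <- colnames(e) <- colnames(lm) <- colnames(vt) <-
    colnames(F_t) <- ctx$muscles
  colnames(eR) <- colnames(tau_mus) <- colnames(tau_exo) <- ctx$joints
  balance <- abs(ctx$tau_id - tau_mus - ctx$weights$T_R * eR - tau_exo)
  structure(list(
    time = ctx$t_mid, t_cycle = ctx$N * ctx$h,
    activations = a, excitations = e, lm_tilde = lm,
    v_tilde = vt, tendon_forces = F_t, reserves = eR, tau_mus = tau_mus,
    tau_exo = tau_exo, tau_id = ctx$tau_id, q = ctx$q,
    a_nodes = ev$a, lm_nodes = ev$lm, t_nodes = ctx$t_nodes,
    objective = ev$J, objective_terms = c(activation = ev$J_a,
                                          reserve = ev$J_r, velocity = ev$J_v),
    status = core$status, constraint_violation = core$viol,
    moment_balance_violation = max(balance),
    weights = ctx$weights, mesh = ctx$N,
    speed_label = trial$speed_label, body_mass = trial$body_mass,
    muscles = ctx$muscles, joints = ctx$joints),
    class = "redundancy_solution")
}

solution_core_state <- function(sol) attr(sol, "core_state")

attach_core_state <- function(sol, core, ctx) {
  attr(sol, "core_state") <- list(init = unpack_x(core$x, ctx),
                                  warm = core$warm, mesh = ctx$N)
  sol
}

#' @export
print.redundancy_solution <- function(x, ...) {
  cat(sprintf("<redundancy_solution> %s: J = %.5g (a %.4g, r %.4g, v %.4g), %s, max dyn viol %.2g\n",
              x$speed_label, x$objective, x$objective_terms[1],
              x$objective_terms[2], x$objective_terms[3], x$status,
              x$constraint_violation))
  invisible(x)
}

#' Solve the unassisted muscle redundancy problem
#'
#' Distributes the net joint moments of a gait trial across the muscles by
#' direct-collocation trajectory optimization under the minimal
#' summed-squared-activation criterion, with implicit activation and
#' contraction dynamics and penalized reserve actuators.
#'
#' @param trial A [gait_trial()].
#' @param params `muscle_params` matching the trial muscle columns.
#' @param weights [solver_weights()].
#' @param options [solver_options()].
#' @return A `redundancy_solution`.
#' @export
solve_unassisted <- function(trial, params, weights = solver_weights(),
                             options = solver_options()) {
  stopifnot(inherits(trial, "gait_trial"))
  if (!identical(params$name, muscles_of(trial)))
    params <- params[match(muscles_of(trial), params$name), ]
  disc <- discretize(trial, options$mesh)
  ctx <- build_context(disc, params, weights, options)
  core <- solve_core(ctx)
  if (core$status != "converged" && core$viol > 100 * options$tol_con)
    stop("redundancy solver did not converge: max dynamics violation ",
         signif(core$viol, 3))
  attach_core_state(as_solution(core, ctx, trial), core, ctx)
}

#' Solve the assisted muscle redundancy problem
#'
#' Adds an ideal assistive device at one joint to the redundancy problem.
#' For a motor device the per-interval torque trajectory enters the
#' optimization as a free, sign-constrained variable. For a spring device
#' the three design variables (stiffness, engagement and disengagement
#' times) are optimized in an outer loop - for fixed design variables the
#' spring torque is a function of the prescribed kinematics only - with a
#' fast rigid-tendon surrogate screening candidate engagement windows,
#' Nelder-Mead polishing, the engagement-closure constraint
#' `(q(t_c) - q(t_d))^2 < 0.01` and unidirectionality enforced by
#' construction of the torque profile.
#'
#' @inheritParams solve_unassisted
#' @param device A [motor_spec()] or [spring_spec()].
#' @param unassisted Optional precomputed unassisted `redundancy_solution`
#'   on the same mesh; the spring search uses its objective for the
#'   zero-stiffness fallback instead of re-solving.
#' @param init_solution Optional `redundancy_solution` on the same mesh
#'   used as an additional starting point for a motor solve (e.g. the
#'   spring solution, whose torque profile is motor-feasible; descent from
#'   it guarantees the motor objective does not exceed the spring's).
#' @return List with `solution` (a `redundancy_solution`) and
#'   `device_solution` (a `device_solution`: torque trajectory plus, for
#'   springs, the fitted design variables, engagement window and
#'   stored-energy diagnostics).
#' @export
solve_assisted <- function(trial, params, weights = solver_weights(),
                           device, options = solver_options(),
                           unassisted = NULL, init_solution = NULL) {
  stopifnot(inherits(trial, "gait_trial"), inherits(device, "device_spec"))
  if (!device$joint %in% joints_of(trial))
    stop("unknown joint: ", device$joint)
  if (!identical(params$name, muscles_of(trial)))
    params <- params[match(muscles_of(trial), params$name), ]
  disc <- discretize(trial, options$mesh)
  if (inherits(device, "motor_spec")) {
    ctx <- build_context(disc, params, weights, options, device = device)
    single <- isTRUE(options$motor_single_start) && !is.null(init_solution) &&
      init_solution$mesh == (length(disc$time) - 1)
    core <- if (single) NULL else solve_core(ctx)
    if (!is.null(init_solution) && init_solution$mesh == ctx$N &&
        (single || core$ev$J > init_solution$objective)) {
      tau0 <- init_solution$tau_exo[, device$joint]
      tau0 <- device$assist_sign * pmin(pmax(device$assist_sign * tau0, 0),
                                        device$torque_bound)
      init2 <- list(a = init_solution$a_nodes, lm = init_solution$lm_nodes,
                    e = init_solution$excitations, tau = tau0)
      core2 <- solve_core(ctx, init = init2)
      if (is.null(core) || core2$ev$J < core$ev$J) core <- core2
    }
    sol <- as_solution(core, ctx, trial)
    jdev <- device$joint
    dev_sol <- structure(list(
      mode = "motor", joint = jdev,
      tau_exo = sol$tau_exo[, jdev],
      time = sol$time,
      peak_torque = max(abs(sol$tau_exo[, jdev]))),
      class = "device_solution")
    return(list(solution = sol, device_solution = dev_sol))
  }
  solve_spring(trial, disc, params, weights, device, options,
               unassisted = unassisted)
}

#' @export
print.device_solution <- function(x, ...) {
  if (x$mode == "motor") {
    cat(sprintf("<device_solution> motor @ %s: peak |torque| %.2f N m\n",
                x$joint, x$peak_torque))
  } else {
    cat(sprintf("<device_solution> spring @ %s: k_r = %.2f N m/rad, window [%.3f, %.3f] s, closure %.2g rad^2\n",
                x$joint, x$k_r, x$t_c, x$t_d, x$closure))
  }
  invisible(x)
}
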