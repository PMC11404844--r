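# Muscle-tendon parameter tuning: a simplified two-step procedure that
# (1) adjusts optimal fiber length, tendon slack length and tendon
# stiffness so simulated quasi-static normalized fiber-length trajectories
# match target trajectories and excursions, and (2) adjusts the passive
# force-length scale/shift so summed muscle passive moments match target
# joint passive moment-angle curves. Both steps are bounded least squares
# with deterministic starts from the nominal parameters.

#' Fiber-length tuning target
#'
#' @param muscle Muscle label.
#' @param pct_cycle Percent-of-gait-cycle grid (0-100).
#' @param lm_tilde Target normalized fiber-length trajectory (positive).
#' @param excursion Target excursion; defaults to `max - min` of the
#'   trajectory and must match it when supplied.
#' @return A `fiber_target`.
#' @export
fiber_target <- function(muscle, pct_cycle, lm_tilde,
                         excursion = max(lm_tilde) - min(lm_tilde)) {
  stopifnot(length(pct_cycle) == length(lm_tilde), all(lm_tilde > 0),
            all(diff(pct_cycle) > 0))
  if (abs(excursion - (max(lm_tilde) - min(lm_tilde))) > 1e-6)
    stop("excursion inconsistent with the trajectory for ", muscle)
  structure(list(muscle = muscle, pct_cycle = pct_cycle,
                 lm_tilde = lm_tilde, excursion = excursion),
            class = "fiber_target")
}

#' Passive moment-angle tuning target
#'
#' @param joint Joint label.
#' @param angles Strictly increasing angle grid (rad).
#' @param moment Passive joint moment at each angle (N m).
#' @return A `passive_moment_target`.
#' @export
passive_moment_target <- function(joint, angles, moment) {
  stopifnot(length(angles) == length(moment), all(diff(angles) > 0))
  structure(list(joint = joint, angles = angles, moment = moment),
            class = "passive_moment_target")
}

# Quasi-static fiber length: solve the Hill equilibrium at fixed activation
# and zero fiber velocity by vectorized Newton iteration over frames,
# falling back to bracketed root-finding where Newton stalls.
quasi_static_fiber <- function(a, l_mt, p) {
  h <- p$l_m_opt * sin(p$alpha_opt)
  along0 <- pmax(l_mt - p$l_t_slack, 1e-4)
  lm <- pmin(pmax(sqrt(along0^2 + h^2) / p$l_m_opt, 0.3), 1.85)
  fv0 <- force_velocity(0)
  res <- function(lm) {
    lm_abs <- lm * p$l_m_opt
    along <- sqrt(pmax(lm_abs^2 - h^2, 1e-10))
    cosA <- along / lm_abs
    lt <- (l_mt - along) / p$l_t_slack
    (a * active_force_length(lm) * fv0 +
       passive_force_length(lm, p$passive_scale, p$passive_shift)) * cosA -
      tendon_force_length(lt, p$k_t)
  }
  dres <- function(lm) {
    d <- 1e-6
    (res(lm + d) - res(lm - d)) / (2 * d)
  }
  for (it in 1:30) {
    r <- res(lm)
    lm_new <- pmin(pmax(lm - r / dres(lm), 0.3), 1.85)
    if (max(abs(lm_new - lm)) < 1e-11) { lm <- lm_new; break }
    lm <- lm_new
  }
  bad <- abs(res(lm)) > 1e-7
  if (any(bad)) {
    for (i in which(bad)) {
      lm[i] <- tryCatch(hill_equilibrium_solve(a, l_mt[i], p), error = function(e) lm[i])
    }
  }
  lm
}

#' Tune fiber-related muscle-tendon parameters
#'
#' Adjusts optimal fiber length, tendon slack length and tendon stiffness
#' per targeted muscle (within +-30% of the nominal values) so that the
#' quasi-static normalized fiber-length trajectory simulated over the
#' trial (Hill equilibrium at a fixed reference activation) matches the
#' target trajectory and excursion in least squares. Muscles are tuned
#' independently (the fiber trajectory of a muscle depends only on its own
#' parameters).
#'
#' @param trial A [gait_trial()] covering one cycle.
#' @param params Nominal `muscle_params`.
#' @param targets List of [fiber_target()]s.
#' @param a_ref Reference activation of the quasi-static simulation.
#' @param bound_frac Box half-width as a fraction of nominal (default 0.3).
#' @param n_frames Frames of the trial used for the simulation (the trial
#'   grid is thinned to this count for speed).
#' @return List with `params` (tuned table), `diagnostics` (per-muscle
#'   data.frame: objective, rmse, convergence flag, at-bound flag).
#'   Warns when a muscle converges onto a parameter bound with a large
#'   residual (infeasible target).
#' @export
tune_fiber_parameters <- function(trial, params, targets, a_ref = 0.05,
                                  bound_frac = 0.3, n_frames = 41) {
  stopifnot(inherits(trial, "gait_trial"))
  tuned <- params
  diags <- list()
  t_grid <- trial$time
  t_span <- t_grid[length(t_grid)] - t_grid[1]
  keep <- unique(round(seq(1, length(t_grid), length.out = n_frames)))
  for (tg in targets) {
    m <- match(tg$muscle, params$name)
    if (is.na(m)) stop("target references unknown muscle: ", tg$muscle)
    l_mt_m <- trial$l_mt[keep, tg$muscle]
    t_target <- t_grid[1] + tg$pct_cycle / 100 * t_span
    interp_sim <- function(lm_sim) {
      stats::approx(t_grid[keep], lm_sim, xout = t_target, rule = 2)$y
    }
    nominal <- c(params$l_m_opt[m], params$l_t_slack[m], params$k_t[m])
    lo <- nominal * (1 - bound_frac); hi <- nominal * (1 + bound_frac)
    obj <- function(par) {
      p <- params[m, ]
      p$l_m_opt <- par[1]; p$l_t_slack <- par[2]; p$k_t <- par[3]
      lm_sim <- tryCatch(quasi_static_fiber(a_ref, l_mt_m, p),
                         error = function(e) rep(10, length(l_mt_m)))
      sim_t <- interp_sim(lm_sim)
      mean((sim_t - tg$lm_tilde)^2) +
        ((max(lm_sim) - min(lm_sim)) - tg$excursion)^2
    }
    fit <- stats::optim(nominal, obj, method = "L-BFGS-B", lower = lo,
                        upper = hi, control = list(maxit = 200, factr = 1e7,
                                                   parscale = nominal))
    tuned$l_m_opt[m] <- fit$par[1]
    tuned$l_t_slack[m] <- fit$par[2]
    tuned$k_t[m] <- fit$par[3]
    at_bound <- any(fit$par <= lo * (1 + 1e-6) | fit$par >= hi * (1 - 1e-6))
    rmse <- sqrt(fit$value)
    if (at_bound && rmse > 0.02)
      warning("fiber tuning for ", tg$muscle,
              " hit a parameter bound with residual RMSE ", signif(rmse, 3),
              " (target may be infeasible for the geometry)")
    diags[[tg$muscle]] <- data.frame(muscle = tg$muscle,
                                     objective = fit$value, rmse = rmse,
                                     converged = fit$convergence == 0,
                                     at_bound = at_bound)
  }
  list(params = tuned, diagnostics = do.call(rbind, diags))
}

#' Joint geometry of the synthetic model for passive-curve tuning
#'
#' Returns a geometry function mapping a joint label and angle grid to the
#' muscle-tendon lengths and (constant) moment arms of the synthetic
#' model, with the other joints held at their neutral angles.
#'
#' @param spec A [synthetic_model_spec()].
#' @return Function `(joint, angles) -> list(l_mt, arms, muscles)`.
#' @export
spec_geometry <- function(spec) {
  function(joint, angles) {
    stopifnot(joint %in% spec$joints)
    q <- matrix(0, length(angles), length(spec$joints),
                dimnames = list(NULL, spec$joints))
    q[, joint] <- angles
    list(l_mt = lmt_from_q(spec, q), arms = spec$arms[, joint],
         muscles = spec$muscles$name)
  }
}

# rigid-tendon passive joint moment for one joint over an angle grid
passive_joint_moment <- function(params, geom, joint, angles) {
  g <- geom(joint, angles)
  tau <- numeric(length(angles))
  for (m in seq_len(nrow(params))) {
    r <- g$arms[m]
    if (r == 0) next
    p <- params[m, ]
    h <- p$l_m_opt * sin(p$alpha_opt)
    along <- pmax(g$l_mt[, m] - p$l_t_slack, 1e-4)
    lm <- pmin(pmax(sqrt(along^2 + h^2) / p$l_m_opt, 0.21), 1.89)
    cosA <- along / (lm * p$l_m_opt)
    f <- p$f_max * passive_force_length(lm, p$passive_scale, p$passive_shift) *
      cosA
    tau <- tau + r * f
  }
  tau
}

#' Tune passive force-length curves against joint passive moments
#'
#' Adjusts the passive-curve scale (and optionally shift) of every muscle
#' spanning the targeted joints so the summed rigid-tendon muscle passive
#' moments match the target moment-angle curves in least squares. The
#' rigid-tendon passive model is linear in the scale parameters, which
#' makes scale recovery exact.
#'
#' @param params Nominal `muscle_params`.
#' @param passive_targets List of [passive_moment_target()]s.
#' @param geometry Geometry function as from [spec_geometry()].
#' @param fit_shift Also fit `passive_shift` (default FALSE: scales only).
#' @param scale_bounds Bounds on `passive_scale`.
#' @param shift_bounds Bounds on `passive_shift`.
#' @return List with `params` (tuned) and `diagnostics` (per-joint rmse in
#'   N m).
#' @export
tune_passive_curves <- function(params, passive_targets, geometry,
                                fit_shift = FALSE,
                                scale_bounds = c(0, 5),
                                shift_bounds = c(-0.3, 0.3)) {
  joints <- vapply(passive_targets, `[[`, character(1), "joint")
  # muscles spanning any targeted joint
  spanning <- unique(unlist(lapply(passive_targets, function(tg) {
    g <- geometry(tg$joint, tg$angles[1])
    g$muscles[g$arms != 0]
  })))
  idx <- match(spanning, params$name)
  n <- length(idx)
  par0 <- params$passive_scale[idx]
  lo <- rep(scale_bounds[1], n); hi <- rep(scale_bounds[2], n)
  if (fit_shift) {
    par0 <- c(par0, params$passive_shift[idx])
    lo <- c(lo, rep(shift_bounds[1], n)); hi <- c(hi, rep(shift_bounds[2], n))
  }
  apply_par <- function(par) {
    p <- params
    p$passive_scale[idx] <- par[seq_len(n)]
    if (fit_shift) p$passive_shift[idx] <- par[n + seq_len(n)]
    p
  }
  obj <- function(par) {
    p <- apply_par(par)
    sum(vapply(passive_targets, function(tg) {
      tau <- passive_joint_moment(p, geometry, tg$joint, tg$angles)
      mean((tau - tg$moment)^2)
    }, numeric(1)))
  }
  fit <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 300, factr = 1e6))
  tuned <- apply_par(fit$par)
  diags <- do.call(rbind, lapply(passive_targets, function(tg) {
    tau <- passive_joint_moment(tuned, geometry, tg$joint, tg$angles)
    data.frame(joint = tg$joint, rmse_nm = sqrt(mean((tau - tg$moment)^2)))
  }))
  list(params = tuned, diagnostics = diags, converged = fit$convergence == 0)
}
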