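# Hill-type muscle-tendon equilibrium with elastic tendon and fixed-height
# pennation. All quantities are normalized: fiber length by optimal fiber
# length, tendon length by slack length, forces by maximum isometric force.

# Small fiber damping (normalized force per unit scaled velocity); improves
# conditioning of the contraction dynamics, standard companion of the curve
# family.
.FIBER_DAMPING <- 0.01

# Velocity scale: dl_m_tilde/dt = VEL_SCALE * v_tilde, so v_tilde in [-1, 1]
# corresponds to +-10 optimal fiber lengths per second.
.VEL_SCALE <- 10

#' Muscle-tendon geometry from normalized fiber length
#'
#' Fixed-height pennation model: the fiber height `l_m_opt * sin(alpha_opt)`
#' is constant, so the pennation angle follows from the current fiber length.
#' Returns the cosine of the pennation angle and the normalized tendon length
#' implied by the muscle-tendon length `l_mt`.
#'
#' @param lm_tilde Normalized fiber length.
#' @param l_mt Muscle-tendon length (m).
#' @param params Single-row `muscle_params` (or list with `l_m_opt`,
#'   `l_t_slack`, `alpha_opt`).
#' @return List with `cos_alpha`, `lt_tilde`, `lm` (absolute fiber length, m)
#'   and `fiber_along_tendon` (m).
#' @export
muscle_geometry <- function(lm_tilde, l_mt, params) {
  h <- params$l_m_opt * sin(params$alpha_opt)
  lm <- lm_tilde * params$l_m_opt
  w2 <- lm^2 - h^2
  if (any(w2 <= 0)) stop("degenerate geometry: fiber shorter than its height (cos pennation <= 0)")
  along <- sqrt(w2)
  cos_alpha <- along / lm
  lt_tilde <- (l_mt - along) / params$l_t_slack
  if (any(lt_tilde <= 0)) stop("degenerate geometry: non-positive tendon length")
  list(cos_alpha = cos_alpha, lt_tilde = lt_tilde, lm = lm,
       fiber_along_tendon = along)
}

#' Hill equilibrium residual
#'
#' Normalized force balance between the fiber (active + passive + damping),
#' projected along the tendon by the pennation angle, and the elastic tendon.
#' A zero residual defines dynamically consistent muscle states; the
#' redundancy solver imposes it as a collocation constraint.
#'
#' @param a Activation.
#' @param lm_tilde Normalized fiber length.
#' @param v_tilde Scaled normalized fiber velocity (control).
#' @param l_mt Muscle-tendon length (m).
#' @param params Single-row `muscle_params`.
#' @return List with `residual` (normalized force units), `f_tendon` (N),
#'   `f_ce` (contractile-element force, N), `f_passive` (N), `cos_alpha`,
#'   `lt_tilde`.
#' @export
hill_equilibrium_residual <- function(a, lm_tilde, v_tilde, l_mt, params) {
  g <- muscle_geometry(lm_tilde, l_mt, params)
  f_act <- active_force_length(lm_tilde)
  f_v <- force_velocity(v_tilde)
  f_pas <- passive_force_length(lm_tilde, params$passive_scale, params$passive_shift)
  f_t <- tendon_force_length(g$lt_tilde, params$k_t)
  fiber_norm <- a * f_act * f_v + f_pas + .FIBER_DAMPING * v_tilde
  res <- fiber_norm * g$cos_alpha - f_t
  list(residual = res,
       f_tendon = f_t * params$f_max,
       f_ce = a * f_act * f_v * params$f_max,
       f_passive = f_pas * params$f_max,
       cos_alpha = g$cos_alpha,
       lt_tilde = g$lt_tilde)
}

# Solve the Hill equilibrium for lm_tilde at fixed activation and velocity by
# root bracketing (used for quasi-static simulation, initial guesses and as
# an independent per-frame check). Vectorized over l_mt.
hill_equilibrium_solve <- function(a, l_mt, params, v_tilde = 0,
                                   interval = c(.LM_TILDE_MIN + 1e-3, .LM_TILDE_MAX)) {
  h <- params$l_m_opt * sin(params$alpha_opt)
  vapply(seq_along(l_mt), function(i) {
    f <- function(lm) hill_equilibrium_residual(a, lm, v_tilde, l_mt[i], params)$residual
    # pennation stays defined above sin(alpha_opt); tendon stays positive
    # below the length where the fiber projection consumes the whole l_mt
    lo <- max(interval[1], sin(params$alpha_opt) + 1e-3)
    hi <- min(interval[2], sqrt((l_mt[i] - 1e-6)^2 + h^2) / params$l_m_opt)
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12)$root
  }, numeric(1))
}

# Rigid-tendon fiber state: tendon fixed at slack length, fiber length and
# velocity follow from the muscle-tendon length and its time derivative.
rigid_tendon_state <- function(l_mt, dl_mt_dt, params) {
  h <- params$l_m_opt * sin(params$alpha_opt)
  along <- l_mt - params$l_t_slack
  if (any(along <= 0)) stop("rigid-tendon geometry: muscle-tendon length shorter than tendon slack length")
  lm <- sqrt(along^2 + h^2)
  lm_tilde <- lm / params$l_m_opt
  cos_alpha <- along / lm
  # dlm/dt = cos(alpha) * dl_mt/dt (fixed-height model)
  v_tilde <- cos_alpha * dl_mt_dt / (params$l_m_opt * .VEL_SCALE)
  list(lm_tilde = lm_tilde, v_tilde = v_tilde, cos_alpha = cos_alpha)
}
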