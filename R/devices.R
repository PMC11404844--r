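# Ideal assistive actuator models: a motor-based free unidirectional torque
# trajectory, and a spring-based torsional element that engages at time t_c
# and disengages at t_d with a smooth tanh window.

#' Device specifications
#'
#' `motor_spec` describes an ideal motor: a per-node torque trajectory, free
#' in shape, constrained to act only in the assisting direction (and
#' optionally magnitude-capped). `spring_spec` describes a unidirectional
#' torsional spring with three design variables (stiffness `k_r`, engagement
#' time `t_c`, disengagement time `t_d`) and tanh smoothing sharpness `b`.
#'
#' The internal sign convention is positive dorsiflexion, knee extension,
#' hip flexion and hip abduction; `assist_sign` is the sign of the assisting
#' moment in that convention (-1 for ankle plantarflexion, +1 for knee
#' extension, hip flexion and hip abduction).
#'
#' @param joint Joint label the device acts on.
#' @param assist_sign +1 or -1, direction of allowed torque.
#' @param torque_bound Magnitude cap (N m, `Inf` = unbounded).
#' @return A device spec object.
#' @export
motor_spec <- function(joint, assist_sign, torque_bound = Inf) {
  stopifnot(assist_sign %in% c(-1, 1), torque_bound > 0)
  structure(list(joint = joint, assist_sign = assist_sign,
                 torque_bound = torque_bound, mode = "motor"),
            class = c("motor_spec", "device_spec"))
}

#' @rdname motor_spec
#' @param k_r Spring stiffness (N m/rad, >= 0); `NA` when left to the
#'   optimizer.
#' @param t_c,t_d Engagement / disengagement times (s); `NA` when left to
#'   the optimizer.
#' @param b Smoothing sharpness (1/s) of the engagement window.
#' @param k_r_max Upper stiffness bound used by the optimizer.
#' @export
spring_spec <- function(joint, assist_sign, k_r = NA, t_c = NA, t_d = NA,
                        b = 1000, k_r_max = 1000) {
  stopifnot(assist_sign %in% c(-1, 1), b > 0)
  if (!is.na(k_r) && k_r < 0) stop("k_r must be >= 0")
  if (!is.na(t_c) && !is.na(t_d) && t_d <= t_c) stop("t_d must exceed t_c")
  structure(list(joint = joint, assist_sign = assist_sign, k_r = k_r,
                 t_c = t_c, t_d = t_d, b = b, k_r_max = k_r_max,
                 mode = "spring"),
            class = c("spring_spec", "device_spec"))
}

#' Spring engagement window
#'
#' Smooth on/off window built from hyperbolic tangents:
#' `P_e = 0.5 + 0.5 tanh(b (t - t_c))`, `P_d = 0.5 + 0.5 tanh(b (t_d - t))`,
#' `P_active = P_e * P_d`.
#'
#' @param t Time (s), vectorized.
#' @param t_c,t_d Engagement / disengagement times (s).
#' @param b Sharpness (1/s).
#' @return List with `P_e`, `P_d`, `P_active`.
#' @export
engagement_window <- function(t, t_c, t_d, b = 1000) {
  P_e <- 0.5 + 0.5 * tanh(b * (t - t_c))
  P_d <- 0.5 + 0.5 * tanh(b * (t_d - t))
  list(P_e = P_e, P_d = P_d, P_active = P_e * P_d)
}

#' Spring assistive moment
#'
#' Torque of the engaged torsional spring: proportional to the angular
#' displacement from the engagement angle, windowed by `P_active`, and
#' restoring toward the engagement angle (the spring loads while the joint
#' moves away from `q(t_c)` and releases on the way back):
#' `tau = k_r * P_active * (q(t_c) - q(t))`.
#'
#' @param t Time grid (s).
#' @param q Joint angle (rad) on the grid.
#' @param k_r Stiffness (N m/rad).
#' @param t_c,t_d Engagement window (s).
#' @param b Sharpness (1/s).
#' @param q_fun Optional function of time returning the angle (used to
#'   evaluate `q(t_c)` off-grid; defaults to a periodic spline through
#'   `(t, q)`).
#' @return Torque trajectory (N m) on the grid.
#' @export
spring_moment <- function(t, q, k_r, t_c, t_d, b = 1000, q_fun = NULL) {
  stopifnot(k_r >= 0)
  if (is.null(q_fun)) q_fun <- periodic_spline(t, q)
  w <- engagement_window(t, t_c, t_d, b)
  k_r * w$P_active * (q_fun(t_c) - q)
}

#' Spring engagement-closure constraint value
#'
#' Squared difference between the angles at engagement and disengagement,
#' `(q(t_c) - q(t_d))^2` (rad^2); feasible springs keep it below 0.01 so the
#' spring engages and disengages at matched joint angles.
#'
#' @inheritParams spring_moment
#' @return Scalar constraint value (rad^2).
#' @export
spring_closure_constraint <- function(t, q, t_c, t_d, q_fun = NULL) {
  if (is.null(q_fun)) q_fun <- periodic_spline(t, q)
  (q_fun(t_c) - q_fun(t_d))^2
}

#' Net spring work over the cycle
#'
#' Path integral of the spring torque over the joint angle,
#' `W = integral tau dq`; an ideal engage/disengage-matched spring is
#' conservative, so the net work is bounded by the tanh-smoothing leakage.
#'
#' @param tau_exo Spring torque (N m) on the grid.
#' @param t Time grid (s).
#' @param q Joint angle (rad) on the grid.
#' @return Net work (J).
#' @export
spring_net_work <- function(tau_exo, t, q) {
  dq_dt <- periodic_spline(t, q)(t, deriv = 1)
  p <- tau_exo * dq_dt
  n <- length(t)
  sum(diff(t) * (p[-n] + p[-1]) / 2)
}

# Peak elastic energy stored in the spring over the cycle (diagnostic used
# to normalize smoothing leakage).
spring_peak_energy <- function(tau_exo, k_r) {
  if (k_r <= 0) return(0)
  max(tau_exo^2) / (2 * k_r)
}

#' Motor sign/magnitude constraint violations
#'
#' Evaluates the motor feasibility conditions on a candidate torque
#' trajectory: the torque must act in the assisting direction at every node
#' (`assist_sign * tau >= 0`) and respect the magnitude bound.
#'
#' @param tau_exo Candidate torque trajectory (N m).
#' @param spec A [motor_spec()].
#' @return List with `sign_violation` and `bound_violation`, per-node
#'   non-negative violation magnitudes.
#' @export
motor_constraints <- function(tau_exo, spec) {
  stopifnot(inherits(spec, "motor_spec"))
  list(sign_violation = pmax(0, -spec$assist_sign * tau_exo),
       bound_violation = pmax(0, abs(tau_exo) - spec$torque_bound))
}
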