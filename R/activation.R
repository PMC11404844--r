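# First-order excitation-activation coupling with faster activation than
# deactivation, written in implicit (residual) form for use as a collocation
# constraint. The rate blends the activation and deactivation branches with a
# smooth tanh switch so the residual is differentiable everywhere.

#' Default activation dynamics constants
#'
#' Activation / deactivation time constants (s) and the lower activation
#' bound. The 15/60 ms pair is the common field standard; `a_min = 0.01`
#' keeps the contraction dynamics well-conditioned (0 is allowed but the
#' Hill equilibrium becomes poorly scaled as active force vanishes).
#'
#' @param tau_act Activation time constant (s).
#' @param tau_deact Deactivation time constant (s).
#' @param a_min Lower bound on activation and excitation.
#' @param blend Steepness of the smooth switch between the activation and
#'   deactivation branches (dimensionless on the excitation-activation gap).
#' @return A list of constants.
#' @export
activation_constants <- function(tau_act = 0.015, tau_deact = 0.060,
                                 a_min = 0.01, blend = 10) {
  stopifnot(tau_act > 0, tau_deact > 0, a_min >= 0, a_min < 1)
  if (a_min == 0)
    warning("a_min = 0: activation dynamics and Hill equilibrium become ill-conditioned near zero activation")
  list(tau_act = tau_act, tau_deact = tau_deact, a_min = a_min, blend = blend)
}

# Activation rate da/dt = g(e, a): tanh-blended Winters-type dynamics with
# activation time constant scaled by (0.5 + 1.5 a).
activation_rate <- function(e, a, const = activation_constants()) {
  f <- 0.5 * tanh(const$blend * (e - a))
  r_act <- 1 / (const$tau_act * (0.5 + 1.5 * a))
  r_deact <- (0.5 + 1.5 * a) / const$tau_deact
  (r_act * (f + 0.5) + r_deact * (0.5 - f)) * (e - a)
}

# Partial derivatives of activation_rate w.r.t. e and a (analytic).
activation_rate_partials <- function(e, a, const = activation_constants()) {
  d <- e - a
  th <- tanh(const$blend * d)
  f <- 0.5 * th
  sech2 <- 1 - th^2
  df_dd <- 0.5 * const$blend * sech2
  r_act <- 1 / (const$tau_act * (0.5 + 1.5 * a))
  r_deact <- (0.5 + 1.5 * a) / const$tau_deact
  mix <- r_act * (f + 0.5) + r_deact * (0.5 - f)
  dmix_dd <- (r_act - r_deact) * df_dd
  dr_act_da <- -1.5 / (const$tau_act * (0.5 + 1.5 * a)^2)
  dr_deact_da <- 1.5 / const$tau_deact
  dmix_da <- dr_act_da * (f + 0.5) + dr_deact_da * (0.5 - f) - dmix_dd
  list(de = dmix_dd * d + mix,
       da = dmix_da * d - mix)
}

#' Activation dynamics residual
#'
#' Implicit form of the excitation-to-activation dynamics: the residual
#' `da/dt - g(e, a)` is zero along dynamically consistent trajectories,
#' where `g` rises with time constant ~`tau_act` when excitation exceeds
#' activation and decays with ~`tau_deact` otherwise.
#'
#' @param e Excitation in `[a_min, 1]`.
#' @param a Activation in `[a_min, 1]`.
#' @param dadt Time derivative of activation (1/s).
#' @param const Constants from [activation_constants()].
#' @return Residual (1/s), zero on consistent trajectories.
#' @export
activation_dynamics_residual <- function(e, a, dadt,
                                         const = activation_constants()) {
  stopifnot(all(e >= const$a_min - 1e-9), all(e <= 1 + 1e-9),
            all(a >= const$a_min - 1e-9), all(a <= 1 + 1e-9))
  dadt - activation_rate(e, a, const)
}

# Inverse dynamics of activation: the excitation that produces a given
# (a, da/dt) pair. Dominant-branch initial guess refined by Newton iteration
# (the rate is strictly increasing in e). Used to recover consistent
# excitations for synthetic ground truths.
activation_inverse <- function(a, dadt, const = activation_constants()) {
  e_up <- a + dadt * const$tau_act * (0.5 + 1.5 * a)
  e_dn <- a + dadt * const$tau_deact / (0.5 + 1.5 * a)
  e <- ifelse(dadt >= 0, e_up, e_dn)
  for (k in 1:8) {
    r <- activation_rate(e, a, const) - dadt
    de <- activation_rate_partials(e, a, const)$de
    e <- e - r / pmax(de, 1e-8)
  }
  e
}
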