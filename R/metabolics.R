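# Per-muscle metabolic rates from the optimization outputs, using a
# Bhargava-family muscle energy model (Bhargava, Pandy & Anderson 2004,
# J Biomech 37:81-88): metabolic rate = contractile-element work rate +
# heat rate, where the heat rate sums activation, maintenance and
# shortening/lengthening components scaled by muscle mass and slow/fast
# fiber recruitment, with a non-negativity adjustment of the total rate.

# Bhargava-family heat coefficients (W/kg): slow/fast activation and
# maintenance heat rates.
.HEAT_COEF <- c(act_slow = 40, act_fast = 133, mnt_slow = 74, mnt_fast = 111)

#' Metabolic model parameters
#'
#' Per-muscle constants of the energy model. Muscle mass is derived from
#' the maximum isometric force via the specific tension `sigma`, density
#' `rho` and optimal fiber length: `mass = (f_max / sigma) * rho * l_m_opt`.
#'
#' @param params A `muscle_params` table (supplies `f_max`, `l_m_opt` and
#'   the `fast_twitch` fraction).
#' @param sigma Specific tension (Pa, default 0.25 MPa).
#' @param rho Muscle density (kg/m^3, default 1059.7).
#' @param basal Basal heat rate coefficient (W/kg body mass) added to the
#'   leg total when positive; 0 (default) restricts the model to
#'   muscle-action rates.
#' @return Data.frame with one row per muscle: `name`, `mass` (kg),
#'   `fast_twitch`, plus the configuration scalars as attributes.
#' @export
metabolic_params <- function(params, sigma = 0.25e6, rho = 1059.7, basal = 0) {
  validate_muscle_params(params)
  stopifnot(sigma > 0, rho > 0, basal >= 0)
  out <- data.frame(name = params$name,
                    mass = params$f_max / sigma * rho * params$l_m_opt,
                    fast_twitch = params$fast_twitch,
                    stringsAsFactors = FALSE)
  attr(out, "sigma") <- sigma
  attr(out, "rho") <- rho
  attr(out, "basal") <- basal
  out
}

#' Contractile-element work rate
#'
#' Mechanical power of the contractile element, the product of its force
#' and velocity with the shortening-positive convention: concentric
#' contraction gives positive work rate, eccentric negative.
#'
#' @param f_ce Contractile-element force (N, >= 0).
#' @param v_ce Fiber velocity (m/s), positive in shortening.
#' @return Work rate (W), same shape as inputs.
#' @export
contractile_work_rate <- function(f_ce, v_ce) {
  stopifnot(all(f_ce >= 0))
  f_ce * v_ce
}

# slow/fast recruitment curves of the size principle approximation
recruitment <- function(e) {
  list(slow = sin(pi / 2 * e), fast = 1 - cos(pi / 2 * e))
}

# fiber-length dependence of the maintenance heat (dimensionless); the
# active force-length multiplier is used as a smooth stand-in for the
# piecewise curve of the original formulation
maintenance_length_dependence <- function(lm_tilde) {
  active_force_length(pmin(pmax(lm_tilde, 0.21), 1.89))
}

#' Muscle heat rate
#'
#' Heat dissipation rate of one muscle: activation heat + maintenance heat
#' (scaled by a fiber-length dependence) + shortening/lengthening heat.
#' Activation and maintenance heats use the excitation-driven slow/fast
#' recruitment curves (`sin(pi/2 e)` and `1 - cos(pi/2 e)`); the
#' shortening heat coefficient is `0.16 F_iso + 0.18 F_CE` during
#' shortening and `0.157 F_CE` during lengthening (where it yields a
#' negative, heat-absorbing rate that the non-negativity adjustment later
#' compensates).
#'
#' @param a Activation.
#' @param e Excitation.
#' @param lm_tilde Normalized fiber length.
#' @param f_ce Contractile-element force (N).
#' @param f_iso Activation-scaled isometric force `a * f_act(lm) * f_max`
#'   (N).
#' @param v_ce Fiber velocity (m/s), shortening-positive.
#' @param mass Muscle mass (kg).
#' @param fast_twitch Fast-twitch fraction in `[0, 1]`.
#' @return Heat rate (W), same shape as inputs.
#' @export
heat_rate <- function(a, e, lm_tilde, f_ce, f_iso, v_ce, mass, fast_twitch) {
  r <- recruitment(pmin(pmax(e, 0), 1))
  f_slow <- 1 - fast_twitch
  h_act <- mass * (f_slow * .HEAT_COEF["act_slow"] * r$slow +
                     fast_twitch * .HEAT_COEF["act_fast"] * r$fast)
  h_mnt <- mass * maintenance_length_dependence(lm_tilde) *
    (f_slow * .HEAT_COEF["mnt_slow"] * r$slow +
       fast_twitch * .HEAT_COEF["mnt_fast"] * r$fast)
  alpha <- ifelse(v_ce >= 0, 0.16 * f_iso + 0.18 * f_ce, 0.157 * f_ce)
  h_sl <- alpha * v_ce
  unname(h_act + h_mnt + h_sl)
}

#' Non-negativity adjustment of the metabolic rate
#'
#' Where the raw rate `W_CE + H` is negative (possible during eccentric
#' contraction when negative muscle power exceeds the heat rate), the heat
#' rate is updated so the recomputed metabolic rate is non-negative: the
#' heat correction exactly cancels the deficit, clamping the rate at zero.
#' The literal printed substitution of the source formulation
#' (`H_mod = -W_CE - H`, which leaves `E = -H`) is available behind
#' `literal = TRUE` for auditability; it does not achieve non-negativity
#' and is not the default.
#'
#' @param w_ce Contractile work rate (W).
#' @param h Heat rate (W).
#' @param literal Use the literal printed substitution instead of the
#'   clamping interpretation.
#' @return List with `h_mod` (adjusted heat rate, W) and `e_dot`
#'   (metabolic rate, W).
#' @export
adjust_negative_rate <- function(w_ce, h, literal = FALSE) {
  raw <- w_ce + h
  if (literal) {
    h_mod <- ifelse(raw < 0, -w_ce - h, h)
    return(list(h_mod = h_mod, e_dot = w_ce + h_mod))
  }
  h_mod <- ifelse(raw < 0, -w_ce, h)
  list(h_mod = h_mod, e_dot = pmax(w_ce + h_mod, 0))
}

#' Compute the metabolic breakdown of a solved gait cycle
#'
#' Evaluates the energy model on every muscle of a redundancy solution:
#' contractile-element work rates, heat rates, the non-negativity
#' adjustment, per-muscle metabolic rates and the one-leg total (the sum
#' over muscles), with cycle averages in W and W/kg body mass.
#'
#' @param solution A `redundancy_solution`.
#' @param params The `muscle_params` used in the solve.
#' @param met_params Optional [metabolic_params()] (defaults derive from
#'   `params`).
#' @param literal_eq12 Use the literal printed negative-rate substitution
#'   (audit flag; see [adjust_negative_rate()]).
#' @return A `metabolic_breakdown`: time series matrices `w_ce`, `h`,
#'   `h_mod`, `e_dot` (node x muscle, W), `f_ce` (N), `v_ce` (m/s),
#'   `e_leg` (leg total, W), and summary fields `avg_e_leg_w`,
#'   `avg_e_leg_w_per_kg`, `avg_e_dot` (per muscle, W).
#' @export
compute_metabolics <- function(solution, params,
                               met_params = metabolic_params(params),
                               literal_eq12 = FALSE) {
  stopifnot(inherits(solution, "redundancy_solution"))
  if (!identical(params$name, solution$muscles))
    params <- params[match(solution$muscles, params$name), ]
  if (!identical(met_params$name, solution$muscles))
    met_params <- met_params[match(solution$muscles, met_params$name), ]
  a <- solution$activations; e <- solution$excitations
  lm <- solution$lm_tilde; vt <- solution$v_tilde
  nt <- nrow(a); nm <- ncol(a)
  rep_row <- function(v) matrix(rep(v, each = nt), nt, nm)
  f_max <- rep_row(params$f_max)
  l_opt <- rep_row(params$l_m_opt)
  mass <- rep_row(met_params$mass)
  ft_frac <- rep_row(met_params$fast_twitch)
  # shortening-positive fiber velocity (m/s); vt is the scaled lengthening-
  # positive normalized velocity
  v_ce <- -vt * .VEL_SCALE * l_opt
  f_act <- active_force_length(pmin(pmax(lm, 0.21), 1.89))
  f_v <- force_velocity(pmin(pmax(vt, -1), 1))
  f_ce <- a * f_act * f_v * f_max
  f_iso <- a * f_act * f_max
  w_ce <- contractile_work_rate(f_ce, v_ce)
  h <- heat_rate(a, e, lm, f_ce, f_iso, v_ce, mass, ft_frac)
  adj <- adjust_negative_rate(w_ce, h, literal = literal_eq12)
  e_dot <- adj$e_dot
  dimnames(e_dot) <- dimnames(w_ce) <- dimnames(adj$h_mod) <-
    dimnames(h) <- dimnames(f_ce) <- dimnames(v_ce) <- dimnames(a)
  e_leg <- rowSums(e_dot)
  basal <- attr(met_params, "basal")
  if (length(basal) && basal > 0) e_leg <- e_leg + basal * solution$body_mass
  t_span <- solution$t_cycle
  avg <- function(x) mean(x)   # uniform midpoint grid: mean = cycle average
  structure(list(
    time = solution$time, w_ce = w_ce, h = h, h_mod = adj$h_mod,
    e_dot = e_dot, f_ce = f_ce, v_ce = v_ce, e_leg = e_leg,
    avg_e_leg_w = avg(e_leg),
    avg_e_leg_w_per_kg = avg(e_leg) / solution$body_mass,
    avg_e_dot = colMeans(e_dot),
    body_mass = solution$body_mass, t_cycle = t_span,
    muscles = solution$muscles),
    class = "metabolic_breakdown")
}

#' One-leg total metabolic rate
#'
#' Pointwise sum of the per-muscle metabolic rates on a shared time grid,
#' with the cycle average in W and (optionally) W/kg body mass.
#'
#' @param e_dot Matrix (time x muscle) of metabolic rates (W).
#' @param time Time grid (s), length `nrow(e_dot)`.
#' @param body_mass Optional body mass (kg) for normalized reporting.
#' @return List with `e_leg` (W time series), `avg_w` and, when
#'   `body_mass` is given, `avg_w_per_kg`.
#' @export
leg_total <- function(e_dot, time, body_mass = NULL) {
  e_dot <- as.matrix(e_dot)
  if (nrow(e_dot) != length(time))
    stop("metabolic series and time grid have mismatched lengths")
  e_leg <- rowSums(e_dot)
  avg <- cycle_average(e_leg, time)
  out <- list(e_leg = e_leg, avg_w = avg)
  if (!is.null(body_mass)) out$avg_w_per_kg <- avg / body_mass
  out
}

#' @export
print.metabolic_breakdown <- function(x, ...) {
  cat(sprintf("<metabolic_breakdown> %d muscles: leg average %.2f W (%.3f W/kg)\n",
              length(x$muscles), x$avg_e_leg_w, x$avg_e_leg_w_per_kg))
  invisible(x)
}

#' Write a metabolic breakdown as a motion-storage table
#'
#' Per-muscle metabolic rate time series plus the leg total, with a
#' key-value summary record of the cycle averages.
#'
#' @param met A `metabolic_breakdown`.
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return The stem path, invisibly.
#' @export
write_metabolics <- function(met, dir, stem) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- data.frame(time = met$time, met$e_dot, e_leg = met$e_leg,
                   check.names = FALSE)
  write_motion_table(df, file.path(dir, paste0(stem, "_metabolics.sto")),
                     name = paste0(stem, " metabolic rates"))
  write_summary_record(list(avg_e_leg_w = met$avg_e_leg_w,
                            avg_e_leg_w_per_kg = met$avg_e_leg_w_per_kg),
                       file.path(dir, paste0(stem, "_metabolics_summary.txt")))
  invisible(file.path(dir, stem))
}
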