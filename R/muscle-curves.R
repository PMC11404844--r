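# Dimensionless muscle-tendon characteristic curves.
#
# Parameterizations follow the direct-collocation muscle redundancy framework of
# De Groote et al. (2016), Ann Biomed Eng 44:2922-2936: a three-Gaussian active
# force-length curve, a logistic (inverse-sinh) force-velocity curve, an
# exponential passive force-length curve and an exponential tendon
# force-length curve. All evaluate vectorized and are smooth (C^inf) on their
# validity ranges; the redundancy solver relies on their analytic derivatives.

# Active force-length Gaussian coefficients (De Groote et al. 2016, Table 1).
.FL_B <- list(
  b1 = c(0.814483478343008, 0.433004984392647, 0.1),
  b2 = c(1.055033428970575, 0.716775413397760, 1.0),
  b3 = c(0.162384573599574, -0.029947116970696, 0.5 * sqrt(0.5)),
  b4 = c(0.063303448465465, 0.200356847296188, 0.0)
)

# Force-velocity coefficients (De Groote et al. 2016).
.FV_D <- c(d1 = -0.318323436899127, d2 = -8.149156043475250,
           d3 = -0.374121508647863, d4 = 0.885644059915004)

# Passive force-length shape: exponential with strain parameterization
# (kpe = 4, e0 = 0.6), rebased to be exactly zero at the lower validity bound
# of the normalized fiber length so that the curve is negligible below the
# engagement region and strictly increasing everywhere.
.PAS_KPE <- 4.0
.PAS_E0 <- 0.6
.LM_TILDE_MIN <- 0.2
.LM_TILDE_MAX <- 1.9

# Tendon force-length: f_t = c1 * exp(k_t * (lt - c2)) - c3 with c1, c2 from
# De Groote et al. (2016) and c3 chosen so that the force is exactly zero at
# the slack length for any stiffness k_t.
.TEN_C1 <- 0.2
.TEN_C2 <- 0.995
.KT_DEFAULT <- 35

#' Active force-length multiplier
#'
#' Dimensionless active force capacity of the contractile element as a
#' function of normalized fiber length, modeled as a sum of three Gaussians
#' peaking near the optimal fiber length.
#'
#' @param lm_tilde Normalized fiber length (fiber length / optimal fiber
#'   length). Must be positive and finite.
#' @return Force multiplier in `[0, ~1]`, same shape as `lm_tilde`.
#' @export
#' @examples
#' active_force_length(1)    # ~1 at optimal length
#' active_force_length(0.6)  # ascending limb
active_force_length <- function(lm_tilde) {
  stopifnot(is.numeric(lm_tilde), all(is.finite(lm_tilde)), all(lm_tilde > 0))
  f <- 0
  for (k in 1:3) {
    den <- .FL_B$b3[k] + .FL_B$b4[k] * lm_tilde
    f <- f + .FL_B$b1[k] * exp(-0.5 * ((lm_tilde - .FL_B$b2[k]) / den)^2)
  }
  f
}

# d f_act / d lm_tilde (analytic; used by the solver)
active_force_length_deriv <- function(lm_tilde) {
  df <- 0
  for (k in 1:3) {
    den <- .FL_B$b3[k] + .FL_B$b4[k] * lm_tilde
    z <- (lm_tilde - .FL_B$b2[k]) / den
    dz <- (den - (lm_tilde - .FL_B$b2[k]) * .FL_B$b4[k]) / den^2
    df <- df + .FL_B$b1[k] * exp(-0.5 * z^2) * (-z * dz)
  }
  df
}

#' Force-velocity multiplier
#'
#' Dimensionless force-velocity relation evaluated at the scaled normalized
#' fiber velocity (`-1` = maximal shortening, `0` = isometric, positive =
#' lengthening). Monotone increasing, ~1 at zero velocity and bounded by the
#' eccentric plateau.
#'
#' @param v_tilde Scaled normalized fiber velocity (dimensionless).
#' @return Force multiplier, same shape as `v_tilde`.
#' @export
force_velocity <- function(v_tilde) {
  stopifnot(is.numeric(v_tilde), all(is.finite(v_tilde)))
  z <- .FV_D["d2"] * v_tilde + .FV_D["d3"]
  unname(.FV_D["d1"] * log(z + sqrt(z^2 + 1)) + .FV_D["d4"])
}

force_velocity_deriv <- function(v_tilde) {
  z <- .FV_D["d2"] * v_tilde + .FV_D["d3"]
  unname(.FV_D["d1"] * .FV_D["d2"] / sqrt(z^2 + 1))
}

# Exact inverse of force_velocity (force multiplier -> scaled velocity).
force_velocity_inverse <- function(fv) {
  y <- (fv - .FV_D["d4"]) / .FV_D["d1"]
  unname((sinh(y) - .FV_D["d3"]) / .FV_D["d2"])
}

#' Passive force-length multiplier
#'
#' Passive (parallel elastic) force of the fiber as a function of normalized
#' fiber length: an exponential engaging above the slack region, scaled by
#' `passive_scale` and shifted along the length axis by `passive_shift` (the
#' two knobs adjusted when tuning to joint passive moment-angle curves).
#'
#' @param lm_tilde Normalized fiber length.
#' @param passive_scale Non-negative multiplier on the curve (default 1).
#' @param passive_shift Offset of the curve along the normalized-length axis
#'   (default 0; positive shifts engagement to longer lengths).
#' @return Force multiplier, same shape as `lm_tilde`.
#' @export
passive_force_length <- function(lm_tilde, passive_scale = 1, passive_shift = 0) {
  stopifnot(is.numeric(lm_tilde), all(is.finite(lm_tilde)), all(lm_tilde > 0),
            all(passive_scale >= 0))
  l <- lm_tilde - passive_shift
  raw <- expm1(.PAS_KPE * (l - 1) / .PAS_E0) / expm1(.PAS_KPE)
  base <- expm1(.PAS_KPE * (.LM_TILDE_MIN - 1) / .PAS_E0) / expm1(.PAS_KPE)
  passive_scale * (raw - base)
}

passive_force_length_deriv <- function(lm_tilde, passive_scale = 1, passive_shift = 0) {
  l <- lm_tilde - passive_shift
  passive_scale * (.PAS_KPE / .PAS_E0) *
    exp(.PAS_KPE * (l - 1) / .PAS_E0) / expm1(.PAS_KPE)
}

#' Tendon force-length multiplier
#'
#' Non-linear elastic tendon force (normalized by maximum isometric force) as
#' a function of tendon length normalized by slack length. The dimensionless
#' stiffness `k_t` sets the exponential slope; force is exactly zero at the
#' slack length.
#'
#' @param lt_tilde Tendon length / tendon slack length.
#' @param k_t Dimensionless tendon stiffness shape parameter (default 35).
#' @return Force multiplier, same shape as `lt_tilde`.
#' @export
tendon_force_length <- function(lt_tilde, k_t = .KT_DEFAULT) {
  stopifnot(is.numeric(lt_tilde), all(is.finite(lt_tilde)), all(lt_tilde > 0))
  .TEN_C1 * (exp(k_t * (lt_tilde - .TEN_C2)) - exp(k_t * (1 - .TEN_C2)))
}

tendon_force_length_deriv <- function(lt_tilde, k_t = .KT_DEFAULT) {
  .TEN_C1 * k_t * exp(k_t * (lt_tilde - .TEN_C2))
}

# Inverse of the tendon curve (normalized force -> normalized length).
tendon_force_length_inverse <- function(f_t, k_t = .KT_DEFAULT) {
  log(f_t / .TEN_C1 + exp(k_t * (1 - .TEN_C2))) / k_t + .TEN_C2
}
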