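# Per-frame static optimization with rigid tendons: at each mesh node,
# minimize sum(a^2) + w_r * sum(eR^2) subject to the moment balance, with the
# reserve eliminated through the balance equation. Muscle force is affine in
# activation at fixed kinematics, so each frame is a box-constrained
# quadratic program solved by an active-set sweep. Used to build synthetic
# ground truths, to initialize the collocation solver, and as a fast
# surrogate when screening spring parameters.

# Affine force decomposition at one frame set: F = f_max*(gain*a + offset)*cos_alpha
# computed for all (node, muscle) at once from rigid-tendon states.
rigid_force_terms <- function(disc, params) {
  nt <- length(disc$time); nm <- nrow(params)
  gain <- offset <- cosA <- lm_t <- v_t <- matrix(0, nt, nm)
  for (m in seq_len(nm)) {
    p <- params[m, ]
    st <- rigid_tendon_state(disc$l_mt[, m], disc$dl_mt[, m], p)
    fl <- active_force_length(pmin(pmax(st$lm_tilde, 0.21), 1.89))
    fv <- force_velocity(pmin(pmax(st$v_tilde, -1), 1))
    fp <- passive_force_length(pmin(pmax(st$lm_tilde, 0.21), 1.89),
                               p$passive_scale, p$passive_shift)
    gain[, m] <- p$f_max * fl * fv * st$cos_alpha
    offset[, m] <- p$f_max * (fp + .FIBER_DAMPING * pmin(pmax(st$v_tilde, -1), 1)) *
      st$cos_alpha
    cosA[, m] <- st$cos_alpha
    lm_t[, m] <- st$lm_tilde
    v_t[, m] <- st$v_tilde
  }
  list(gain = gain, offset = offset, cos_alpha = cosA,
       lm_tilde = lm_t, v_tilde = v_t)
}

#' Per-frame static optimization (rigid tendon)
#'
#' Distributes the net joint moments across muscles frame by frame under the
#' minimal summed-squared-activation criterion with penalized reserves,
#' assuming rigid tendons (fiber state follows directly from the
#' muscle-tendon length). Fast, decoupled in time; no activation dynamics.
#'
#' @param disc Discretized trial from [discretize()].
#' @param params `muscle_params` table (rows match `disc` muscle columns).
#' @param weights [solver_weights()].
#' @param tau_exo Optional matrix (node x joint) of assistive moments.
#' @param a_min Lower activation bound.
#' @return List with `activations` (node x muscle), `reserves` (node x
#'   joint), `objective` (quadrature value of the activation + reserve
#'   terms), `tau_mus` (node x joint).
#' @export
static_optimize <- function(disc, params, weights = solver_weights(),
                            tau_exo = NULL, a_min = 0.01, ft = NULL) {
  nt <- length(disc$time); nm <- nrow(params); nj <- ncol(disc$tau_id)
  if (is.null(tau_exo)) tau_exo <- matrix(0, nt, nj)
  if (is.null(ft)) ft <- rigid_force_terms(disc, params)
  wrT <- weights$w_r / weights$T_R^2
  a <- matrix(a_min, nt, nm, dimnames = list(NULL, params$name))
  eR <- matrix(0, nt, nj, dimnames = list(NULL, colnames(disc$tau_id)))
  for (i in seq_len(nt)) {
    R <- matrix(disc$moment_arms[i, , ], nm, nj)       # muscle x joint
    G <- t(R) %*% diag(ft$gain[i, ], nm)               # joint x muscle
    tau_res <- disc$tau_id[i, ] - tau_exo[i, ] - as.vector(t(R) %*% ft$offset[i, ])
    free <- rep(TRUE, nm); a_i <- rep(a_min, nm)
    for (sweep in 1:(nm + 1)) {
      idx <- which(free)
      rhs_tau <- tau_res - as.vector(G[, !free, drop = FALSE] %*% a_i[!free])
      if (length(idx)) {
        Gf <- G[, idx, drop = FALSE]
        A <- diag(length(idx)) + wrT * (t(Gf) %*% Gf)
        b <- wrT * as.vector(t(Gf) %*% rhs_tau)
        sol <- solve(A, b)
        a_i[idx] <- sol
      }
      viol_lo <- free & (a_i < a_min); viol_hi <- free & (a_i > 1)
      if (!any(viol_lo | viol_hi)) break
      a_i[viol_lo] <- a_min; a_i[viol_hi] <- 1
      free <- free & !(viol_lo | viol_hi)
    }
    a[i, ] <- a_i
    eR[i, ] <- (tau_res - as.vector(G %*% a_i)) / weights$T_R
  }
  tau_mus <- sapply(seq_len(nj), function(j) {
    rowSums(disc$moment_arms[, , j] * (ft$gain * a + ft$offset))
  })
  colnames(tau_mus) <- colnames(disc$tau_id)
  obj <- sum(disc$w * (weights$w_a * rowSums(a^2) + weights$w_r * rowSums(eR^2)))
  list(activations = a, reserves = eR, objective = obj, tau_mus = tau_mus,
       fiber = ft)
}
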