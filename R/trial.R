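# Gait-trial container: one gait cycle of prescribed kinematics and dynamics
# plus muscle-tendon geometry, everything on a shared time grid.

#' Construct a gait trial
#'
#' Bundles the per-gait-cycle inputs of the redundancy solver: joint angles,
#' net joint moments from inverse dynamics, muscle-tendon lengths and moment
#' arms, all sampled on one common time grid.
#'
#' @param time Strictly increasing time grid (s) covering one gait cycle
#'   `[t_i, t_f]`.
#' @param q Matrix (time x joints) of joint angles (rad); column names are
#'   joint labels.
#' @param tau_id Matrix (time x joints) of net joint moments (N m).
#' @param l_mt Matrix (time x muscles) of muscle-tendon lengths (m); column
#'   names are muscle labels.
#' @param moment_arms Array (time x muscles x joints) of moment arms (m),
#'   zero for muscles not spanning a joint; `dimnames` give muscle and joint
#'   labels.
#' @param body_mass Body mass (kg), used for normalized reporting.
#' @param speed_label One of `"slow"`, `"normal"`, `"fast"`.
#' @param cycle_events Optional percent-of-cycle of the stance-to-swing
#'   transition.
#' @return A `gait_trial` object.
#' @export
gait_trial <- function(time, q, tau_id, l_mt, moment_arms, body_mass = 69,
                       speed_label = "normal", cycle_events = c(toe_off = 60)) {
  q <- as.matrix(q); tau_id <- as.matrix(tau_id); l_mt <- as.matrix(l_mt)
  nt <- length(time)
  if (nt < 2 || any(diff(time) <= 0)) stop("time grid must be strictly increasing")
  stopifnot(nrow(q) == nt, nrow(tau_id) == nt, nrow(l_mt) == nt,
            dim(moment_arms)[1] == nt,
            dim(moment_arms)[2] == ncol(l_mt),
            dim(moment_arms)[3] == ncol(q),
            ncol(tau_id) == ncol(q))
  if (is.null(colnames(q))) stop("q needs joint labels as column names")
  if (is.null(colnames(l_mt))) stop("l_mt needs muscle labels as column names")
  colnames(tau_id) <- colnames(q)
  dimnames(moment_arms) <- list(NULL, colnames(l_mt), colnames(q))
  structure(list(time = time, q = q, tau_id = tau_id, l_mt = l_mt,
                 moment_arms = moment_arms, body_mass = body_mass,
                 speed_label = speed_label, cycle_events = cycle_events),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s speed: %d samples over %.3f s, joints [%s], %d muscles\n",
              x$speed_label, length(x$time), diff(range(x$time)),
              paste(colnames(x$q), collapse = ", "), ncol(x$l_mt)))
  invisible(x)
}

joints_of <- function(trial) colnames(trial$q)
muscles_of <- function(trial) colnames(trial$l_mt)

# Periodic interpolator for a trial signal sampled on [t_i, t_f] with equal
# endpoint values; falls back to natural splines if not periodic.
periodic_spline <- function(time, y) {
  if (abs(y[1] - y[length(y)]) < 1e-9) {
    y[length(y)] <- y[1]
    stats::splinefun(time, y, method = "periodic")
  } else {
    stats::splinefun(time, y, method = "natural")
  }
}
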