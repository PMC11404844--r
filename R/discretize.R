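# Collocation mesh for the trajectory optimization.

#' Discretize a gait trial onto a collocation mesh
#'
#' Resamples every trial quantity onto a uniform mesh of `mesh` intervals
#' over the cycle by spline interpolation (periodic where the signal closes
#' on itself), returning node times and trapezoidal quadrature weights. The
#' interpolant passes through the input samples, so a mesh whose nodes
#' coincide with the input grid reproduces the inputs exactly.
#'
#' @param trial A [gait_trial()].
#' @param mesh Number of mesh intervals (>= 10).
#' @return List with `time` (mesh + 1 node times), `h` (step), `w`
#'   (quadrature weights), and resampled `q`, `dq` (angular velocity),
#'   `tau_id`, `l_mt`, `dl_mt` (lengthening velocity), `moment_arms`.
#' @export
discretize <- function(trial, mesh = 100) {
  stopifnot(inherits(trial, "gait_trial"))
  if (mesh < 10) stop("mesh must be at least 10 intervals")
  if (any(diff(trial$time) <= 0)) stop("non-monotone time grid")
  t0 <- trial$time[1]; t1 <- trial$time[length(trial$time)]
  tt <- seq(t0, t1, length.out = mesh + 1)
  h <- (t1 - t0) / mesh
  w <- c(h / 2, rep(h, mesh - 1), h / 2)

  resample <- function(mat, deriv = 0) {
    out <- sapply(seq_len(ncol(mat)), function(j) {
      periodic_spline(trial$time, mat[, j])(tt, deriv = deriv)
    })
    colnames(out) <- colnames(mat)
    out
  }
  nj <- ncol(trial$q); nm <- ncol(trial$l_mt)
  arms <- array(0, c(length(tt), nm, nj),
                dimnames = list(NULL, muscles_of(trial), joints_of(trial)))
  for (j in seq_len(nj)) for (m in seq_len(nm)) {
    ya <- trial$moment_arms[, m, j]
    arms[, m, j] <- if (all(ya == ya[1])) ya[1] else periodic_spline(trial$time, ya)(tt)
  }
  out <- list(time = tt, h = h, w = w,
              q = resample(trial$q), dq = resample(trial$q, deriv = 1),
              tau_id = resample(trial$tau_id),
              l_mt = resample(trial$l_mt), dl_mt = resample(trial$l_mt, deriv = 1),
              moment_arms = arms)
  # exact-alignment fast path: when the trial grid is twice as fine as the
  # mesh, its odd samples fall on the interval midpoints; the solver can
  # then read collocation data without interpolation error
  if (length(trial$time) == 2 * mesh + 1 &&
      max(abs(trial$time - seq(t0, t1, length.out = 2 * mesh + 1))) < 1e-9) {
    mid_idx <- seq(2, 2 * mesh, by = 2)
    out$exact_mid <- list(q = trial$q[mid_idx, , drop = FALSE],
                          tau_id = trial$tau_id[mid_idx, , drop = FALSE],
                          l_mt = trial$l_mt[mid_idx, , drop = FALSE])
  }
  out
}
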