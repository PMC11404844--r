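# Writers/readers for solver outputs: per-muscle state/control trajectories
# and per-joint moments as a motion-storage table, plus a key-value summary
# record with the objective terms, solver status and violations.

#' Write / read a redundancy solution
#'
#' `<stem>_solution.sto` holds the time series (per-muscle activation `a_`,
#' excitation `e_`, normalized fiber length `lm_`, scaled fiber velocity
#' `vt_`, tendon force `ft_`; per-joint `tau_mus_`, `reserve_`, `tau_exo_`);
#' `<stem>_solution_summary.txt` the objective terms, status and
#' violations. Reading reconstructs a `redundancy_solution` sufficient for
#' the metabolics and comparison layers.
#'
#' @param sol A `redundancy_solution`.
#' @param dir Output directory.
#' @param stem File-name stem.
#' @return The stem path, invisibly.
#' @export
write_solution <- function(sol, dir, stem) {
  stopifnot(inherits(sol, "redundancy_solution"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pref <- function(M, p) {
    colnames(M) <- paste0(p, colnames(M)); as.data.frame(M)
  }
  df <- cbind(data.frame(time = sol$time),
              pref(sol$activations, "a_"), pref(sol$excitations, "e_"),
              pref(sol$lm_tilde, "lm_"), pref(sol$v_tilde, "vt_"),
              pref(sol$tendon_forces, "ft_"),
              pref(sol$tau_mus, "tau_mus_"), pref(sol$reserves, "reserve_"),
              pref(sol$tau_exo, "tau_exo_"))
  write_motion_table(df, file.path(dir, paste0(stem, "_solution.sto")),
                     name = paste0(stem, " redundancy solution"))
  write_summary_record(list(
    objective = sol$objective,
    objective_activation = unname(sol$objective_terms["activation"]),
    objective_reserve = unname(sol$objective_terms["reserve"]),
    objective_velocity = unname(sol$objective_terms["velocity"]),
    status = sol$status,
    constraint_violation = sol$constraint_violation,
    moment_balance_violation = sol$moment_balance_violation,
    mesh = sol$mesh, t_cycle = sol$t_cycle,
    body_mass = sol$body_mass, speed_label = sol$speed_label),
    file.path(dir, paste0(stem, "_solution_summary.txt")))
  invisible(file.path(dir, stem))
}

#' @rdname write_solution
#' @export
read_solution <- function(dir, stem) {
  df <- read_motion_table(file.path(dir, paste0(stem, "_solution.sto")))$data
  meta <- read_summary_record(file.path(dir, paste0(stem, "_solution_summary.txt")))
  grab <- function(p) {
    cols <- grep(paste0("^", p), names(df), value = TRUE)
    M <- as.matrix(df[cols])
    colnames(M) <- sub(paste0("^", p), "", cols)
    M
  }
  a <- grab("a_")
  structure(list(
    time = df$time, t_cycle = meta$t_cycle,
    activations = a, excitations = grab("e_"), lm_tilde = grab("lm_"),
    v_tilde = grab("vt_"), tendon_forces = grab("ft_"),
    tau_mus = grab("tau_mus_"), reserves = grab("reserve_"),
    tau_exo = grab("tau_exo_"),
    objective = meta$objective,
    objective_terms = c(activation = meta$objective_activation,
                        reserve = meta$objective_reserve,
                        velocity = meta$objective_velocity),
    status = meta$status,
    constraint_violation = meta$constraint_violation,
    moment_balance_violation = meta$moment_balance_violation,
    mesh = meta$mesh, weights = solver_weights(),
    speed_label = meta$speed_label, body_mass = meta$body_mass,
    muscles = colnames(a), joints = colnames(grab("tau_mus_"))),
    class = "redundancy_solution")
}
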