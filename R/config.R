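# Run configuration: flat structured text (key: value with nested
# sections, YAML dialect). Defaults reproduce the study settings
# (w_a = 1, w_r = 1000, w_v = 0.001, T_R = 100 N m, b = 1000).

#' Default run configuration
#'
#' @return Nested list with `paths`, `solver`, `device`, `metabolics`,
#'   `output` and `seed` sections.
#' @export
default_config <- function() {
  list(
    paths = list(trial_dir = ".", trial_stem = NULL,
                 muscle_table = NULL, group_map = NULL),
    solver = list(mesh = 100, w_a = 1, w_r = 1000, w_v = 0.001, T_R = 100,
                  tol_con = 1e-7, a_min = 0.01),
    device = list(mode = "none", joint = NULL, b = 1000),
    metabolics = list(basal = 0, sigma = 0.25e6, rho = 1059.7),
    output = list(dir = "results"),
    seed = 0
  )
}

#' Read / write a run configuration
#'
#' @param path Config file path.
#' @return `read_config`: the config list, with defaults filled in for
#'   missing keys and angle columns flagged `in_degrees` converted later
#'   at load time.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  merge_cfg(default_config(), cfg)
}

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_cfg <- function(base, over) {
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
      merge_cfg(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

config_weights <- function(cfg) {
  solver_weights(w_a = cfg$solver$w_a, w_r = cfg$solver$w_r,
                 w_v = cfg$solver$w_v, T_R = cfg$solver$T_R)
}

config_options <- function(cfg) {
  solver_options(mesh = cfg$solver$mesh, tol_con = cfg$solver$tol_con,
                 a_min = cfg$solver$a_min)
}
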