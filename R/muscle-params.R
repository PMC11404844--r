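# Muscle-tendon parameter tables.

#' Construct a muscle-tendon parameter table
#'
#' Per-muscle constants of the Hill-type muscle-tendon units. Stored as a
#' `data.frame` of class `muscle_params`, one row per muscle.
#'
#' @param name Muscle labels (unique).
#' @param f_max Maximum isometric force (N), positive.
#' @param l_m_opt Optimal fiber length (m), positive.
#' @param l_t_slack Tendon slack length (m), positive.
#' @param k_t Dimensionless tendon stiffness shape parameter (default 35).
#' @param alpha_opt Pennation angle at optimal fiber length (rad), in
#'   `[0, pi/2)`.
#' @param v_max Maximum contraction velocity (optimal fiber lengths per
#'   second; default 10, matching the velocity scale of the framework).
#' @param passive_scale Multiplier on the passive force-length curve (>= 0).
#' @param passive_shift Normalized-length offset of the passive curve.
#' @param fast_twitch Fast-twitch fiber fraction in `[0, 1]` (used by the
#'   metabolic model).
#' @return A `muscle_params` data.frame.
#' @export
muscle_params <- function(name, f_max, l_m_opt, l_t_slack,
                          k_t = 35, alpha_opt = 0, v_max = 10,
                          passive_scale = 1, passive_shift = 0,
                          fast_twitch = 0.5) {
  p <- data.frame(name = as.character(name), f_max = f_max, l_m_opt = l_m_opt,
                  l_t_slack = l_t_slack, k_t = k_t, alpha_opt = alpha_opt,
                  v_max = v_max, passive_scale = passive_scale,
                  passive_shift = passive_shift, fast_twitch = fast_twitch,
                  stringsAsFactors = FALSE)
  validate_muscle_params(p)
  class(p) <- c("muscle_params", "data.frame")
  p
}

validate_muscle_params <- function(p) {
  req <- c("name", "f_max", "l_m_opt", "l_t_slack", "k_t", "alpha_opt",
           "v_max", "passive_scale", "passive_shift", "fast_twitch")
  missing <- setdiff(req, names(p))
  if (length(missing))
    stop("muscle_params missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(p$name)) stop("duplicate muscle names")
  with(p, {
    stopifnot(all(f_max > 0), all(l_m_opt > 0), all(l_t_slack > 0),
              all(v_max > 0), all(alpha_opt >= 0), all(alpha_opt < pi / 2),
              all(passive_scale >= 0), all(k_t > 0),
              all(fast_twitch >= 0), all(fast_twitch <= 1))
  })
  invisible(p)
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf("<muscle_params> %d muscles\n", nrow(x)))
  NextMethod()
}

#' Default lower-limb muscle set
#'
#' A reduced nine-muscle lower-limb set spanning ankle (sagittal), knee
#' (sagittal), hip (sagittal) and hip (frontal) degrees of freedom, each with
#' at least one agonist and one antagonist. The plantarflexor/dorsiflexor
#' maximum isometric forces follow the adjusted values used with the
#' Rajagopal-model workflow (soleus 3586 N, gastrocnemius lateralis 606 N,
#' gastrocnemius medialis 1308 N, tibialis anterior 674 N), which yield
#' excitation magnitudes closer to normalized EMG than the generic model's
#' defaults. Other parameters are representative adult lower-limb values for
#' lumped muscle groups.
#'
#' @return A `muscle_params` data.frame with 9 rows.
#' @export
default_muscle_set <- function() {
  muscle_params(
    name = c("soleus", "gas_med", "gas_lat", "tib_ant", "vasti",
             "hamstrings", "iliopsoas", "glut_med", "adductors"),
    f_max = c(3586, 1308, 606, 674, 5000, 3000, 2000, 2500, 2000),
    l_m_opt = c(0.044, 0.051, 0.059, 0.068, 0.090, 0.100, 0.110, 0.073, 0.100),
    l_t_slack = c(0.277, 0.384, 0.380, 0.241, 0.160, 0.300, 0.100, 0.060, 0.080),
    k_t = 35,
    alpha_opt = c(0.49, 0.17, 0.21, 0.17, 0.08, 0.20, 0.14, 0.35, 0.30),
    v_max = 10,
    passive_scale = 1,
    passive_shift = 0,
    fast_twitch = c(0.20, 0.45, 0.50, 0.30, 0.50, 0.45, 0.50, 0.45, 0.45)
  )
}

#' Read / write a muscle parameter table
#'
#' Tab- or comma-delimited file with one row per muscle and columns exactly
#' the `muscle_params` fields. Lines starting with `#` are treated as
#' comments (the writer emits a provenance header line this way).
#'
#' @param path File path.
#' @return `read_muscle_params`: a `muscle_params` data.frame.
#' @export
read_muscle_params <- function(path) {
  first <- readLines(path, n = 20)
  first <- first[!startsWith(first, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  p <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE)
  validate_muscle_params(p)
  class(p) <- c("muscle_params", "data.frame")
  p
}

#' @rdname read_muscle_params
#' @param params A `muscle_params` table.
#' @param comment Optional provenance line written as a `#` comment.
#' @export
write_muscle_params <- function(params, path, comment = NULL) {
  validate_muscle_params(params)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  utils::write.table(params, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
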