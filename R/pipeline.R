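# Pipeline conveniences tying the modules together: assisted-joint codes,
# one-condition runs, and the full synthetic experiment (speeds x devices x
# joints) with comparison tables.

# assisted-joint codes -> (joint, sign, assisted group)
.ASSIST_TABLE <- data.frame(
  code = c("ankle_pf", "knee_ext", "hip_flex", "hip_abd"),
  joint = c("ankle", "knee", "hip_sagittal", "hip_frontal"),
  sign = c(-1, 1, 1, 1),
  group = c("plantarflexion", "knee_extension", "hip_flexion", "hip_abduction"),
  stringsAsFactors = FALSE
)

#' Assisted-joint codes
#'
#' The four assisted muscle groups and their joint/sign/group mapping in
#' the internal convention (positive dorsiflexion, knee extension, hip
#' flexion, hip abduction; ankle plantarflexion assistance therefore acts
#' with negative sign).
#'
#' @return Data.frame with columns `code`, `joint`, `sign`, `group`.
#' @export
assist_codes <- function() .ASSIST_TABLE

#' Build a device specification from an assisted-joint code
#'
#' @param code One of `"ankle_pf"`, `"knee_ext"`, `"hip_flex"`, `"hip_abd"`.
#' @param mode `"motor"` or `"spring"`.
#' @param b Spring smoothing sharpness (1/s).
#' @return A [motor_spec()] or [spring_spec()].
#' @export
device_for <- function(code, mode = c("motor", "spring"), b = 1000) {
  mode <- match.arg(mode)
  row <- .ASSIST_TABLE[.ASSIST_TABLE$code == code, ]
  if (!nrow(row)) stop("unknown assisted-joint code: ", code,
                       " (use one of ", paste(.ASSIST_TABLE$code, collapse = ", "), ")")
  if (mode == "motor") motor_spec(row$joint, row$sign)
  else spring_spec(row$joint, row$sign, b = b)
}

#' Run one condition of the experiment
#'
#' Solves the redundancy problem for a trial in one condition (no device,
#' motor, or spring at one assisted joint) and computes the metabolic
#' breakdown.
#'
#' @param trial A [gait_trial()].
#' @param params `muscle_params`.
#' @param mode `"none"`, `"motor"` or `"spring"`.
#' @param code Assisted-joint code (required unless `mode = "none"`).
#' @param weights [solver_weights()].
#' @param options [solver_options()].
#' @param unassisted Optional precomputed unassisted solution on the same
#'   mesh (spring solves use it for the zero-stiffness fallback).
#' @return List with `solution`, `device_solution` (NULL for `"none"`),
#'   `metabolics`, `mode`, `code`, `group`.
#' @export
run_condition <- function(trial, params, mode = "none", code = NULL,
                          weights = solver_weights(),
                          options = solver_options(), unassisted = NULL) {
  if (mode == "none") {
    sol <- solve_unassisted(trial, params, weights, options)
    dev <- NULL; group <- NA_character_
  } else {
    device <- device_for(code, mode)
    res <- solve_assisted(trial, params, weights, device, options,
                          unassisted = unassisted)
    sol <- res$solution; dev <- res$device_solution
    group <- .ASSIST_TABLE$group[.ASSIST_TABLE$code == code]
  }
  list(solution = sol, device_solution = dev,
       metabolics = compute_metabolics(sol, params),
       mode = mode, code = code, group = group)
}

#' Run the full synthetic assistance experiment
#'
#' For each speed: generates the synthetic trial, solves the unassisted
#' problem, then each requested assisted joint with each actuation mode,
#' computes metabolic breakdowns, and writes solutions, device summaries
#' and the per-speed comparison tables under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the synthetic trials.
#' @param speed_scales Speeds as fractions of preferred walking speed.
#' @param codes Assisted-joint codes to run.
#' @param modes Actuation modes to run.
#' @param weights [solver_weights()].
#' @param options [solver_options()].
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list per speed label with all condition results
#'   and the `comparison_result` table.
#' @export
run_experiment <- function(out_dir, seed = 0,
                           speed_scales = c(0.55, 1, 1.45),
                           codes = assist_codes()$code,
                           modes = c("motor", "spring"),
                           weights = solver_weights(),
                           options = solver_options(),
                           quiet = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list()
  for (ss in speed_scales) {
    spec <- synthetic_model_spec(speed_scale = ss)
    label <- spec$speed_label
    t0 <- Sys.time()
    trial <- synthetic_trial(spec, seed = seed)
    say("[%s] synthetic trial generated (%.1f s)", label,
        as.numeric(Sys.time() - t0, units = "secs"))
    t0 <- Sys.time()
    un <- run_condition(trial, spec$muscles, "none", weights = weights,
                        options = options)
    say("[%s] unassisted: %s, J = %.4f (%.1f s)", label,
        un$solution$status, un$solution$objective,
        as.numeric(Sys.time() - t0, units = "secs"))
    write_solution(un$solution, out_dir, paste0(label, "_unassisted"))
    write_metabolics(un$metabolics, out_dir, paste0(label, "_unassisted"))
    assisted <- list()
    for (code in codes) {
      for (mode in modes) {
        t0 <- Sys.time()
        res <- run_condition(trial, spec$muscles, mode, code,
                             weights = weights, options = options,
                             unassisted = un$solution)
        say("[%s] %s %s: %s, J = %.4f (%.1f s)", label, code, mode,
            res$solution$status, res$solution$objective,
            as.numeric(Sys.time() - t0, units = "secs"))
        stem <- paste0(label, "_", code, "_", mode)
        write_solution(res$solution, out_dir, stem)
        write_metabolics(res$metabolics, out_dir, stem)
        if (mode == "spring") {
          d <- res$device_solution
          write_summary_record(list(
            k_r = d$k_r, t_c = d$t_c, t_d = d$t_d, b = d$b,
            k_r_per_kg = d$k_r / trial$body_mass,
            closure_rad2 = d$closure, net_work_j = d$net_work,
            peak_energy_j = d$peak_energy),
            file.path(out_dir, paste0(stem, "_device.txt")))
        }
        assisted[[paste0(code, "_", mode)]] <-
          list(solution = res$solution, metabolics = res$metabolics,
               group = res$group)
      }
    }
    report <- condition_report(un, assisted)
    write_comparison(report, file.path(out_dir,
                                       paste0(label, "_comparison.tsv")))
    out[[label]] <- list(trial = trial, unassisted = un, assisted = assisted,
                         report = report)
  }
  invisible(out)
}
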