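# Comparison layer: group-averaged time series, gait-cycle averages and
# percent change between unassisted and assisted conditions for muscle
# activations, net muscle moments and metabolic rates.

#' Muscle group map
#'
#' Maps functional muscle groups (plantarflexion, dorsiflexion, knee
#' extension/flexion, hip flexion/extension, hip abduction/adduction,
#' all-leg) to their member muscles, with the antagonist pairing used in
#' the assisted-condition reports. Bi-articular muscles may appear in
#' several groups.
#'
#' @param members Named list of character vectors (group -> muscle labels).
#' @param antagonists Named character vector (group -> antagonist group).
#' @return A `muscle_group_map`.
#' @export
muscle_group_map <- function(members, antagonists) {
  stopifnot(is.list(members), all(lengths(members) > 0))
  bad <- setdiff(names(antagonists), names(members))
  if (length(bad)) stop("antagonist refers to unknown group: ",
                        paste(bad, collapse = ", "))
  structure(list(members = members, antagonists = antagonists),
            class = "muscle_group_map")
}

#' Default group map for the synthetic lower-limb muscle set
#'
#' @return A `muscle_group_map` covering the nine-muscle default set.
#' @export
default_group_map <- function() {
  muscle_group_map(
    members = list(
      plantarflexion = c("soleus", "gas_med", "gas_lat"),
      dorsiflexion = "tib_ant",
      knee_extension = "vasti",
      knee_flexion = c("gas_med", "gas_lat", "hamstrings"),
      hip_flexion = "iliopsoas",
      hip_extension = "hamstrings",
      hip_abduction = "glut_med",
      hip_adduction = "adductors",
      all_leg = c("soleus", "gas_med", "gas_lat", "tib_ant", "vasti",
                  "hamstrings", "iliopsoas", "glut_med", "adductors")),
    antagonists = c(plantarflexion = "dorsiflexion",
                    dorsiflexion = "plantarflexion",
                    knee_extension = "knee_flexion",
                    knee_flexion = "knee_extension",
                    hip_flexion = "hip_extension",
                    hip_extension = "hip_flexion",
                    hip_abduction = "hip_adduction",
                    hip_adduction = "hip_abduction"))
}

#' Group-averaged time series
#'
#' Arithmetic mean over the member muscles of a group at each time point.
#'
#' @param series Matrix (time x muscle) with muscle labels as column names.
#' @param group Group label in `map`, or a character vector of muscle
#'   labels.
#' @param map A [muscle_group_map()].
#' @return Numeric vector (time).
#' @export
group_average_timeseries <- function(series, group, map = default_group_map()) {
  members <- if (length(group) == 1 && group %in% names(map$members))
    map$members[[group]] else group
  missing <- setdiff(members, colnames(series))
  if (length(missing))
    stop("muscle(s) missing from series: ", paste(missing, collapse = ", "))
  rowMeans(series[, members, drop = FALSE])
}

#' Gait-cycle average
#'
#' Time average of a signal over the cycle: the trapezoidal integral
#' divided by the cycle duration.
#'
#' @param x Signal values on `time`.
#' @param time Time grid (s); for signals on the solver midpoint grid the
#'   implied cycle wraps periodically.
#' @param t_span Optional cycle duration (defaults to the grid span plus
#'   one step for periodic midpoint grids, or the plain span otherwise).
#' @return Scalar average.
#' @export
cycle_average <- function(x, time, t_span = NULL) {
  stopifnot(length(x) == length(time), length(x) >= 2)
  dt <- diff(time)
  if (is.null(t_span)) {
    # uniform periodic midpoint grid: every sample carries equal weight
    if (max(abs(dt - dt[1])) < 1e-9 * dt[1]) return(mean(x))
    t_span <- time[length(time)] - time[1]
  }
  sum(dt * (x[-length(x)] + x[-1]) / 2) / t_span
}

#' Percent change between unassisted and assisted averages
#'
#' `(unassisted - assisted) / unassisted * 100`: positive values are
#' reductions relative to the unassisted condition, negative values
#' increases.
#'
#' @param x_unassisted Cycle-average in the unassisted condition.
#' @param x_assisted Cycle-average in the assisted condition.
#' @return Percent change; `NA` with a warning for a zero baseline.
#' @export
percent_change <- function(x_unassisted, x_assisted) {
  out <- (x_unassisted - x_assisted) / x_unassisted * 100
  if (any(x_unassisted == 0)) {
    warning("zero unassisted baseline: percent change undefined, reported as NA")
    out[x_unassisted == 0] <- NA_real_
  }
  out
}

# percent change with the 0/0 case reported as no change (arises for
# directional moments that are identically zero in both conditions)
safe_delta <- function(xu, xa) {
  if (xu == 0 && xa == 0) return(0)
  suppressWarnings(percent_change(xu, xa))
}

# resample a time series to the field-standard 101 points (0-100% cycle)
resample_percent_cycle <- function(x, time, t_cycle, n = 101) {
  tt_closed <- c(time, time[1] + t_cycle)
  x_closed <- c(x, x[1])
  periodic_spline(tt_closed, x_closed)(seq(time[1], time[1] + t_cycle,
                                           length.out = n))
}

# net muscle moment in the assisted direction for a group/joint (reported
# with the assisted-direction-positive sign convention)
group_joint <- c(plantarflexion = "ankle", dorsiflexion = "ankle",
                 knee_extension = "knee", knee_flexion = "knee",
                 hip_flexion = "hip_sagittal", hip_extension = "hip_sagittal",
                 hip_abduction = "hip_frontal", hip_adduction = "hip_frontal")
group_sign <- c(plantarflexion = -1, dorsiflexion = 1,
                knee_extension = 1, knee_flexion = -1,
                hip_flexion = 1, hip_extension = -1,
                hip_abduction = 1, hip_adduction = -1)

#' Compare unassisted and assisted conditions
#'
#' Builds the percent-change table between an unassisted solve and one or
#' more assisted solves: change in the group-averaged muscle activations
#' and metabolic rates for the assisted group, its antagonist group and
#' all leg muscles, and change in the directional net muscle moments of
#' the assisted and antagonist groups. All series are resampled to 101
#' points (percent gait cycle) before averaging.
#'
#' @param unassisted List with `solution` (a `redundancy_solution`) and
#'   `metabolics` (a `metabolic_breakdown`) for the unassisted condition.
#' @param assisted Named list (condition label -> list with `solution`,
#'   `metabolics`, `group` = assisted group label).
#' @param map A [muscle_group_map()].
#' @return A `comparison_result` data.frame: one row per condition x
#'   quantity x group with the unassisted and assisted cycle averages and
#'   the percent change.
#' @export
condition_report <- function(unassisted, assisted, map = default_group_map()) {
  stopifnot(inherits(unassisted$solution, "redundancy_solution"))
  rows <- list()
  for (cond in names(assisted)) {
    as_c <- assisted[[cond]]
    grp <- as_c$group
    if (!grp %in% names(map$members)) stop("unknown assisted group: ", grp)
    antag <- map$antagonists[[grp]]
    sets <- c(assisted_group = grp, antagonist_group = antag, all_leg = "all_leg")
    for (set_name in names(sets)) {
      g <- sets[[set_name]]
      if (is.na(g) || is.null(map$members[[g]])) next
      for (quantity in c("activation", "metabolic_rate")) {
        ser_u <- if (quantity == "activation") unassisted$solution$activations
                 else unassisted$metabolics$e_dot
        ser_a <- if (quantity == "activation") as_c$solution$activations
                 else as_c$metabolics$e_dot
        xu <- cycle_average(group_average_timeseries(ser_u, g, map),
                            unassisted$solution$time)
        xa <- cycle_average(group_average_timeseries(ser_a, g, map),
                            as_c$solution$time)
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, group = g, role = set_name, quantity = quantity,
          unassisted = xu, assisted = xa,
          delta_pct = safe_delta(xu, xa))
      }
    }
    # directional net muscle moments (mean absolute moment in the group's
    # action direction) for assisted + antagonist groups
    for (set_name in c("assisted_group", "antagonist_group")) {
      g <- sets[[set_name]]
      joint <- group_joint[[g]]
      sgn <- group_sign[[g]]
      mu <- cycle_average(pmax(sgn * unassisted$solution$tau_mus[, joint], 0),
                          unassisted$solution$time)
      ma <- cycle_average(pmax(sgn * as_c$solution$tau_mus[, joint], 0),
                          as_c$solution$time)
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, group = g, role = set_name,
        quantity = "net_muscle_moment",
        unassisted = mu, assisted = ma,
        delta_pct = safe_delta(mu, ma))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_result", "data.frame")
  out
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d rows (positive delta_pct = reduction vs unassisted)\n",
              nrow(x)))
  NextMethod()
}

#' Write a comparison table
#'
#' @param report A `comparison_result`.
#' @param path Output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
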