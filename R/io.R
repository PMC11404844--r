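# Motion-storage table reader/writer: the tab-delimited header-then-matrix
# time-series convention used by the common musculoskeletal toolchain
# (name / metadata lines, `endheader`, a column-label row, then data rows
# with `time` first).

#' Read a motion-storage table
#'
#' @param path File path.
#' @return A `motion_table`: list with `name`, `in_degrees`, and `data`
#'   (data.frame whose first column is `time`).
#' @export
read_motion_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r$", "", lines)  # accept CRLF
  end <- which(trimws(lines) == "endheader")
  if (length(end) != 1)
    stop("malformed motion-storage header in ", path, ": missing 'endheader'")
  header <- lines[seq_len(end - 1)]
  name <- if (end > 1 && !grepl("=", header[1])) header[1] else basename(path)
  get_field <- function(key, default = NA) {
    hit <- grep(paste0("^", key, "\\s*="), header, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(".*=", "", hit[1]))
  }
  in_degrees <- identical(tolower(get_field("inDegrees", "no")), "yes")

  body <- lines[(end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  labels <- strsplit(body[1], "\t")[[1]]
  if (anyDuplicated(labels))
    stop("duplicated column label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         " (line ", end + 1, ")")
  if (!"time" %in% labels) stop("missing time column (line ", end + 1, ")")
  rows <- strsplit(body[-1], "\t")
  nc <- lengths(rows)
  if (any(nc != length(labels)))
    stop("ragged row at line ", end + 1 + which(nc != length(labels))[1])
  data <- as.data.frame(matrix(as.numeric(unlist(rows)), ncol = length(labels),
                               byrow = TRUE))
  names(data) <- labels
  data <- data[c("time", setdiff(labels, "time"))]
  if (any(diff(data$time) <= 0)) stop("non-monotone time column")
  n_rows <- suppressWarnings(as.integer(get_field("nRows")))
  if (!is.na(n_rows) && n_rows != nrow(data))
    stop("header declares nRows=", n_rows, " but found ", nrow(data))
  structure(list(name = name, in_degrees = in_degrees, data = data),
            class = "motion_table")
}

#' Write a motion-storage table
#'
#' @param data Data.frame whose first column is `time` (strictly
#'   increasing), or a `motion_table`.
#' @param path Output path.
#' @param name Table name written in the header.
#' @param in_degrees Whether angle columns are in degrees (`"yes"`/`"no"`
#'   header flag; this writer never converts, it annotates).
#' @return `path`, invisibly.
#' @export
write_motion_table <- function(data, path, name = basename(path),
                               in_degrees = FALSE) {
  if (inherits(data, "motion_table")) {
    name <- data$name; in_degrees <- data$in_degrees; data <- data$data
  }
  stopifnot(is.data.frame(data), names(data)[1] == "time")
  if (any(diff(data$time) <= 0)) stop("non-monotone time column")
  if (anyDuplicated(names(data))) stop("duplicated column labels")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               paste0("nRows=", nrow(data)),
               paste0("nColumns=", ncol(data)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(data), collapse = "\t")), con)
  mat <- as.matrix(data)
  writeLines(apply(mat, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "\t")), con)
  invisible(path)
}

# Key-value summary record ("key: value" lines, nested keys joined by dots).
write_summary_record <- function(x, path) {
  flat <- unlist(x)
  writeLines(paste0(names(flat), ": ",
                    vapply(flat, function(v)
                      if (is.numeric(v)) formatC(v, format = "g", digits = 17) else as.character(v),
                      character(1))), path)
  invisible(path)
}

read_summary_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  keys <- sub(":.*$", "", lines)
  vals <- trimws(sub("^[^:]*:", "", lines))
  num <- suppressWarnings(as.numeric(vals))
  out <- lapply(seq_along(vals), function(i)
    if (is.na(num[i])) vals[i] else num[i])
  names(out) <- keys
  out
}

#' Convert a gait trial to/from motion-storage tables
#'
#' A trial serializes to three tables sharing a directory and stem:
#' `<stem>_kinematics.sto` (angles and net moments), `<stem>_lmt.sto`
#' (muscle-tendon lengths) and `<stem>_arms.sto` (moment arms, columns
#' `muscle@joint`), plus `<stem>_meta.txt` (body mass, speed label, events).
#'
#' @param trial A [gait_trial()].
#' @param dir Directory.
#' @param stem File-name stem.
#' @return `write_gait_trial`: the stem path, invisibly.
#'   `read_gait_trial`: the reconstructed `gait_trial`.
#' @export
write_gait_trial <- function(trial, dir, stem) {
  stopifnot(inherits(trial, "gait_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kin <- data.frame(time = trial$time,
                    trial$q, stats::setNames(as.data.frame(trial$tau_id),
                                             paste0("tau_", colnames(trial$tau_id))),
                    check.names = FALSE)
  write_motion_table(kin, file.path(dir, paste0(stem, "_kinematics.sto")),
                     name = paste0(stem, " kinematics"))
  lmt <- data.frame(time = trial$time, trial$l_mt, check.names = FALSE)
  write_motion_table(lmt, file.path(dir, paste0(stem, "_lmt.sto")),
                     name = paste0(stem, " muscle-tendon lengths"))
  nm <- muscles_of(trial); nj <- joints_of(trial)
  arms <- do.call(cbind, lapply(seq_along(nj), function(j) {
    a <- trial$moment_arms[, , j, drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, ncol = length(nm))
    colnames(a) <- paste0(nm, "@", nj[j])
    a
  }))
  keep <- colSums(arms != 0) > 0
  arms_df <- data.frame(time = trial$time, arms[, keep, drop = FALSE],
                        check.names = FALSE)
  write_motion_table(arms_df, file.path(dir, paste0(stem, "_arms.sto")),
                     name = paste0(stem, " moment arms"))
  write_summary_record(list(body_mass = trial$body_mass,
                            speed_label = trial$speed_label,
                            toe_off = unname(trial$cycle_events[1])),
                       file.path(dir, paste0(stem, "_meta.txt")))
  invisible(file.path(dir, stem))
}

#' @rdname write_gait_trial
#' @export
read_gait_trial <- function(dir, stem) {
  kin <- read_motion_table(file.path(dir, paste0(stem, "_kinematics.sto")))$data
  lmt <- read_motion_table(file.path(dir, paste0(stem, "_lmt.sto")))$data
  arms <- read_motion_table(file.path(dir, paste0(stem, "_arms.sto")))$data
  meta <- read_summary_record(file.path(dir, paste0(stem, "_meta.txt")))
  jn <- grep("^tau_", names(kin), value = TRUE)
  joints <- sub("^tau_", "", jn)
  q <- as.matrix(kin[, joints, drop = FALSE])
  tau <- as.matrix(kin[, jn, drop = FALSE]); colnames(tau) <- joints
  muscles <- setdiff(names(lmt), "time")
  l_mt <- as.matrix(lmt[, muscles, drop = FALSE])
  arr <- array(0, c(nrow(kin), length(muscles), length(joints)),
               dimnames = list(NULL, muscles, joints))
  for (cn in setdiff(names(arms), "time")) {
    parts <- strsplit(cn, "@", fixed = TRUE)[[1]]
    arr[, parts[1], parts[2]] <- arms[[cn]]
  }
  gait_trial(kin$time, q, tau, l_mt, arr, body_mass = meta$body_mass,
             speed_label = meta$speed_label,
             cycle_events = c(toe_off = meta$toe_off))
}
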