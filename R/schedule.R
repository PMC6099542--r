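#' Dynamic PET frame schedule
#'
#' A frame schedule is the acquisition time grid of a dynamic PET scan:
#' per-frame start times and durations, in seconds, starting at injection
#' (t = 0). Frames must be contiguous and non-overlapping. Mid-frame times
#' are derived and carried both in seconds and minutes; all kinetic code in
#' this package works in minutes (rate constants are min^-1), seconds appear
#' only at the I/O boundary.
#'
#' @param start_s numeric vector of frame start times (seconds).
#' @param duration_s numeric vector of frame durations (seconds), all > 0.
#' @return An object of class `frame_schedule` with fields `start_s`,
#'   `duration_s`, `mid_s`, and the minute-unit counterparts `start_min`,
#'   `end_min`, `mid_min`.
#' @examples
#' sch <- frame_schedule(c(0, 5, 10), c(5, 5, 10))
#' sch$mid_s
#' @export
frame_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s)
  duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s) || length(start_s) == 0L)
    stop("start_s and duration_s must be non-empty and of equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite")
  if (any(duration_s <= 0))
    stop("frame durations must be positive")
  if (abs(start_s[1L]) > 1e-9)
    stop("first frame must start at t = 0")
  n <- length(start_s)
  if (n > 1L) {
    expected <- start_s[-n] + duration_s[-n]
    if (any(abs(start_s[-1L] - expected) > 1e-6))
      stop("frames must be contiguous and non-overlapping ",
           "(start[i+1] = start[i] + duration[i])")
  }
  structure(
    list(
      start_s = start_s,
      duration_s = duration_s,
      mid_s = start_s + duration_s / 2,
      start_min = start_s / 60,
      end_min = (start_s + duration_s) / 60,
      mid_min = (start_s + duration_s / 2) / 60
    ),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> %d frames, 0 to %.0f s (%.1f min)\n",
              length(x$start_s), max(x$start_s + x$duration_s),
              max(x$end_min)))
  invisible(x)
}

#' Number of frames in a schedule
#' @param schedule a `frame_schedule`.
#' @return integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$start_s)

#' The study's 120-minute dynamic acquisition schedule
#'
#' 25 contiguous frames: 12 x 5 s, 4 x 60 s, 2 x 300 s, 7 x 900 s, spanning
#' 7200 s from injection. This is the grid on which all synthetic cohorts
#' are generated.
#'
#' @return a `frame_schedule` with 25 frames.
#' @examples
#' sch <- default_frame_schedule()
#' n_frames(sch)                     # 25
#' sum(sch$duration_s)               # 7200
#' @export
default_frame_schedule <- function() {
  durations <- c(rep(5, 12), rep(60, 4), rep(300, 2), rep(900, 7))
  frame_schedule(cumsum(c(0, durations[-length(durations)])), durations)
}

#' Regional time-activity curve
#'
#' One subject's activity concentration per frame in one region. Values are
#' unit-tagged (default `"%ID/g"`). Negative values are permitted only when
#' the curve is tagged `noisy = TRUE` (measured data); they are stored as-is
#' so noise statistics stay unbiased.
#'
#' @param schedule a `frame_schedule`.
#' @param value numeric vector, one activity concentration per frame.
#' @param region region label, e.g. "whole brain", "cortex".
#' @param subject_id subject label.
#' @param unit concentration unit tag; `"%ID/g"` by default.
#' @param noisy logical; TRUE for measured/noise-bearing curves.
#' @param corrected logical; TRUE once metabolite-corrected.
#' @return an object of class `tac`.
#' @export
tac <- function(schedule, value, region = "whole brain",
                subject_id = "subject", unit = "%ID/g",
                noisy = FALSE, corrected = FALSE) {
  if (!inherits(schedule, "frame_schedule"))
    stop("schedule must be a frame_schedule")
  value <- as.numeric(value)
  if (length(value) != n_frames(schedule))
    stop("value must have one entry per frame (",
         n_frames(schedule), " frames, got ", length(value), ")")
  if (any(!is.finite(value)))
    stop("TAC values must be finite")
  if (!noisy && any(value < 0))
    stop("negative TAC values are only allowed for noisy measured curves")
  structure(
    list(schedule = schedule, value = value, region = region,
         subject_id = subject_id, unit = unit, noisy = noisy,
         corrected = corrected),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s / %s, %d frames [%s]%s%s\n",
              x$subject_id, x$region, n_frames(x$schedule), x$unit,
              if (x$noisy) ", noisy" else "",
              if (x$corrected) ", metabolite-corrected" else ""))
  invisible(x)
}

#' Plasma sample series
#'
#' Discrete arterial plasma samples: sample times (minutes, strictly
#' increasing, >= 0), total plasma activity concentration, and optionally
#' the observed parent (unmetabolized) fraction at each time.
#'
#' @param time_min numeric sample times in minutes.
#' @param total_plasma total plasma activity concentration per sample.
#' @param parent_fraction_obs optional observed parent fraction in [0, 1].
#' @return an object of class `plasma_series`.
#' @export
plasma_series <- function(time_min, total_plasma, parent_fraction_obs = NULL) {
  time_min <- as.numeric(time_min)
  total_plasma <- as.numeric(total_plasma)
  if (length(time_min) != length(total_plasma) || length(time_min) == 0L)
    stop("time_min and total_plasma must be non-empty and of equal length")
  if (any(time_min < 0) || any(diff(time_min) <= 0))
    stop("sample times must be >= 0 and strictly increasing")
  if (any(!is.finite(total_plasma)) || any(total_plasma < 0))
    stop("total plasma concentrations must be finite and >= 0")
  if (!is.null(parent_fraction_obs)) {
    parent_fraction_obs <- as.numeric(parent_fraction_obs)
    if (length(parent_fraction_obs) != length(time_min))
      stop("parent_fraction_obs must match sample times in length")
    if (any(parent_fraction_obs < 0 | parent_fraction_obs > 1, na.rm = TRUE))
      stop("parent fractions must lie in [0, 1]")
  }
  structure(
    list(time_min = time_min, total_plasma = total_plasma,
         parent_fraction_obs = parent_fraction_obs),
    class = "plasma_series"
  )
}

# ---- tabular I/O -----------------------------------------------------------
# CSV dialect: comma-separated, dot decimal, UTF-8, mandatory header.
# Frame times in the files are SECONDS (scanner convention); conversion to
# the internal minute unit happens here and only here.

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("malformed table '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
}

#' Read time-activity curves from a CSV table
#'
#' Expected columns: `subject_id, region, frame_start_s, frame_duration_s,
#' value, unit` (optional logical columns `noisy`, `corrected`). One curve
#' per (subject_id, region) pair; frames must satisfy the schedule
#' invariants.
#'
#' @param path CSV file path.
#' @return list of `tac` objects (possibly empty; empty file -> warning).
#' @export
read_tac_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("empty TAC table: ", path)
    return(list())
  }
  .require_columns(df, c("subject_id", "region", "frame_start_s",
                         "frame_duration_s", "value", "unit"), path)
  keys <- unique(df[, c("subject_id", "region")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$subject_id == keys$subject_id[i] &
                df$region == keys$region[i], , drop = FALSE]
    sub <- sub[order(sub$frame_start_s), , drop = FALSE]
    sch <- frame_schedule(sub$frame_start_s, sub$frame_duration_s)
    noisy <- if ("noisy" %in% names(sub)) as.logical(sub$noisy[1L]) else TRUE
    corrected <- if ("corrected" %in% names(sub))
      as.logical(sub$corrected[1L]) else FALSE
    out[[i]] <- tac(sch, sub$value, region = keys$region[i],
                    subject_id = keys$subject_id[i], unit = sub$unit[1L],
                    noisy = noisy, corrected = corrected)
  }
  out
}

#' Write time-activity curves to a CSV table
#'
#' Inverse of [read_tac_table()]: round-trip write-then-read reproduces the
#' curves up to float text precision.
#'
#' @param tacs a `tac` or list of `tac` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac_table <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- lapply(tacs, function(x) {
    data.frame(subject_id = x$subject_id, region = x$region,
               frame_start_s = x$schedule$start_s,
               frame_duration_s = x$schedule$duration_s,
               value = x$value, unit = x$unit,
               noisy = x$noisy, corrected = x$corrected)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a plasma sample table from CSV
#'
#' Expected columns: `sample_time_min, total_plasma`, optional
#' `parent_fraction_obs`.
#'
#' @param path CSV file path.
#' @return a `plasma_series`.
#' @export
read_plasma_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("sample_time_min", "total_plasma"), path)
  pf <- if ("parent_fraction_obs" %in% names(df)) df$parent_fraction_obs
  plasma_series(df$sample_time_min, df$total_plasma, pf)
}

#' Write a plasma sample table to CSV
#' @param samples a `plasma_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plasma_table <- function(samples, path) {
  df <- data.frame(sample_time_min = samples$time_min,
                   total_plasma = samples$total_plasma)
  if (!is.null(samples$parent_fraction_obs))
    df$parent_fraction_obs <- samples$parent_fraction_obs
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
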