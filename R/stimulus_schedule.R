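#' Assay timeline: acclimation, blank periods, alternating stimulus periods
#'
#' The standard assay records one frame every 6 seconds for two hours,
#' structured as twelve 10-minute periods: periods 1-2 on a blank background,
#' then ten stimulus periods in which projected lines alternate moving
#' downward (odd periods 3, 5, 7, 9, 11) and upward (even periods 4, 6, 8,
#' 10, 12). A 1-hour acclimation precedes recording; if acclimation frames
#' are present in an input series they are tagged period 0 and excluded from
#' scoring.
#'
#' @param frame_interval Seconds between frames (default 6).
#' @param period_length Seconds per period (default 600); must be divisible
#'   by `frame_interval`.
#' @param n_blank Leading blank periods (default 2).
#' @param n_stimulus Stimulus periods (default 10); direction alternates
#'   starting with `first_direction`.
#' @param first_direction Direction of the first stimulus period
#'   (default `"down"`, making odd periods downward).
#' @param acclimation Acclimation time in seconds before recording
#'   (default 3600); informational unless acclimation frames are supplied.
#' @return An object of class `period_schedule` with a `periods` data.frame
#'   (`period`, `stimulus` in `none`/`down`/`up`).
#' @examples
#' sched <- period_schedule()
#' recording_frames(sched)        # 1200 frames for the 2-hour assay
#' period_of_frame(sched, 250)    # period 3, stimulus "down"
#' @export
period_schedule <- function(frame_interval = 6, period_length = 600,
                            n_blank = 2, n_stimulus = 10,
                            first_direction = c("down", "up"),
                            acclimation = 3600) {
  first_direction <- match.arg(first_direction)
  if (frame_interval <= 0 || period_length <= 0)
    stop("frame_interval and period_length must be positive")
  if (period_length %% frame_interval != 0)
    stop("period_length must be divisible by frame_interval")
  if (n_blank < 0 || n_stimulus < 0 || n_blank + n_stimulus < 1)
    stop("schedule needs at least one period")
  dirs <- if (n_stimulus > 0) {
    alt <- c("down", "up")
    if (first_direction == "up") alt <- rev(alt)
    rep_len(alt, n_stimulus)
  } else character(0)
  periods <- data.frame(
    period = seq_len(n_blank + n_stimulus),
    stimulus = c(rep("none", n_blank), dirs),
    stringsAsFactors = FALSE)
  structure(list(frame_interval = frame_interval,
                 period_length = period_length,
                 periods = periods,
                 acclimation = acclimation),
            class = "period_schedule")
}

#' @export
print.period_schedule <- function(x, ...) {
  cat(sprintf("period_schedule: %d periods x %ds, frame every %gs (%d frames)\n",
              nrow(x$periods), x$period_length, x$frame_interval,
              recording_frames(x)))
  invisible(x)
}

#' Number of frames in a recording
#'
#' @param schedule A `period_schedule`.
#' @return Integer frame count: total recording seconds / frame interval.
#' @export
recording_frames <- function(schedule) {
  stopifnot(inherits(schedule, "period_schedule"))
  as.integer(nrow(schedule$periods) * schedule$period_length /
               schedule$frame_interval)
}

#' Frames per period
#' @param schedule A `period_schedule`.
#' @return Integer number of frames in each period.
#' @export
frames_per_period <- function(schedule) {
  as.integer(schedule$period_length / schedule$frame_interval)
}

#' Map frame indices to periods and stimulus directions
#'
#' Frames are indexed from 0 at the start of recording, so frame `i` is
#' acquired at time `i * frame_interval` seconds and frames 0-99 of the
#' default schedule fall in period 1. The mapping is total: every in-range
#' frame belongs to exactly one period.
#'
#' @param schedule A `period_schedule`.
#' @param frame Integer vector of 0-based frame indices.
#' @return Data.frame with columns `frame`, `period`, `stimulus`.
#' @export
period_of_frame <- function(schedule, frame) {
  stopifnot(inherits(schedule, "period_schedule"))
  frame <- as.integer(frame)
  nf <- recording_frames(schedule)
  if (any(frame < 0L) || any(frame >= nf))
    stop(sprintf("frame index out of range [0, %d)", nf))
  fpp <- frames_per_period(schedule)
  period <- frame %/% fpp + 1L
  data.frame(frame = frame, period = period,
             stimulus = schedule$periods$stimulus[period],
             stringsAsFactors = FALSE)
}

#' Moving-line stimulus geometry
#'
#' Describes the projected pattern: red lines 1 mm thick separated by a 7 mm
#' gap (pattern pitch 8 mm, edge-to-edge reading of the spacing), travelling
#' at 7 mm per 8 seconds, on a light gray background. Colors are the
#' projected slide values; what the camera records is governed separately by
#' [render_spec()].
#'
#' @param line_thickness_mm Line thickness (default 1).
#' @param line_gap_mm Edge-to-edge gap between lines (default 7).
#' @param speed_mm_s Pattern speed in mm per second (default 7/8).
#' @param line_color,background_color RGB triples in 0-255.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(line_thickness_mm = 1, line_gap_mm = 7,
                          speed_mm_s = 7 / 8,
                          line_color = c(255, 0, 0),
                          background_color = c(191, 191, 191)) {
  if (line_thickness_mm <= 0 || line_gap_mm <= 0 || speed_mm_s <= 0)
    stop("thickness, gap and speed must be positive")
  for (col in list(line_color, background_color))
    if (length(col) != 3 || any(col < 0) || any(col > 255))
      stop("colors must be RGB triples in [0, 255]")
  structure(list(line_thickness_mm = line_thickness_mm,
                 line_gap_mm = line_gap_mm,
                 speed_mm_s = speed_mm_s,
                 line_color = as.numeric(line_color),
                 background_color = as.numeric(background_color)),
            class = "stimulus_spec")
}

#' Pattern pitch (line thickness + gap) in mm
#' @param spec A `stimulus_spec`.
#' @export
pattern_pitch <- function(spec) spec$line_thickness_mm + spec$line_gap_mm

#' Displacement of the line pattern at a given time
#'
#' The pattern is periodic with pitch `thickness + gap`, so the offset is the
#' travelled distance `speed * t` wrapped modulo the pitch and signed by
#' direction: positive offsets move the pattern downward (larger y), negative
#' upward. `direction = "none"` returns 0.
#'
#' @param spec A `stimulus_spec`.
#' @param t Time in seconds since the pattern started moving (vectorized).
#' @param direction `"down"`, `"up"`, or `"none"`.
#' @return Numeric offset(s) in mm, in `(-pitch, pitch)`.
#' @examples
#' stimulus_offset(stimulus_spec(), 8, "down")   # 7 mm
#' stimulus_offset(stimulus_spec(), 16, "down")  # 14 mm wraps to 6 mm
#' @export
stimulus_offset <- function(spec, t, direction = c("down", "up", "none")) {
  stopifnot(inherits(spec, "stimulus_spec"))
  direction <- match.arg(direction)
  if (any(t < 0)) stop("t must be >= 0")
  if (direction == "none") return(rep(0, length(t)))
  sgn <- if (direction == "down") 1 else -1
  sgn * ((spec$speed_mm_s * t) %% pattern_pitch(spec))
}
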