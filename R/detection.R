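#' Detection configuration
#'
#' Parameters of the image-analysis core. The defaults are the reference
#' macro's operating point: pixels of the difference image are foreground
#' when their intensity reaches `diff_threshold` (threshold window 25-255),
#' and a larva counts as having moved when the per-well foreground area
#' reaches `move_area_min` (20 pixels).
#'
#' @param diff_threshold Minimum difference intensity counted as foreground
#'   (8-bit units, default 25).
#' @param move_area_min Minimum suprathreshold area (pixels) scored as a
#'   movement (default 20).
#' @param channel `"auto"` selects the channel in which stimulus lines and
#'   background are most similar (so the moving stimulus vanishes from the
#'   difference images); or force `"red"`, `"green"`, `"blue"`.
#' @param mode `"subtractive"` differences consecutive frames (the multi-well
#'   default); `"background"` differences every frame against a median
#'   background, detecting larvae even when static.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(diff_threshold = 25, move_area_min = 20,
                             channel = c("auto", "red", "green", "blue"),
                             mode = c("subtractive", "background")) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  if (diff_threshold <= 0 || diff_threshold > 255)
    stop("diff_threshold must be in (0, 255]")
  if (move_area_min < 1) stop("move_area_min must be >= 1")
  structure(list(diff_threshold = diff_threshold,
                 move_area_min = move_area_min,
                 channel = channel, mode = mode),
            class = "detection_config")
}

channel_index <- function(channel) {
  match(channel, c("red", "green", "blue"))
}

# extract one channel as a matrix from a HxW or HxWx3 array
get_channel <- function(frame, channel) {
  if (length(dim(frame)) == 2) return(frame)
  frame[, , channel]
}

#' Select the analysis channel
#'
#' Picks the color channel in which the stimulus lines and the background
#' have the most similar intensity, so that the moving stimulus disappears
#' from difference images and only displaced larvae remain. Pixels are
#' classified as line or background by nearest projected color; the channel
#' minimizing `|mean line intensity - mean background intensity|` wins, with
#' ties broken in R, G, B order.
#'
#' @param frame An RGB frame (array `h x w x 3`, 0-255) containing visible
#'   stimulus lines.
#' @param stimulus A `stimulus_spec` providing the projected line and
#'   background colors used for pixel classification.
#' @return Channel index (1 = red, 2 = green, 3 = blue), or `NA` when no
#'   line pixels are found (caller should fall back to a configured channel).
#' @examples
#' # gray background with pure red lines: the red channel has contrast
#' # |255 - 191| = 64, far below green/blue's 191, so red is selected
#' @export
select_channel <- function(frame, stimulus = stimulus_spec()) {
  if (length(dim(frame)) != 3) stop("select_channel needs an RGB frame")
  lc <- stimulus$line_color
  bc <- stimulus$background_color
  r <- frame[, , 1]; g <- frame[, , 2]; b <- frame[, , 3]
  d_line <- (r - lc[1])^2 + (g - lc[2])^2 + (b - lc[3])^2
  d_bg <- (r - bc[1])^2 + (g - bc[2])^2 + (b - bc[3])^2
  is_line <- d_line < d_bg
  if (!any(is_line) || all(is_line)) return(NA_integer_)
  contrast <- vapply(1:3, function(ch) {
    m <- frame[, , ch]
    abs(mean(m[is_line]) - mean(m[!is_line]))
  }, numeric(1))
  which.min(contrast)  # ties resolve to the lowest index: R, G, B order
}

#' Absolute difference of two frames
#'
#' The subtractive analysis: consecutive frames are differenced so that
#' static structures (well walls, plate edges) cancel and displaced larvae
#' remain. The difference is unsigned, so dark-to-light and light-to-dark
#' transitions contribute equally, and symmetric in its arguments.
#'
#' @param frame_i,frame_j Single-channel matrices, or RGB arrays with
#'   `channel` given. Same dimensions required.
#' @param channel Channel index to difference when passing RGB arrays.
#' @return Matrix of absolute differences (0-255).
#' @export
frame_difference <- function(frame_i, frame_j, channel = 1) {
  a <- get_channel(frame_i, channel)
  b <- get_channel(frame_j, channel)
  if (!identical(dim(a), dim(b)))
    stop(sprintf("frame dimension mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  abs(a - b)
}

#' Difference a frame against a fixed background
#'
#' Background mode: each frame is differenced against a reference background
#' (typically the per-pixel median of the series), so even a motionless larva
#' is detected. Downstream thresholding and measurement are identical to
#' subtractive mode.
#'
#' @param frame Single-channel matrix or RGB array.
#' @param background Background image of matching dimensions.
#' @inheritParams frame_difference
#' @return Matrix of absolute differences.
#' @export
background_subtract <- function(frame, background, channel = 1) {
  frame_difference(frame, background, channel)
}

#' Per-pixel median background of a frame series
#'
#' @param series A `frame_series`.
#' @param channel Channel index to extract.
#' @param max_frames At most this many frames, evenly spaced through the
#'   series, are used for the median (memory bound).
#' @return Single-channel background matrix.
#' @export
median_background <- function(series, channel = 1, max_frames = 25) {
  idx <- unique(round(seq(1, series$n, length.out = min(max_frames, series$n))))
  stack <- vapply(idx, function(i) get_channel(series$get(i), channel),
                  matrix(0, nrow(get_channel(series$get(1), channel)),
                         ncol(get_channel(series$get(1), channel))))
  apply(stack, c(1, 2), stats::median)
}

#' Measure one well in a difference image
#'
#' Counts the pixels inside the well region whose difference intensity
#' reaches the threshold, takes the unweighted centroid of those pixels
#' (all suprathreshold pixels in the well, not a single connected
#' component — a moving larva leaves an old-plus-new-position dumbbell), and
#' flags a movement when the area reaches `move_area_min`.
#'
#' @param diff Single-channel difference matrix covering the region.
#' @param region One row of a [well_regions()] data.frame.
#' @param config A `detection_config`.
#' @param mask_radius_px Optional circular-mask radius; pixels outside the
#'   circle centered on the well center are ignored.
#' @return One-row data.frame: `area`, `centroid_x`, `centroid_y`
#'   (NA when area is 0), `move`.
#' @export
measure_well <- function(diff, region, config = detection_config(),
                         mask_radius_px = NULL) {
  rows <- (region$y0 + 1L):region$y1
  cols <- (region$x0 + 1L):region$x1
  if (max(rows) > nrow(diff) || max(cols) > ncol(diff) || min(rows) < 1 ||
      min(cols) < 1)
    stop("difference image does not cover the well region")
  patch <- diff[rows, cols, drop = FALSE]
  fg <- patch >= config$diff_threshold
  if (!is.null(mask_radius_px)) {
    cx <- (region$x0 + region$x1) / 2
    cy <- (region$y0 + region$y1) / 2
    px <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
    py <- matrix(rows - 0.5, length(rows), length(cols))
    fg <- fg & ((px - cx)^2 + (py - cy)^2 <= mask_radius_px^2)
  }
  area <- sum(fg)
  if (area == 0) {
    cx_out <- NA_real_; cy_out <- NA_real_
  } else {
    hit <- which(fg, arr.ind = TRUE)
    cy_out <- mean(rows[hit[, 1]] - 0.5)   # pixel centers
    cx_out <- mean(cols[hit[, 2]] - 0.5)
  }
  data.frame(area = area, centroid_x = cx_out, centroid_y = cy_out,
             move = as.integer(area >= config$move_area_min))
}

#' Classify a larva as up or down within its well
#'
#' Compares the measured centroid to the well's geometric center: smaller y
#' (closer to the image top) is "up". A centroid exactly at the center
#' classifies as down (0), a deterministic tie rule for a measure-zero
#' event. When no centroid is defined (area 0), the result is `NA`.
#'
#' @param measurement One-row result of [measure_well()].
#' @param region The matching well region row.
#' @return `1L` (up), `0L` (down), or `NA_integer_`.
#' @export
classify_up <- function(measurement, region) {
  if (is.na(measurement$centroid_y)) return(NA_integer_)
  center_y <- (region$y0 + region$y1) / 2
  as.integer(measurement$centroid_y < center_y)
}

#' Run detection over a full frame series
#'
#' The pipeline core: selects the analysis channel, walks the series frame by
#' frame (holding at most two frames in memory), differences consecutive
#' frames (or each frame against a median background), and measures every
#' well of the layout in every difference image.
#'
#' Each difference row is attributed to the *later* frame of its pair, so
#' `frame_pair = f` (0-based) describes the interval ending at frame `f` and
#' carries that frame's period and stimulus direction. If the series is
#' longer than the schedule's recording, the leading excess frames are
#' treated as acclimation: tagged period 0 and excluded from scoring
#' downstream.
#'
#' @param series A `frame_series`.
#' @param layout A `plate_layout`.
#' @param schedule A `period_schedule`.
#' @param config A `detection_config`.
#' @param regions Optional precomputed [well_regions()] table.
#' @return Data.frame with one row per (well, frame pair): `plate`, `row`,
#'   `col`, `frame_pair`, `period`, `stimulus`, `area`, `centroid_x`,
#'   `centroid_y`, `move`, `up`, `valid` (`FALSE` for pairs touching an
#'   unreadable frame, whose measurements are NA).
#' @export
run_detection <- function(series, layout, schedule,
                          config = detection_config(), regions = NULL) {
  stopifnot(inherits(series, "frame_series"), inherits(layout, "plate_layout"),
            inherits(schedule, "period_schedule"))
  if (series$n < 2 && config$mode == "subtractive")
    stop("subtractive analysis needs at least 2 frames")
  if (is.null(regions)) regions <- well_regions(layout)
  mask_r <- attr(regions, "mask_radius_px")
  nw <- nrow(regions)
  nf <- series$n
  rec_nf <- recording_frames(schedule)
  acclim_offset <- max(0L, nf - rec_nf)   # leading frames beyond the schedule

  # per-frame period/stimulus, 0-based frame index f
  frame_period <- function(f) {
    rec <- f - acclim_offset
    if (rec < 0L) c(period = 0L, stimulus = "none")
    else {
      p <- period_of_frame(schedule, rec)
      c(period = p$period, stimulus = p$stimulus)
    }
  }

  ch <- resolve_channel(series, schedule, config, acclim_offset)

  # precompute integer index ranges per well
  row_idx <- lapply(seq_len(nw), function(i) (regions$y0[i] + 1L):regions$y1[i])
  col_idx <- lapply(seq_len(nw), function(i) (regions$x0[i] + 1L):regions$x1[i])
  masks <- NULL
  if (!is.null(mask_r)) {
    masks <- lapply(seq_len(nw), function(i) {
      cx <- regions$cx[i]; cy <- regions$cy[i]
      px <- matrix(col_idx[[i]] - 0.5, length(row_idx[[i]]),
                   length(col_idx[[i]]), byrow = TRUE)
      py <- matrix(row_idx[[i]] - 0.5, length(row_idx[[i]]),
                   length(col_idx[[i]]))
      (px - cx)^2 + (py - cy)^2 <= mask_r^2
    })
  }

  thr <- config$diff_threshold
  amin <- config$move_area_min
  measure_into <- function(d, off, out) {
    for (i in seq_len(nw)) {
      patch <- d[row_idx[[i]], col_idx[[i]], drop = FALSE]
      fg <- patch >= thr
      if (!is.null(masks)) fg <- fg & masks[[i]]
      area <- sum(fg)
      k <- off + i
      out$area[k] <- area
      if (area > 0) {
        hit <- which(fg, arr.ind = TRUE)
        cy <- mean(row_idx[[i]][hit[, 1]] - 0.5)
        cx <- mean(col_idx[[i]][hit[, 2]] - 0.5)
        out$centroid_x[k] <- cx
        out$centroid_y[k] <- cy
        out$up[k] <- as.integer(cy < regions$cy[i])
      }
      out$move[k] <- as.integer(area >= amin)
      out$valid[k] <- TRUE
    }
    out
  }

  get_safe <- function(i) {
    tryCatch(get_channel(series$get(i), ch), error = function(e) {
      warning(sprintf("frame %d unreadable, flagging affected pairs: %s",
                      i, conditionMessage(e)), call. = FALSE)
      NULL
    })
  }

  if (config$mode == "background") {
    bg <- median_background(series, ch)
    n_out <- nf * nw
    later_frames <- seq_len(nf) - 1L
  } else {
    n_out <- (nf - 1L) * nw
    later_frames <- seq_len(nf - 1L)
  }

  out <- list(area = rep(NA_integer_, n_out),
              centroid_x = rep(NA_real_, n_out),
              centroid_y = rep(NA_real_, n_out),
              move = rep(NA_integer_, n_out),
              up = rep(NA_integer_, n_out),
              valid = rep(FALSE, n_out))

  if (config$mode == "background") {
    for (k in seq_len(nf)) {
      cur <- get_safe(k)
      if (!is.null(cur)) out <- measure_into(abs(cur - bg), (k - 1L) * nw, out)
    }
  } else {
    prev <- get_safe(1)
    for (k in 2:nf) {
      cur <- get_safe(k)
      if (!is.null(prev) && !is.null(cur)) {
        if (!identical(dim(prev), dim(cur)))
          stop(sprintf("frame %d dimension mismatch", k))
        out <- measure_into(abs(cur - prev), (k - 2L) * nw, out)
      }
      prev <- cur
    }
  }

  pp <- vapply(later_frames, frame_period, c(period = "", stimulus = ""))
  res <- data.frame(
    plate = rep(regions$plate, length(later_frames)),
    row = rep(regions$row, length(later_frames)),
    col = rep(regions$col, length(later_frames)),
    frame_pair = rep(later_frames, each = nw),
    period = rep(as.integer(pp["period", ]), each = nw),
    stimulus = rep(pp["stimulus", ], each = nw),
    area = out$area, centroid_x = out$centroid_x,
    centroid_y = out$centroid_y, move = out$move, up = out$up,
    valid = out$valid, stringsAsFactors = FALSE)
  res
}

# choose the analysis channel: configured channel, or automatic selection on
# a frame from the middle of the first stimulus period visible in the series
resolve_channel <- function(series, schedule, config, acclim_offset = 0L) {
  if (config$channel != "auto") return(channel_index(config$channel))
  stim <- schedule$periods[schedule$periods$stimulus != "none", ]
  if (nrow(stim) > 0) {
    fpp <- frames_per_period(schedule)
    f0 <- (stim$period[1] - 1L) * fpp + fpp %/% 2L   # 0-based mid-period frame
    idx <- f0 + acclim_offset + 1L                   # 1-based series index
    if (idx <= series$n) {
      frame <- tryCatch(series$get(idx), error = function(e) NULL)
      if (!is.null(frame) && length(dim(frame)) == 3) {
        ch <- select_channel(frame)
        if (!is.na(ch)) return(ch)
      }
    }
  }
  1L  # no stimulus visible: default to red
}
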