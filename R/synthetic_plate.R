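#' Simulated larva behavioral parameters
#'
#' The simulator treats each larva as a stochastic agent observed at the
#' frame interval: in each interval it displaces with probability `p_move`,
#' and when it does, the displacement direction is a mixture of a uniform
#' random direction (weight `1 - optomotor_gain`) and the current stimulus
#' direction (weight `optomotor_gain`). Gain 0 models a blind larva, gain
#' near 1 strong stimulus-following. A 5-dpf larva is about 4 mm long; the
#' rendered body models its dark, high-contrast head/yolk region as a rigid
#' ellipse (the translucent tail rarely crosses the detection threshold).
#'
#' @param p_move Probability of displacing in one frame interval, in [0, 1].
#' @param optomotor_gain Stimulus-following weight g in [0, 1].
#' @param step_length_mm Displacement per moving interval (mm). The source
#'   assay does not constrain larval speed; 1 mm per 6-s interval is a
#'   simulator convention.
#' @param body_axes_mm Ellipse semi-axes (major, minor) in mm for rendering.
#' @param body_intensity RGB triple of larva pixels; dark gray on the light
#'   plate background gives a frame-difference contrast of about 131,
#'   comfortably above the detection threshold of 25.
#' @return An object of class `larva_params`.
#' @export
larva_params <- function(p_move = 0.5, optomotor_gain = 0.8,
                         step_length_mm = 1,
                         body_axes_mm = c(1.1, 0.6),
                         body_intensity = c(60, 60, 60)) {
  if (p_move < 0 || p_move > 1) stop("p_move must be in [0, 1]")
  if (optomotor_gain < 0 || optomotor_gain > 1)
    stop("optomotor_gain must be in [0, 1]")
  if (step_length_mm <= 0) stop("step_length_mm must be positive")
  if (length(body_axes_mm) != 2 || any(body_axes_mm <= 0))
    stop("body_axes_mm must be two positive semi-axes")
  structure(list(p_move = p_move, optomotor_gain = optomotor_gain,
                 step_length_mm = step_length_mm,
                 body_axes_mm = as.numeric(body_axes_mm),
                 body_intensity = as.numeric(body_intensity)),
            class = "larva_params")
}

#' Named behavioral presets
#'
#' `"untreated"` is a typical healthy larva (moves in about half of all
#' 6-s intervals, strong optomotor following); `"immotile"` models complete
#' anesthesia/sedation (e.g. 612 uM tricaine or 80 uM diazepam);
#' `"hyperactive"` models an activity-increasing treatment; `"blind"` moves
#' normally but ignores the stimulus (gain 0), the dissociation seen with
#' vision-suppressing treatments.
#'
#' @param preset One of `"untreated"`, `"immotile"`, `"hyperactive"`,
#'   `"blind"`.
#' @return A `larva_params` object.
#' @export
larva_preset <- function(preset = c("untreated", "immotile", "hyperactive",
                                    "blind")) {
  switch(match.arg(preset),
         untreated = larva_params(p_move = 0.5, optomotor_gain = 0.8),
         immotile = larva_params(p_move = 0, optomotor_gain = 0),
         hyperactive = larva_params(p_move = 0.9, optomotor_gain = 0.8),
         blind = larva_params(p_move = 0.5, optomotor_gain = 0))
}

#' Rendering parameters for synthetic frames
#'
#' Controls how simulated scenes are rasterized into the 8-bit RGB frames the
#' detection stage consumes. `line_render_color` is the color the *camera
#' records* for the projected red lines: on the physical rig, projector
#' brightness and camera exposure are matched so that the red channel of the
#' red lines is nearly identical to the gray background, which is what makes
#' channel selection plus frame differencing blind to the moving stimulus.
#' The default (196, 60, 50) reproduces that property for the default
#' projected colors (lines RGB 255,0,0 on RGB 191,191,191).
#'
#' @param pixels_per_mm Rendering scale (the reference rig captures about
#'   20.7 px/mm; lower values render faster and remain well above the
#'   detection area cutoff for the default body size).
#' @param noise_sd Additive Gaussian intensity noise (8-bit units, 0 = none).
#' @param line_render_color RGB triple recorded for stimulus-line pixels.
#' @param background_render_color RGB recorded for the background; defaults
#'   to the projected background color.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(pixels_per_mm = 5, noise_sd = 0,
                        line_render_color = c(196, 60, 50),
                        background_render_color = c(191, 191, 191)) {
  if (pixels_per_mm <= 0) stop("pixels_per_mm must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(pixels_per_mm = pixels_per_mm, noise_sd = noise_sd,
                 line_render_color = as.numeric(line_render_color),
                 background_render_color = as.numeric(background_render_color)),
            class = "render_spec")
}

# well diameter of the shallow-well plate (mm); larva centers are confined to
# this circle minus the body minor semi-axis so the body stays inside the well
WELL_DIAMETER_MM <- 7.15

larva_bound_radius <- function(params) {
  WELL_DIAMETER_MM / 2 - params$body_axes_mm[2]
}

#' Advance one simulated larva by one frame interval
#'
#' With probability `p_move` the larva displaces by `step_length_mm` along a
#' unit vector `v / |v|` where `v = (1-g) u + g s`, `u` a uniform random
#' direction and `s` the stimulus direction (down = +y, up = -y; when the
#' stimulus is `"none"`, the direction is purely `u`). A displacement that
#' would leave the confinement circle is reflected off the wall (the outward
#' component of the direction is flipped and the full step re-taken, with any
#' residual radial excess clamped to the wall). Uses the current
#' R random number stream.
#'
#' @param position Numeric `c(x, y)` in mm, well-centered coordinates
#'   (y increases downward, matching image coordinates).
#' @param params A `larva_params`.
#' @param direction `"down"`, `"up"`, or `"none"`.
#' @return List with `position` (c(x, y)), `moved` (logical), and `heading`
#'   (radians; unchanged heading when the larva did not move).
#' @param heading Previous heading in radians (kept when not moving).
#' @export
step_larva <- function(position, params, direction = c("none", "down", "up"),
                       heading = 0) {
  direction <- match.arg(direction)
  if (stats::runif(1) >= params$p_move)
    return(list(position = position, moved = FALSE, heading = heading))
  theta <- stats::runif(1, 0, 2 * pi)
  u <- c(cos(theta), sin(theta))
  g <- params$optomotor_gain
  v <- if (direction == "none") u else {
    s <- if (direction == "down") c(0, 1) else c(0, -1)
    (1 - g) * u + g * s
  }
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) v <- u else v <- v / nv
  bound <- larva_bound_radius(params)
  newpos <- position + params$step_length_mm * v
  if (sum(newpos^2) > bound^2) {
    # bounce off the wall: flip the outward component of the direction and
    # take the full step, so a larva pushed against the wall still displaces
    # by a detectable amount instead of folding back onto itself
    rp <- sqrt(sum(position^2))
    if (rp > 1e-9) {
      nhat <- position / rp
      out <- sum(v * nhat)
      if (out > 0) v <- v - 2 * out * nhat
    }
    newpos <- position + params$step_length_mm * v
    r2 <- sqrt(sum(newpos^2))
    if (r2 > bound) newpos <- newpos * (bound / r2)  # graze: clamp to the wall
  }
  list(position = newpos, moved = TRUE, heading = atan2(v[2], v[1]))
}

# simulate a full trajectory for one larva; dirs is the per-interval stimulus
# direction vector (length n_frames - 1, the step into frame f uses dirs[f]).
simulate_one_trajectory <- function(n_frames, params, dirs) {
  bound <- larva_bound_radius(params)
  # initial position: uniform in the confinement disk
  repeat {
    p0 <- stats::runif(2, -bound, bound)
    if (sum(p0^2) <= bound^2) break
  }
  pos <- matrix(NA_real_, n_frames, 2)
  moved <- logical(n_frames)
  heading <- numeric(n_frames)
  pos[1, ] <- p0
  moved[1] <- NA
  heading[1] <- stats::runif(1, 0, 2 * pi)
  if (n_frames > 1) {
    cur <- list(position = p0, heading = heading[1])
    for (f in 2:n_frames) {
      cur <- step_larva(cur$position, params, dirs[f - 1], cur$heading)
      pos[f, ] <- cur$position
      moved[f] <- cur$moved
      heading[f] <- cur$heading
    }
  }
  list(pos = pos, moved = moved, heading = heading)
}

# deterministic per-larva RNG substreams: L'Ecuyer-CMRG streams assigned in
# (plate, row, col) order from the master seed, so results are independent of
# iteration order and reproducible from the seed alone.
larva_streams <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

with_rng_state <- function(state, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state, envir = globalenv())
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Assign treatment-group labels to plate rows
#'
#' The assay's group design is row-based: all 12 larvae in a physical row
#' receive the same treatment. Labels are recycled over rows in plate-major
#' order.
#'
#' @param layout A `plate_layout`.
#' @param labels Character vector of group labels, recycled across all rows.
#' @return Data.frame with columns `plate`, `row`, `group`.
#' @export
assign_row_groups <- function(layout, labels) {
  total_rows <- layout$n_plates * layout$rows_per_plate
  data.frame(plate = rep(seq_len(layout$n_plates), each = layout$rows_per_plate),
             row = rep(seq_len(layout$rows_per_plate), layout$n_plates),
             group = rep_len(as.character(labels), total_rows),
             stringsAsFactors = FALSE)
}

#' Simulate a full plate experiment
#'
#' Generates per-larva trajectories for every well under the given schedule
#' and returns (a) a ground-truth table with true positions, per-interval
#' moved flags and generating parameters, and (b) a lazily rendered frame
#' series suitable for [run_detection()]. Fully reproducible from `seed`:
#' each larva draws from its own RNG substream derived from
#' `(seed, plate, row, col)`.
#'
#' The stimulus direction applied to the step into frame `f` is the direction
#' of the period containing frame `f`, matching how detection attributes a
#' frame difference to the later frame.
#'
#' @param layout A `plate_layout`, typically from [synthetic_layout()].
#' @param schedule A `period_schedule`.
#' @param params A single `larva_params` for all wells, or a named list of
#'   `larva_params` keyed by group label, combined with `group_map`.
#' @param group_map Optional data.frame (`plate`, `row`, `group`) mapping rows
#'   to group labels, e.g. from [assign_row_groups()]; required when `params`
#'   is a list.
#' @param seed Integer seed.
#' @param stimulus A `stimulus_spec`.
#' @param render A `render_spec`.
#' @param frames_dir Optional directory; when given, frames are written as
#'   numbered PNGs (`frame_000001.png`, ...) together with `ground_truth.csv`
#'   and the generating configuration.
#' @return An object of class `omr_simulation`: list with `truth` (data.frame:
#'   plate, row, col, group, frame, x_mm, y_mm, moved, p_move, gain), `series`
#'   (a `frame_series`), plus the layout, schedule, stimulus, render and seed
#'   used.
#' @examples
#' layout <- synthetic_layout(n_plates = 1, rows_per_plate = 1, wells_per_row = 4)
#' sched <- period_schedule(period_length = 60)
#' sim <- simulate_experiment(layout, sched, larva_preset("untreated"), seed = 1)
#' head(sim$truth)
#' @export
simulate_experiment <- function(layout, schedule, params = larva_preset("untreated"),
                                group_map = NULL, seed = 1,
                                stimulus = stimulus_spec(),
                                render = render_spec(),
                                frames_dir = NULL) {
  stopifnot(inherits(layout, "plate_layout"), inherits(schedule, "period_schedule"))
  if (inherits(params, "larva_params")) {
    if (is.null(group_map)) group_map <- assign_row_groups(layout, "all")
    params <- stats::setNames(rep(list(params), length(unique(group_map$group))),
                              unique(group_map$group))
  } else {
    if (is.null(group_map))
      stop("group_map is required when params is a list of groups")
    if (!all(group_map$group %in% names(params)))
      stop("every group in group_map needs an entry in params")
  }
  wells <- well_regions(layout)
  wells <- wells[order(wells$plate, wells$row, wells$col), ]
  key <- paste(wells$plate, wells$row)
  gm_key <- paste(group_map$plate, group_map$row)
  wells$group <- group_map$group[match(key, gm_key)]
  if (anyNA(wells$group)) stop("group_map does not cover all layout rows")

  nf <- recording_frames(schedule)
  dirs <- period_of_frame(schedule, seq_len(nf - 1))$stimulus  # step into frame f
  streams <- larva_streams(seed, nrow(wells))

  n <- nrow(wells)
  traj <- array(NA_real_, c(n, nf, 2))
  headings <- matrix(NA_real_, n, nf)
  moved <- matrix(NA, n, nf)
  for (i in seq_len(n)) {
    pw <- params[[wells$group[i]]]
    tr <- with_rng_state(streams[[i]],
                         simulate_one_trajectory(nf, pw, dirs))
    traj[i, , ] <- tr$pos
    moved[i, ] <- tr$moved
    headings[i, ] <- tr$heading
  }

  p_move <- vapply(wells$group, function(g) params[[g]]$p_move, numeric(1))
  gain <- vapply(wells$group, function(g) params[[g]]$optomotor_gain, numeric(1))
  truth <- data.frame(
    plate = rep(wells$plate, each = nf), row = rep(wells$row, each = nf),
    col = rep(wells$col, each = nf), group = rep(wells$group, each = nf),
    frame = rep(seq_len(nf) - 1L, n),
    x_mm = as.vector(t(traj[, , 1])), y_mm = as.vector(t(traj[, , 2])),
    moved = as.integer(as.vector(t(moved))),
    p_move = rep(p_move, each = nf), gain = rep(gain, each = nf),
    stringsAsFactors = FALSE)

  fpp <- frames_per_period(schedule)
  pmap <- period_of_frame(schedule, seq_len(nf) - 1L)
  body <- lapply(wells$group, function(g) params[[g]])
  sim_env <- list(wells = wells, traj = traj, headings = headings,
                  body = body, layout = layout, stimulus = stimulus,
                  render = render, schedule = schedule, pmap = pmap, seed = seed)
  get_frame <- function(i) {
    if (i < 1 || i > nf) stop(sprintf("frame %d out of range [1, %d]", i, nf))
    dir <- sim_env$pmap$stimulus[i]
    t_in_period <- ((i - 1L) %% fpp) * schedule$frame_interval
    states <- data.frame(
      cx = sim_env$wells$cx, cy = sim_env$wells$cy,
      x_mm = sim_env$traj[, i, 1], y_mm = sim_env$traj[, i, 2],
      heading = sim_env$headings[, i])
    frame <- render_frame(states, sim_env$layout, sim_env$stimulus,
                          sim_env$render, t = t_in_period, direction = dir,
                          body = sim_env$body, noise_key = sim_env$seed + i)
    frame
  }
  series <- frame_series(get_frame, nf, schedule$frame_interval)

  sim <- structure(list(truth = truth, series = series, layout = layout,
                        schedule = schedule, stimulus = stimulus,
                        render = render, group_map = group_map,
                        params = params, seed = seed),
                   class = "omr_simulation")
  if (!is.null(frames_dir)) write_simulation(sim, frames_dir)
  sim
}

#' @export
print.omr_simulation <- function(x, ...) {
  cat(sprintf("omr_simulation: %d larvae x %d frames (seed %d)\n",
              nrow(x$truth) / x$series$n, x$series$n, x$seed))
  invisible(x)
}

#' Render one frame of a simulated scene
#'
#' Fills the background, draws the horizontal stimulus lines at the offset
#' for time `t` (only when `direction` is not `"none"`), draws each larva as
#' a filled ellipse rotated to its heading, then optionally adds Gaussian
#' intensity noise and clips to [0, 255].
#'
#' @param states Data.frame with one larva per row: `cx`, `cy` (well center,
#'   px), `x_mm`, `y_mm` (well-centered position), and optionally `heading`
#'   (radians, default 0).
#' @param layout A `plate_layout`; image dimensions come from its
#'   `image_width`/`image_height` attributes (as produced by
#'   [synthetic_layout()]) or, failing that, from the row outlines plus a
#'   border equal to the leading margin.
#' @param stimulus A `stimulus_spec`.
#' @param render A `render_spec`.
#' @param t Seconds since the current stimulus phase started.
#' @param direction Stimulus direction for this frame.
#' @param body A single `larva_params` or a list, one per state row.
#' @param noise_key Optional integer; when noise is enabled, seeds a local
#'   RNG stream so the same frame renders identically on repeated access.
#' @return Numeric array `height x width x 3`, intensities in 0-255.
#' @export
render_frame <- function(states, layout, stimulus = stimulus_spec(),
                         render = render_spec(), t = 0,
                         direction = c("none", "down", "up"),
                         body = larva_params(), noise_key = NULL) {
  direction <- match.arg(direction)
  s <- render$pixels_per_mm
  w <- attr(layout, "image_width")
  h <- attr(layout, "image_height")
  if (is.null(w) || is.null(h)) {
    # derive from the outlines with a border matching the leading margin
    ro <- layout$row_outlines
    w <- ceiling(max(ro$x1) + min(ro$x0))
    h <- ceiling(max(ro$y1) + min(ro$y0))
  }
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- render$background_render_color[ch]

  if (direction != "none") {
    off <- stimulus_offset(stimulus, t, direction)
    pitch <- pattern_pitch(stimulus)
    y_mm <- (seq_len(h) - 0.5) / s               # pixel-row centers in mm
    line_rows <- ((y_mm - off) %% pitch) < stimulus$line_thickness_mm
    if (any(line_rows))
      for (ch in 1:3) img[line_rows, , ch] <- render$line_render_color[ch]
  }

  if (nrow(states) > 0) {
    if (!inherits(body, "larva_params") && length(body) != nrow(states))
      stop("body must be one larva_params or one per larva")
    heading <- if ("heading" %in% names(states)) states$heading else rep(0, nrow(states))
    for (i in seq_len(nrow(states))) {
      bp <- if (inherits(body, "larva_params")) body else body[[i]]
      px <- states$cx[i] + states$x_mm[i] * s
      py <- states$cy[i] + states$y_mm[i] * s
      a <- bp$body_axes_mm[1] * s
      b <- bp$body_axes_mm[2] * s
      r0 <- floor(py - a); r1 <- ceiling(py + a)
      c0 <- floor(px - a); c1 <- ceiling(px + a)
      if (r0 < 0 || c0 < 0 || r1 > h || c1 > w)
        stop(sprintf("render error: larva %d outside image bounds", i))
      rows <- (r0 + 1L):r1; cols <- (c0 + 1L):c1
      dy <- (rows - 0.5) - py
      dx <- (cols - 0.5) - px
      ct <- cos(heading[i]); st <- sin(heading[i])
      # rotated-ellipse interior test on the local patch grid
      DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
      DY <- matrix(dy, length(rows), length(cols))
      inside <- ((DX * ct + DY * st) / a)^2 + ((-DX * st + DY * ct) / b)^2 <= 1
      if (any(inside))
        for (ch in 1:3) {
          patch <- img[rows, cols, ch]
          patch[inside] <- bp$body_intensity[ch]
          img[rows, cols, ch] <- patch
        }
    }
  }

  if (render$noise_sd > 0) {
    add_noise <- function() {
      img <<- img + array(stats::rnorm(length(img), 0, render$noise_sd), dim(img))
    }
    if (is.null(noise_key)) add_noise()
    else with_rng_state(local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(noise_key %% .Machine$integer.max)
      s <- get(".Random.seed", globalenv())
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
      s
    }), add_noise())
    img[img < 0] <- 0
    img[img > 255] <- 255
  }
  img
}

#' Measure the rendered line-pattern displacement between two frames
#'
#' Recovers how far the stimulus pattern travelled between two frames by
#' maximizing the row-wise cross-correlation over circular shifts of the
#' row-mean intensity profile, searching shifts from 0 up to one pattern
#' pitch in the direction of motion. Uses the channel with the strongest
#' line/background contrast (green for the default colors).
#'
#' @param frame_a,frame_b RGB arrays rendered `dt` seconds apart.
#' @param pixels_per_mm Rendering scale used for the frames.
#' @param stimulus The `stimulus_spec` (for the pattern pitch).
#' @param direction Direction the pattern moved between the frames.
#' @param channel Channel index to correlate (default 2, green).
#' @return List with `shift_px` and `shift_mm`.
#' @export
measure_line_shift <- function(frame_a, frame_b, pixels_per_mm,
                               stimulus = stimulus_spec(),
                               direction = c("down", "up"), channel = 2) {
  direction <- match.arg(direction)
  pa <- rowMeans(frame_a[, , channel])
  pb <- rowMeans(frame_b[, , channel])
  n <- length(pa)
  max_shift <- round(pattern_pitch(stimulus) * pixels_per_mm) - 1L
  sgn <- if (direction == "down") 1L else -1L
  cors <- vapply(0:max_shift, function(k) {
    idx <- ((seq_len(n) - 1L - sgn * k) %% n) + 1L  # pattern moved by sgn*k rows
    stats::cor(pa[idx], pb)
  }, numeric(1))
  k <- which.max(cors) - 1L
  list(shift_px = k, shift_mm = k / pixels_per_mm)
}

#' Write a simulation to disk
#'
#' Writes numbered PNG frames (`frame_000001.png`, ...), the ground-truth
#' table (`ground_truth.csv`) and the generating configuration
#' (`simulation_config.yaml`).
#'
#' @param sim An `omr_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "omr_simulation"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory: %s", dir))
  for (i in seq_len(sim$series$n)) {
    f <- sim$series$get(i)
    png::writePNG(f / 255, file.path(dir, sprintf("frame_%06d.png", i)))
  }
  utils::write.csv(sim$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  cfg <- list(seed = sim$seed,
              layout = layout_to_config(sim$layout),
              schedule = list(frame_interval = sim$schedule$frame_interval,
                              period_length = sim$schedule$period_length,
                              periods = sim$schedule$periods$stimulus),
              groups = stats::setNames(
                lapply(sim$params, function(p)
                  list(p_move = p$p_move, optomotor_gain = p$optomotor_gain,
                       step_length_mm = p$step_length_mm)),
                names(sim$params)))
  yaml::write_yaml(cfg, file.path(dir, "simulation_config.yaml"))
  invisible(dir)
}

#' Detection-free behavioral simulation of larva scores
#'
#' Simulates trajectories only (no rendering or image analysis) and scores
#' them directly from ground truth: activity is the moved fraction, the up
#' flag is `y < 0`. Intended for statistical calibration studies (type-I
#' error, power curves) where thousands of larvae are needed and the imaging
#' stages have already been validated separately.
#'
#' @param n Number of larvae.
#' @param params A `larva_params`.
#' @param schedule A `period_schedule`.
#' @param seed Integer seed.
#' @return A larva-score data.frame compatible with [bin_scores()] /
#'   [chi2_homogeneity()] inputs: columns `id`, `activity`,
#'   `activity_headline`, `eo`, `eo_valid`.
#' @export
simulate_scores <- function(n, params, schedule, seed = 1) {
  nf <- recording_frames(schedule)
  dirs <- period_of_frame(schedule, seq_len(nf - 1))$stimulus
  pmap <- period_of_frame(schedule, seq_len(nf) - 1L)
  streams <- larva_streams(seed, n)
  stim_periods <- schedule$periods$period[schedule$periods$stimulus != "none"]
  first_period_frames <- which(pmap$period == 1L)[-1]  # intervals in period 1
  out <- data.frame(id = seq_len(n), activity = NA_real_,
                    activity_headline = NA_real_, eo = NA_real_,
                    eo_valid = NA)
  for (i in seq_len(n)) {
    tr <- with_rng_state(streams[[i]],
                         simulate_one_trajectory(nf, params, dirs))
    moved <- tr$moved[-1]
    up <- as.integer(tr$pos[, 2] < 0)
    out$activity[i] <- 100 * mean(moved)
    out$activity_headline[i] <- 100 * mean(tr$moved[first_period_frames])
    up_pct <- vapply(stim_periods, function(p)
      100 * mean(up[pmap$period == p]), numeric(1))
    out$eo[i] <- eo_statistic(stim_periods, up_pct)
    out$eo_valid[i] <- is.finite(out$eo[i]) && out$activity[i] >= 5
  }
  out
}
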