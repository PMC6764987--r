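# build a one-color test frame with optional horizontal line rows
flat_frame <- function(h, w, bg, line_color = NULL, line_rows = NULL) {
  f <- array(0, c(h, w, 3))
  for (ch in 1:3) f[, , ch] <- bg[ch]
  if (!is.null(line_rows))
    for (ch in 1:3) f[line_rows, , ch] <- line_color[ch]
  f
}

test_that("channel selection minimizes stimulus/background contrast", {
  # gray background, pure red lines: red contrast 64 beats green/blue's 191
  f <- flat_frame(40, 30, c(191, 191, 191), c(255, 0, 0), 1:5)
  expect_equal(select_channel(f), 1L)

  # blue lines: blue channel has contrast 64, red/green 191
  f <- flat_frame(40, 30, c(191, 191, 191), c(0, 0, 255), 1:5)
  expect_equal(select_channel(f, stimulus_spec(line_color = c(0, 0, 255))), 3L)

  # grayscale stimulus: all contrasts equal, tie-break picks red
  f <- flat_frame(40, 30, c(191, 191, 191), c(100, 100, 100), 1:5)
  expect_equal(select_channel(f, stimulus_spec(line_color = c(100, 100, 100))), 1L)

  # no line pixels at all: NA so the caller falls back to its configured channel
  f <- flat_frame(40, 30, c(191, 191, 191))
  expect_true(is.na(select_channel(f)))
})

test_that("frame difference is absolute, symmetric, and shape-checked", {
  a <- matrix(191, 10, 10)
  expect_true(all(frame_difference(a, a) == 0))
  b <- a; b[3, 4] <- 60
  d <- frame_difference(a, b)
  expect_equal(d[3, 4], 131)            # |191 - 60|
  expect_equal(frame_difference(a, b), frame_difference(b, a))
  expect_error(frame_difference(a, matrix(0, 5, 5)), "dimension mismatch")
})

test_that("frame difference equals a brute-force per-pixel loop", {
  set.seed(42)
  for (rep in 1:5) {
    a <- matrix(sample(0:255, 400, TRUE), 20, 20)
    b <- matrix(sample(0:255, 400, TRUE), 20, 20)
    oracle <- matrix(0, 20, 20)
    for (i in 1:20) for (j in 1:20) oracle[i, j] <- abs(a[i, j] - b[i, j])
    expect_equal(frame_difference(a, b), oracle, ignore_attr = TRUE)
  }
})

test_that("background subtraction detects static structure against a median", {
  frames <- list(matrix(191, 8, 8), matrix(191, 8, 8), matrix(191, 8, 8))
  frames[[2]][4, 4] <- 60               # transient dark pixel
  series <- frame_series(function(i) frames[[i]], 3)
  bg <- median_background(series)
  expect_true(all(bg == 191))           # median of the constant majority
  d <- background_subtract(frames[[2]], bg)
  expect_equal(d[4, 4], 131)
  expect_equal(sum(d != 0), 1)
  expect_true(all(background_subtract(frames[[1]], bg) == 0))
})

test_that("measure_well applies the 20-px movement cutoff at threshold 25", {
  layout <- tiny_layout()
  regs <- well_regions(layout)
  dims <- c(attr(layout, "image_height"), attr(layout, "image_width"))
  cfg <- detection_config()

  # exactly 20 suprathreshold pixels: a movement
  d <- blob_diff_image(regs[1, ], 20, 131, dims)
  m <- measure_well(d, regs[1, ], cfg)
  expect_equal(m$area, 20)
  expect_equal(m$move, 1L)

  # 19 pixels: not a movement, but area and centroid still measured
  d <- blob_diff_image(regs[1, ], 19, 131, dims)
  m <- measure_well(d, regs[1, ], cfg)
  expect_equal(m$area, 19)
  expect_equal(m$move, 0L)
  expect_false(is.na(m$centroid_x))

  # intensity 24 is below the 25-255 threshold window: nothing is foreground
  d <- blob_diff_image(regs[1, ], 100, 24, dims)
  m <- measure_well(d, regs[1, ], cfg)
  expect_equal(m$area, 0)
  expect_equal(m$move, 0L)
  expect_true(is.na(m$centroid_x))
})

test_that("the centroid is the unweighted mean of suprathreshold pixels", {
  reg <- data.frame(x0 = 0, y0 = 0, x1 = 20, y1 = 20, cx = 10, cy = 10)
  d <- matrix(0, 20, 20)
  d[3, 5] <- 200; d[7, 9] <- 200        # pixel centers (4.5,2.5) and (8.5,6.5)
  m <- measure_well(d, reg, detection_config(move_area_min = 1))
  expect_equal(m$centroid_x, mean(c(4.5, 8.5)))
  expect_equal(m$centroid_y, mean(c(2.5, 6.5)))
})

test_that("up/down classification compares centroid y to the well center", {
  reg <- data.frame(x0 = 0, y0 = 0, x1 = 100, y1 = 100, cx = 50, cy = 50)
  expect_equal(classify_up(data.frame(centroid_x = 50, centroid_y = 10), reg), 1L)
  expect_equal(classify_up(data.frame(centroid_x = 50, centroid_y = 90), reg), 0L)
  # exact tie classifies down, deterministically
  expect_equal(classify_up(data.frame(centroid_x = 50, centroid_y = 50), reg), 0L)
  expect_true(is.na(classify_up(data.frame(centroid_x = NA_real_,
                                           centroid_y = NA_real_), reg)))
})

test_that("raising thresholds never increases movement counts", {
  layout <- tiny_layout()
  regs <- well_regions(layout)
  dims <- c(attr(layout, "image_height"), attr(layout, "image_width"))
  set.seed(42)
  d <- matrix(sample(0:60, prod(dims), TRUE), dims[1], dims[2])
  moves <- function(thr, amin) {
    cfg <- detection_config(diff_threshold = thr, move_area_min = amin)
    sum(vapply(seq_len(nrow(regs)),
               function(i) measure_well(d, regs[i, ], cfg)$move, integer(1)))
  }
  for (thr in c(10, 25, 40)) {
    expect_gte(moves(thr, 10), moves(thr, 20))
    expect_gte(moves(thr, 20), moves(thr, 40))
  }
  for (amin in c(5, 20)) {
    expect_gte(moves(10, amin), moves(25, amin))
    expect_gte(moves(25, amin), moves(40, amin))
  }
})

test_that("run_detection produces one row per well and frame pair", {
  sim <- test_sim()
  res <- test_detection_results()
  nw <- n_wells(sim$layout)
  expect_equal(nrow(res), nw * (sim$series$n - 1))
  expect_setequal(unique(res$frame_pair), 1:(sim$series$n - 1))
  expect_true(all(res$valid))
  # period/stimulus attribution follows the later frame of each pair
  p <- period_of_frame(sim$schedule, res$frame_pair)
  expect_equal(res$period, p$period)
  expect_equal(res$stimulus, p$stimulus)
})

test_that("a static scene yields no movements anywhere", {
  layout <- tiny_layout()
  regs <- well_regions(layout)
  st <- data.frame(cx = regs$cx, cy = regs$cy,
                   x_mm = rep(0, nrow(regs)), y_mm = rep(0, nrow(regs)))
  f <- render_frame(st, layout, stimulus_spec(), render_spec(), direction = "none")
  series <- frame_series(function(i) f, 5)
  res <- run_detection(series, layout, period_schedule(period_length = 30,
                                                       n_blank = 1),
                       detection_config())
  expect_true(all(res$move == 0))
  expect_true(all(res$area == 0))
})

test_that("moving stimulus lines are invisible to detection in empty wells", {
  # the camera-matched line color keeps the red-channel line/background
  # difference below threshold, so a well without a larva never fires even
  # though the lines sweep through it between frames
  layout <- tiny_layout()
  empty <- data.frame(cx = numeric(0), cy = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0))
  sched <- period_schedule(period_length = 30, n_blank = 0, n_stimulus = 4)
  series <- frame_series(function(i) {
    p <- period_of_frame(sched, i - 1)
    render_frame(empty, layout, stimulus_spec(), render_spec(),
                 t = (i - 1) * 6, direction = p$stimulus)
  }, 10)
  res <- run_detection(series, layout, sched)
  expect_true(all(res$move == 0))
})

test_that("detection matches simulator ground truth on noise-free renders", {
  sim <- test_sim()
  res <- test_detection_results()
  truth <- truth_with_displacement(sim$truth)
  m <- merge(res, truth[truth$frame >= 1, ],
             by.x = c("plate", "row", "col", "frame_pair"),
             by.y = c("plate", "row", "col", "frame"))
  # a larva that did not displace can never fire the detector
  expect_equal(sum(m$move == 1 & m$moved == 0), 0)
  # every resolvable displacement (>= 0.5 mm net) is detected; smaller net
  # displacements (wall reflections folding the step back) legitimately fall
  # below the 20-px area cutoff, which exists to ignore sub-threshold motion
  resolvable <- m$moved == 1 & m$displacement >= 0.5
  expect_true(all(m$move[resolvable] == 1))
  # and the vast majority of all true movements are recovered
  expect_gt(mean(m$move[m$moved == 1] == 1), 0.95)
})

test_that("an unreadable frame flags its pairs instead of dropping them", {
  layout <- tiny_layout()
  regs <- well_regions(layout)
  st <- data.frame(cx = regs$cx, cy = regs$cy,
                   x_mm = rep(0, nrow(regs)), y_mm = rep(0, nrow(regs)))
  f <- render_frame(st, layout, stimulus_spec(), render_spec(), direction = "none")
  series <- frame_series(function(i) {
    if (i == 3) stop("disk error") else f
  }, 5)
  expect_warning(
    res <- run_detection(series, layout,
                         period_schedule(period_length = 30, n_blank = 1),
                         detection_config()),
    "frame 3 unreadable")
  nw <- nrow(regs)
  bad <- res$frame_pair %in% c(2, 3)    # pairs (2,3) and (3,4)
  expect_true(all(!res$valid[bad]))
  expect_true(all(is.na(res$area[bad])))
  expect_true(all(res$valid[!bad]))
})
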