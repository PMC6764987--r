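# Shared fixtures. The expensive simulated experiment is built once per test
# run and reused across files.

fixture_env <- new.env(parent = emptyenv())

# small but complete assay: 12 wells in 2 rows, 12 one-minute periods
# (2 blank + 10 alternating), 120 frames at the standard 6-s interval
tiny_layout <- function(pixels_per_mm = 5) {
  synthetic_layout(n_plates = 1, rows_per_plate = 2, wells_per_row = 6,
                   pixels_per_mm = pixels_per_mm)
}

tiny_schedule <- function() period_schedule(period_length = 60)

test_sim <- function() {
  if (is.null(fixture_env$sim))
    fixture_env$sim <- simulate_experiment(tiny_layout(), tiny_schedule(),
                                           larva_preset("untreated"), seed = 7)
  fixture_env$sim
}

test_detection_results <- function() {
  if (is.null(fixture_env$results)) {
    sim <- test_sim()
    fixture_env$results <- run_detection(sim$series, sim$layout, sim$schedule)
  }
  fixture_env$results
}

# per-interval net displacement added to a ground-truth table
truth_with_displacement <- function(truth) {
  truth <- truth[order(truth$plate, truth$row, truth$col, truth$frame), ]
  id <- paste(truth$plate, truth$row, truth$col)
  truth$displacement <- unlist(lapply(split(seq_len(nrow(truth)), id)[unique(id)],
    function(ii) c(NA, sqrt(diff(truth$x_mm[ii])^2 + diff(truth$y_mm[ii])^2))))
  truth
}

# uniform-intensity square blob of a given pixel area in an otherwise zero
# difference image covering one well region
blob_diff_image <- function(region, area, intensity, img_dim) {
  d <- matrix(0, img_dim[1], img_dim[2])
  side <- floor(sqrt(area))
  extra <- area - side^2
  r0 <- floor((region$y0 + region$y1) / 2) - floor(side / 2)
  c0 <- floor((region$x0 + region$x1) / 2) - floor(side / 2)
  d[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side)] <- intensity
  if (extra > 0) d[r0 + side + 1, (c0 + 1):(c0 + extra)] <- intensity
  d
}
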