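#' Plate layout: plates, rows, and per-well analysis regions
#'
#' A `plate_layout` describes the geometry of one imaging session: how many
#' plates are in the field of view, how many rows each plate has, how many
#' wells each row holds, and where each physical row sits in the image
#' (a user-outlined bounding box per row, as drawn during setup).
#'
#' Coordinate convention: image origin at the top-left corner, x increasing
#' rightward, y increasing downward; all rectangles are half-open
#' `[x0, x1) x [y0, y1)` in pixel units. "Up" within a well therefore means
#' smaller y.
#'
#' @param n_plates Number of plates in the image.
#' @param rows_per_plate Rows per plate (8 for a 96-well plate in landscape).
#' @param wells_per_row Wells per row (12 for a 96-well plate).
#' @param row_outlines A data.frame with columns `x0, y0, x1, y1` (one row per
#'   physical plate row, ordered plate-major then top-to-bottom), or a matrix
#'   with those four columns. Must contain `n_plates * rows_per_plate` rows.
#' @param pixel_scale Optional micrometres per pixel (the reference rig
#'   resolves 48.3 um/px). Used to convert the 7.15 mm well diameter into
#'   pixels when circular masking is requested.
#' @return An object of class `plate_layout`.
#' @examples
#' layout <- synthetic_layout(n_plates = 1, rows_per_plate = 2)
#' nrow(well_regions(layout))
#' @export
plate_layout <- function(n_plates, rows_per_plate, wells_per_row, row_outlines,
                         pixel_scale = NULL) {
  n_plates <- as.integer(n_plates)
  rows_per_plate <- as.integer(rows_per_plate)
  wells_per_row <- as.integer(wells_per_row)
  if (n_plates < 1L || rows_per_plate < 1L || wells_per_row < 1L)
    stop("invalid geometry: plate, row and well counts must be >= 1")
  row_outlines <- as.data.frame(row_outlines)
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(row_outlines)))
    stop("row_outlines must have columns x0, y0, x1, y1")
  row_outlines <- row_outlines[, need]
  if (nrow(row_outlines) != n_plates * rows_per_plate)
    stop(sprintf("invalid geometry: expected %d row outlines, got %d",
                 n_plates * rows_per_plate, nrow(row_outlines)))
  if (any(row_outlines$x1 <= row_outlines$x0) ||
      any(row_outlines$y1 <= row_outlines$y0))
    stop("invalid geometry: row outlines must have positive width and height")
  structure(
    list(n_plates = n_plates, rows_per_plate = rows_per_plate,
         wells_per_row = wells_per_row, row_outlines = row_outlines,
         pixel_scale = pixel_scale),
    class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d plate(s) x %d row(s) x %d well(s) = %d wells\n",
              x$n_plates, x$rows_per_plate, x$wells_per_row,
              x$n_plates * x$rows_per_plate * x$wells_per_row))
  if (!is.null(x$pixel_scale))
    cat(sprintf("  pixel scale: %.1f um/px\n", x$pixel_scale))
  invisible(x)
}

#' Total number of wells in a layout
#' @param layout A `plate_layout`.
#' @return Integer well count.
#' @export
n_wells <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  layout$n_plates * layout$rows_per_plate * layout$wells_per_row
}

#' Partition a row outline into equal-width well regions
#'
#' Splits one user-outlined row bounding box into `n_wells` adjacent regions
#' of equal width. When the outline width is not divisible by `n_wells`, the
#' remainder pixels are distributed one per region starting from the leftmost
#' region, so region widths differ by at most one pixel and the regions tile
#' the outline exactly.
#'
#' @param outline Numeric vector `c(x0, y0, x1, y1)` (half-open rectangle) or
#'   a one-row data.frame with those columns.
#' @param n_wells Number of wells in the row.
#' @return A data.frame with one region per row: columns `col`, `x0`, `y0`,
#'   `x1`, `y1`, `cx`, `cy` (geometric center), ordered left to right.
#' @examples
#' partition_row(c(0, 0, 1200, 100), 12)  # twelve 100-px regions
#' @export
partition_row <- function(outline, n_wells) {
  if (is.data.frame(outline)) outline <- unlist(outline[1, c("x0", "y0", "x1", "y1")])
  outline <- as.numeric(outline)
  n_wells <- as.integer(n_wells)
  if (length(outline) != 4L) stop("outline must be c(x0, y0, x1, y1)")
  x0 <- outline[1]; y0 <- outline[2]; x1 <- outline[3]; y1 <- outline[4]
  if (n_wells < 1L) stop("invalid geometry: n_wells must be >= 1")
  w <- x1 - x0
  if (w <= 0 || y1 <= y0) stop("invalid geometry: degenerate outline")
  if (w < n_wells) stop("invalid geometry: outline narrower than one pixel per well")
  base <- floor(w / n_wells)
  extra <- w - base * n_wells          # leftmost regions get one extra pixel
  widths <- rep(base, n_wells) + c(rep(1, extra), rep(0, n_wells - extra))
  xr <- x0 + cumsum(c(0, widths))
  data.frame(col = seq_len(n_wells),
             x0 = xr[-length(xr)], y0 = y0, x1 = xr[-1], y1 = y1,
             cx = (xr[-length(xr)] + xr[-1]) / 2, cy = (y0 + y1) / 2)
}

#' Geometric center of a well region
#'
#' @param region A one-row data.frame (or list) with `x0, y0, x1, y1`.
#' @return Numeric `c(x, y)`; fractional coordinates are allowed.
#' @export
well_center <- function(region) {
  c(x = (region$x0 + region$x1) / 2, y = (region$y0 + region$y1) / 2)
}

#' Enumerate all well regions of a layout
#'
#' Applies [partition_row()] to every row outline and indexes the resulting
#' regions by plate, row, and column. Within a row, regions are disjoint and
#' tile the row outline exactly; across the layout each pixel inside an
#' outline belongs to exactly one well.
#'
#' @param layout A `plate_layout`.
#' @param mask_shape `"rectangle"` (default) measures the full rectangular
#'   region; `"circle"` restricts analysis to the inscribed circular well of
#'   diameter 7.15 mm (requires `pixel_scale`). The rectangular default
#'   mirrors region-based measurement of thresholded selections in standard
#'   image-analysis macros.
#' @return Data.frame with columns `plate`, `row`, `col`, `x0`, `y0`, `x1`,
#'   `y1`, `cx`, `cy` and attribute `mask_shape` (plus `mask_radius_px` for
#'   circular masks).
#' @export
well_regions <- function(layout, mask_shape = c("rectangle", "circle")) {
  stopifnot(inherits(layout, "plate_layout"))
  mask_shape <- match.arg(mask_shape)
  out <- vector("list", nrow(layout$row_outlines))
  for (i in seq_len(nrow(layout$row_outlines))) {
    regs <- partition_row(layout$row_outlines[i, ], layout$wells_per_row)
    regs$plate <- (i - 1L) %/% layout$rows_per_plate + 1L
    regs$row <- (i - 1L) %% layout$rows_per_plate + 1L
    out[[i]] <- regs
  }
  out <- do.call(rbind, out)
  out <- out[, c("plate", "row", "col", "x0", "y0", "x1", "y1", "cx", "cy")]
  rownames(out) <- NULL
  attr(out, "mask_shape") <- mask_shape
  if (mask_shape == "circle") {
    if (is.null(layout$pixel_scale))
      stop("circular masking requires pixel_scale (um per pixel)")
    attr(out, "mask_radius_px") <- (7.15 / 2) * 1000 / layout$pixel_scale
  }
  out
}

#' Build a regular synthetic layout
#'
#' Convenience constructor for simulated experiments: plates are stacked
#' vertically, each row outline spans `wells_per_row` wells at a fixed
#' center-to-center pitch (9 mm for a standard 96-well plate).
#'
#' @param n_plates,rows_per_plate,wells_per_row Plate grid; defaults give the
#'   four-plate, 384-well configuration.
#' @param pixels_per_mm Rendering scale in pixels per millimetre.
#' @param well_pitch_mm Well center-to-center spacing.
#' @param plate_gap_mm Vertical gap between plates.
#' @param margin_mm Image border around the outermost outlines.
#' @return A `plate_layout` whose `pixel_scale` is `1000 / pixels_per_mm` and
#'   that carries the implied image size as attributes `image_width` and
#'   `image_height` (pixels).
#' @export
synthetic_layout <- function(n_plates = 4, rows_per_plate = 8, wells_per_row = 12,
                             pixels_per_mm = 5, well_pitch_mm = 9,
                             plate_gap_mm = 4, margin_mm = 2) {
  s <- pixels_per_mm
  row_w <- round(wells_per_row * well_pitch_mm * s)
  row_h <- round(well_pitch_mm * s)
  margin <- round(margin_mm * s)
  gap <- round(plate_gap_mm * s)
  outlines <- vector("list", n_plates * rows_per_plate)
  k <- 0L
  y <- margin
  for (p in seq_len(n_plates)) {
    for (r in seq_len(rows_per_plate)) {
      k <- k + 1L
      outlines[[k]] <- data.frame(x0 = margin, y0 = y,
                                  x1 = margin + row_w, y1 = y + row_h)
      y <- y + row_h
    }
    y <- y + gap
  }
  layout <- plate_layout(n_plates, rows_per_plate, wells_per_row,
                         do.call(rbind, outlines), pixel_scale = 1000 / s)
  attr(layout, "pixels_per_mm") <- s
  attr(layout, "image_width") <- 2L * margin + row_w
  attr(layout, "image_height") <- y - gap + margin
  layout
}

#' Read or write a plate layout configuration file
#'
#' The YAML schema has top-level keys `n_plates`, `rows_per_plate`,
#' `wells_per_row`, optional `pixel_scale` (um/px), and `row_outlines`, a list
#' of `[x0, y0, x1, y1]` rectangles ordered plate-major, top to bottom.
#'
#' @param path File path.
#' @return `read_layout` returns a `plate_layout`; `write_layout` returns
#'   `path` invisibly.
#' @export
read_layout <- function(path) {
  cfg <- yaml::read_yaml(path)
  layout_from_config(cfg)
}

#' @rdname read_layout
#' @param layout A `plate_layout` to serialize.
#' @export
write_layout <- function(layout, path) {
  yaml::write_yaml(layout_to_config(layout), path)
  invisible(path)
}

layout_from_config <- function(cfg) {
  ro <- do.call(rbind, lapply(cfg$row_outlines, function(r) {
    stats::setNames(as.data.frame(as.list(as.numeric(r))),
                    c("x0", "y0", "x1", "y1"))
  }))
  plate_layout(cfg$n_plates, cfg$rows_per_plate, cfg$wells_per_row, ro,
               pixel_scale = cfg$pixel_scale)
}

layout_to_config <- function(layout) {
  list(n_plates = layout$n_plates,
       rows_per_plate = layout$rows_per_plate,
       wells_per_row = layout$wells_per_row,
       pixel_scale = layout$pixel_scale,
       row_outlines = lapply(seq_len(nrow(layout$row_outlines)), function(i)
         as.numeric(layout$row_outlines[i, c("x0", "y0", "x1", "y1")])))
}
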