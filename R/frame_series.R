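#' Frame series: an ordered, lazily loaded image sequence
#'
#' A `frame_series` abstracts over where frames come from — a directory of
#' image files or an in-memory renderer — so the detection stage can stream
#' through arbitrarily long recordings while holding at most two frames.
#'
#' @param get Function taking a 1-based frame index and returning the frame
#'   as a numeric array `height x width x 3` (or `height x width`) with
#'   intensities in 0-255.
#' @param n Number of frames (must be >= 2 for subtractive analysis).
#' @param frame_interval Seconds between frames.
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(get, n, frame_interval = 6) {
  stopifnot(is.function(get), n >= 1)
  structure(list(get = get, n = as.integer(n),
                 frame_interval = frame_interval),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames, one every %gs\n", x$n, x$frame_interval))
  invisible(x)
}

# read one image file into a 0-255 numeric array; higher bit depths are
# rescaled to 8-bit with a warning
read_frame_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop(sprintf("unsupported image format: %s", path))),
    error = function(e) stop(sprintf("cannot read frame '%s': %s",
                                     path, conditionMessage(e))))
  if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]  # drop alpha
  if (max(img) > 1 + 1e-9) {
    warning(sprintf("rescaling %s from >8-bit to 8-bit", basename(path)))
    img <- img / max(img)
  }
  img * 255
}

#' Load an image directory as a frame series
#'
#' Files are taken in lexicographic order, which must equal acquisition
#' order (the usual `frame_000001.png` naming guarantees this). Dimensions
#' are validated lazily against the first frame; a mismatching or unreadable
#' file raises an error naming the offending file.
#'
#' @param directory Directory containing PNG/TIFF/JPEG frames.
#' @param frame_interval Seconds between frames (default 6).
#' @param pattern Optional filename regexp filter.
#' @return A `frame_series`.
#' @export
load_frames <- function(directory, frame_interval = 6,
                        pattern = "\\.(png|tif|tiff|jpg|jpeg)$") {
  if (!dir.exists(directory))
    stop(sprintf("input directory does not exist: %s", directory))
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0)
    stop(sprintf("no image frames found in %s", directory))
  ref_dim <- NULL
  get <- function(i) {
    img <- read_frame_file(files[i])
    d <- dim(img)[1:2]
    if (is.null(ref_dim)) ref_dim <<- d
    else if (!identical(d, ref_dim))
      stop(sprintf("frame dimension mismatch in '%s': %dx%d, expected %dx%d",
                   basename(files[i]), d[1], d[2], ref_dim[1], ref_dim[2]))
    img
  }
  frame_series(get, length(files), frame_interval)
}
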