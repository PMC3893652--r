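#' Frame stack: flattened grey-scale video
#'
#' The ISOMAP input: an `n x d` integer matrix whose row `i` is frame `i`
#' scanned in row-major order (`d = width x height` pixels, grey levels in
#' 0..255). At the experimental scale a trial is `n = 900` frames of
#' `960 x 640` pixels, so `d = 614400`.
#'
#' @param data `n x d` matrix of grey levels (n >= 2).
#' @param width,height frame size in pixels, with `d = width * height`.
#' @param fps frames per second of the source video.
#' @param sampling_period temporal sampling period in frames.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(data, width, height, fps = 30, sampling_period = 1) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("a frame stack needs at least 2 frames")
  if (ncol(data) != width * height) {
    stop("ncol(data) must equal width * height (= ", width * height, ")")
  }
  rng <- range(data)
  if (anyNA(data) || rng[1] < 0 || rng[2] > 255) {
    stop("grey levels must lie in {0, ..., 255}")
  }
  structure(list(data = data, width = as.integer(width),
                 height = as.integer(height), fps = fps,
                 sampling_period = as.integer(sampling_period)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat("Frame stack:", nrow(x$data), "frames of", x$width, "x", x$height,
      "pixels (d =", ncol(x$data), "), fps =", x$fps,
      ", sampling period =", x$sampling_period, "frames\n")
  invisible(x)
}

#' Convert an RGB frame to grey scale
#'
#' Luminance-weighted combination `0.299 R + 0.587 G + 0.114 B`, rounded half
#' away from zero to an integer grey level in 0..255. The three colour
#' channels of such footage are strongly correlated, so any fixed convention
#' works; the broadcast-standard weights are used because they are documented
#' and testable.
#'
#' @param rgb_frame `h x w x 3` array with channel values in 0..255.
#' @return `h x w` integer matrix of grey levels.
#' @export
to_grayscale <- function(rgb_frame) {
  d <- dim(rgb_frame)
  if (length(d) != 3L || d[3] != 3L) {
    stop("rgb_frame must be an h x w x 3 array")
  }
  if (anyNA(rgb_frame) || min(rgb_frame) < 0 || max(rgb_frame) > 255) {
    stop("channel values must lie in 0..255")
  }
  g <- 0.299 * rgb_frame[, , 1] + 0.587 * rgb_frame[, , 2] + 0.114 * rgb_frame[, , 3]
  matrix(as.integer(floor(g + 0.5)), d[1], d[2])
}

#' Speed-scaled sampling period
#'
#' The sampling period `s` is chosen inversely proportional to the species'
#' characteristic speed `v_pix` (pixels/frame), so that frame-to-frame
#' changes are comparable across species: `s = round(s_ref * v_ref / v_pix)`,
#' at least 1. The reference is the fastest system (fish in the presence of
#' stimuli, `s_ref = 1` frame).
#'
#' @param v_pix characteristic speed of the recorded species (pixels/frame).
#' @param v_ref reference speed (pixels/frame).
#' @param s_ref integer sampling period at the reference speed (frames).
#' @return Integer sampling period in frames (>= 1).
#' @examples
#' compute_sampling_period(1, 1)          # reference species: 1
#' compute_sampling_period(1 / 20, 1)     # 20x slower: 20
#' @export
compute_sampling_period <- function(v_pix, v_ref, s_ref = 1L) {
  check_scalar(v_pix, "v_pix"); check_scalar(v_ref, "v_ref")
  check_scalar(s_ref, "s_ref")
  if (v_pix <= 0 || v_ref <= 0) stop("speeds must be > 0")
  if (s_ref < 1 || s_ref != round(s_ref)) stop("s_ref must be an integer >= 1")
  max(1L, as.integer(round(s_ref * v_ref / v_pix)))
}

#' Temporally subsample a frame stack
#'
#' Retains frames at indices 0, s, 2s, ... (0-based; the first frame is
#' always kept) and records the sampling period. With `T` seconds of video at
#' `fps` frames/second this leaves `floor((T * fps - 1) / s) + 1` frames —
#' 900 for every species preset in [sampling_presets()].
#'
#' @param stack a [frame_stack()].
#' @param s integer sampling period in frames (>= 1).
#' @return A new `frame_stack` with the retained frames.
#' @export
sample_frames <- function(stack, s) {
  stopifnot(inherits(stack, "frame_stack"))
  check_scalar(s, "s")
  if (s < 1 || s != round(s)) stop("s must be an integer >= 1")
  idx <- seq(1L, nrow(stack$data), by = as.integer(s))
  if (length(idx) < 2L) stop("fewer than 2 frames retained; lower s or supply more frames")
  frame_stack(stack$data[idx, , drop = FALSE], stack$width, stack$height,
              fps = stack$fps,
              sampling_period = stack$sampling_period * as.integer(s))
}

#' Flatten frames into the ISOMAP input matrix
#'
#' Row `i` of the result is frame `i` scanned in row-major order, so each
#' frame becomes a point in pixel space; a `960 x 640` frame yields a row of
#' 614400 entries.
#'
#' @param frames list of `h x w` grey-level matrices with common dimensions.
#' @param fps,sampling_period metadata stored in the result.
#' @return A [frame_stack()].
#' @export
flatten_frames <- function(frames, fps = 30, sampling_period = 1) {
  if (!is.list(frames) || length(frames) < 1L) stop("frames must be a non-empty list")
  dims <- dim(frames[[1]])
  if (is.null(dims) || length(dims) != 2L) stop("frames must be h x w matrices")
  for (f in frames) {
    if (!identical(dim(f), dims)) stop("all frames must share the same dimensions")
  }
  data <- t(vapply(frames, function(f) as.vector(t(f)), numeric(prod(dims))))
  frame_stack(data, width = dims[2], height = dims[1], fps = fps,
              sampling_period = sampling_period)
}

#' Reshape one flattened frame back to an image matrix
#'
#' Inverse of the row-major flattening used by [flatten_frames()].
#'
#' @param row numeric vector of length `width * height`.
#' @param width,height frame size in pixels.
#' @return `height x width` matrix.
#' @export
unflatten_frame <- function(row, width, height) {
  if (length(row) != width * height) stop("length(row) must equal width * height")
  matrix(row, nrow = height, ncol = width, byrow = TRUE)
}

#' Read a directory of image frames into a frame stack
#'
#' Files are taken in lexicographic order; PNG and TIFF are supported (video
#' is decoded to frames by an external pre-step, e.g. ffmpeg). RGB images are
#' converted with [to_grayscale()].
#'
#' @param dir directory containing the frames.
#' @param pattern filename regular expression.
#' @param fps frames per second of the source video.
#' @return A [frame_stack()].
#' @export
read_frame_dir <- function(dir, pattern = "\\.(png|tif|tiff)$", fps = 30) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) < 2L) stop("need at least 2 frame files in ", dir)
  read_one <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
      png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF frames requires the 'tiff' package")
      }
      tiff::readTIFF(f)
    }
    img <- img * 255
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
      to_grayscale(img)
    } else {
      matrix(as.integer(floor(img + 0.5)), nrow(img), ncol(img))
    }
  }
  flatten_frames(lapply(files, read_one), fps = fps)
}

#' Experimental sampling parameters by species
#'
#' Video length `T` (seconds), sampling period `s` (frames) and stimulus
#' separation `sigma` (cm) for each recorded species, plus the slowed-down
#' no-stimulus fish condition, all at 30 frames per second. Every row
#' satisfies `floor((T * 30 - 1) / s) + 1 = 900` frames after sampling.
#'
#' @return data.frame with columns `species`, `T`, `s`, `sigma`, `fps`.
#' @export
sampling_presets <- function() {
  data.frame(
    species = c("ants", "fish", "frogs", "chickens", "humans", "fish_nostim"),
    T = c(390, 30, 480, 480, 600, 600),
    s = c(13L, 1L, 16L, 16L, 20L, 20L),
    sigma = c(1, 16, 16, 35, 700, NA),
    fps = 30,
    stringsAsFactors = FALSE
  )
}

#' Number of frames retained after speed-scaled sampling
#'
#' @param T video length in seconds.
#' @param fps frames per second.
#' @param s sampling period in frames.
#' @return Integer count of retained frames.
#' @export
expected_frame_count <- function(T, fps = 30, s = 1) {
  total <- floor(T * fps)
  if (total < 1) stop("T * fps must be >= 1")
  as.integer(floor((total - 1) / s) + 1)
}
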