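#' Construct a frame sequence
#'
#' A frame sequence is the unit the vision pipeline consumes: an ordered list
#' of equally sized grayscale frames, each a numeric matrix of intensities in
#' `[0, 255]` (row, col indexed, origin top-left), plus the camera frame rate
#' as metadata.
#'
#' @param frames List of numeric matrices with identical dimensions, values
#'   in `[0, 255]`.
#' @param frame_rate Frames per second (metadata only; not used by the
#'   detection algorithms, which assume the operator matched frame rate to
#'   flow rate).
#' @return An object of class `frame_sequence`: a list with elements
#'   `frames`, `frame_rate`, `height`, `width`.
#' @export
frame_sequence <- function(frames, frame_rate = NA_real_) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop("empty input: a frame_sequence needs at least one frame", call. = FALSE)
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: frames have inconsistent dimensions", call. = FALSE)
  }
  rng <- range(vapply(frames, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) {
    stop("frame intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(frames = frames, frame_rate = frame_rate,
         height = dims[1, 1], width = dims[2, 1]),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frame(s), %d x %d px, frame rate %s fps\n",
              length(x$frames), x$height, x$width,
              ifelse(is.na(x$frame_rate), "unknown", format(x$frame_rate))))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Convert a decoded image array to an 8-bit grayscale matrix
#'
#' RGB(A) arrays are reduced with the standard BT.601 luma weights
#' (0.299, 0.587, 0.114); an already-gray image is returned unchanged
#' (identity). Inputs on the `[0, 1]` scale (as returned by the png/tiff
#' readers) are rescaled to `[0, 255]`; 16-bit sources therefore map linearly
#' onto the 8-bit range the downstream thresholds are defined on.
#'
#' @param img Numeric matrix or 3-d array (h x w x channels) with values in
#'   `[0, 1]` or `[0, 255]`.
#' @return Numeric matrix, values in `[0, 255]`.
#' @export
as_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  if (max(img) <= 1) img <- img * 255
  img
}

# numeric-aware ordering of image file names: sort on the last integer run
# in the basename so frame_2 < frame_10
order_numbered <- function(paths) {
  base <- basename(paths)
  num <- suppressWarnings(as.numeric(sub(".*?(\\d+)(?!.*\\d).*", "\\1",
                                         base, perl = TRUE)))
  if (anyNA(num)) order(base) else order(num, base)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("I/O error: unsupported image format: ", path, call. = FALSE)
  )
  as_gray(img)
}

#' Read a video as ordered grayscale frames
#'
#' Reads a numbered PNG/TIFF image sequence (a directory, or a character
#' vector of file paths) into a [frame_sequence()]. Frames are ordered by the
#' number embedded in the file name and converted to single-channel 8-bit
#' intensity. Container formats (AVI/MP4) are not decoded; export the
#' recording as an image sequence first (e.g. `ffmpeg -i run.avi f_%04d.png`).
#'
#' @param path Directory containing the numbered images, or a character
#'   vector of image file paths.
#' @param start 1-based index of the first frame to keep.
#' @param count Number of frames to read, or `Inf` for all.
#' @param frame_rate Frames per second, attached as metadata.
#' @return A [frame_sequence()].
#' @export
read_frames <- function(path, start = 1L, count = Inf, frame_rate = NA_real_) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
  } else {
    if (length(path) == 1L && !file.exists(path)) {
      stop("I/O error: path does not exist: ", path, call. = FALSE)
    }
    ext <- tolower(tools::file_ext(path[1]))
    if (ext %in% c("avi", "mp4", "mov", "mkv")) {
      stop("I/O error: video containers are not decoded; convert to a ",
           "numbered PNG/TIFF sequence first (e.g. with ffmpeg)",
           call. = FALSE)
    }
    files <- path
  }
  if (length(files) == 0L) stop("empty input: no frames found", call. = FALSE)
  files <- files[order_numbered(files)]
  idx <- seq_along(files)
  idx <- idx[idx >= start]
  if (is.finite(count)) idx <- head(idx, count)
  if (length(idx) == 0L) stop("empty input: no frames in requested range", call. = FALSE)
  frame_sequence(lapply(files[idx], read_one_image), frame_rate = frame_rate)
}

#' Write a frame sequence as a numbered lossless image sequence
#'
#' Each frame is written as an 8-bit grayscale PNG; re-reading with
#' [read_frames()] reproduces every pixel of an integer-valued sequence
#' exactly. Non-integer intensities are rounded on write.
#'
#' @param seq A [frame_sequence()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix; files are named `<prefix>_<index>.png`
#'   with zero-padded 1-based indices.
#' @return Invisibly, the vector of written file paths.
#' @export
write_frames <- function(seq, dir, prefix = "frame") {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(seq$frames)
  fmt <- sprintf("%%s_%%0%dd.png", max(4L, nchar(n)))
  paths <- character(n)
  for (i in seq_len(n)) {
    paths[i] <- file.path(dir, sprintf(fmt, prefix, i))
    png::writePNG(round(seq$frames[[i]]) / 255, paths[i])
  }
  invisible(paths)
}

#' Iterate over consecutive frame pairs
#'
#' Applies `fn(prev, curr, index)` to every strictly consecutive frame pair
#' (stride 1), where `index` is the 1-based index of the later frame.
#'
#' @param seq A [frame_sequence()].
#' @param fn Function of `(prev, curr, index)`.
#' @return List of `fn` results, one per pair.
#' @export
frame_pairs <- function(seq, fn) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- length(seq$frames)
  if (n < 2L) return(list())
  lapply(2:n, function(i) fn(seq$frames[[i - 1L]], seq$frames[[i]], i))
}
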