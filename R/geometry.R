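#' Estimate the skew angle of a frame
#'
#' The outlet channels must run horizontally for the rest of the pipeline.
#' Edge pixels ([canny_edges()]) are fed to the near-horizontal segment
#' detector ([hough_segments()]); the skew estimate is the plain mean of the
#' detected segments' angles from the horizontal, counterclockwise positive.
#'
#' @param frame Numeric matrix, intensities in `[0, 255]`.
#' @param line_params A [hough_params()] list.
#' @param edge_params A [canny_params()] list.
#' @return Skew angle in degrees (counterclockwise tilt of the content).
#' @export
estimate_skew_angle <- function(frame, line_params = hough_params(),
                                edge_params = canny_params()) {
  segs <- hough_segments(canny_edges(frame, edge_params), line_params)
  if (nrow(segs) == 0L) {
    stop("no lines detected: cannot estimate skew", call. = FALSE)
  }
  mean(segs$angle)
}

# Damping policy for iterative rotation: when the cumulative requested
# rotation exceeds twice the first estimate, the request is replaced (not
# added to) by 1.5 x the first estimate.
rotation_request <- function(total, correction, first) {
  requested <- total + correction
  if (abs(requested) > 2 * abs(first)) {
    list(total = 1.5 * first, damped = TRUE)
  } else {
    list(total = requested, damped = FALSE)
  }
}

#' Automatically rotate a frame until the channel walls are horizontal
#'
#' Iteratively estimates the skew, rotates-and-crops about the frame center,
#' and re-verifies on the result, stopping when the residual skew is within
#' `tolerance` or after `max_iterations`. Each applied rotation resamples the
#' original frame once at the cumulative angle, so repeated iterations do not
#' accumulate interpolation blur.
#'
#' A damping rule guards against runaway correction: whenever the requested
#' cumulative rotation exceeds twice the first skew estimate, the request is
#' replaced by 1.5 times the first estimate.
#'
#' @param frame Numeric matrix.
#' @param tolerance Residual skew tolerance, degrees.
#' @param max_iterations Maximum estimate/rotate cycles.
#' @param line_params,edge_params Detector parameters, as in
#'   [estimate_skew_angle()].
#' @param fill Intensity used outside the source during resampling (the
#'   interior crop removes it, but it still feeds the crop's margin rows).
#' @return List: `frame` (rotated and cropped; the input itself when no
#'   rotation was needed) and `rotation` (class `rotation_result`:
#'   `total_angle` in degrees counterclockwise, `iterations`, `converged`,
#'   `damped`).
#' @export
auto_rotate <- function(frame, tolerance = 0.5, max_iterations = 5L,
                        line_params = hough_params(),
                        edge_params = canny_params(), fill = 0) {
  stopifnot(tolerance > 0, max_iterations >= 1)
  first <- NULL
  total <- 0
  damped <- FALSE
  out <- frame
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iterations) {
    iterations <- iterations + 1L
    skew <- estimate_skew_angle(out, line_params, edge_params)
    if (abs(skew) <= tolerance) {
      converged <- TRUE
      break
    }
    correction <- -skew
    if (is.null(first)) first <- correction
    req <- rotation_request(total, correction, first)
    if (req$damped) damped <- TRUE
    total <- req$total
    out <- rotate_frame(frame, total, crop = "interior", fill = fill)
  }
  # a final re-check when the loop ended on an applied rotation
  if (!converged && iterations == max_iterations) {
    final_skew <- tryCatch(estimate_skew_angle(out, line_params, edge_params),
                           error = function(e) NA_real_)
    if (!is.na(final_skew) && abs(final_skew) <= tolerance) converged <- TRUE
  }
  structure_rot <- structure(
    list(total_angle = total, iterations = iterations,
         converged = converged, damped = damped),
    class = "rotation_result")
  list(frame = out, rotation = structure_rot)
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("rotation_result: total %.3f deg, %d iteration(s), %s%s\n",
              x$total_angle, x$iterations,
              if (x$converged) "converged" else "NOT converged",
              if (x$damped) " (damped)" else ""))
  invisible(x)
}

#' Construct an observation window
#'
#' Pixel bounds of the outlet-channel region within a frame; all bounds are
#' 1-based and inclusive.
#'
#' @param left_col,right_col,top_row,bottom_row Inclusive pixel bounds.
#' @return An `observation_window` list.
#' @export
observation_window <- function(left_col, right_col, top_row, bottom_row) {
  if (!(left_col < right_col) || !(top_row < bottom_row)) {
    stop("invalid window: bounds must satisfy left < right and top < bottom",
         call. = FALSE)
  }
  structure(list(left_col = left_col, right_col = right_col,
                 top_row = top_row, bottom_row = bottom_row),
            class = "observation_window")
}

#' Locate the left and right window bounds by template matching
#'
#' Two templates mark the upper and lower ends of the outlet-channel array;
#' each spans the array's full width. Both are matched by normalized
#' cross-correlation on the de-skewed frame (template matching is sensitive
#' to rotation), taking the best-match upper-left corner per template. The
#' left bound is the mean of the two matched columns and the right bound is
#' the left bound plus the mean template width, both clamped to the frame.
#'
#' @param frame De-skewed numeric matrix.
#' @param templates List with elements `top` and `bottom`, each a numeric
#'   matrix strictly smaller than the frame.
#' @param min_score Matches scoring below this NCC floor raise a
#'   low-confidence error.
#' @return List: `left_col`, `right_col` (inclusive), plus the per-template
#'   match rows/cols and scores.
#' @export
locate_horizontal_bounds <- function(frame, templates, min_score = 0.5) {
  stopifnot(is.list(templates), !is.null(templates$top), !is.null(templates$bottom))
  mt <- match_template(frame, templates$top)
  mb <- match_template(frame, templates$bottom)
  if (mt$max_score < min_score || mb$max_score < min_score) {
    stop(sprintf(
      "low-confidence template match (scores %.2f / %.2f, floor %.2f)",
      mt$max_score, mb$max_score, min_score), call. = FALSE)
  }
  left <- round(mean(c(mt$best["col"], mb$best["col"])))
  width <- round(mean(c(ncol(templates$top), ncol(templates$bottom))))
  left <- max(1L, min(as.integer(left), ncol(frame) - 1L))
  right <- min(as.integer(left + width - 1L), ncol(frame))
  list(left_col = left, right_col = right,
       top_match = mt$best, bottom_match = mb$best,
       scores = c(top = mt$max_score, bottom = mb$max_score))
}

#' Locate the top and bottom window bounds from detected lines
#'
#' Runs the segment detector on the de-skewed frame restricted to columns
#' `[left_col, right_col]` and keeps the uppermost and lowest rows over all
#' detected segments, aiming at the outermost outlet-channel walls.
#'
#' @param frame De-skewed numeric matrix.
#' @param left_col,right_col Inclusive column bounds from
#'   [locate_horizontal_bounds()].
#' @param line_params A [hough_params()] list.
#' @param edge_params A [canny_params()] list.
#' @return List: `top_row`, `bottom_row` (inclusive).
#' @export
locate_vertical_bounds <- function(frame, left_col, right_col,
                                   line_params = hough_params(),
                                   edge_params = canny_params()) {
  stopifnot(left_col >= 1, right_col <= ncol(frame), left_col < right_col)
  sub <- frame[, left_col:right_col, drop = FALSE]
  segs <- hough_segments(canny_edges(sub, edge_params), line_params)
  if (nrow(segs) == 0L) {
    stop("no lines detected within the column bounds", call. = FALSE)
  }
  rows <- round(c(segs$r1, segs$r2))
  top <- min(rows); bottom <- max(rows)
  if (top >= bottom) {
    stop("invalid window: a single line row cannot bound the window",
         call. = FALSE)
  }
  list(top_row = top, bottom_row = bottom)
}

#' Group wall votes into wall rows
#'
#' The core grouping rule of wall detection, exposed for direct use: the
#' (multiset) vote list of row indices is sorted and partitioned into groups
#' of consecutive rows, breaking wherever the gap between adjacent distinct
#' rows exceeds `gap_threshold`; within each group the wall row is the row
#' with the maximum vote count, ties resolved to the smaller row index.
#'
#' @param votes Integer vector of row votes (repeats allowed).
#' @param gap_threshold Break groups where the inter-row gap exceeds this
#'   many rows.
#' @return Integer vector of wall rows, strictly increasing.
#' @export
group_votes <- function(votes, gap_threshold = 3) {
  if (length(votes) == 0L) return(integer(0))
  tb <- table(votes)
  rows <- as.integer(names(tb))
  counts <- as.integer(tb)
  brk <- c(0L, which(diff(rows) > gap_threshold), length(rows))
  walls <- integer(0)
  for (g in seq_len(length(brk) - 1L)) {
    sel <- (brk[g] + 1L):brk[g + 1L]
    walls <- c(walls, rows[sel][which.max(counts[sel])])  # tie -> smaller row
  }
  walls
}

#' Construct channel geometry from wall rows
#'
#' @param wall_rows Strictly increasing wall row indices.
#' @return A `channel_geometry` list: `wall_rows` and a `channels` data frame
#'   (`channel_id` 1-based top-to-bottom, `upper_wall_row`,
#'   `lower_wall_row`). Channels tile `[first wall, last wall]`.
#' @export
channel_geometry <- function(wall_rows) {
  wall_rows <- as.numeric(wall_rows)
  if (length(wall_rows) < 2L || any(diff(wall_rows) <= 0)) {
    stop("insufficient walls: need >= 2 strictly increasing wall rows",
         call. = FALSE)
  }
  n <- length(wall_rows) - 1L
  structure(list(
    wall_rows = wall_rows,
    channels = data.frame(channel_id = seq_len(n),
                          upper_wall_row = wall_rows[-length(wall_rows)],
                          lower_wall_row = wall_rows[-1])),
    class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("channel_geometry: %d walls, %d channels (rows %s..%s)\n",
              length(x$wall_rows), nrow(x$channels),
              x$wall_rows[1], x$wall_rows[length(x$wall_rows)]))
  invisible(x)
}

#' Detect the outlet-channel walls
#'
#' Builds a vote list of row indices from (a) rows flagged by Canny edge
#' detection and (b) rows covered by detected near-horizontal line segments,
#' then groups it with [group_votes()]. A row contributes Canny votes (one
#' per edge pixel) only when its edge-pixel count exceeds `min_row_fill`
#' times the window width, so sparse vertical structure cannot bridge wall
#' groups.
#'
#' @param window_pixels Numeric matrix restricted to the observation window
#'   (>= 3 rows tall).
#' @param edge_params A [canny_params()] list.
#' @param line_params A [hough_params()] list.
#' @param gap_threshold Grouping gap, rows (see [group_votes()]).
#' @param min_row_fill Minimum fraction of window width a row's edge-pixel
#'   count must reach to contribute Canny votes.
#' @return A [channel_geometry()].
#' @export
detect_walls <- function(window_pixels, edge_params = canny_params(),
                         line_params = hough_params(), gap_threshold = 3,
                         min_row_fill = 0.2) {
  stopifnot(nrow(window_pixels) >= 3L)
  edges <- canny_edges(window_pixels, edge_params)
  per_row <- rowSums(edges)
  keep_rows <- which(per_row >= min_row_fill * ncol(window_pixels))
  canny_votes <- rep(keep_rows, times = per_row[keep_rows])
  segs <- hough_segments(edges, line_params)
  hough_votes <- attr(segs, "row_votes")
  votes <- c(canny_votes, hough_votes)
  walls <- group_votes(votes, gap_threshold)
  if (length(walls) < 2L) {
    stop("insufficient walls: fewer than 2 wall rows detected", call. = FALSE)
  }
  channel_geometry(walls)
}
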