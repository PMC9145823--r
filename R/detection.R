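#' Blob detection parameters
#'
#' Filtering parameters for [detect_blobs()]. Area limits are in px^2;
#' circularity is `4 * pi * area / perimeter^2` with the perimeter measured
#' as crack (pixel-edge boundary) length, under which a digitized disk
#' scores roughly 0.45-0.6 and thin elongated shapes fall well below 0.4.
#' The threshold sweep mirrors the multi-threshold strategy of standard
#' blob detectors: a blob must be recovered at `min_repeatability` or more
#' threshold levels to count, which suppresses unstable noise responses.
#'
#' @param min_area,max_area Connected-component area bounds, px^2.
#' @param min_circularity Minimum circularity in `[0, 1]`.
#' @param threshold_range `c(low, high, step)` intensity sweep.
#' @param min_repeatability Minimum number of threshold levels at which a
#'   blob must appear.
#' @param min_dist Centroids closer than this (px) across threshold levels
#'   are merged into one blob.
#' @param smooth_sigma Gaussian pre-smoothing of the input matrix, px; 0
#'   disables it. Smoothing acts as a matched filter for disk-shaped
#'   particles: it stabilizes centroids of partial footprints at the window
#'   edge and pushes sensor noise below the threshold sweep.
#' @return A `blob_params` list.
#' @export
blob_params <- function(min_area = 20, max_area = 5000,
                        min_circularity = 0.4,
                        threshold_range = c(10, 220, 10),
                        min_repeatability = 2L, min_dist = 2,
                        smooth_sigma = 0) {
  stopifnot(min_area > 0, min_area <= max_area,
            min_circularity >= 0, min_circularity <= 1,
            length(threshold_range) == 3L, threshold_range[3] > 0,
            smooth_sigma >= 0)
  structure(list(min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 threshold_range = threshold_range,
                 min_repeatability = as.integer(min_repeatability),
                 min_dist = min_dist, smooth_sigma = smooth_sigma),
            class = "blob_params")
}

#' Blob parameters scaled from the nominal particle size
#'
#' Derives the area window from the projected disk area of a particle of
#' nominal diameter `diameter_um` at `um_per_px` microns per pixel:
#' `min_area` is half the projected area (tolerating partial footprints at
#' window edges) and `max_area` four times it.
#'
#' @param diameter_um Nominal particle diameter, µm.
#' @param um_per_px Image scale, µm per pixel.
#' @param ... Passed on to [blob_params()].
#' @return A `blob_params` list.
#' @export
blob_params_for_particle <- function(diameter_um, um_per_px, ...) {
  r_px <- diameter_um / 2 / um_per_px
  disk <- pi * r_px^2
  blob_params(min_area = 0.5 * disk, max_area = 4 * disk,
              smooth_sigma = 0.8, ...)
}

label_matrix <- function(bin) {
  lab <- EBImage::bwlabel(bin * 1)
  matrix(as.integer(lab), nrow(bin), ncol(bin))
}

#' Detect blobs in a residual or difference image
#'
#' Thresholds the matrix at every level of the sweep, labels connected
#' components, filters them by area and circularity, and merges the
#' surviving candidates across thresholds: centroids within `min_dist` px of
#' an existing group join it, and only groups recovered at
#' `min_repeatability` or more levels are reported. The reported centroid is
#' the mean over the group's per-threshold centroids.
#'
#' @param mat Numeric matrix (non-negative; typically a clamped difference).
#' @param params A [blob_params()] list.
#' @param return_mask If `TRUE`, also return the union pixel mask of all
#'   accepted blobs (needed by [build_background()]).
#' @return Data frame with columns `row`, `col` (float centroids), `area`
#'   (mean component area) and `n_levels`; when `return_mask` is `TRUE`, a
#'   list `(blobs, mask)`.
#' @export
detect_blobs <- function(mat, params = blob_params(), return_mask = FALSE) {
  full_dim <- dim(mat)
  if (params$smooth_sigma > 0) {
    mat <- sepconv(mat, gauss_kernel(params$smooth_sigma))
  }
  # restrict the sweep to the bounding box of supra-floor pixels; the
  # labeling cost then scales with the active region, not the window
  act <- mat >= params$threshold_range[1]
  if (!any(act)) {
    empty <- data.frame(row = numeric(0), col = numeric(0),
                        area = numeric(0), n_levels = integer(0))
    if (!return_mask) return(empty)
    return(list(blobs = empty, mask = matrix(FALSE, full_dim[1], full_dim[2])))
  }
  rr <- range(which(rowSums(act) > 0)); cc <- range(which(colSums(act) > 0))
  r_off <- max(1L, rr[1] - 2L) - 1L
  c_off <- max(1L, cc[1] - 2L) - 1L
  mat <- mat[(r_off + 1L):min(full_dim[1], rr[2] + 2L),
             (c_off + 1L):min(full_dim[2], cc[2] + 2L), drop = FALSE]
  thr <- seq(params$threshold_range[1], params$threshold_range[2],
             by = params$threshold_range[3])
  groups <- list()  # each: row, col (running means), areas, n, pix
  top <- suppressWarnings(max(mat))
  for (t in thr) {
    if (t > top) break
    bin <- mat >= t
    if (!any(bin)) break
    st <- label_stats(label_matrix(bin))
    st <- st[st$area >= params$min_area & st$area <= params$max_area &
               st$circularity >= params$min_circularity, , drop = FALSE]
    if (nrow(st) == 0L) next
    lab <- if (return_mask) label_matrix(bin) else NULL
    for (i in seq_len(nrow(st))) {
      assigned <- FALSE
      if (length(groups)) {
        gr <- vapply(groups, function(g) g$row / g$n, numeric(1))
        gc <- vapply(groups, function(g) g$col / g$n, numeric(1))
        d <- sqrt((gr - st$row[i])^2 + (gc - st$col[i])^2)
        j <- which.min(d)
        if (d[j] <= params$min_dist) {
          groups[[j]]$row <- groups[[j]]$row + st$row[i]
          groups[[j]]$col <- groups[[j]]$col + st$col[i]
          groups[[j]]$area <- groups[[j]]$area + st$area[i]
          groups[[j]]$n <- groups[[j]]$n + 1L
          if (return_mask) {
            groups[[j]]$pix <- union(groups[[j]]$pix,
                                     which(lab == st$label[i]))
          }
          assigned <- TRUE
        }
      }
      if (!assigned) {
        groups[[length(groups) + 1L]] <- list(
          row = st$row[i], col = st$col[i], area = st$area[i], n = 1L,
          pix = if (return_mask) which(lab == st$label[i]) else NULL)
      }
    }
  }
  keep <- vapply(groups, function(g) g$n >= params$min_repeatability, logical(1))
  groups <- groups[keep]
  blobs <- data.frame(
    row = vapply(groups, function(g) g$row / g$n, numeric(1)) + r_off,
    col = vapply(groups, function(g) g$col / g$n, numeric(1)) + c_off,
    area = vapply(groups, function(g) g$area / g$n, numeric(1)),
    n_levels = vapply(groups, function(g) g$n, integer(1)))
  if (!return_mask) return(blobs)
  mask <- matrix(FALSE, full_dim[1], full_dim[2])
  nr_sub <- nrow(mat)
  for (g in groups) {
    sub_r <- ((g$pix - 1L) %% nr_sub) + 1L
    sub_c <- ((g$pix - 1L) %/% nr_sub) + 1L
    mask[cbind(sub_r + r_off, sub_c + c_off)] <- TRUE
  }
  list(blobs = blobs, mask = mask)
}

#' Build the background from the first frame
#'
#' The first ("zeroth") frame of a recording is the frame most likely to
#' contain only the background. It is blob-detected at the supplied
#' parameters; if no blobs are found it is returned unchanged. Otherwise
#' every pixel inside a detected blob is replaced by the mean of the
#' non-blob pixels of its own row, which restores the background brightness
#' profile; a row consisting entirely of blob pixels falls back to the
#' global non-blob mean and is flagged.
#'
#' @param zeroth Numeric matrix: the first frame (signal-bright; invert dark
#'   recordings first).
#' @param params A [blob_params()] list used to find particles to patch.
#' @param mask Optional logical matrix naming the pixels to patch directly
#'   (bypasses blob detection; useful for testing and manual overrides).
#' @return A `dld_background` list: `pixels`, `source_frame` (1),
#'   `patched_regions` (data frame: `row`, `n_pixels`, `global_fallback`).
#' @export
build_background <- function(zeroth, params = blob_params(), mask = NULL) {
  if (is.null(mask)) {
    det <- detect_blobs(zeroth, params, return_mask = TRUE)
    mask <- det$mask
  }
  stopifnot(identical(dim(mask), dim(zeroth)))
  px <- zeroth
  patched <- data.frame(row = integer(0), n_pixels = integer(0),
                        global_fallback = logical(0))
  if (any(mask)) {
    global_mean <- mean(zeroth[!mask])
    rows <- which(rowSums(mask) > 0)
    for (r in rows) {
      bad <- mask[r, ]
      fallback <- all(bad)
      val <- if (fallback) global_mean else mean(zeroth[r, !bad])
      px[r, bad] <- val
      patched <- rbind(patched, data.frame(
        row = r, n_pixels = sum(bad), global_fallback = fallback))
    }
  }
  structure(list(pixels = px, source_frame = 1L, patched_regions = patched),
            class = "dld_background")
}

#' Subtract the background from a frame
#'
#' Elementwise `frame - background`, negative values clamped to zero, so
#' only content brighter than the static scene (moving particles) remains.
#'
#' @param frame Numeric matrix.
#' @param bg A `dld_background` or a numeric matrix of the same shape.
#' @return Numeric matrix of non-negative residuals.
#' @export
subtract_background <- function(frame, bg) {
  px <- if (inherits(bg, "dld_background")) bg$pixels else bg
  if (!identical(dim(frame), dim(px))) {
    stop("dimension error: frame and background shapes differ", call. = FALSE)
  }
  pmax(frame - px, 0)
}

#' Difference two consecutive background-subtracted residuals
#'
#' Elementwise `curr - prev` with negatives clamped to zero; the nonzero
#' support approximates the newly occupied particle positions of the later
#' frame.
#'
#' @param curr_residual,prev_residual Numeric matrices of equal shape.
#' @return Numeric matrix of non-negative differences.
#' @export
frame_difference <- function(curr_residual, prev_residual) {
  if (!identical(dim(curr_residual), dim(prev_residual))) {
    stop("dimension error: residual shapes differ", call. = FALSE)
  }
  pmax(curr_residual - prev_residual, 0)
}

#' Create an empty detection ledger
#'
#' The ledger carries the repeat-suppression state across frame pairs: the
#' centroid set of the immediately preceding pair and the cumulative list of
#' unique detections.
#'
#' @param row_tolerance Row tolerance in px for the repeat rules (one pixel
#'   at the magnification the rules were designed for; expose for other
#'   scales).
#' @return A `detection_ledger` list.
#' @export
new_detection_ledger <- function(row_tolerance = 1) {
  structure(list(
    previous = data.frame(row = numeric(0), col = numeric(0)),
    detections = data.frame(frame_index = integer(0), row = numeric(0),
                            col = numeric(0)),
    row_tolerance = row_tolerance),
    class = "detection_ledger")
}

round01 <- function(x) round(x, 1)

#' Classify current centroids as new particles or repeat detections
#'
#' Implements the repeat-suppression rule set on which double-count
#' prevention rests. Centroids are rounded to 0.1 px and de-duplicated, then
#' each is compared with the previous pair's centroid set:
#'
#' * NEW when its row differs from every previous row by more than the
#'   tolerance (a particle at a new row);
#' * NEW when its (row, col) exactly equals a previous centroid — a real
#'   particle can never be stationary in the flow, so an identical repeat
#'   must be a new arrival;
#' * REPEAT (suppressed) when its row is within tolerance of a previous
#'   centroid while its position has changed — the same particle advected
#'   downstream.
#'
#' When several previous rows fall within tolerance the nearest row is
#' matched, ties resolved by the smaller column gap. New detections are
#' appended to the ledger and the previous-centroid set is replaced by the
#' full current set.
#'
#' @param current Data frame with columns `row`, `col` (this pair's
#'   centroids).
#' @param ledger A [new_detection_ledger()] state.
#' @param frame_index 1-based index of the later frame of the pair (>= 2).
#' @param stationary_is_new Treat an exact positional repeat as a new
#'   arrival (the default, and the rule the counting protocol states).
#'   `FALSE` selects the conservative alternative that suppresses it, for
#'   recordings where stationary artifacts survive background subtraction.
#' @return List: `new` (data frame `frame_index`, `row`, `col`) and the
#'   updated `ledger`.
#' @export
filter_new_particles <- function(current, ledger, frame_index,
                                 stationary_is_new = TRUE) {
  stopifnot(inherits(ledger, "detection_ledger"))
  tol <- ledger$row_tolerance
  cur <- data.frame(row = round01(current$row), col = round01(current$col))
  cur <- unique(cur)
  prev <- ledger$previous
  is_new <- logical(nrow(cur))
  for (i in seq_len(nrow(cur))) {
    if (nrow(prev) == 0L) { is_new[i] <- TRUE; next }
    dr <- abs(prev$row - cur$row[i])
    cand <- which(dr <= tol)
    if (length(cand) == 0L) { is_new[i] <- TRUE; next }
    j <- cand[order(dr[cand], abs(prev$col[cand] - cur$col[i]))][1]
    is_new[i] <- stationary_is_new &&
      prev$row[j] == cur$row[i] && prev$col[j] == cur$col[i]
  }
  new <- cur[is_new, , drop = FALSE]
  if (nrow(new)) {
    new <- cbind(frame_index = as.integer(frame_index), new)
    ledger$detections <- rbind(ledger$detections, new)
  } else {
    new <- data.frame(frame_index = integer(0), row = numeric(0),
                      col = numeric(0))
  }
  ledger$previous <- cur
  list(new = new, ledger = ledger)
}

#' Assign detections to outlet channels
#'
#' A detection at row `r` belongs to channel `i` when
#' `wall_rows[i] < r <= wall_rows[i + 1]` (a centroid exactly on an interior
#' wall goes to the upper channel). Rows outside the wall span are marked
#' unassigned (`NA`).
#'
#' @param detections Data frame with a `row` column.
#' @param geometry A [channel_geometry()].
#' @return `detections` with a `channel_id` column added.
#' @export
assign_channels <- function(detections, geometry) {
  stopifnot(inherits(geometry, "channel_geometry"))
  w <- geometry$wall_rows
  idx <- findInterval(detections$row, w, left.open = TRUE)
  idx[idx < 1L | detections$row > w[length(w)]] <- NA_integer_
  detections$channel_id <- idx
  detections
}

#' Summarize a finished detection run
#'
#' Produces the per-run report: per-channel counts, per-channel percentages
#' of the assigned total, the grand total of unique detections, and the
#' per-particle table (frame detected, centroid coordinates, channel).
#'
#' @param ledger Finalized [new_detection_ledger()] state.
#' @param geometry A [channel_geometry()].
#' @param metadata Named list carried into the summary (flow rate, particle
#'   size, source path, ...).
#' @return A `dld_run_summary` list: `channel_counts` (named by channel id),
#'   `percentages`, `total`, `n_assigned`, `unassigned`, `particles`,
#'   `metadata`.
#' @export
summarize_run <- function(ledger, geometry, metadata = list()) {
  stopifnot(inherits(ledger, "detection_ledger"))
  particles <- assign_channels(ledger$detections, geometry)
  n_ch <- nrow(geometry$channels)
  counts <- tabulate(particles$channel_id[!is.na(particles$channel_id)], n_ch)
  names(counts) <- as.character(seq_len(n_ch))
  total <- nrow(particles)
  n_assigned <- sum(counts)
  pct <- if (n_assigned > 0) 100 * counts / n_assigned else counts * 0
  structure(list(channel_counts = counts, percentages = pct, total = total,
                 n_assigned = n_assigned, unassigned = total - n_assigned,
                 particles = particles, metadata = metadata),
            class = "dld_run_summary")
}

#' @export
print.dld_run_summary <- function(x, ...) {
  cat("DLD run summary\n")
  if (length(x$metadata)) {
    for (nm in names(x$metadata)) {
      cat(sprintf("  %s: %s\n", nm, format(x$metadata[[nm]])))
    }
  }
  cat(sprintf("  total unique detections: %d (%d assigned, %d unassigned)\n",
              x$total, x$n_assigned, x$unassigned))
  tab <- data.frame(outlet = names(x$channel_counts),
                    count = as.integer(x$channel_counts),
                    percent = sprintf("%.1f", x$percentages))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a run summary as CSV plus JSON sidecar
#'
#' The CSV holds one row per detected particle (`frame_index`, `row`, `col`,
#' `channel`), the JSON the per-channel counts, percentages, total and
#' metadata. Output is deterministic: identical summaries produce
#' byte-identical files.
#'
#' @param summary A `dld_run_summary`.
#' @param dir Output directory (created if missing).
#' @param stem File name stem (`<stem>_particles.csv`,
#'   `<stem>_summary.json`).
#' @return Invisibly, the two file paths.
#' @export
write_run_summary <- function(summary, dir, stem = "run") {
  stopifnot(inherits(summary, "dld_run_summary"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, "_particles.csv"))
  js <- file.path(dir, paste0(stem, "_summary.json"))
  p <- summary$particles
  tab <- data.frame(frame_index = p$frame_index,
                    row = sprintf("%.1f", p$row),
                    col = sprintf("%.1f", p$col),
                    channel = ifelse(is.na(p$channel_id), "unassigned",
                                     as.character(p$channel_id)))
  write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    total = summary$total,
    n_assigned = summary$n_assigned,
    unassigned = summary$unassigned,
    channel_counts = as.list(setNames(as.integer(summary$channel_counts),
                                      names(summary$channel_counts))),
    percentages = as.list(setNames(round(summary$percentages, 4),
                                   names(summary$percentages))),
    metadata = summary$metadata), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}

#' Run the full particle-detection pipeline on a frame sequence
#'
#' Pipeline order: de-skew ([auto_rotate()] on the first frame; the fitted
#' rotation is applied to every frame), locate the observation window
#' ([locate_horizontal_bounds()], [locate_vertical_bounds()]), segment the
#' channel walls ([detect_walls()]), build the background from the first
#' frame, then walk consecutive frame pairs: background subtraction, frame
#' differencing, blob detection inside the window, repeat suppression, and
#' channel assignment. Entirely deterministic: reruns on the same input give
#' identical summaries.
#'
#' @param seq A [frame_sequence()].
#' @param templates List with `top`/`bottom` template matrices (see
#'   [locate_horizontal_bounds()]).
#' @param blob A [blob_params()] list.
#' @param row_tolerance Repeat-suppression row tolerance, px.
#' @param polarity `"bright"` for bright particles on a darker background,
#'   `"dark"` for the inverse; detection math is polarity-normalized
#'   internally.
#' @param tolerance,max_iterations De-skew settings ([auto_rotate()]).
#' @param edge,lines Canny/Hough parameters shared by the geometry stages.
#' @param gap_threshold Wall-grouping gap, rows.
#' @param min_score Template-match NCC floor.
#' @param metadata Named list stored in the summary.
#' @return A `dld_run_summary`, with the window, channel geometry and
#'   rotation result attached as attributes `window`, `geometry`,
#'   `rotation`.
#' @export
detect_particles <- function(seq, templates, blob = blob_params(),
                             row_tolerance = 1,
                             polarity = c("bright", "dark"),
                             tolerance = 0.5, max_iterations = 5L,
                             edge = canny_params(), lines = hough_params(),
                             gap_threshold = 3, min_score = 0.5,
                             metadata = list()) {
  stopifnot(inherits(seq, "frame_sequence"))
  polarity <- match.arg(polarity)
  if (length(seq$frames) < 2L) {
    stop("empty input: need at least 2 frames for pair differencing",
         call. = FALSE)
  }
  inv <- function(m) if (polarity == "dark") 255 - m else m

  rot <- auto_rotate(seq$frames[[1]], tolerance = tolerance,
                     max_iterations = max_iterations,
                     line_params = lines, edge_params = edge,
                     fill = median(seq$frames[[1]]))
  frames <- seq$frames
  if (rot$rotation$total_angle != 0) {
    fillv <- median(seq$frames[[1]])
    frames <- lapply(frames, rotate_frame, angle = rot$rotation$total_angle,
                     crop = "interior", fill = fillv)
  }
  f1 <- frames[[1]]

  hb <- locate_horizontal_bounds(f1, templates, min_score = min_score)
  vb <- locate_vertical_bounds(f1, hb$left_col, hb$right_col,
                               line_params = lines, edge_params = edge)
  win <- observation_window(hb$left_col, hb$right_col, vb$top_row, vb$bottom_row)

  # pad the wall-detection crop so the outermost walls' upper/lower Canny
  # edges are not clipped by the window boundary
  wtop <- max(1L, win$top_row - 2L)
  wbot <- min(nrow(f1), win$bottom_row + 2L)
  wpix <- f1[wtop:wbot, win$left_col:win$right_col, drop = FALSE]
  geom_rel <- detect_walls(wpix, edge_params = edge, line_params = lines,
                           gap_threshold = gap_threshold)
  geom <- channel_geometry(geom_rel$wall_rows + wtop - 1)

  crop <- function(m) m[win$top_row:win$bottom_row,
                        win$left_col:win$right_col, drop = FALSE]
  bg <- build_background(crop(inv(f1)), blob)
  prev_res <- subtract_background(crop(inv(f1)), bg)
  ledger <- new_detection_ledger(row_tolerance)
  for (i in 2:length(frames)) {
    res <- subtract_background(crop(inv(frames[[i]])), bg)
    diff <- frame_difference(res, prev_res)
    blobs <- detect_blobs(diff, blob)
    blobs$row <- blobs$row + win$top_row - 1
    blobs$col <- blobs$col + win$left_col - 1
    step <- filter_new_particles(blobs, ledger, i)
    ledger <- step$ledger
    prev_res <- res
  }
  out <- summarize_run(ledger, geom, metadata)
  attr(out, "window") <- win
  attr(out, "geometry") <- geom
  attr(out, "rotation") <- rot$rotation
  out
}
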