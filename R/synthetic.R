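#' Synthetic outlet-video configuration
#'
#' Describes a ground-truthed synthetic recording of a DLD outlet region:
#' a horizontal array of outlet channels separated by dark wall lines, with
#' bright (or dark) circular particles advected left to right at constant
#' row — post-sorting flow is channelized, so within the observation window
#' a particle's mode information is carried by which channel it occupies,
#' not by lateral motion. Short vertical end-caps just outside the wall span
#' mark the ends of the array so the templates localize horizontally.
#'
#' Defaults emulate a 12-outlet device imaged at roughly 1.5 µm/px: 10 px
#' particle diameter (circulating-tumor-cell scale, 10-20 µm), 20 px channel
#' pitch, and an advection of 12 px/frame so consecutive particle footprints
#' do not overlap (frame rate matched to flow rate, as the operator is
#' assumed to do).
#'
#' @param n_channels Number of outlet channels (walls = channels + 1).
#' @param wall_spacing Wall-to-wall pitch, px.
#' @param wall_thickness Wall line thickness, px.
#' @param width Frame width, px (height follows from the wall stack).
#' @param n_particles Number of particles traversing the video.
#' @param particle_radius Particle radius, px.
#' @param advection Columns advanced per frame (>= 2; flow is left->right).
#' @param channel_assignment Optional integer vector (length `n_particles`)
#'   fixing each particle's channel; `NULL` draws channels uniformly.
#' @param intensity_bg,intensity_wall,intensity_particle Gray levels.
#' @param noise_sd Gaussian sensor noise standard deviation (intensity
#'   units); clipped to `[0, 255]`.
#' @param skew_angle Global frame skew applied last, degrees
#'   (counterclockwise).
#' @param first_frame_particles If `TRUE`, particles may already be in view
#'   in frame 1 (exercises background patching).
#' @param concurrency Target number of simultaneously visible particles;
#'   sets the video length.
#' @param min_row_sep Minimum row separation enforced between particles
#'   whose transits overlap in time, px (keeps the 1 px repeat-suppression
#'   tolerance meaningful).
#' @param seed Integer seed fixing all randomness.
#' @return A `video_fixture_config` list.
#' @export
video_fixture_config <- function(n_channels = 12L, wall_spacing = 20L,
                                 wall_thickness = 2L, width = 256L,
                                 n_particles = 50L, particle_radius = 5L,
                                 advection = 12, channel_assignment = NULL,
                                 intensity_bg = 100, intensity_wall = 30,
                                 intensity_particle = 220, noise_sd = 0,
                                 skew_angle = 0, first_frame_particles = FALSE,
                                 concurrency = 16L, min_row_sep = 3L,
                                 seed = 1L) {
  stopifnot(n_channels >= 1, advection > 0, n_particles >= 0,
            wall_spacing > wall_thickness, particle_radius >= 1)
  band <- wall_spacing - wall_thickness - 2 * (particle_radius + 1)
  if (band < 1) {
    stop("configuration error: particle footprints overlap the walls ",
         "(increase wall_spacing or shrink particle_radius)", call. = FALSE)
  }
  if (!is.null(channel_assignment) &&
      (length(channel_assignment) != n_particles ||
       any(channel_assignment < 1 | channel_assignment > n_channels))) {
    stop("configuration error: invalid channel_assignment", call. = FALSE)
  }
  structure(as.list(environment()), class = "video_fixture_config")
}

# wall top rows and derived layout for a fixture config
fixture_layout <- function(cfg) {
  top_margin <- 15L
  walls <- top_margin + (seq_len(cfg$n_channels + 1L) - 1L) * cfg$wall_spacing
  height <- max(walls) + cfg$wall_thickness + 13L
  wall_left <- 12L
  wall_right <- cfg$width - 11L
  list(walls = walls, height = height,
       wall_left = wall_left, wall_right = wall_right,
       tick_cols_left = (wall_left - 3L):(wall_left - 1L),
       tick_cols_right = (wall_right + 1L):(wall_right + 3L))
}

# Particle-free scene: walls plus short vertical corner ticks above the top
# wall and below the bottom wall. The ticks give the (array-wide) templates
# distinctive corners so normalized cross-correlation localizes the columns,
# and they sit outside the channels so particles never cross them.
fixture_scene <- function(cfg) {
  lay <- fixture_layout(cfg)
  m <- matrix(cfg$intensity_bg, lay$height, cfg$width)
  for (w in lay$walls) {
    m[w:(w + cfg$wall_thickness - 1L), lay$wall_left:lay$wall_right] <-
      cfg$intensity_wall
  }
  top_tick <- (lay$walls[1] - 6L):(lay$walls[1] - 1L)
  bot_tick <- (max(lay$walls) + cfg$wall_thickness):
    (max(lay$walls) + cfg$wall_thickness + 5L)
  for (cols in list(lay$tick_cols_left, lay$tick_cols_right)) {
    m[top_tick, cols] <- cfg$intensity_wall
    m[bot_tick, cols] <- cfg$intensity_wall
  }
  m
}

# stamp an anti-aliased disk; returns the modified matrix
stamp_disk <- function(m, row, col, radius, intensity) {
  rs <- max(1L, floor(row - radius - 1)):min(nrow(m), ceiling(row + radius + 1))
  cs <- max(1L, floor(col - radius - 1)):min(ncol(m), ceiling(col + radius + 1))
  if (length(rs) == 0L || length(cs) == 0L) return(m)
  d <- sqrt(outer((rs - row)^2, (cs - col)^2, "+"))
  cov <- pmin(pmax(radius + 0.5 - d, 0), 1)
  m[rs, cs] <- m[rs, cs] * (1 - cov) + intensity * cov
  m
}

#' Generate a ground-truthed synthetic DLD outlet video
#'
#' Renders the fixture described by a [video_fixture_config()]: static walls,
#' anti-aliased particles advected left to right at constant rows, Gaussian
#' sensor noise, and (last) a global skew rotation. Frame 1 is particle-free
#' unless `first_frame_particles` is set. Fully determined by the config and
#' its seed.
#'
#' @param config A [video_fixture_config()].
#' @return List: `frames` (a [frame_sequence()]), `truth` (a `ground_truth`
#'   list: `true_total`, `true_per_channel`, `trajectories` — per-particle
#'   data frames of `(frame, row, col)` while in view — and `applied_skew`),
#'   `templates` (top/bottom matrices for [locate_horizontal_bounds()]),
#'   and `layout` (wall rows and column span, for reference).
#' @export
generate_dld_video <- function(config = video_fixture_config()) {
  cfg <- config
  set.seed(cfg$seed)
  lay <- fixture_layout(cfg)
  scene <- fixture_scene(cfg)

  transit <- ceiling((cfg$width + 2 * cfg$particle_radius) / cfg$advection) + 1L
  n_frames <- max(transit + 5L,
                  ceiling(cfg$n_particles * transit / cfg$concurrency) + transit)
  t0_min <- if (cfg$first_frame_particles) 1L - transit %/% 2L else 2L

  channel <- if (is.null(cfg$channel_assignment)) {
    sample.int(cfg$n_channels, cfg$n_particles, replace = TRUE)
  } else as.integer(cfg$channel_assignment)

  # allowed center-row band per channel
  band <- lapply(seq_len(cfg$n_channels), function(k) {
    lo <- lay$walls[k] + cfg$wall_thickness + cfg$particle_radius + 1L
    hi <- lay$walls[k + 1L] - cfg$particle_radius - 2L
    lo:hi
  })

  t0 <- integer(cfg$n_particles)
  rowpos <- numeric(cfg$n_particles)
  if (cfg$n_particles > 0) {
    t0 <- sort(sample(seq(t0_min, max(t0_min, n_frames - transit)),
                      cfg$n_particles, replace = TRUE))
    # Greedy row placement. Temporally overlapping particles keep their rows
    # min_row_sep apart so repeat suppression cannot merge them. Particles
    # whose entry frames are close enough that their columns (advection
    # being uniform) ever coincide within a footprint — in the same frame
    # (fusion into one component) or one frame apart (a follower hidden in
    # the leader's previous-position wake, which frame differencing
    # subtracts away) — keep a full particle diameter apart instead.
    feasible <- function(i) {
      dt <- t0[seq_len(i - 1L)] - t0[i]
      prior <- rowpos[seq_len(i - 1L)]
      diam <- 2 * cfg$particle_radius + 2
      colgap <- pmin(abs(cfg$advection * dt),
                     abs(cfg$advection * (dt - 1L)),
                     abs(cfg$advection * (dt + 1L)))
      wake <- prior[colgap < diam]
      near <- prior[abs(dt) <= transit + 2L]
      ok <- band[[channel[i]]]
      if (length(near)) {
        ok <- ok[vapply(ok, function(r) all(abs(r - near) >= cfg$min_row_sep),
                        logical(1))]
      }
      if (length(wake) && length(ok)) {
        ok <- ok[vapply(ok, function(r) all(abs(r - wake) >= diam + 1),
                        logical(1))]
      }
      ok
    }
    for (i in seq_len(cfg$n_particles)) {
      ok <- feasible(i)
      while (length(ok) == 0L) {
        # no clear row in this channel right now: delay entry until one frees
        t0[i] <- t0[i] + transit
        ok <- feasible(i)
      }
      rowpos[i] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }
    n_frames <- max(n_frames, max(t0) + transit + 2L)
  }

  frames <- vector("list", n_frames)
  traj <- replicate(cfg$n_particles,
                    data.frame(frame = integer(0), row = numeric(0),
                               col = numeric(0)), simplify = FALSE)
  for (t in seq_len(n_frames)) {
    m <- scene
    if (cfg$n_particles > 0) {
      for (i in seq_len(cfg$n_particles)) {
        col <- -cfg$particle_radius + cfg$advection * (t - t0[i])
        if (col < 1 - cfg$particle_radius || col > cfg$width + cfg$particle_radius) next
        m <- stamp_disk(m, rowpos[i], col, cfg$particle_radius,
                        cfg$intensity_particle)
        if (col >= 1 && col <= cfg$width) {
          traj[[i]] <- rbind(traj[[i]],
                             data.frame(frame = t, row = rowpos[i], col = col))
        }
      }
    }
    if (cfg$noise_sd > 0) {
      m <- m + matrix(rnorm(length(m), 0, cfg$noise_sd), nrow(m), ncol(m))
      m <- pmin(pmax(m, 0), 255)
    }
    if (cfg$skew_angle != 0) {
      m <- rotate_frame(m, cfg$skew_angle, crop = "none",
                        fill = cfg$intensity_bg)
      m <- pmin(pmax(m, 0), 255)
    }
    frames[[t]] <- m
  }

  tw <- (lay$wall_left - 3L):(lay$wall_right + 3L)
  top_tpl <- scene[(lay$walls[1] - 6L):(lay$walls[1] + cfg$wall_thickness + 3L),
                   tw, drop = FALSE]
  last <- max(lay$walls)
  bot_tpl <- scene[(last - 4L):(last + cfg$wall_thickness + 5L),
                   tw, drop = FALSE]

  truth <- structure(list(
    true_total = cfg$n_particles,
    true_per_channel = setNames(tabulate(channel, cfg$n_channels),
                                as.character(seq_len(cfg$n_channels))),
    trajectories = traj,
    applied_skew = cfg$skew_angle), class = "ground_truth")

  list(frames = frame_sequence(frames),
       truth = truth,
       templates = list(top = top_tpl, bottom = bot_tpl),
       layout = lay)
}

#' Generate a mode-labeled synthetic dataset
#'
#' Draws labeled run records for the separation-mode classifiers. Flow rate
#' is uniform on 0.5-4.0 mL/min (the operating range of high-throughput DLD
#' experiments); particle size follows the class label (10 µm -> zigzag,
#' 15 µm -> mixed, 20 µm -> bumped); and the 12-outlet distribution is drawn
#' from a mode-specific Dirichlet-style profile: zigzag mass on outlets 1-4
#' (the undisplaced side), mixed on 5-8, bumped on 9-12 (the displaced
#' side). `noise_sd` controls spill of mass outside the mode's outlet block;
#' at 0 the three classes have disjoint distribution supports and are
#' linearly separable by construction.
#'
#' @param n_records Number of records (>= 15 so every class can fill 5
#'   stratified folds).
#' @param class_balance Numeric length-3 vector of class proportions
#'   (zigzag, mixed, bumped); need not be normalized.
#' @param noise_sd Standard deviation of non-negative spill mass added to
#'   every outlet before renormalization.
#' @param seed Integer seed.
#' @return A `mode_dataset`: list with `records` (data frame:
#'   `flow_rate_ml_min`, `particle_size_um`, `outlet_01`..`outlet_12`,
#'   `mode`), `features` (n x 14 matrix), `labels` (factor with levels
#'   zigzag, mixed, bumped).
#' @export
generate_mode_dataset <- function(n_records = 66L,
                                  class_balance = c(1, 1, 1),
                                  noise_sd = 0, seed = 1L) {
  if (n_records < 15L) {
    stop("configuration error: need n_records >= 15 for stratified 5-fold CV",
         call. = FALSE)
  }
  if (length(class_balance) != 3L || any(class_balance < 0) ||
      sum(class_balance) == 0) {
    stop("configuration error: class_balance must be 3 non-negative ",
         "proportions", call. = FALSE)
  }
  set.seed(seed)
  modes <- c("zigzag", "mixed", "bumped")
  sizes <- c(zigzag = 10, mixed = 15, bumped = 20)
  blocks <- list(zigzag = 1:4, mixed = 5:8, bumped = 9:12)
  p <- class_balance / sum(class_balance)
  counts <- floor(n_records * p)
  rem <- n_records - sum(counts)
  if (rem > 0) counts[order(-(n_records * p - counts))[seq_len(rem)]] <-
      counts[order(-(n_records * p - counts))[seq_len(rem)]] + 1
  lab <- factor(rep(modes, counts), levels = modes)

  dist <- matrix(0, n_records, 12)
  for (i in seq_len(n_records)) {
    w <- numeric(12)
    w[blocks[[as.character(lab[i])]]] <- rgamma(4, shape = 5, rate = 1)
    if (noise_sd > 0) w <- w + abs(rnorm(12, 0, noise_sd))
    dist[i, ] <- w / sum(w)
  }
  records <- data.frame(
    flow_rate_ml_min = runif(n_records, 0.5, 4.0),
    particle_size_um = unname(sizes[as.character(lab)]))
  for (k in 1:12) records[[sprintf("outlet_%02d", k)]] <- dist[, k]
  records$mode <- lab
  mode_dataset(records)
}

#' Construct a mode dataset from a record data frame
#'
#' @param records Data frame with columns `flow_rate_ml_min`,
#'   `particle_size_um`, `outlet_01`..`outlet_12`, `mode`.
#' @return A `mode_dataset` (see [generate_mode_dataset()]).
#' @export
mode_dataset <- function(records) {
  need <- c("flow_rate_ml_min", "particle_size_um",
            sprintf("outlet_%02d", 1:12), "mode")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("dimension error: missing feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(records$flow_rate_ml_min <= 0) || any(records$particle_size_um <= 0)) {
    stop("flow rate and particle size must be positive", call. = FALSE)
  }
  labels <- factor(records$mode, levels = c("zigzag", "mixed", "bumped"))
  if (anyNA(labels)) {
    stop("labeling error: mode must be one of zigzag/mixed/bumped",
         call. = FALSE)
  }
  features <- as.matrix(records[, need[1:14]])
  structure(list(records = records[, need], features = features,
                 labels = labels), class = "mode_dataset")
}

#' @export
print.mode_dataset <- function(x, ...) {
  cat(sprintf("mode_dataset: %d records x 14 features; classes: %s\n",
              nrow(x$features),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
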