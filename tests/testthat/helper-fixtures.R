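# shared fixtures and independent oracles, built in code at test time

# dark near-horizontal lines at content angle `theta` (deg, CCW positive)
# on a bright background
render_line_frame <- function(theta, nr = 200, nc = 300,
                              rows = c(50, 100, 150), bg = 200, fg = 30) {
  m <- matrix(bg, nr, nc)
  s <- -tan(theta * pi / 180)
  for (r0 in rows) {
    for (cc in 20:(nc - 20)) {
      rr <- round(r0 + s * (cc - nc / 2))
      if (rr >= 1 && rr <= nr - 1) m[rr:(rr + 1), cc] <- fg
    }
  }
  m
}

# brute-force gap-split grouping oracle: split the sorted distinct vote rows
# at every gap > gap_threshold; within each group take the most-voted row,
# ties to the smaller row
oracle_group_votes <- function(votes, gap_threshold) {
  if (length(votes) == 0L) return(integer(0))
  rows <- sort(unique(votes))
  counts <- sapply(rows, function(r) sum(votes == r))
  groups <- list(1L)
  for (i in seq_along(rows)[-1]) {
    if (rows[i] - rows[i - 1L] > gap_threshold) {
      groups[[length(groups) + 1L]] <- i
    } else {
      groups[[length(groups)]] <- c(groups[[length(groups)]], i)
    }
  }
  out <- integer(0)
  for (g in groups) {
    best <- g[counts[g] == max(counts[g])]
    out <- c(out, rows[min(best)])
  }
  out
}

# brute-force repeat-suppression oracle: a transparent double loop encoding
# the rule table — NEW if the row differs from every previous row by more
# than the tolerance, NEW if (row, col) exactly repeats a previous centroid
# (a particle cannot be stationary), REPEAT otherwise (nearest row within
# tolerance, same particle advected). Duplicate current centroids collapse
# first. Returns the NEW subset in order.
oracle_filter_new <- function(current, previous, tol = 1) {
  cur <- unique(data.frame(row = round(current$row, 1),
                           col = round(current$col, 1)))
  keep <- logical(nrow(cur))
  for (i in seq_len(nrow(cur))) {
    if (nrow(previous) == 0L) { keep[i] <- TRUE; next }
    within <- abs(previous$row - cur$row[i]) <= tol
    if (!any(within)) { keep[i] <- TRUE; next }
    dr <- abs(previous$row - cur$row[i]); dr[!within] <- Inf
    ord <- order(dr, abs(previous$col - cur$col[i]))
    j <- ord[1]
    keep[i] <- previous$row[j] == cur$row[i] && previous$col[j] == cur$col[i]
  }
  cur[keep, , drop = FALSE]
}

# random centroid sets on a small grid (rows/cols rounded to 0.5 px) for
# property tests of the rule table
random_centroids <- function(n, seed_rows = NULL) {
  if (n == 0L) return(data.frame(row = numeric(0), col = numeric(0)))
  data.frame(row = sample(seq(1, 20, by = 0.5), n, replace = TRUE),
             col = sample(seq(1, 60, by = 0.5), n, replace = TRUE))
}

# small, quick synthetic video for integration tests
quick_video <- function(n_particles = 12L, noise_sd = 0, seed = 1L, ...) {
  generate_dld_video(video_fixture_config(
    n_particles = n_particles, noise_sd = noise_sd, seed = seed, ...))
}

quick_blob_params <- function() blob_params_for_particle(10, 1.0)
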