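test_that("a blob-free first frame passes through bit-identical", {
  v0 <- quick_video(n_particles = 0L, noise_sd = 3, seed = 30)
  frame <- v0$frames$frames[[1]]
  bg <- build_background(frame, quick_blob_params())
  expect_identical(bg$pixels, frame)
  expect_equal(nrow(bg$patched_regions), 0L)
})

test_that("blob pixels are replaced by their row's non-blob mean", {
  # 10x10 frame, a 3x3 blob at rows 4-6 / cols 5-7: each affected row's
  # blob pixels become the mean of that row's other 7 pixels
  frame <- matrix(rep(seq(10, 100, by = 10), each = 10), 10, 10)
  frame <- frame + matrix(rep(0:9, times = 10), 10, 10)  # row/col gradient
  mask <- matrix(FALSE, 10, 10)
  mask[4:6, 5:7] <- TRUE
  bg <- build_background(frame, mask = mask)
  for (r in 4:6) {
    expected <- mean(frame[r, c(1:4, 8:10)])
    expect_equal(unname(bg$pixels[r, 5:7]), rep(expected, 3))
  }
  expect_identical(bg$pixels[!mask], frame[!mask])
  expect_equal(bg$patched_regions$row, 4:6)
  expect_false(any(bg$patched_regions$global_fallback))
})

test_that("an all-blob row falls back to the global non-blob mean, flagged", {
  frame <- matrix(50, 6, 8)
  frame[3, ] <- 200
  mask <- matrix(FALSE, 6, 8)
  mask[3, ] <- TRUE
  bg <- build_background(frame, mask = mask)
  expect_equal(unname(bg$pixels[3, ]), rep(50, 8))
  expect_true(bg$patched_regions$global_fallback[bg$patched_regions$row == 3])
})

test_that("patching a stamped particle restores the particle-free scene", {
  v0 <- quick_video(n_particles = 0L, seed = 31)
  clean <- v0$frames$frames[[1]]
  dirty <- dldflow:::stamp_disk(clean, 65, 120, 5, 220)
  bg <- build_background(dirty, quick_blob_params())
  expect_lt(max(abs(bg$pixels - clean)), 6)
  expect_gt(nrow(bg$patched_regions), 0L)
})

test_that("background construction is idempotent", {
  v0 <- quick_video(n_particles = 0L, seed = 32)
  dirty <- dldflow:::stamp_disk(v0$frames$frames[[1]], 45, 80, 5, 220)
  bg1 <- build_background(dirty, quick_blob_params())
  bg2 <- build_background(bg1$pixels, quick_blob_params())
  expect_identical(bg2$pixels, bg1$pixels)
})

test_that("background subtraction clamps negatives at zero", {
  bg <- matrix(c(50, 80), 2, 2)
  frame <- matrix(c(80, 50), 2, 2)
  expect_equal(subtract_background(frame, bg), matrix(c(30, 0), 2, 2))
  expect_equal(subtract_background(bg, bg), matrix(0, 2, 2))
  expect_error(subtract_background(matrix(0, 2, 3), bg), "dimension error")
})

test_that("residual support stays on the particle footprint", {
  v0 <- quick_video(n_particles = 0L, seed = 33)
  clean <- v0$frames$frames[[1]]
  bg <- build_background(clean, quick_blob_params())
  withp <- dldflow:::stamp_disk(clean, 65, 120, 5, 220)
  res <- subtract_background(withp, bg)
  on <- which(res > 5, arr.ind = TRUE)
  expect_gt(nrow(on), 0L)
  expect_true(all(sqrt((on[, 1] - 65)^2 + (on[, 2] - 120)^2) <= 7))
})

test_that("frame differencing isolates newly occupied positions", {
  a <- matrix(0, 30, 40)
  expect_equal(frame_difference(a, a), a)
  curr <- dldflow:::stamp_disk(a, 15, 30, 4, 100)
  expect_equal(frame_difference(curr, a), curr)   # subtraction of zero
  prev <- dldflow:::stamp_disk(a, 15, 20, 4, 100)
  d <- frame_difference(curr, prev)
  on <- which(d > 5, arr.ind = TRUE)
  expect_true(all(on[, 2] > 24))  # support concentrated at the new location
  expect_error(frame_difference(a, matrix(0, 2, 2)), "dimension error")
})

test_that("blob detection finds disk centroids and rejects thin shapes", {
  expect_equal(nrow(detect_blobs(matrix(0, 40, 50))), 0L)
  m <- matrix(0, 40, 60)
  d <- sqrt(outer((1:40 - 20)^2, (1:60 - 30)^2, "+"))
  m[d <= 5] <- 200
  b <- detect_blobs(m, blob_params(min_area = 20))
  expect_equal(nrow(b), 1L)
  expect_equal(b$row, 20, tolerance = 0.05)
  expect_equal(b$col, 30, tolerance = 0.05)
  # a 1x4 segment fails a 0.7 circularity floor; a same-area compact blob passes
  seg <- matrix(0, 20, 20); seg[10, 8:11] <- 200
  expect_equal(nrow(detect_blobs(seg, blob_params(min_area = 2,
                                                  min_circularity = 0.7))), 0L)
  sq <- matrix(0, 20, 20); sq[9:10, 9:10] <- 200
  expect_equal(nrow(detect_blobs(sq, blob_params(min_area = 2,
                                                 min_circularity = 0.7))), 1L)
})

test_that("repeat suppression follows the stated rule set", {
  led <- new_detection_ledger(row_tolerance = 1)
  # seed the previous pair
  st <- filter_new_particles(data.frame(row = 100, col = 50), led, 2)
  expect_equal(nrow(st$new), 1L)
  # same row, column advanced -> repeat, suppressed
  st2 <- filter_new_particles(data.frame(row = 100, col = 60), st$ledger, 3)
  expect_equal(nrow(st2$new), 0L)
  # row moved beyond the 1 px tolerance -> new particle
  st3 <- filter_new_particles(data.frame(row = 105, col = 60), st2$ledger, 4)
  expect_equal(nrow(st3$new), 1L)
  # identical position -> new (a real particle can never be stationary)
  led2 <- filter_new_particles(data.frame(row = 100, col = 50),
                               new_detection_ledger(1), 2)$ledger
  st4 <- filter_new_particles(data.frame(row = 100, col = 50), led2, 3)
  expect_equal(nrow(st4$new), 1L)
  # the conservative flag suppresses the stationary repeat instead
  st4b <- filter_new_particles(data.frame(row = 100, col = 50), led2, 3,
                               stationary_is_new = FALSE)
  expect_equal(nrow(st4b$new), 0L)
  # duplicates collapse before classification; within-tolerance row with a
  # changed column is a repeat
  led3 <- filter_new_particles(data.frame(row = 100, col = 50),
                               new_detection_ledger(1), 2)$ledger
  st5 <- filter_new_particles(data.frame(row = c(100.5, 100.5),
                                         col = c(60, 60)), led3, 3)
  expect_equal(nrow(st5$new), 0L)
  expect_equal(nrow(st5$ledger$previous), 1L)
})

test_that("repeat suppression matches the brute-force rule table", {
  set.seed(7)
  for (case in 1:300) {
    prev <- random_centroids(sample(0:5, 1))
    cur <- random_centroids(sample(0:5, 1))
    led <- new_detection_ledger(1)
    led$previous <- data.frame(row = round(prev$row, 1),
                               col = round(prev$col, 1))
    got <- filter_new_particles(cur, led, 5)$new
    want <- oracle_filter_new(cur, led$previous, tol = 1)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$row, want$row)
      expect_equal(got$col, want$col)
    }
  }
})

test_that("unique detections grow monotonically over frames", {
  set.seed(8)
  led <- new_detection_ledger(1)
  n_prev <- 0L
  for (f in 2:20) {
    led <- filter_new_particles(random_centroids(sample(0:4, 1)), led, f)$ledger
    expect_gte(nrow(led$detections), n_prev)
    n_prev <- nrow(led$detections)
  }
})

test_that("channel assignment uses half-open wall intervals", {
  geom <- channel_geometry(c(0, 10, 20))
  det <- data.frame(row = c(5, 10, 25, 0.5, 20))
  out <- assign_channels(det, geom)
  expect_equal(out$channel_id, c(1L, 1L, NA_integer_, 1L, 2L))
})

test_that("run summaries report counts, percentages and the particle table", {
  geom <- channel_geometry(c(0, 10, 20, 30))
  led <- new_detection_ledger(1)
  rows <- c(rep(5, 2), rep(15, 3), rep(25, 5))
  led$detections <- data.frame(frame_index = seq_along(rows) + 1L,
                               row = rows, col = seq_along(rows) * 10)
  s <- summarize_run(led, geom, metadata = list(flow_rate = 2.5))
  expect_equal(as.integer(s$channel_counts), c(2L, 3L, 5L))
  expect_equal(unname(s$percentages), c(20, 30, 50))
  expect_equal(s$total, 10L)
  expect_equal(nrow(s$particles), 10L)
  expect_equal(s$metadata$flow_rate, 2.5)
})

test_that("the reported outlet totals add up as in a published run table", {
  # outlets 9-12 carrying 4, 5, 7 and 9 particles sum to a 25-particle run
  counts <- c(rep(0, 8), 4, 5, 7, 9)
  geom <- channel_geometry(seq(0, 120, by = 10))
  rows <- unlist(mapply(function(ch, n) rep(ch * 10 - 5, n), 1:12, counts))
  led <- new_detection_ledger(1)
  led$detections <- data.frame(frame_index = 2L, row = rows,
                               col = seq_along(rows))
  s <- summarize_run(led, geom)
  expect_equal(as.integer(s$channel_counts), counts)
  expect_equal(s$total, 25L)
})

test_that("an empty ledger summarizes to zeros with guarded percentages", {
  s <- summarize_run(new_detection_ledger(1), channel_geometry(c(0, 10, 20)))
  expect_equal(s$total, 0L)
  expect_equal(as.integer(s$channel_counts), c(0L, 0L))
  expect_equal(unname(s$percentages), c(0, 0))
})

test_that("counts conserve and percentages sum to 100 on random ledgers", {
  set.seed(9)
  geom <- channel_geometry(seq(0, 60, by = 5))
  for (i in 1:20) {
    n <- sample(1:40, 1)
    led <- new_detection_ledger(1)
    led$detections <- data.frame(frame_index = 2L,
                                 row = runif(n, -5, 70),
                                 col = runif(n, 1, 100))
    s <- summarize_run(led, geom)
    expect_equal(s$n_assigned + s$unassigned, s$total)
    expect_equal(sum(s$channel_counts), s$n_assigned)
    if (s$n_assigned > 0) expect_equal(sum(s$percentages), 100)
  }
})

test_that("the full pipeline recovers exact counts on a noise-free video", {
  v <- quick_video(n_particles = 12L, noise_sd = 0, seed = 41)
  s <- detect_particles(v$frames, v$templates, blob = quick_blob_params())
  expect_equal(s$total, 12L)
  expect_equal(as.integer(s$channel_counts),
               as.integer(v$truth$true_per_channel))
  expect_equal(s$unassigned, 0L)
})
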