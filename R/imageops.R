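# Low-level raster operations shared by the geometry and detection stages.
# All functions take plain numeric matrices in (row, col) orientation.

# shift a matrix by (dr, dc), filling vacated cells
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# shift with edge replication (for convolution padding)
shift_rep <- function(m, dr, dc) {
  rs <- pmin(pmax(seq_len(nrow(m)) - dr, 1L), nrow(m))
  cs <- pmin(pmax(seq_len(ncol(m)) - dc, 1L), ncol(m))
  m[rs, cs]
}

# separable convolution with a symmetric odd-length 1-d kernel
sepconv <- function(m, k) {
  rad <- (length(k) - 1L) / 2L
  offs <- seq(-rad, rad)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(offs)) out <- out + k[i] * shift_rep(m, offs[i], 0)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_along(offs)) out <- out + k[i] * shift_rep(m2, 0, offs[i])
  out
}

gauss_kernel <- function(sigma) {
  rad <- max(1L, ceiling(2.5 * sigma))
  k <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
  k / sum(k)
}

# 3x3 binary dilation
dilate3 <- function(mask) {
  out <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) out <- out | shift_mat(mask, dr, dc, FALSE)
  }
  out
}

#' Canny edge detection
#'
#' Classic Canny pipeline: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and double
#' thresholding. Hysteresis keeps strong edges plus weak edges within one
#' pixel of a strong edge. When `low`/`high` are `NULL` they default to the
#' median-intensity rule `0.66 * median(frame)` and `1.33 * median(frame)`.
#'
#' @param frame Numeric matrix, intensities in `[0, 255]`.
#' @param params A [canny_params()] list.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(frame, params = canny_params()) {
  low <- params$low; high <- params$high
  if (is.null(low) || is.null(high)) {
    v <- median(frame)
    if (is.null(low)) low <- 0.66 * v
    if (is.null(high)) high <- 1.33 * v
  }
  sm <- sepconv(frame, gauss_kernel(params$sigma))
  # Sobel: smoothing [1 2 1] across, difference [-1 0 1] along
  sx <- function(m) shift_rep(m, 0, -1) + 2 * m + shift_rep(m, 0, 1)
  sy <- function(m) shift_rep(m, -1, 0) + 2 * m + shift_rep(m, 1, 0)
  gx <- sy(shift_rep(sm, 0, -1) - shift_rep(sm, 0, 1))   # d/dcol
  gy <- sx(shift_rep(sm, -1, 0) - shift_rep(sm, 1, 0))   # d/drow
  mag <- sqrt(gx^2 + gy^2)
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  # quantized direction bins -> neighbor offsets along the gradient
  bins <- list(
    h  = list(sel = ang < 22.5 | ang >= 157.5, o = c(0L, 1L)),
    d1 = list(sel = ang >= 22.5 & ang < 67.5, o = c(1L, 1L)),
    v  = list(sel = ang >= 67.5 & ang < 112.5, o = c(1L, 0L)),
    d2 = list(sel = ang >= 112.5 & ang < 157.5, o = c(1L, -1L))
  )
  keep <- matrix(FALSE, nrow(frame), ncol(frame))
  for (b in bins) {
    n1 <- shift_mat(mag, -b$o[1], -b$o[2], Inf)  # neighbor in +gradient dir
    n2 <- shift_mat(mag, b$o[1], b$o[2], Inf)    # neighbor in -gradient dir
    # ties keep both pixels: a two-pixel plateau (anti-aliased edge exactly
    # between rows) must not open a hole in the edge chain
    keep <- keep | (b$sel & mag >= n1 & mag >= n2)
  }
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  # hysteresis: grow strong edges through 8-connected weak pixels until
  # no further pixels join (fills threshold dips along anti-aliased lines)
  repeat {
    grown <- dilate3(strong) & weak & !strong
    if (!any(grown)) break
    strong <- strong | grown
  }
  strong
}

#' Canny parameters
#'
#' @param low,high Hysteresis thresholds on the Sobel gradient magnitude;
#'   `NULL` selects the automatic median-based rule (see [canny_edges()]).
#' @param sigma Gaussian smoothing standard deviation in pixels.
#' @return A parameter list.
#' @export
canny_params <- function(low = NULL, high = NULL, sigma = 1.0) {
  list(low = low, high = high, sigma = sigma)
}

#' Hough parameters for near-horizontal line-segment detection
#'
#' @param angles Candidate content angles from the horizontal, in degrees
#'   (counterclockwise positive).
#' @param min_length Minimum segment extent along the column axis, in px;
#'   `NULL` means 25% of the image width (at least 20 px).
#' @param max_gap Maximum column gap within a segment, px.
#' @param vote_threshold Minimum supporting pixels for a candidate line;
#'   `NULL` means the resolved `min_length`.
#' @param rho_tol Perpendicular distance (rows) within which a pixel supports
#'   a line.
#' @return A parameter list.
#' @export
hough_params <- function(angles = seq(-8, 8, by = 0.25), min_length = NULL,
                         max_gap = 5, vote_threshold = NULL, rho_tol = 1) {
  list(angles = angles, min_length = min_length, max_gap = max_gap,
       vote_threshold = vote_threshold, rho_tol = rho_tol)
}

#' Detect near-horizontal line segments
#'
#' A deterministic Hough-style segment detector specialized to
#' near-horizontal structure: for every candidate angle the edge pixels are
#' binned by line intercept; peaks above the vote threshold are processed in
#' descending vote order, each claiming its supporting pixels (within
#' `rho_tol` rows of the line), which are least-squares refined and split
#' into segments wherever the column gap exceeds `max_gap`. Segments shorter
#' than `min_length` columns are dropped.
#'
#' Angles are content angles from the horizontal, counterclockwise positive
#' (a line whose rows decrease as columns increase has positive angle).
#'
#' @param edges Logical matrix of edge/foreground pixels.
#' @param params A [hough_params()] list.
#' @return A data frame with one row per segment (`c1`, `c2`, `r1`, `r2`,
#'   `angle`, `n_pix`), carrying an attribute `row_votes`: the rounded row of
#'   every supporting pixel of every accepted segment (used for wall voting).
#' @export
hough_segments <- function(edges, params = hough_params()) {
  empty <- data.frame(c1 = numeric(0), c2 = numeric(0), r1 = numeric(0),
                      r2 = numeric(0), angle = numeric(0), n_pix = integer(0))
  attr(empty, "row_votes") <- integer(0)
  pts <- which(edges, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(empty)
  min_length <- params$min_length
  if (is.null(min_length)) min_length <- max(20, round(0.25 * ncol(edges)))
  vote_threshold <- params$vote_threshold
  if (is.null(vote_threshold)) vote_threshold <- min_length
  r <- pts[, 1]; c <- pts[, 2]
  slopes <- -tan(params$angles * pi / 180)  # drow/dcol for CCW-positive angle
  # accumulate (angle, intercept) votes
  cand <- vector("list", length(slopes))
  for (ai in seq_along(slopes)) {
    b <- round(r - slopes[ai] * c)
    tb <- table(b)
    hit <- tb >= vote_threshold
    if (any(hit)) {
      cand[[ai]] <- data.frame(ai = ai, b = as.numeric(names(tb))[hit],
                               votes = as.integer(tb[hit]))
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$votes), , drop = FALSE]
  used <- logical(length(r))
  segs <- list(); votes <- list()
  for (i in seq_len(nrow(cand))) {
    s <- slopes[cand$ai[i]]
    memb <- !used & abs(r - (cand$b[i] + s * c)) <= params$rho_tol
    if (sum(memb) < vote_threshold) next
    used[memb] <- TRUE
    mr <- r[memb]; mc <- c[memb]
    ord <- order(mc, mr)
    mr <- mr[ord]; mc <- mc[ord]
    brk <- c(0L, which(diff(mc) > params$max_gap), length(mc))
    for (g in seq_len(length(brk) - 1L)) {
      sel <- (brk[g] + 1L):brk[g + 1L]
      gc <- mc[sel]; gr <- mr[sel]
      if (gc[length(gc)] - gc[1] + 1 < min_length) next
      vx <- var(gc)
      sl <- if (is.na(vx) || vx == 0) 0 else cov(gc, gr) / vx
      ic <- mean(gr) - sl * mean(gc)
      segs[[length(segs) + 1L]] <- data.frame(
        c1 = gc[1], c2 = gc[length(gc)],
        r1 = ic + sl * gc[1], r2 = ic + sl * gc[length(gc)],
        angle = atan(-sl) * 180 / pi, n_pix = length(gc))
      votes[[length(votes) + 1L]] <- as.integer(round(gr))
    }
  }
  if (length(segs) == 0L) return(empty)
  out <- do.call(rbind, segs)
  out <- out[order(out$r1, out$c1), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "row_votes") <- unlist(votes)
  out
}

# largest axis-aligned rectangle inside a w x h rectangle rotated by `angle`
# degrees (the classic closed form)
interior_rect <- function(w, h, angle) {
  a <- abs(angle) * pi / 180
  if (a < 1e-12) return(c(w = w, h = h))
  sin_a <- sin(a); cos_a <- cos(a)
  long <- max(w, h); short <- min(w, h)
  if (short <= 2 * sin_a * cos_a * long || abs(sin_a - cos_a) < 1e-10) {
    x <- 0.5 * short
    if (w >= h) c(w = x / sin_a, h = x / cos_a) else c(w = x / cos_a, h = x / sin_a)
  } else {
    cos2 <- cos_a^2 - sin_a^2
    c(w = (w * cos_a - h * sin_a) / cos2, h = (h * cos_a - w * sin_a) / cos2)
  }
}

#' Rotate a frame about its center
#'
#' Bilinear rotation of the image content by `angle` degrees
#' (counterclockwise positive, matching the sign convention of
#' [estimate_skew_angle()]). With `crop = "interior"` the output is cropped
#' to the largest axis-aligned rectangle guaranteed free of fill pixels,
#' since fill corrupts downstream edge detection; with `crop = "none"` the
#' full-size frame is returned with `fill` outside the source support.
#'
#' @param frame Numeric matrix.
#' @param angle Degrees, counterclockwise positive.
#' @param crop `"interior"` or `"none"`.
#' @param fill Intensity for out-of-source pixels when `crop = "none"`.
#' @return Numeric matrix (dimensions shrink when cropping).
#' @export
rotate_frame <- function(frame, angle, crop = c("interior", "none"), fill = 0) {
  crop <- match.arg(crop)
  if (abs(angle) < 1e-9) return(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  t <- -angle * pi / 180
  # content CCW (visual, y-up) == CW in (row-down, col) coords; the inverse
  # map therefore rotates output coords CCW in row-down space
  co <- cos(t); si <- sin(t)
  dr <- rep(seq_len(nr) - cy, times = nc)
  dc <- rep(seq_len(nc) - cx, each = nr)
  src_r <- co * dr - si * dc + cy
  src_c <- si * dr + co * dc + cx
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  inside <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  gi <- function(rr, cc) {
    v <- numeric(length(rr))
    ok <- inside
    v[ok] <- frame[cbind(rr[ok], cc[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * gi(r0, c0) + (1 - fr) * fc * gi(r0, c0 + 1) +
       fr * (1 - fc) * gi(r0 + 1, c0) + fr * fc * gi(r0 + 1, c0 + 1)
  v[!inside] <- fill
  out <- matrix(v, nr, nc)
  if (crop == "interior") {
    ir <- interior_rect(nc, nr, angle)
    hh <- max(3L, floor(ir["h"]) - 2L); ww <- max(3L, floor(ir["w"]) - 2L)
    rt <- floor(cy - hh / 2); ct <- floor(cx - ww / 2)
    out <- out[rt:(rt + hh - 1L), ct:(ct + ww - 1L)]
  }
  out
}

#' Normalized cross-correlation template matching
#'
#' Slides `template` over `frame` and returns the normalized
#' cross-correlation score at every valid upper-left position (FFT-based
#' numerator, integral-image local statistics). Scores lie in `[-1, 1]`;
#' zero-variance patches score 0.
#'
#' @param frame Numeric matrix.
#' @param template Numeric matrix, strictly smaller than `frame` in both
#'   dimensions.
#' @return List: `score` (matrix of NCC values, dim `(nr-tr+1) x (nc-tc+1)`),
#'   `best` (upper-left `(row, col)` of the best match), `max_score`.
#' @export
match_template <- function(frame, template) {
  nr <- nrow(frame); nc <- ncol(frame)
  tr <- nrow(template); tc <- ncol(template)
  if (tr >= nr || tc >= nc) {
    stop("template must be strictly smaller than the frame", call. = FALSE)
  }
  pr <- nr + tr - 1L; pc <- nc + tc - 1L
  pf <- matrix(0, pr, pc); pf[1:nr, 1:nc] <- frame
  pt <- matrix(0, pr, pc); pt[1:tr, 1:tc] <- template
  cross <- Re(fft(fft(pf) * Conj(fft(pt)), inverse = TRUE)) / (pr * pc)
  cross <- cross[1:(nr - tr + 1L), 1:(nc - tc + 1L), drop = FALSE]
  # local sums over tr x tc patches via integral images
  ii <- function(m) {
    s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumsum2d
    t(s)
  }
  patch_sum <- function(m) {
    s <- ii(m)
    s <- rbind(0, cbind(0, s))
    a <- s[(tr + 1L):(nr + 1L), (tc + 1L):(nc + 1L), drop = FALSE]
    b <- s[1:(nr - tr + 1L), (tc + 1L):(nc + 1L), drop = FALSE]
    d <- s[(tr + 1L):(nr + 1L), 1:(nc - tc + 1L), drop = FALSE]
    e <- s[1:(nr - tr + 1L), 1:(nc - tc + 1L), drop = FALSE]
    a - b - d + e
  }
  n <- tr * tc
  s1 <- patch_sum(frame)
  s2 <- patch_sum(frame^2)
  tm <- mean(template)
  tss <- sum((template - tm)^2)
  num <- cross - s1 * tm
  den2 <- (s2 - s1^2 / n) * tss
  den2[den2 < 1e-9] <- NA
  score <- num / sqrt(den2)
  score[is.na(score)] <- 0
  score[score > 1] <- 1; score[score < -1] <- -1
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  list(score = score, best = c(row = unname(best[1]), col = unname(best[2])),
       max_score = max(score))
}

# per-component statistics of a label matrix (labels 1..k, 0 = background):
# area, centroid, crack-length perimeter (count of pixel edges between the
# component and anything else)
label_stats <- function(lab) {
  k <- max(lab)
  if (k == 0L) {
    return(data.frame(label = integer(0), area = integer(0),
                      row = numeric(0), col = numeric(0),
                      perimeter = integer(0), circularity = numeric(0)))
  }
  idx <- which(lab > 0)
  v <- lab[idx]
  nr <- nrow(lab)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(v, k)
  sr <- rowsum(as.numeric(rows), v)
  sc <- rowsum(as.numeric(cols), v)
  labs_present <- as.integer(rownames(sr))
  per <- integer(k)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(lab, d[1], d[2], 0L)
    mism <- lab > 0L & nb != lab
    per <- per + tabulate(lab[mism], k)
  }
  cen_r <- numeric(k); cen_c <- numeric(k)
  cen_r[labs_present] <- sr[, 1] / area[labs_present]
  cen_c[labs_present] <- sc[, 1] / area[labs_present]
  data.frame(label = seq_len(k), area = area, row = cen_r, col = cen_c,
             perimeter = per,
             circularity = ifelse(per > 0, 4 * pi * area / per^2, 0))
}
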