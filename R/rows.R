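#' Boundary pixels of a binary mask
#'
#' Returns every foreground pixel with at least one background 8-neighbour
#' (image-border foreground pixels count as boundary). On a binary input this
#' is exactly the edge set a Canny detector reduces to, computed instead by a
#' deterministic, parameter-free morphological rule: it equals the difference
#' between the mask and its 8-connected erosion.
#'
#' @param mask a [binary_mask] or logical matrix.
#' @return `N x 2` matrix with columns `x` (col) and `y` (row); zero rows for
#'   an empty mask.
#' @export
edge_points <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) return(cbind(x = numeric(0), y = numeric(0)))
  mi <- matrix(as.integer(m), nrow(m), ncol(m))
  interior <- matrix(TRUE, nrow(m), ncol(m))
  for (k in seq_len(nrow(NEIGH8))) {
    interior <- interior & shift_mat(mi, NEIGH8[k, 1], NEIGH8[k, 2], 0L) == 1L
  }
  idx <- which(m & !interior, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Hough accumulator for line detection
#'
#' Votes every point into every orientation bin using the normal line
#' parameterization `rho = x cos(theta) + y sin(theta)` (x = column,
#' y = row; `theta_row = 90` degrees corresponds to horizontal lines). The
#' default axes follow the crop-row detection setup: orientations over
#' (-90, 90] degrees in 0.1 degree steps and offsets -3000..3000 px in 1 px
#' steps.
#'
#' @param points `N x 2` matrix (columns x, y), e.g. from [edge_points()].
#' @param theta_deg orientation bin centres, degrees.
#' @param rho_axis offset bin centres, pixels (regular spacing).
#' @return An object of class `hough_acc`: integer `counts` matrix indexed
#'   `[theta bin, rho bin]` plus the two axes.
#' @export
hough_accumulate <- function(points,
                             theta_deg = seq(-89.9, 90, by = 0.1),
                             rho_axis = seq(-3000, 3000, by = 1)) {
  points <- matrix(as.numeric(points), ncol = 2)
  wd_assert(nrow(points) >= 1, "wheatdens_degenerate_input", "no points to vote")
  rho0 <- rho_axis[1]
  step <- if (length(rho_axis) > 1) rho_axis[2] - rho_axis[1] else 1
  nr <- length(rho_axis)
  x <- points[, 1]; y <- points[, 2]
  counts <- matrix(0L, nrow = length(theta_deg), ncol = nr)
  for (i in seq_along(theta_deg)) {
    th <- theta_deg[i] * pi / 180
    rho <- x * cos(th) + y * sin(th)
    bin <- round((rho - rho0) / step) + 1
    if (any(bin < 1 | bin > nr)) {
      wd_error("wheatdens_range_error",
               "point falls outside the rho axis; crop the image or widen rho_axis")
    }
    counts[i, ] <- tabulate(bin, nbins = nr)
  }
  structure(list(counts = counts, theta_deg = theta_deg, rho_axis = rho_axis,
                 n_points = nrow(points)),
            class = "hough_acc")
}

#' Dominant row orientation from a Hough accumulator
#'
#' Rows being parallel, all their votes at the true orientation concentrate
#' in a few rho bins, which maximizes the variance of the vote counts across
#' rho at that theta column. Ties are broken towards |theta| closest to 90
#' degrees since rows are near-horizontal by acquisition design.
#'
#' @param acc a `hough_acc`.
#' @param flat_tol relative spread of the variance profile below which the
#'   orientation is declared undetectable.
#' @return Orientation `theta_row` in degrees.
#' @export
row_orientation <- function(acc, flat_tol = 0.05) {
  wd_assert(inherits(acc, "hough_acc"), "wheatdens_shape_error", "need a hough_acc")
  wd_assert(acc$n_points >= 2, "wheatdens_degenerate_input",
            "orientation needs at least 2 points")
  cnt <- acc$counts
  n <- ncol(cnt)
  mu <- rowSums(cnt) / n
  v <- rowSums(cnt^2) / n - mu^2
  vmax <- max(v)
  if (vmax <= 0 || (vmax - min(v)) < flat_tol * vmax) {
    wd_error("wheatdens_orientation_undetectable",
             "no dominant orientation: variance profile is flat")
  }
  cand <- which(v >= vmax * (1 - 1e-12))
  acc$theta_deg[cand[which.max(abs(acc$theta_deg[cand]))]]
}

#' Row offsets from the Hough column at the row orientation
#'
#' Extracts the vote profile over rho at `theta_row`, smooths it with a short
#' boxcar (rows are bands of plants, not 1-px lines), and picks local maxima
#' above a prominence threshold, greedily in decreasing height subject to a
#' minimum mutual separation.
#'
#' @param acc a `hough_acc`.
#' @param theta_row orientation from [row_orientation()].
#' @param min_separation_px minimum distance between accepted peaks,
#'   typically 0.6 x expected row spacing.
#' @param prominence accept peaks above `prominence * max(profile)`.
#' @param smooth_px boxcar half-window for profile smoothing; default scales
#'   with the separation.
#' @return Increasing vector of rho offsets (pixels).
#' @export
row_positions <- function(acc, theta_row, min_separation_px,
                          prominence = 0.3, smooth_px = NULL) {
  it <- which.min(abs(acc$theta_deg - theta_row))
  profile <- as.numeric(acc$counts[it, ])
  step <- if (length(acc$rho_axis) > 1) acc$rho_axis[2] - acc$rho_axis[1] else 1
  sw <- smooth_px %||% max(1, round(0.08 * min_separation_px / step))
  if (sw > 0) {
    kern <- rep(1 / (2 * sw + 1), 2 * sw + 1)
    profile <- as.numeric(stats::filter(profile, kern, sides = 2))
    profile[is.na(profile)] <- 0
  }
  pmax_all <- max(profile)
  if (pmax_all <= 0) wd_error("wheatdens_no_rows", "empty vote profile: no rows")
  n <- length(profile)
  left <- c(-Inf, profile[-n]); right <- c(profile[-1], -Inf)
  is_peak <- profile >= left & profile > right & profile >= prominence * pmax_all
  peaks <- which(is_peak)
  if (length(peaks) == 0) wd_error("wheatdens_no_rows", "no peak above threshold")
  ord <- peaks[order(profile[peaks], decreasing = TRUE)]
  sep_bins <- min_separation_px / step
  kept <- numeric(0)
  for (p in ord) {
    if (all(abs(p - kept) >= sep_bins)) kept <- c(kept, p)
  }
  # refine each kept peak by centroid over +/- half the separation window
  half <- max(1, floor(sep_bins / 2))
  rho <- vapply(kept, function(p) {
    win <- max(1, p - half):min(n, p + half)
    sum(acc$rho_axis[win] * profile[win]) / sum(profile[win])
  }, numeric(1))
  sort(rho)
}

#' Crop-row model
#'
#' @param theta_deg row orientation (degrees, `90` = horizontal) in the
#'   original (unrotated) frame.
#' @param rho_rows increasing offsets of the detected row lines (pixels).
#' @param rho_frame_theta orientation of the frame the offsets are expressed
#'   in: after the mask has been rotated rows-horizontal the offsets are
#'   plain y positions, i.e. the line family at 90 degrees (the default);
#'   pass `theta_deg` for offsets measured in the unrotated frame.
#' @return An object of class `row_model` with the median `row_spacing_px`.
#' @export
row_model <- function(theta_deg, rho_rows, rho_frame_theta = 90) {
  rho_rows <- sort(as.numeric(rho_rows))
  wd_assert(abs(theta_deg) <= 90, "wheatdens_shape_error", "|theta| must be <= 90")
  spacing <- if (length(rho_rows) > 1) stats::median(diff(rho_rows)) else NA_real_
  structure(list(theta_deg = theta_deg, rho_rows = rho_rows,
                 rho_frame_theta = rho_frame_theta, row_spacing_px = spacing),
            class = "row_model")
}

#' @export
print.row_model <- function(x, ...) {
  cat(sprintf("<row_model theta = %.1f deg, %d rows, spacing %.1f px>\n",
              x$theta_deg, length(x$rho_rows), x$row_spacing_px))
  invisible(x)
}

#' Rotate a raster so that detected rows become horizontal
#'
#' Rotates by `(90 - theta_row) mod 180` (mapped to `[-90, 90)`) about the
#' raster centre, growing the canvas to contain the rotated content. Masks
#' and label rasters use nearest-neighbour resampling.
#'
#' @param raster matrix, [binary_mask] or [rgb_image].
#' @param theta_row row orientation in degrees.
#' @param interp `"nearest"` or `"bilinear"`.
#' @return Rotated raster of the same class.
#' @export
rotate_rows_horizontal <- function(raster, theta_row,
                                   interp = c("nearest", "bilinear")) {
  interp <- match.arg(interp)
  ang <- (90 - theta_row) %% 180
  if (ang >= 90) ang <- ang - 180
  rotate_raster(raster, ang, interp)
}

#' Rotate a raster by an angle about its centre
#'
#' Positive angles rotate content from the +x (right) axis towards +y (down).
#' Inverse-mapping resampling; the canvas grows to the rotated bounding box.
#'
#' @inheritParams rotate_rows_horizontal
#' @param angle_deg rotation angle in degrees.
#' @param fill background value for unmapped output pixels.
#' @export
rotate_raster <- function(raster, angle_deg, interp = c("nearest", "bilinear"),
                          fill = 0) {
  interp <- match.arg(interp)
  if (abs(angle_deg %% 360) < 1e-9) return(raster)
  if (inherits(raster, "rgb_image")) {
    chans <- lapply(1:3, function(ch)
      rotate_raster(raster$px[, , ch], angle_deg, "bilinear", fill))
    out <- array(0, dim = c(dim(chans[[1]]), 3))
    for (ch in 1:3) out[, , ch] <- chans[[ch]]
    return(rgb_image(pmin(pmax(out, 0), 255), raster$resolution_mm))
  }
  if (inherits(raster, "binary_mask")) {
    m <- rotate_raster(raster$values * 1, angle_deg, "nearest", 0)
    return(binary_mask(m > 0.5))
  }
  m <- raster
  a <- angle_deg * pi / 180
  h <- nrow(m); w <- ncol(m)
  ca <- cos(a); sa <- sin(a)
  cin <- c((w + 1) / 2, (h + 1) / 2)
  corners <- cbind(c(1, w, 1, w), c(1, 1, h, h))
  rot <- cbind(ca * (corners[, 1] - cin[1]) - sa * (corners[, 2] - cin[2]),
               sa * (corners[, 1] - cin[1]) + ca * (corners[, 2] - cin[2]))
  wout <- ceiling(max(rot[, 1]) - min(rot[, 1]) + 1)
  hout <- ceiling(max(rot[, 2]) - min(rot[, 2]) + 1)
  cout <- c((wout + 1) / 2, (hout + 1) / 2)
  px <- rep(seq_len(wout), each = hout) - cout[1]
  py <- rep(seq_len(hout), times = wout) - cout[2]
  # inverse rotation back into source coordinates
  qx <- ca * px + sa * py + cin[1]
  qy <- -sa * px + ca * py + cin[2]
  matrix(resample_at(m, qx, qy, interp, fill), hout, wout)
}

# Row-likelihood score of accumulator columns: variance of the band-smoothed
# vote profile, gated by its autocorrelation at the expected row-spacing lag.
# Crop rows are wide bands repeating at the sown spacing; leaf-scale strokes
# produce high raw variance but no spacing periodicity.
row_band_score <- function(counts, band_px, spacing_px) {
  # smooth every theta profile at once (stats::filter is column-wise)
  kern <- rep(1 / band_px, band_px)
  S <- stats::filter(t(counts), kern, sides = 2)
  S[is.na(S)] <- 0                      # profiles in columns
  n <- nrow(S)
  v <- apply(S, 2, stats::var)
  acf_at <- function(L) {
    if (L >= n - 2) return(rep(0, ncol(S)))
    a <- S[1:(n - L), , drop = FALSE]; b <- S[(L + 1):n, , drop = FALSE]
    am <- colMeans(a); bm <- colMeans(b)
    num <- colSums(a * b) - (n - L) * am * bm
    den <- sqrt(pmax(colSums(a^2) - (n - L) * am^2, 0) *
                  pmax(colSums(b^2) - (n - L) * bm^2, 0))
    ifelse(den > 0, num / den, 0)
  }
  lags <- unique(round(seq(0.9 * spacing_px, 1.1 * spacing_px, length.out = 7)))
  ac <- do.call(pmax, lapply(lags, acf_at))
  # true row profiles alternate at the sown spacing: correlated at one
  # spacing, anti-correlated at half a spacing. Broad non-row structure is
  # correlated at both, so the contrast suppresses it.
  ac_half <- acf_at(round(spacing_px / 2))
  ifelse(is.finite(v) & v > 0, v * pmax(ac - pmax(ac_half, 0), 0), 0)
}

# Weighted common-slope refinement of the row orientation from object
# centroids: rotate centroids to the candidate frame, locate row centres from
# the smoothed across-row histogram, then fit one shared slope across rows
# (weights = object areas; merged objects carry more plants, hence tighter
# centroids). Iterates to convergence; returns the refined theta.
refine_theta_centroids <- function(cx, cy, wgt, theta, spacing_px, band_px,
                                   max_iter = 4L) {
  th <- theta
  for (it in seq_len(max_iter)) {
    a <- (90 - th) * pi / 180
    xr <- cos(a) * cx - sin(a) * cy
    yr <- sin(a) * cx + cos(a) * cy
    hy <- tabulate(pmax(1L, round(yr - min(yr) + 1)))
    kern <- rep(1 / band_px, band_px)
    hs <- as.numeric(stats::filter(hy, kern, sides = 2)); hs[is.na(hs)] <- 0
    n <- length(hs)
    pk <- which(hs >= c(-Inf, hs[-n]) & hs > c(hs[-1], -Inf) & hs > 0.25 * max(hs))
    if (!length(pk)) break
    ord <- pk[order(hs[pk], decreasing = TRUE)]
    kept <- numeric(0)
    for (p in ord) if (all(abs(p - kept) >= 0.6 * spacing_px)) kept <- c(kept, p)
    rho <- sort(kept) + min(yr) - 1
    near <- vapply(yr, function(v) which.min(abs(v - rho)), integer(1))
    ok <- abs(yr - rho[near]) < 0.35 * spacing_px
    num <- 0; den <- 0
    for (r in unique(near[ok])) {
      s <- ok & near == r
      xm <- sum(wgt[s] * xr[s]) / sum(wgt[s])
      ym <- sum(wgt[s] * yr[s]) / sum(wgt[s])
      num <- num + sum(wgt[s] * (xr[s] - xm) * (yr[s] - ym))
      den <- den + sum(wgt[s] * (xr[s] - xm)^2)
    }
    if (den <= 0) break
    delta <- atan(num / den) * 180 / pi
    th <- th + delta
    if (abs(delta) < 0.005) break
  }
  th
}

#' Detect crop rows in a vegetation mask
#'
#' Three-stage estimate of the row orientation and positions. A coarse
#' 1-degree Hough sweep scores every orientation by the variance of its
#' band-smoothed vote profile gated by periodicity at the expected row
#' spacing (rows are bands repeating at the sown spacing, which separates
#' them from leaf-scale strokes); a 0.2-degree sweep refines the winning
#' family (the perpendicular family is kept as a fallback candidate). The
#' orientation is then polished to sub-tenth-degree accuracy by fitting a
#' common slope through the object centroids of each row. Finally the mask
#' is rotated to make rows horizontal and the row offsets are read from the
#' edge-vote profile at 90 degrees.
#'
#' @param mask a [binary_mask].
#' @param expected_spacing_px sown row spacing in (rectified) pixels; sets the
#'   minimum peak separation (0.6 x spacing).
#' @param prominence peak threshold, fraction of the tallest peak.
#' @param snap_deg rotations smaller than this are skipped (the mask is
#'   treated as already row-aligned); avoids resampling for sub-bin angles.
#' @return List: `model` (a [row_model] in the rotated frame, with the
#'   original `theta_deg`), `rotated_mask`, and `rotation_deg` applied.
#' @export
detect_rows <- function(mask, expected_spacing_px, prominence = 0.3,
                        snap_deg = 0) {
  m <- as_mask_matrix(mask)
  pts <- edge_points(m)
  if (nrow(pts) < 2) wd_error("wheatdens_no_rows", "mask has no usable edges")
  band_px <- max(3L, round(0.25 * expected_spacing_px))
  rho_max <- ceiling(sqrt(nrow(m)^2 + ncol(m)^2)) + 1
  rho_axis <- seq(-rho_max, rho_max, by = 1)
  coarse <- hough_accumulate(pts, theta_deg = seq(-89, 90, by = 1), rho_axis = rho_axis)
  sc <- row_band_score(coarse$counts, band_px, expected_spacing_px)
  if (max(sc) <= 0) wd_error("wheatdens_no_rows", "no periodic row structure found")
  th_c <- coarse$theta_deg[which.max(sc)]
  wrap_theta <- function(t) { t <- ((t + 90) %% 180) - 90; t[t == -90] <- 90; t }
  best_theta <- NA_real_; best_score <- -Inf
  for (cand in c(th_c, wrap_theta(th_c + 90))) {
    fine_axis <- wrap_theta(seq(cand - 2, cand + 2, by = 0.2))
    fine <- hough_accumulate(pts, theta_deg = fine_axis, rho_axis = rho_axis)
    scf <- row_band_score(fine$counts, band_px, expected_spacing_px)
    if (max(scf) > best_score) {
      best_score <- max(scf)
      best_theta <- fine$theta_deg[which.max(scf)]
    }
  }
  # sub-degree polish on object centroids
  objs <- connected_components(m)
  if (length(objs) >= 5) {
    cx <- vapply(objs, function(o) o$centroid[1], numeric(1))
    cy <- vapply(objs, function(o) o$centroid[2], numeric(1))
    wgt <- vapply(objs, function(o) nrow(o$coords), numeric(1))
    best_theta <- refine_theta_centroids(cx, cy, wgt, best_theta,
                                         expected_spacing_px, band_px)
  }
  theta_row <- wrap_theta(best_theta)
  ang <- (90 - theta_row) %% 180
  if (ang >= 90) ang <- ang - 180
  rot_mask <- if (abs(ang) <= snap_deg) binary_mask(m)
              else rotate_rows_horizontal(binary_mask(m), theta_row)
  pts2 <- edge_points(rot_mask)
  rm2 <- nrow(rot_mask$values) + 1
  acc2 <- hough_accumulate(pts2, theta_deg = 90, rho_axis = seq(0, rm2, by = 1))
  rho <- row_positions(acc2, 90, min_separation_px = 0.6 * expected_spacing_px,
                       prominence = prominence)
  snapped <- abs(ang) <= snap_deg
  list(model = row_model(theta_row, rho), rotated_mask = rot_mask,
       rotation_deg = if (snapped) 0 else ang,
       # objects of the unrotated mask; reusable downstream when no rotation
       # was applied (the mask is then byte-identical)
       objects = if (snapped) objs else NULL)
}

#' Assign objects to their closest row line
#'
#' Each object goes to the row minimizing the perpendicular distance from its
#' centroid to the row line `x cos(theta) + y sin(theta) = rho`. Exact ties go
#' to the lower row index.
#'
#' @param objects list of plant objects (see [connected_components()]).
#' @param rows a [row_model] in the same frame as the object centroids.
#' @return `data.frame(object, row_index, distance_px)`; the input objects are
#'   also returned with `row_index` filled, as attribute `objects`.
#' @export
assign_objects_to_rows <- function(objects, rows) {
  wd_assert(length(rows$rho_rows) >= 1, "wheatdens_no_rows", "no rows to assign to")
  th <- (rows$rho_frame_theta %||% rows$theta_deg) * pi / 180
  res <- data.frame(object = seq_along(objects),
                    row_index = NA_integer_, distance_px = NA_real_)
  for (i in seq_along(objects)) {
    ctr <- objects[[i]]$centroid  # (x, y)
    d <- abs(ctr[1] * cos(th) + ctr[2] * sin(th) - rows$rho_rows)
    j <- which.min(d)  # which.min takes the first (lowest index) on ties
    res$row_index[i] <- j
    res$distance_px[i] <- d[j]
    objects[[i]]$row_index <- j
  }
  attr(res, "objects") <- objects
  res
}

#' Serialize a row model to JSON
#' @param rows a [row_model].
#' @param path output path.
#' @export
write_row_model <- function(rows, path) {
  jsonlite::write_json(list(theta_row_deg = rows$theta_deg,
                            rho_rows_px = rows$rho_rows,
                            spacing_px = rows$row_spacing_px),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
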