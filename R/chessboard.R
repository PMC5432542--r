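#' Chessboard interior-corner grid
#'
#' @param points `N x 2` matrix of (x, y) pixel coordinates in row-major grid
#'   order (first grid row left to right, then second row, ...).
#' @param pattern_rows,pattern_cols interior corner grid dimensions.
#' @param square_size_mm physical square edge length, if known.
#' @return An object of class `corner_grid`.
#' @export
corner_grid <- function(points, pattern_rows, pattern_cols,
                        square_size_mm = NA_real_) {
  points <- matrix(as.numeric(points), ncol = 2)
  wd_assert(pattern_rows >= 2 && pattern_cols >= 2, "wheatdens_detection_error",
            "pattern must be at least 2 x 2 interior corners")
  wd_assert(nrow(points) == pattern_rows * pattern_cols,
            "wheatdens_detection_error", "point count does not match pattern")
  structure(list(points = points, pattern_rows = pattern_rows,
                 pattern_cols = pattern_cols, square_size_mm = square_size_mm),
            class = "corner_grid")
}

#' Metric ground-plane coordinates of a corner grid
#'
#' Row-major lattice `(j-1, i-1) * square_size_mm`, origin at the first corner.
#' @param grid a [corner_grid].
#' @param square_size_mm overrides the stored square size.
#' @return `N x 2` matrix of (x, y) ground coordinates in mm.
#' @export
corner_grid_ground <- function(grid, square_size_mm = NULL) {
  s <- square_size_mm %||% grid$square_size_mm
  wd_assert(is.finite(s) && s > 0, "wheatdens_fit_error",
            "square_size_mm must be known and positive")
  ij <- expand.grid(j = seq_len(grid$pattern_cols), i = seq_len(grid$pattern_rows))
  cbind(x = (ij$j - 1) * s, y = (ij$i - 1) * s)
}

# Corner response via the quadrant kernel (+ - / - +), computed with integral
# images: R(p) = sum(NW) + sum(SE) - sum(NE) - sum(SW) over s x s quadrants.
corner_response <- function(gray, s = 4L) {
  h <- nrow(gray); w <- ncol(gray)
  ii <- matrix(0, h + 1, w + 1)
  ii[-1, -1] <- t(apply(apply(gray, 2, cumsum), 1, cumsum))
  boxsum <- function(r0, c0, r1, c1) {
    # sum over rows r0..r1, cols c0..c1 for every anchor, matrices of indices
    ii[cbind(r1 + 1, c1 + 1)] - ii[cbind(r0, c1 + 1)] -
      ii[cbind(r1 + 1, c0)] + ii[cbind(r0, c0)]
  }
  rs <- (s + 1):(h - s); cs <- (s + 1):(w - s)
  if (length(rs) < 1 || length(cs) < 1) return(matrix(0, h, w))
  R <- matrix(0, h, w)
  rr <- rep(rs, times = length(cs)); cc <- rep(cs, each = length(rs))
  nw <- boxsum(rr - s, cc - s, rr - 1, cc - 1)
  se <- boxsum(rr, cc, rr + s - 1, cc + s - 1)
  ne <- boxsum(rr - s, cc, rr - 1, cc + s - 1)
  sw <- boxsum(rr, cc - s, rr + s - 1, cc - 1)
  R[cbind(rr, cc)] <- nw + se - ne - sw
  R
}

# Sub-pixel refinement by thresholded centroid of the response peak. The
# quadrant-filter response falls off linearly from the corner (a pyramid,
# not a paraboloid), so a quadratic apex fit is phase-biased; the centroid
# of the half-maximum region is unbiased for this symmetric profile.
subpixel_peak <- function(resp, r, c, win = 3L) {
  h <- nrow(resp); w <- ncol(resp)
  rs <- max(1, r - win):min(h, r + win)
  cs <- max(1, c - win):min(w, c + win)
  z <- resp[rs, cs, drop = FALSE]
  z <- z - 0.5 * max(z)
  z[z < 0] <- 0
  tot <- sum(z)
  dx <- sum(z * matrix(cs, nrow(z), ncol(z), byrow = TRUE)) / tot - c
  dy <- sum(z * matrix(rs, nrow(z), ncol(z))) / tot - r
  # the quadrant kernel is centred on the pixel corner between (r-1, c-1)
  # and (r, c), i.e. at (r - 0.5, c - 0.5) in pixel-centre coordinates
  c(x = c - 0.5 + dx, y = r - 0.5 + dy)
}

#' Detect the interior corners of a chessboard calibration target
#'
#' Finds saddle-type corners with a quadrant-contrast filter, refines them to
#' sub-pixel accuracy by quadratic interpolation of the response, and orders
#' them row-major by fitting a projective map from the unit lattice to the
#' four extreme corners. Works for fronto-parallel and moderately warped
#' boards; for failed detections supply correspondences manually (the
#' calibration CLI accepts a corner CSV).
#'
#' @param image an [rgb_image] (or grayscale matrix) showing the full board.
#' @param pattern_rows,pattern_cols interior corner counts.
#' @return A [corner_grid] in canonical row-major order (first corner nearest
#'   the image top-left).
#' @export
detect_chessboard <- function(image, pattern_rows, pattern_cols) {
  gray <- if (inherits(image, "rgb_image")) {
    (image$px[, , 1] + image$px[, , 2] + image$px[, , 3]) / (3 * 255)
  } else image
  n_want <- pattern_rows * pattern_cols
  resp <- abs(corner_response(gray, s = 4L))
  mx <- max(resp)
  if (mx < 1) wd_error("wheatdens_detection_error", "no chessboard-like corners found")
  # local maxima over a 5x5 neighbourhood
  loc <- resp
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    loc <- pmax(loc, shift_mat(resp, dr, dc, 0))
  }
  cand <- which(resp >= loc & resp > 0.25 * mx, arr.ind = TRUE)
  if (nrow(cand) < n_want) {
    wd_error("wheatdens_detection_error",
             sprintf("found %d corner candidates, need %d", nrow(cand), n_want))
  }
  stren <- resp[cand]
  ord <- order(stren, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  # greedy non-max suppression, then keep the strongest n_want
  min_d2 <- (0.35 * sqrt(nrow(gray) * ncol(gray) / n_want))^2
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= n_want) break
    ok <- TRUE
    for (k in keep) {
      if (sum((cand[i, ] - cand[k, ])^2) < min_d2) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  if (length(keep) < n_want) {
    wd_error("wheatdens_detection_error",
             sprintf("only %d well-separated corners, need %d", length(keep), n_want))
  }
  pts <- t(vapply(keep, function(i) subpixel_peak(resp, cand[i, 1], cand[i, 2]),
                  numeric(2)))
  order_corner_lattice(pts, pattern_rows, pattern_cols)
}

# Order detected corner points into a row-major lattice using the four
# extreme corners and a projective fit from grid indices.
order_corner_lattice <- function(pts, pattern_rows, pattern_cols) {
  n <- nrow(pts)
  hull <- grDevices::chull(pts)
  hv <- pts[hull, , drop = FALSE]
  # max-area quadrilateral among hull vertices (hull is small)
  nh <- nrow(hv)
  wd_assert(nh >= 4, "wheatdens_detection_error", "degenerate corner layout")
  quad_area <- function(q) {
    x <- q[, 1]; y <- q[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  best <- NULL; besta <- -1
  cmb <- utils::combn(nh, 4)
  for (k in seq_len(ncol(cmb))) {
    idx <- sort(cmb[, k])     # preserves hull (cyclic) order
    a <- quad_area(hv[idx, , drop = FALSE])
    if (a > besta) { besta <- a; best <- hv[idx, , drop = FALSE] }
  }
  grid_corners <- cbind(c(1, pattern_cols, pattern_cols, 1),
                        c(1, 1, pattern_rows, pattern_rows))
  target <- expand.grid(j = seq_len(pattern_cols), i = seq_len(pattern_rows))
  best_fit <- NULL; best_score <- Inf
  for (rot in 0:3) for (flip in 0:1) {
    quad <- best[((seq_len(4) - 1 + rot) %% 4) + 1, , drop = FALSE]
    if (flip) quad <- quad[4:1, , drop = FALSE]
    H <- tryCatch(fit_homography(grid_corners, quad), error = function(e) NULL)
    if (is.null(H)) next
    pred <- apply_homography(H, cbind(target$j, target$i))
    # nearest detected point to each predicted lattice node
    d2 <- outer(pred[, 1], pts[, 1], "-")^2 + outer(pred[, 2], pts[, 2], "-")^2
    nn <- apply(d2, 1, which.min)
    score <- sum(d2[cbind(seq_len(nrow(pred)), nn)])
    if (anyDuplicated(nn) == 0 && score < best_score) {
      best_score <- score
      best_fit <- pts[nn, , drop = FALSE]
    }
  }
  if (is.null(best_fit)) {
    wd_error("wheatdens_detection_error", "could not order corners into a lattice")
  }
  canonicalize_lattice(best_fit, pattern_rows, pattern_cols)
}

# Put the lattice in canonical reading order: first corner nearest the image
# top-left, rows running left-to-right.
canonicalize_lattice <- function(pts, pattern_rows, pattern_cols) {
  as_grid <- function(p) array(seq_len(nrow(p)), dim = c(pattern_cols, pattern_rows))
  idx <- as_grid(pts)  # idx[j, i] = row-major position of grid node (i, j)
  variants <- list(
    idx,
    idx[rev(seq_len(pattern_cols)), , drop = FALSE],
    idx[, rev(seq_len(pattern_rows)), drop = FALSE],
    idx[rev(seq_len(pattern_cols)), rev(seq_len(pattern_rows)), drop = FALSE]
  )
  score <- vapply(variants, function(v) sum(pts[v[1, 1], ]), numeric(1))
  v <- variants[[which.min(score)]]
  ord <- as.vector(v)  # column-major over (j, i) = row-major over grid
  corner_grid(pts[ord, , drop = FALSE], pattern_rows, pattern_cols)
}
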