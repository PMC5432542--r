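#' Projective transformation between image pixels and the ground plane
#'
#' @param M 3x3 nonsingular matrix mapping homogeneous source coordinates to
#'   destination coordinates. Normalized so `M[3,3] == 1` when that entry is
#'   nonzero.
#' @param residual RMS reprojection residual of the fit (destination units).
#' @param src_frame,dst_frame free-text frame labels.
#' @return An object of class `homography`.
#' @export
homography <- function(M, residual = NA_real_,
                       src_frame = "image pixels", dst_frame = "ground mm") {
  M <- as.matrix(M)
  wd_assert(all(dim(M) == c(3, 3)), "wheatdens_fit_error", "M must be 3 x 3")
  wd_assert(abs(det(M)) > 1e-12, "wheatdens_fit_error", "M must be nonsingular")
  if (abs(M[3, 3]) > 1e-12) M <- M / M[3, 3]
  structure(list(M = M, residual = residual,
                 src_frame = src_frame, dst_frame = dst_frame),
            class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat(sprintf("<homography %s -> %s, residual %.4g>\n",
              x$src_frame, x$dst_frame, x$residual))
  print(signif(x$M, 5))
  invisible(x)
}

#' Apply a homography to 2-D points
#'
#' @param H a [homography] (or 3x3 matrix).
#' @param pts `N x 2` matrix of (x, y) coordinates.
#' @param inverse map destination back to source.
#' @return `N x 2` matrix of mapped coordinates.
#' @export
apply_homography <- function(H, pts, inverse = FALSE) {
  M <- if (inherits(H, "homography")) H$M else H
  if (inverse) M <- solve(M)
  pts <- matrix(as.numeric(pts), ncol = 2)
  ph <- cbind(pts, 1) %*% t(M)
  ph[, 1:2] / ph[, 3]
}

#' Fit a homography by the normalized direct linear transform
#'
#' Least-squares projective fit of `dst ~ H src` from point correspondences,
#' with Hartley normalization of both point sets for numerical conditioning.
#'
#' @param src,dst `N x 2` matrices of corresponding (x, y) points, `N >= 4`.
#' @param src_frame,dst_frame frame labels stored on the result.
#' @return A [homography] with its RMS reprojection `residual`.
#' @export
fit_homography <- function(src, dst, src_frame = "image pixels",
                           dst_frame = "ground mm") {
  src <- matrix(as.numeric(src), ncol = 2)
  dst <- matrix(as.numeric(dst), ncol = 2)
  n <- nrow(src)
  wd_assert(n >= 4 && nrow(dst) == n, "wheatdens_fit_error",
            "need at least 4 point correspondences")
  norm_T <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, byrow = TRUE)
  }
  Ts <- norm_T(src); Td <- norm_T(dst)
  sn <- apply_homography(Ts, src); dn <- apply_homography(Td, dst)
  x <- sn[, 1]; y <- sn[, 2]; u <- dn[, 1]; v <- dn[, 2]
  A <- rbind(
    cbind(-x, -y, -1, 0 * x, 0 * x, 0 * x, u * x, u * y, u),
    cbind(0 * x, 0 * x, 0 * x, -x, -y, -1, v * x, v * y, v)
  )
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1]) {
    wd_error("wheatdens_fit_error",
             "rank-deficient correspondences (collinear points?)")
  }
  Hn <- matrix(sv$v[, 9], 3, byrow = TRUE)
  M <- solve(Td) %*% Hn %*% Ts
  resid <- sqrt(mean(rowSums((apply_homography(M, src) - dst)^2)))
  homography(M, residual = resid, src_frame = src_frame, dst_frame = dst_frame)
}

# Bilinear / nearest sampling of matrix `m` at fractional (x = col, y = row)
# positions. Out-of-range positions return `fill`.
resample_at <- function(m, xs, ys, interp = c("bilinear", "nearest"),
                        fill = NA_real_) {
  interp <- match.arg(interp)
  h <- nrow(m); w <- ncol(m)
  out <- rep(as.numeric(fill), length(xs))
  if (interp == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    out[ok] <- m[cbind(yi[ok], xi[ok])]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
    fx <- (xs - x0)[ok]; fy <- (ys - y0)[ok]
    x0 <- x0[ok]; y0 <- y0[ok]
    out[ok] <-
      m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      m[cbind(y0 + 1, x0 + 1)] * fx * fy
    # fall back to nearest on the 1-px border
    brd <- !ok & round(xs) >= 1 & round(xs) <= w & round(ys) >= 1 & round(ys) <= h
    out[brd] <- m[cbind(round(ys)[brd], round(xs)[brd])]
  }
  out
}

#' Rectify an image or mask to a constant-resolution orthoimage
#'
#' Resamples the raster onto a regular ground-plane grid using the calibrated
#' homography, removing the perspective scale change across the image. RGB
#' images are interpolated bilinearly; masks and label rasters use
#' nearest-neighbour so class identities are preserved.
#'
#' @param raster an [rgb_image], [binary_mask], or plain matrix.
#' @param H [homography] mapping source pixels (x, y) to ground mm.
#' @param out_resolution_mm output ground sampling distance, mm/pixel.
#' @return A list with the rectified `raster` (same class as the input),
#'   `origin_mm` (ground coordinates of the top-left pixel corner),
#'   `resolution_mm`, and `valid` (logical matrix, FALSE where the output had
#'   no source support).
#' @export
rectify_image <- function(raster, H, out_resolution_mm) {
  wd_assert(out_resolution_mm > 0, "wheatdens_geometry_error",
            "out_resolution_mm must be positive")
  is_img <- inherits(raster, "rgb_image")
  is_mask <- inherits(raster, "binary_mask")
  m <- if (is_img) raster$px else as_mask_matrix_or_matrix(raster)
  h <- if (is_img) dim(m)[1] else nrow(m)
  w <- if (is_img) dim(m)[2] else ncol(m)
  corners <- cbind(c(0.5, w + 0.5, 0.5, w + 0.5), c(0.5, 0.5, h + 0.5, h + 0.5))
  g <- apply_homography(H, corners)
  x0 <- min(g[, 1]); x1 <- max(g[, 1]); y0 <- min(g[, 2]); y1 <- max(g[, 2])
  wout <- floor((x1 - x0) / out_resolution_mm)
  hout <- floor((y1 - y0) / out_resolution_mm)
  if (wout < 1 || hout < 1) {
    wd_error("wheatdens_geometry_error", "empty rectified output window")
  }
  gx <- x0 + (seq_len(wout) - 0.5) * out_resolution_mm
  gy <- y0 + (seq_len(hout) - 0.5) * out_resolution_mm
  pts <- cbind(rep(gx, each = hout), rep(gy, times = wout))
  sp <- apply_homography(H, pts, inverse = TRUE)
  xs <- sp[, 1]; ys <- sp[, 2]
  valid <- matrix(xs >= 0.5 & xs <= w + 0.5 & ys >= 0.5 & ys <= h + 0.5,
                  hout, wout)
  if (is_img) {
    out <- array(0, dim = c(hout, wout, 3))
    for (ch in 1:3) {
      v <- resample_at(m[, , ch], xs, ys, "bilinear", fill = 0)
      out[, , ch] <- matrix(v, hout, wout)
    }
    res <- rgb_image(pmin(pmax(out, 0), 255), resolution_mm = out_resolution_mm)
  } else if (is_mask) {
    v <- resample_at(m * 1, xs, ys, "nearest", fill = 0)
    res <- binary_mask(matrix(v > 0.5, hout, wout))
  } else {
    res <- matrix(resample_at(m, xs, ys, "nearest", fill = 0), hout, wout)
  }
  list(raster = res, origin_mm = c(x = x0, y = y0),
       resolution_mm = out_resolution_mm, valid = valid)
}

as_mask_matrix_or_matrix <- function(x) {
  if (inherits(x, "binary_mask")) x$values else {
    wd_assert(is.matrix(x), "wheatdens_shape_error", "expected a matrix raster")
    x
  }
}

#' Save / load a camera calibration as JSON
#'
#' @param H a [homography].
#' @param path JSON path.
#' @param square_size_mm,pattern chessboard metadata stored alongside.
#' @export
write_calibration <- function(H, path, square_size_mm = NA, pattern = c(NA, NA)) {
  jsonlite::write_json(
    list(matrix = H$M, residual = H$residual, square_size_mm = square_size_mm,
         pattern = pattern, src_frame = H$src_frame, dst_frame = H$dst_frame),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  homography(matrix(unlist(j$matrix), 3, 3), residual = j$residual %||% NA_real_,
             src_frame = j$src_frame %||% "image pixels",
             dst_frame = j$dst_frame %||% "ground mm")
}
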