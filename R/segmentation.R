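#' Binary vegetation mask
#'
#' Logical matrix aligned with a source image: `TRUE` marks vegetation.
#'
#' @param values logical matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values) {
  wd_assert(is.matrix(values) && is.logical(values),
            "wheatdens_shape_error", "`values` must be a logical matrix")
  structure(list(values = values, source_shape = dim(values)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, %d foreground px (%.1f%%)>\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values)))
  invisible(x)
}

# Accept binary_mask or plain logical matrix everywhere.
as_mask_matrix <- function(mask) {
  if (inherits(mask, "binary_mask")) return(mask$values)
  wd_assert(is.matrix(mask), "wheatdens_shape_error", "expected a mask matrix")
  if (is.logical(mask)) mask else mask > 0
}

#' Otsu threshold of a real-valued sample
#'
#' Builds a 256-bin histogram over the observed sample range and returns the
#' cut maximizing the between-class variance, i.e. the classical Otsu
#' criterion. The returned threshold is the bin edge between the two classes,
#' so `sample < threshold` reproduces the low class exactly.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return Scalar threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- values[is.finite(values)]
  wd_assert(length(values) >= 2, "wheatdens_degenerate_input",
            "need at least two observations")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) {
    wd_error("wheatdens_degenerate_input",
             sprintf("constant sample (value %.6g): no threshold exists", lo),
             value = lo)
  }
  # bin index in 1..n_bins; top value folded into the last bin
  idx <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  # between-class variance for a cut after bin k (k = 1..n_bins-1)
  k <- seq_len(n_bins - 1L)
  w0k <- w0[k]
  valid <- w0k > 0 & w0k < 1
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  # ties (e.g. an empty gap between two modes gives a plateau of maximal
  # between-class variance) resolve to the middle of the plateau
  vmax <- max(sigma_b)
  best <- round(mean(which(sigma_b >= vmax - 1e-12 * abs(vmax))))
  # edge between bin `best` and `best + 1`
  lo + best * (hi - lo) / n_bins
}

#' Segment green vegetation from soil background
#'
#' Converts the image to CIELab and thresholds the a* channel with
#' [otsu_threshold()]. Vegetation is always the low-a* (green) class;
#' pixels exactly at the threshold go to background.
#'
#' @param image an [rgb_image].
#' @param on_degenerate what to do when the a* channel is constant (no
#'   contrast): `"error"` (default) raises a degenerate-input condition,
#'   `"empty"` returns an all-background mask.
#' @return A [binary_mask] with attributes `threshold` and `a_range`.
#' @export
segment_green <- function(image, on_degenerate = c("error", "empty")) {
  on_degenerate <- match.arg(on_degenerate)
  lab <- rgb_to_lab(image)
  a <- lab[, , 2]
  rng <- range(a)
  if (diff(rng) < 1e-9) {
    if (on_degenerate == "empty") {
      return(binary_mask(matrix(FALSE, nrow(a), ncol(a))))
    }
    wd_error("wheatdens_degenerate_input",
             sprintf("a* channel is constant (%.4f); nothing to segment", rng[1]),
             value = rng[1])
  }
  thr <- otsu_threshold(as.vector(a))
  mask <- binary_mask(a < thr)
  attr(mask, "threshold") <- thr
  attr(mask, "a_range") <- rng
  mask
}
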