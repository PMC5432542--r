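FEATURE_NAMES <- c("F1_Area", "F2_FilledArea", "F3_ConvexArea", "F4_Solidity",
                   "F5_Extent", "F6_EquivDiameter", "F7_MajorAxisLength",
                   "F8_MinorAxisLength", "F9_Eccentricity", "F10_Orientation",
                   "F11_LengthSkelet", "F12_NumEnd", "F13_NumBranch")

# 8-connected labelling: EBImage::bwlabel gives 4-connected labels at C speed;
# labels touching diagonally are then merged with a union-find pass.
label_components8 <- function(m) {
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  L <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m))))
  storage.mode(L) <- "integer"
  nlab <- max(L)
  if (nlab > 1) {
    h <- nrow(L); w <- ncol(L)
    a1 <- L[-h, -w]; b1 <- L[-1, -1]       # NW-SE diagonal pairs
    a2 <- L[-h, -1]; b2 <- L[-1, -w]       # NE-SW diagonal pairs
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pa <- c(a1[sel1], a2[sel2]); pb <- c(b1[sel1], b2[sel2])
    if (length(pa)) {
      parent <- seq_len(nlab)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_along(pa)) {
        ra <- find(pa[k]); rb <- find(pb[k])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      relab <- match(root, sort(unique(root)))
      L[L > 0L] <- relab[L[L > 0L]]
    }
  }
  L
}

#' Extract 8-connected components from a mask
#'
#' Every foreground pixel belongs to exactly one object; two pixels touching
#' only diagonally are the same object. Objects are sorted by the top-left
#' corner of their bounding box (row, then column).
#'
#' @param mask a [binary_mask] or logical matrix.
#' @param min_area drop components smaller than this many pixels (default 1,
#'   i.e. keep all).
#' @return List of `plant_object`s: each has `coords` (`n x 2`, (row, col)),
#'   `centroid` (x, y), `bbox` (rmin, rmax, cmin, cmax), `label`, and unset
#'   `features` / `row_index` / `true_count`.
#' @export
connected_components <- function(mask, min_area = 1L) {
  m <- as_mask_matrix(mask)
  L <- label_components8(m)
  if (max(L) == 0L) return(list())
  idx <- which(L > 0L)
  coords <- arrayInd(idx, dim(L))
  groups <- split(seq_along(idx), L[idx])
  objs <- lapply(groups, function(g) {
    rc <- coords[g, , drop = FALSE]
    structure(list(
      coords = rc,
      centroid = c(x = mean(rc[, 2]), y = mean(rc[, 1])),
      bbox = c(rmin = min(rc[, 1]), rmax = max(rc[, 1]),
               cmin = min(rc[, 2]), cmax = max(rc[, 2])),
      label = L[rc[1, 1], rc[1, 2]],
      features = NULL, row_index = NA_integer_, true_count = NA_real_
    ), class = "plant_object")
  })
  objs <- objs[vapply(objs, function(o) nrow(o$coords), integer(1)) >= min_area]
  ord <- order(vapply(objs, function(o) o$bbox["rmin"], numeric(1)),
               vapply(objs, function(o) o$bbox["cmin"], numeric(1)))
  unname(objs[ord])
}

#' @export
print.plant_object <- function(x, ...) {
  cat(sprintf("<plant_object %d px at (%.1f, %.1f)%s>\n",
              nrow(x$coords), x$centroid[1], x$centroid[2],
              if (is.na(x$true_count)) "" else sprintf(", true count %g", x$true_count)))
  invisible(x)
}

# crop an object to its padded bounding-box as a logical matrix
object_crop <- function(obj, pad = 1L) {
  b <- obj$bbox
  h <- b["rmax"] - b["rmin"] + 1 + 2 * pad
  w <- b["cmax"] - b["cmin"] + 1 + 2 * pad
  m <- matrix(FALSE, h, w)
  m[cbind(obj$coords[, 1] - b["rmin"] + 1 + pad,
          obj$coords[, 2] - b["cmin"] + 1 + pad)] <- TRUE
  m
}

# lattice points inside (or on) the convex hull of the pixel centres
convex_area_px <- function(coords) {
  pts <- cbind(coords[, 2], coords[, 1])  # (x, y)
  if (nrow(pts) <= 2) return(nrow(unique(pts)))
  hull <- grDevices::chull(pts)
  hv <- pts[hull, , drop = FALSE]
  if (nrow(hv) <= 2) {
    # collinear object: hull degenerates to a segment through all pixels
    return(nrow(unique(pts)))
  }
  xr <- range(pts[, 1]); yr <- range(pts[, 2])
  gx <- seq(xr[1], xr[2]); gy <- seq(yr[1], yr[2])
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  nh <- nrow(hv)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hv[j, 1] - hv[i, 1]; ey <- hv[j, 2] - hv[i, 2]
    # chull returns clockwise order in standard xy; points inside have
    # cross-product <= 0 for every edge (tolerance admits boundary points)
    cr <- ex * (py - hv[i, 2]) - ey * (px - hv[i, 1])
    inside <- inside & (cr <= 1e-7)
    if (!any(inside)) break
  }
  if (!any(inside)) { # orientation was counter-clockwise; flip the test
    inside <- rep(TRUE, length(px))
    for (i in seq_len(nh)) {
      j <- if (i == nh) 1L else i + 1L
      ex <- hv[j, 1] - hv[i, 1]; ey <- hv[j, 2] - hv[i, 2]
      cr <- ex * (py - hv[i, 2]) - ey * (px - hv[i, 1])
      inside <- inside & (cr >= -1e-7)
    }
  }
  sum(inside)
}

#' Region features F1-F10 of a plant object
#'
#' Pixel-count and moment-ellipse descriptors in the regionprops convention:
#' the equivalent ellipse has the same normalized second central moments as
#' the pixel set, each pixel contributing the variance of a unit square
#' (the +1/12 term). Orientation is measured in degrees counter-clockwise
#' from the horizontal axis (as displayed), in (-90, 90].
#'
#' @param obj a `plant_object` from [connected_components()].
#' @return Named numeric vector `F1..F10`.
#' @export
compute_region_features <- function(obj) {
  rc <- obj$coords
  n <- nrow(rc)
  wd_assert(n >= 1, "wheatdens_degenerate_input", "empty object")
  area <- n
  crop <- object_crop(obj)
  filled <- EBImage::imageData(EBImage::fillHull(matrix(as.numeric(crop), nrow(crop))))
  filled_area <- sum(filled > 0.5)
  convex_area <- convex_area_px(rc)
  bbox_area <- (obj$bbox["rmax"] - obj$bbox["rmin"] + 1) *
    (obj$bbox["cmax"] - obj$bbox["cmin"] + 1)
  x <- rc[, 2]; y <- rc[, 1]
  uxx <- mean(x^2) - mean(x)^2 + 1 / 12
  uyy <- mean(y^2) - mean(y)^2 + 1 / 12
  uxy <- -(mean(x * y) - mean(x) * mean(y))  # minus: y runs downward on screen
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  major <- 2 * sqrt(2) * sqrt(uxx + uyy + common)
  minor <- 2 * sqrt(2) * sqrt(pmax(uxx + uyy - common, 0))
  ecc <- if (major > 0) sqrt(pmax(1 - (minor / major)^2, 0)) else 0
  orientation <- if (uyy > uxx) {
    if (uxy == 0 && uyy == uxx) 0 else atan2(uyy - uxx + common, 2 * uxy) * 180 / pi
  } else {
    if (uxy == 0 && (uxx - uyy + common) == 0) 0
    else atan2(2 * uxy, uxx - uyy + common) * 180 / pi
  }
  if (orientation <= -90) orientation <- orientation + 180
  if (orientation > 90) orientation <- orientation - 180
  c(F1_Area = area, F2_FilledArea = filled_area, F3_ConvexArea = convex_area,
    F4_Solidity = area / convex_area, F5_Extent = area / as.numeric(bbox_area),
    F6_EquivDiameter = 2 * sqrt(area / pi),
    F7_MajorAxisLength = major, F8_MinorAxisLength = minor,
    F9_Eccentricity = ecc, F10_Orientation = orientation)
}

#' Skeletonize an object by Zhang-Suen thinning
#'
#' Iterative two-subpass morphological thinning to a unit-width, 8-connected
#' skeleton that preserves the topology (connected components and holes) of
#' the object.
#'
#' @param obj a `plant_object`, or a logical matrix.
#' @return Logical matrix of the skeleton, same frame as the input (for a
#'   `plant_object`: its padded bounding-box crop, with attribute `offset`
#'   giving the (row, col) shift back to mask coordinates).
#' @export
skeletonize <- function(obj) {
  if (inherits(obj, "plant_object")) {
    m <- object_crop(obj, pad = 1L)
    off <- c(obj$bbox["rmin"] - 2L, obj$bbox["cmin"] - 2L)
  } else {
    m <- obj; off <- c(0L, 0L)
  }
  sk <- thin_zhang_suen(m)
  attr(sk, "offset") <- off
  sk
}

# Zhang & Suen (1984) thinning, vectorized over the whole crop per iteration.
thin_zhang_suen <- function(m) {
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  if (!any(m)) return(m)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(seq_len(8), function(k)
        shift_mat(matrix(as.integer(m), nrow(m)), NEIGH8_CW[k, 1], NEIGH8_CW[k, 2], 0L))
      # p[[1]]..p[[8]] = P2..P9 (N, NE, E, SE, S, SW, W, NW)
      B <- Reduce(`+`, p)
      seqp <- c(p, p[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(k)
        (seqp[[k]] == 0L) * (seqp[[k + 1]] == 1L)))
      if (sub == 1) {
        c1 <- p[[1]] * p[[3]] * p[[5]] == 0L   # P2 P4 P6
        c2 <- p[[3]] * p[[5]] * p[[7]] == 0L   # P4 P6 P8
      } else {
        c1 <- p[[1]] * p[[3]] * p[[7]] == 0L   # P2 P4 P8
        c2 <- p[[1]] * p[[5]] * p[[7]] == 0L   # P2 P6 P8
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# clockwise neighbour order P2..P9 starting north (shift offsets bring the
# neighbour's value onto the centre pixel)
NEIGH8_CW <- cbind(
  dr = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
  dc = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
)

#' End and branch points of a skeleton
#'
#' End points are skeleton pixels with exactly one skeleton 8-neighbour.
#' Branch-point candidates are pixels with three or more skeleton
#' 8-neighbours; because pixels flanking a junction are diagonal neighbours
#' of each other, a single junction can produce a clump of such candidates
#' (a plus-shaped crossing yields five), so the branch count is the number
#' of 8-connected candidate clusters - one per junction.
#'
#' @param skeleton logical matrix (e.g. from [skeletonize()]).
#' @return `c(NumEnd = ..., NumBranch = ...)`.
#' @export
skeleton_points <- function(skeleton) {
  sk <- matrix(as.logical(skeleton), nrow(skeleton), ncol(skeleton))
  if (!any(sk)) return(c(NumEnd = 0L, NumBranch = 0L))
  nb <- neighbour_count8(sk)
  cand <- sk & nb >= 3L
  n_branch <- if (any(cand)) max(label_components8(cand)) else 0L
  c(NumEnd = sum(sk & nb == 1L), NumBranch = as.integer(n_branch))
}

#' Compute the full 13-feature vector of an object
#'
#' F1-F10 region and moment-ellipse features plus the three skeleton features
#' (skeleton pixel count, end points, branch points).
#'
#' @param obj a `plant_object`.
#' @return The object with `$features` set to the named F1..F13 vector.
#' @export
compute_features <- function(obj) {
  f10 <- compute_region_features(obj)
  sk <- skeletonize(obj)
  ep <- skeleton_points(sk)
  obj$features <- c(f10, F11_LengthSkelet = sum(sk),
                    F12_NumEnd = unname(ep["NumEnd"]),
                    F13_NumBranch = unname(ep["NumBranch"]))
  obj
}

#' Build the per-object feature table for an image
#'
#' Runs [connected_components()] and [compute_features()] over a mask and
#' returns the standard feature-table interchange format used for training
#' and prediction.
#'
#' @param mask a [binary_mask] (rectified and rotated so rows are horizontal).
#' @param rows optional [row_model] for row assignment.
#' @param image_id identifier copied into the table.
#' @param resolution_mm mm per pixel, for metric centroids (NA allowed).
#' @param min_area passed to [connected_components()].
#' @param objects precomputed result of [connected_components()] on `mask`
#'   (e.g. from [detect_rows()] when no rotation was applied); avoids
#'   relabelling. `min_area` is still applied.
#' @return `data.frame`: image_id, object_id, row_index, centroid_x_mm,
#'   centroid_y_mm, F1..F13, border_flag, true_count (NA when unknown).
#'   The object list is attached as attribute `objects`.
#' @export
extract_object_features <- function(mask, rows = NULL, image_id = "image",
                                    resolution_mm = NA_real_, min_area = 1L,
                                    objects = NULL) {
  m <- as_mask_matrix(mask)
  objs <- if (is.null(objects)) connected_components(m, min_area = min_area)
          else objects[vapply(objects, function(o) nrow(o$coords), integer(1)) >= min_area]
  if (length(objs) == 0) {
    df <- empty_feature_table()
    attr(df, "objects") <- list()
    return(df)
  }
  objs <- lapply(objs, compute_features)
  dist_px <- rep(NA_real_, length(objs))
  if (!is.null(rows)) {
    asg <- assign_objects_to_rows(objs, rows)
    objs <- attr(asg, "objects")
    dist_px <- asg$distance_px
  }
  W <- ncol(m)
  feats <- do.call(rbind, lapply(objs, function(o) o$features))
  df <- data.frame(
    image_id = image_id,
    object_id = seq_along(objs),
    row_index = vapply(objs, function(o) o$row_index, integer(1)),
    row_distance_px = dist_px,
    centroid_x_mm = vapply(objs, function(o) o$centroid[1], numeric(1)) * resolution_mm,
    centroid_y_mm = vapply(objs, function(o) o$centroid[2], numeric(1)) * resolution_mm,
    feats,
    border_flag = vapply(objs, function(o)
      o$bbox["cmin"] == 1L || o$bbox["cmax"] == W, logical(1)),
    true_count = vapply(objs, function(o) o$true_count, numeric(1)),
    row.names = NULL
  )
  attr(df, "objects") <- objs
  df
}

empty_feature_table <- function() {
  df <- data.frame(image_id = character(0), object_id = integer(0),
                   row_index = integer(0), row_distance_px = numeric(0),
                   centroid_x_mm = numeric(0), centroid_y_mm = numeric(0))
  for (f in FEATURE_NAMES) df[[f]] <- numeric(0)
  df$border_flag <- logical(0)
  df$true_count <- numeric(0)
  df
}

#' Write / read the object feature table CSV
#' @param df feature table from [extract_object_features()].
#' @param path CSV path.
#' @export
write_object_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
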