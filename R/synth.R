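#' Specification of a synthetic seedling scene
#'
#' Describes a ground-truthed synthetic field scene: parallel rows of young
#' wheat plants (1-2 erect leaves, Haun stage ~1.5) rendered as tapered green
#' strokes over textured brown soil, with plant-coloured distractor objects
#' (stone/residue stand-ins) that segment as vegetation but contain no plant.
#' Plants are placed along each row as a homogeneous Poisson process, so
#' plant overlap - and with it multi-plant objects - emerges naturally as
#' sowing density increases.
#'
#' @param sowing_density_seeds_m2 seeds per square metre (field range 100-600).
#' @param row_spacing_mm distance between row centres (default 175 mm).
#' @param n_rows number of rows (default 5).
#' @param segment_length_mm sown length of each row in the scene.
#' @param row_angle_deg row orientation in the Hough convention (90 =
#'   horizontal rows; the field images deviate a few degrees, e.g. -88.2).
#' @param resolution_mm rendered ground resolution, mm per pixel.
#' @param emergence_rate fraction of seeds that produce a visible plant.
#' @param null_object_rate distractor intensity: expected distractors per
#'   plant; calibrated so 10-20% of segmented objects contain no plant.
#' @param leaf_length_mm,leaf_width_mm ranges (min, max) for leaf size.
#' @param perspective optional [homography] mapping camera pixels to ground
#'   mm; when supplied the returned image is the oblique camera view.
#' @param seed RNG seed; scenes are bit-reproducible given the spec.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(sowing_density_seeds_m2 = 300,
                       row_spacing_mm = 175,
                       n_rows = 5L,
                       segment_length_mm = 450,
                       row_angle_deg = 90,
                       resolution_mm = 0.6,
                       emergence_rate = 0.9,
                       null_object_rate = 0.15,
                       leaf_length_mm = c(20, 60),
                       leaf_width_mm = c(1.5, 3),
                       perspective = NULL,
                       seed = 1L) {
  wd_assert(sowing_density_seeds_m2 >= 0, "wheatdens_shape_error",
            "density must be nonnegative")
  wd_assert(row_spacing_mm > 0 && segment_length_mm > 0 && resolution_mm > 0,
            "wheatdens_shape_error", "physical dimensions must be positive")
  wd_assert(emergence_rate >= 0 && emergence_rate <= 1 &&
              null_object_rate >= 0 && null_object_rate <= 1,
            "wheatdens_shape_error", "rates must lie in [0, 1]")
  wd_assert(abs(row_angle_deg) <= 90, "wheatdens_shape_error",
            "|row_angle_deg| must be <= 90")
  structure(list(sowing_density_seeds_m2 = sowing_density_seeds_m2,
                 row_spacing_mm = row_spacing_mm, n_rows = as.integer(n_rows),
                 segment_length_mm = segment_length_mm,
                 row_angle_deg = row_angle_deg, resolution_mm = resolution_mm,
                 emergence_rate = emergence_rate,
                 null_object_rate = null_object_rate,
                 leaf_length_mm = leaf_length_mm, leaf_width_mm = leaf_width_mm,
                 perspective = perspective, seed = as.integer(seed)),
            class = "scene_spec")
}

# stamp disks of radius r (px) at fractional centres onto linear indices
stamp_indices <- function(cx, cy, r, h, w) {
  R <- max(1L, ceiling(max(r)))
  off <- expand.grid(dx = -R:R, dy = -R:R)
  ns <- length(cx)
  no <- nrow(off)
  px <- round(rep(cx, each = no)) + rep(off$dx, times = ns)
  py <- round(rep(cy, each = no)) + rep(off$dy, times = ns)
  rr <- rep(r, each = no)
  d2 <- (px - rep(cx, each = no))^2 + (py - rep(cy, each = no))^2
  sel <- d2 <= rr^2 & px >= 1 & px <= w & py >= 1 & py <= h
  unique((px[sel] - 1L) * h + py[sel])  # column-major linear index
}

# render one leaf as a tapered quadratic curve; returns linear pixel indices
render_leaf <- function(base_xy, angle_deg, length_mm, width_mm, res, h, w) {
  len_px <- length_mm / res
  a <- angle_deg * pi / 180
  p0 <- base_xy
  p2 <- base_xy + len_px * c(cos(a), sin(a))
  bend <- stats::rnorm(1, 0, 0.12 * len_px)
  p1 <- (p0 + p2) / 2 + bend * c(-sin(a), cos(a))
  ts <- seq(0, 1, length.out = max(8L, ceiling(2 * len_px)))
  bx <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1]
  by <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2]
  rad <- pmax(0.5, (width_mm / 2 / res) * (1 - 0.75 * ts))
  stamp_indices(bx, by, rad, h, w)
}

#' Generate a ground-truthed synthetic seedling scene
#'
#' Renders the scene described by a [scene_spec] and records complete ground
#' truth: per-plant pixel footprints, per-object plant counts under
#' 8-connectivity, the true row lines in Hough parameters, and the true plant
#' density of the rendered segment.
#'
#' @param spec a [scene_spec].
#' @return An object of class `wheat_scene`: `image` (an [rgb_image]),
#'   `truth` (list: `plants` data.frame, `plant_pixels`, `distractor_pixels`,
#'   `foreground` mask, `rows` = list(theta_deg, rho_px), `n_plants`,
#'   `area_m2`, `density_true_m2`, `dim`), and `spec`.
#' @export
generate_scene <- function(spec) {
  wd_assert(inherits(spec, "scene_spec"), "wheatdens_shape_error",
            "`spec` must be a scene_spec")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  res <- spec$resolution_mm
  phi <- (spec$row_angle_deg - 90) * pi / 180   # deviation from horizontal
  u <- c(cos(phi), sin(phi))                    # along-row unit (x, y)
  nv <- c(-sin(phi), cos(phi))                  # across-row unit
  L <- spec$segment_length_mm
  offsets <- (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$row_spacing_mm
  ends <- rbind(
    t(vapply(offsets, function(o) -L / 2 * u + o * nv, numeric(2))),
    t(vapply(offsets, function(o) L / 2 * u + o * nv, numeric(2)))
  )
  pad <- 70
  x0 <- min(ends[, 1]) - pad; x1 <- max(ends[, 1]) + pad
  y0 <- min(ends[, 2]) - pad; y1 <- max(ends[, 2]) + pad
  w <- ceiling((x1 - x0) / res); h <- ceiling((y1 - y0) / res)
  mm_to_px <- function(p_mm) c((p_mm[1] - x0) / res + 0.5, (p_mm[2] - y0) / res + 0.5)

  # --- soil background -------------------------------------------------
  base_rgb <- c(115, 88, 58)
  coarse <- matrix(stats::rnorm(h * w), h, w)
  coarse <- EBImage::imageData(EBImage::gblur(coarse, sigma = 10 / res * 0.6))
  coarse <- coarse / max(stats::sd(coarse), 1e-9)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- base_rgb[ch] + 9 * coarse +
      matrix(stats::rnorm(h * w, 0, 3), h, w)
  }
  # bright stones (stay on the soil side of the a* threshold)
  n_stone <- stats::rpois(1, h * w * res^2 / 4e4)
  stone_idx <- integer(0); stone_tone <- numeric(0)
  for (s in seq_len(n_stone)) {
    ctr <- c(stats::runif(1, 1, w), stats::runif(1, 1, h))
    rad <- stats::runif(1, 1.5, 5) / res
    idx <- stamp_indices(ctr[1], ctr[2], rad, h, w)
    stone_idx <- c(stone_idx, idx)
    stone_tone <- c(stone_tone, rep(stats::runif(1, 135, 165), length(idx)))
  }
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[stone_idx] <- stone_tone - c(0, 10, 25)[ch] +
      stats::rnorm(length(stone_idx), 0, 4)
    img[, , ch] <- plane
  }

  # --- plants ----------------------------------------------------------
  lambda_per_mm <- spec$sowing_density_seeds_m2 * spec$emergence_rate *
    (spec$row_spacing_mm / 1e6)                 # plants per mm of row
  plant_pixels <- list()
  plant_row <- integer(0); plant_bx <- numeric(0); plant_by <- numeric(0)
  pid <- 0L
  for (ri in seq_len(spec$n_rows)) {
    n_i <- stats::rpois(1, lambda_per_mm * L)
    if (n_i == 0) next
    tpos <- sort(stats::runif(n_i, 0, L))
    for (t in tpos) {
      pid <- pid + 1L
      jit <- stats::rnorm(1, 0, 2.5)
      base_mm <- (t - L / 2) * u + (offsets[ri] + jit) * nv
      base <- mm_to_px(base_mm)
      n_leaf <- sample(1:2, 1, prob = c(0.45, 0.55))
      idx <- integer(0)
      for (lf in seq_len(n_leaf)) {
        side <- sample(c(-1, 1), 1)
        dev <- stats::rnorm(1, 15, 10)
        ang <- (spec$row_angle_deg - 90) + side * (90 - dev)
        idx <- c(idx, render_leaf(base, ang,
                                  stats::runif(1, spec$leaf_length_mm[1], spec$leaf_length_mm[2]),
                                  stats::runif(1, spec$leaf_width_mm[1], spec$leaf_width_mm[2]),
                                  res, h, w))
      }
      # small basal blob so the leaves of one plant always connect
      idx <- unique(c(idx, stamp_indices(base[1], base[2], 1.5 / res, h, w)))
      plant_pixels[[pid]] <- idx
      plant_row[pid] <- ri; plant_bx[pid] <- base[1]; plant_by[pid] <- base[2]
    }
  }
  n_plants <- pid
  plants <- data.frame(id = seq_len(n_plants), row = plant_row,
                       base_x_px = plant_bx, base_y_px = plant_by)

  # --- distractors (null objects) --------------------------------------
  n_distr <- stats::rpois(1, spec$null_object_rate * max(n_plants, 1))
  distractor_pixels <- list()
  for (d in seq_len(n_distr)) {
    ctr <- c(stats::runif(1, pad / res, w - pad / res),
             stats::runif(1, pad / res, h - pad / res))
    a_mm <- stats::runif(1, 2, 5); b_mm <- stats::runif(1, 1, 3)
    ang <- stats::runif(1, 0, pi)
    ts <- seq(0, 1, length.out = 12)
    cx <- ctr[1] + (ts - 0.5) * 2 * (a_mm / res) * cos(ang)
    cy <- ctr[2] + (ts - 0.5) * 2 * (a_mm / res) * sin(ang)
    distractor_pixels[[d]] <- stamp_indices(cx, cy, rep(b_mm / res, 12), h, w)
  }

  # --- paint vegetation-coloured pixels (one pass per channel) ---------
  npx_p <- lengths(plant_pixels); npx_d <- lengths(distractor_pixels)
  veg_idx <- c(unlist(plant_pixels), unlist(distractor_pixels))
  base_cols <- rbind(
    matrix(rep(c(45, 115, 50), each = max(n_plants, 0)), ncol = 3) +
      matrix(stats::rnorm(3 * n_plants, 0, 8), ncol = 3),
    matrix(rep(c(70, 105, 55), each = length(npx_d)), ncol = 3) +
      matrix(stats::rnorm(3 * length(npx_d), 0, 7), ncol = 3)
  )
  reps <- c(npx_p, npx_d)
  if (length(veg_idx)) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[veg_idx] <- rep(base_cols[, ch], times = reps) +
        stats::rnorm(length(veg_idx), 0, 6)
      img[, , ch] <- plane
    }
  }
  img <- pmin(pmax(img, 0), 255)

  fg <- matrix(FALSE, h, w)
  fg[unlist(plant_pixels)] <- TRUE
  fg[unlist(distractor_pixels)] <- TRUE

  # true row lines in Hough parameters (theta = row angle, rho = offset)
  ctr_mm <- c(-x0, -y0)  # scene centre of the row pattern, in canvas mm
  ctr_px <- c(ctr_mm[1] / res + 0.5, ctr_mm[2] / res + 0.5)
  theta <- spec$row_angle_deg
  th <- theta * pi / 180
  rho_rows <- (ctr_px[1] * cos(th) + ctr_px[2] * sin(th)) + offsets / res

  area_m2 <- (L / 1000) * (spec$row_spacing_mm / 1000) * spec$n_rows
  truth <- list(plants = plants, plant_pixels = plant_pixels,
                distractor_pixels = distractor_pixels, foreground = fg,
                rows = list(theta_deg = theta, rho_px = sort(rho_rows)),
                n_plants = n_plants, area_m2 = area_m2,
                density_true_m2 = n_plants / area_m2,
                dim = c(h, w), resolution_mm = res,
                origin_mm = c(x = x0, y = y0))
  image <- rgb_image(img, resolution_mm = res)

  if (!is.null(spec$perspective)) {
    image <- project_to_camera(image, spec$perspective, truth)
  }
  structure(list(image = image, truth = truth, spec = spec), class = "wheat_scene")
}

#' @export
print.wheat_scene <- function(x, ...) {
  cat(sprintf("<wheat_scene %d plants, %.0f plants/m2, %d x %d px%s>\n",
              x$truth$n_plants, x$truth$density_true_m2,
              x$truth$dim[1], x$truth$dim[2],
              if (is.null(x$spec$perspective)) "" else ", perspective view"))
  invisible(x)
}

# oblique camera view of a flat ground scene: sample the ground image at
# H(camera px); H maps camera px -> ground mm. The camera canvas is sized so
# the full ground extent stays in frame.
project_to_camera <- function(image, H, truth) {
  h0 <- truth$dim[1]; w0 <- truth$dim[2]; res <- truth$resolution_mm
  gc <- cbind(c(0, w0, 0, w0), c(0, 0, h0, h0)) * res
  cc <- apply_homography(H, gc, inverse = TRUE)
  if (any(!is.finite(cc)) || min(cc) < -0.5) {
    wd_error("wheatdens_geometry_error",
             "perspective places the scene outside the camera frame")
  }
  w <- ceiling(max(cc[, 1])); h <- ceiling(max(cc[, 2]))
  if (h * w > 4e7) {
    wd_error("wheatdens_geometry_error", "perspective camera frame too large")
  }
  pts <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
  g <- apply_homography(H, pts)
  gx <- g[, 1] / res + 0.5; gy <- g[, 2] / res + 0.5
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    out[, , ch] <- matrix(resample_at(image$px[, , ch], gx, gy, "bilinear",
                                      fill = c(115, 88, 58)[ch]), h, w)
  }
  rgb_image(pmin(pmax(out, 0), 255), resolution_mm = NA_real_)
}

#' Fill true plant counts of extracted objects from scene truth
#'
#' Each rendered plant is attributed to the object covering the majority of
#' its pixels; an object's true count is the number of plants attributed to
#' it (0 for distractor-only objects). When the mask was rotated before
#' object extraction, pass the rotation so plant footprints are mapped into
#' the rotated frame first.
#'
#' @param objects list of plant objects (from [connected_components()] /
#'   [extract_object_features()]'s `objects` attribute).
#' @param truth `truth` component of a [generate_scene()] result.
#' @param mask_dim dimensions of the mask the objects came from.
#' @param rotation_deg rotation (degrees, about the original raster centre)
#'   that was applied to the mask, 0 for none.
#' @return Integer vector of true counts, one per object; unmatched plants
#'   (those whose pixels fell outside every object) are counted in the
#'   attribute `n_unmatched`.
#' @export
match_truth_counts <- function(objects, truth, mask_dim = truth$dim,
                               rotation_deg = 0) {
  objlab <- matrix(0L, mask_dim[1], mask_dim[2])
  for (i in seq_along(objects)) {
    objlab[objects[[i]]$coords] <- i
  }
  counts <- integer(length(objects))
  n_plants <- length(truth$plant_pixels)
  n_unmatched <- 0L
  h0 <- truth$dim[1]; w0 <- truth$dim[2]
  if (n_plants > 0) {
    idx <- unlist(truth$plant_pixels, use.names = FALSE)
    pid <- rep.int(seq_len(n_plants), lengths(truth$plant_pixels))
    rr <- ((idx - 1L) %% h0) + 1L
    cc <- ((idx - 1L) %/% h0) + 1L
    if (rotation_deg != 0) {
      a <- rotation_deg * pi / 180
      cin <- c((w0 + 1) / 2, (h0 + 1) / 2)
      cout <- c((ncol(objlab) + 1) / 2, (nrow(objlab) + 1) / 2)
      xr <- cos(a) * (cc - cin[1]) - sin(a) * (rr - cin[2]) + cout[1]
      yr <- sin(a) * (cc - cin[1]) + cos(a) * (rr - cin[2]) + cout[2]
      cc <- round(xr); rr <- round(yr)
      ok <- cc >= 1 & cc <= ncol(objlab) & rr >= 1 & rr <= nrow(objlab)
      cc <- cc[ok]; rr <- rr[ok]; pid <- pid[ok]
    }
    labs <- objlab[(cc - 1L) * nrow(objlab) + rr]
    keep <- labs > 0L
    labs <- labs[keep]; pid <- pid[keep]
    if (length(labs)) {
      # majority object per plant, in one pass over (plant, object) pairs
      pair_count <- rowsum(rep(1L, length(labs)),
                           group = pid * (length(objects) + 1) + labs)
      key <- as.numeric(rownames(pair_count))
      pair_pid <- key %/% (length(objects) + 1)
      pair_lab <- key %% (length(objects) + 1)
      ord <- order(pair_pid, -pair_count[, 1])
      first <- !duplicated(pair_pid[ord])
      wins <- pair_lab[ord][first]
      tab <- tabulate(wins, nbins = length(objects))
      counts <- counts + as.integer(tab)
      n_unmatched <- n_plants - length(wins)
    } else {
      n_unmatched <- n_plants
    }
  }
  attr(counts, "n_unmatched") <- n_unmatched
  counts
}

#' Render a chessboard calibration target
#'
#' Flat board at the requested resolution, optionally seen through a known
#' camera-to-ground homography, with the true interior-corner lattice
#' recorded for validation.
#'
#' @param square_mm physical square edge length.
#' @param pattern_rows,pattern_cols interior corner grid size.
#' @param resolution_mm ground resolution of the flat rendering.
#' @param H optional [homography] (camera px -> ground mm).
#' @param noise_sd additive image noise (0-255 scale).
#' @param margin_mm white margin around the board.
#' @param seed RNG seed for the noise.
#' @return List: `image` (an [rgb_image]), `truth` (a [corner_grid] in image
#'   pixels), `square_mm`.
#' @export
generate_chessboard <- function(square_mm = 30, pattern_rows = 6L,
                                pattern_cols = 9L, resolution_mm = 0.6,
                                H = NULL, noise_sd = 2, margin_mm = 25,
                                seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  res <- resolution_mm
  bw_mm <- (pattern_cols + 1) * square_mm
  bh_mm <- (pattern_rows + 1) * square_mm
  w <- ceiling((bw_mm + 2 * margin_mm) / res)
  h <- ceiling((bh_mm + 2 * margin_mm) / res)
  board_value <- function(x_mm, y_mm) {
    inx <- x_mm >= margin_mm & x_mm <= margin_mm + bw_mm
    iny <- y_mm >= margin_mm & y_mm <= margin_mm + bh_mm
    sq <- (floor((x_mm - margin_mm) / square_mm) +
             floor((y_mm - margin_mm) / square_mm)) %% 2
    val <- ifelse(inx & iny, ifelse(sq == 0, 20, 235), 160)
    val
  }
  # 3x supersampled rendering (anti-aliasing keeps edge positions unbiased;
  # plain point sampling would quantize corners to pixel boundaries)
  sub <- c(-1, 0, 1) / 3
  gray <- matrix(0, h, w)
  px <- rep(seq_len(w), each = h); py <- rep(seq_len(h), times = w)
  for (ox in sub) for (oy in sub) {
    if (is.null(H)) {
      gx <- (px + ox - 0.5) * res; gy <- (py + oy - 0.5) * res
    } else {
      g <- apply_homography(H, cbind(px + ox, py + oy))
      gx <- g[, 1]; gy <- g[, 2]
    }
    gray <- gray + matrix(board_value(gx, gy), h, w)
  }
  gray <- gray / 9
  gray <- EBImage::imageData(EBImage::gblur(gray, sigma = 0.8))
  gray <- gray + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  img <- array(pmin(pmax(gray, 0), 255), dim = c(h, w, 3))

  # true interior corners: ground mm -> image px
  ij <- expand.grid(j = seq_len(pattern_cols), i = seq_len(pattern_rows))
  corners_mm <- cbind(margin_mm + ij$j * square_mm, margin_mm + ij$i * square_mm)
  if (is.null(H)) {
    corners_px <- cbind(corners_mm[, 1] / res + 0.5, corners_mm[, 2] / res + 0.5)
  } else {
    corners_px <- apply_homography(H, corners_mm, inverse = TRUE)
  }
  if (any(corners_px[, 1] < 1 | corners_px[, 1] > w |
            corners_px[, 2] < 1 | corners_px[, 2] > h)) {
    wd_error("wheatdens_geometry_error", "board corners fall outside the frame")
  }
  list(image = rgb_image(img, resolution_mm = if (is.null(H)) res else NA_real_),
       truth = corner_grid(corners_px, pattern_rows, pattern_cols,
                           square_size_mm = square_mm),
       square_mm = square_mm)
}

#' Build a labelled training table from synthetic scenes
#'
#' Runs the image pipeline (segmentation, row detection, object extraction)
#' on each scene and fills the `true_count` column from the scene truth by
#' majority pixel overlap, yielding the standard feature-table format used
#' by [train_network()] and [recursive_feature_elimination()].
#'
#' @param specs list of [scene_spec]s (or `wheat_scene`s already generated).
#' @param min_area minimum object size in pixels.
#' @return Feature table `data.frame` with `true_count` filled.
#' @export
generate_training_set <- function(specs, min_area = 1L) {
  tabs <- lapply(seq_along(specs), function(i) {
    sc <- specs[[i]]
    if (inherits(sc, "scene_spec")) sc <- generate_scene(sc)
    pr <- scene_objects(sc, min_area = min_area)
    pr$table
  })
  do.call(rbind, tabs)
}

# segment + rows + objects on one scene, with true counts matched in
scene_objects <- function(scene, min_area = 1L, prominence = 0.3,
                          snap_deg = 0.35) {
  mask <- segment_green(scene$image)
  spacing_px <- scene$spec$row_spacing_mm / scene$truth$resolution_mm
  rd <- detect_rows(mask, spacing_px, prominence = prominence,
                    snap_deg = snap_deg)
  tab <- extract_object_features(rd$rotated_mask, rows = rd$model,
                                 image_id = sprintf("scene%d", scene$spec$seed),
                                 resolution_mm = scene$truth$resolution_mm,
                                 min_area = min_area, objects = rd$objects)
  objs <- attr(tab, "objects")
  counts <- match_truth_counts(objs, scene$truth,
                               mask_dim = dim(rd$rotated_mask$values),
                               rotation_deg = rd$rotation_deg)
  tab$true_count <- as.numeric(counts)
  attr(tab, "objects") <- objs
  list(table = tab, rows = rd$model, rotated_mask = rd$rotated_mask,
       rotation_deg = rd$rotation_deg, n_unmatched = attr(counts, "n_unmatched"))
}
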