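# Shared fixtures, built lazily and memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast scene (3 rows, short segment) for unit tests
small_scene <- function(density = 300, seed = 11, angle = 90, ...) {
  key <- paste0("scene_", density, "_", seed, "_", angle)
  memo(key, generate_scene(scene_spec(
    sowing_density_seeds_m2 = density, n_rows = 3, segment_length_mm = 300,
    row_angle_deg = angle, seed = seed, ...)))
}

# labelled object table over a spread of densities (shared by feature and
# count-model tests)
shared_training_table <- function() {
  memo("train_tab", {
    specs <- lapply(seq_along(c(100, 300, 600)), function(i)
      scene_spec(sowing_density_seeds_m2 = c(100, 300, 600)[i], seed = 900 + i))
    generate_training_set(specs)
  })
}

# plant_object from a logical matrix (for hand-built shapes)
object_from_matrix <- function(m) {
  objs <- connected_components(m)
  stopifnot(length(objs) == 1)
  objs[[1]]
}

# simple flood-fill labelling oracle (8-connectivity), recursive frontier
flood_fill_label8 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  todo <- which(m)
  for (start in todo) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    h <- nrow(m)
    while (length(frontier)) {
      new_frontier <- integer(0)
      for (p in frontier) {
        r <- ((p - 1L) %% h) + 1L; c <- ((p - 1L) %/% h) + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || rr > h || cc < 1 || cc > ncol(m)) next
          q <- (cc - 1L) * h + rr
          if (m[q] && lab[q] == 0L) { lab[q] <- nxt; new_frontier <- c(new_frontier, q) }
        }
      }
      frontier <- new_frontier
    }
  }
  lab
}

# count of holes (4-connected background components not touching the border)
count_holes <- function(m) {
  pad <- matrix(FALSE, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  bg <- !pad
  lab <- EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(bg), nrow(bg))))
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  length(setdiff(unique(lab[lab > 0]), border_labs))
}

# mild oblique-view homography (camera px -> ground mm), like a 45 deg shot
make_view_homography <- function(res = 0.6, g = 2.2e-4, rot_deg = 2) {
  a <- rot_deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  P <- matrix(c(1, 0, 0, 0, 1, 0, 0, g, 1), 3, byrow = TRUE)
  homography(diag(c(res, res, 1)) %*% R %*% P)
}

# brute-force Otsu oracle: try every histogram cut, maximize between-class
# variance computed directly from the binned sample
otsu_bruteforce <- function(values, n_bins = 256) {
  lo <- min(values); hi <- max(values)
  idx <- pmin(floor((values - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  vs <- rep(-Inf, n_bins - 1L)
  for (k in seq_len(n_bins - 1L)) {
    a <- centers[idx[idx <= k]]; b <- centers[idx[idx > k]]
    if (!length(a) || !length(b)) next
    vs[k] <- (length(a) * (mean(a) - mean(centers[idx]))^2 +
                length(b) * (mean(b) - mean(centers[idx]))^2) / length(values)
  }
  best_k <- round(mean(which(vs >= max(vs) - 1e-12 * abs(max(vs)))))
  lo + best_k * (hi - lo) / n_bins
}
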