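test_that("components use 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE            # diagonal touch
  expect_identical(length(connected_components(m)), 1L)
  m2 <- matrix(FALSE, 5, 5)
  m2[2, 2] <- TRUE; m2[2, 4] <- TRUE          # one-pixel gap
  expect_identical(length(connected_components(m2)), 2L)
  expect_identical(connected_components(matrix(FALSE, 3, 3)), list())
})

test_that("labelling matches a flood-fill oracle on random masks", {
  set.seed(23)
  for (i in 1:8) {
    m <- matrix(stats::runif(25 * 30) < 0.3, 25, 30)
    objs <- connected_components(m)
    oracle <- flood_fill_label8(m)
    expect_identical(length(objs), max(oracle))
    # union of pixel sets = mask, pairwise disjoint
    all_px <- do.call(rbind, lapply(objs, function(o) o$coords))
    expect_identical(nrow(all_px), sum(m))
    expect_identical(anyDuplicated(all_px), 0L)
    # object pixel sets coincide with oracle label classes
    for (o in objs) {
      labs <- oracle[o$coords]
      expect_identical(length(unique(labs)), 1L)
    }
  }
})

test_that("region features match closed forms on canonical shapes", {
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  f <- compute_region_features(object_from_matrix(sq))
  expect_equal(unname(f[c("F1_Area", "F2_FilledArea", "F3_ConvexArea")]), c(9, 9, 9))
  expect_equal(unname(f["F4_Solidity"]), 1)
  expect_equal(unname(f["F5_Extent"]), 1)
  expect_equal(unname(f["F6_EquivDiameter"]), 2 * sqrt(9 / pi), tolerance = 1e-12)
  expect_equal(unname(f["F9_Eccentricity"]), 0, tolerance = 1e-9)

  ring <- matrix(FALSE, 5, 5); ring[2:4, 2:4] <- TRUE; ring[3, 3] <- FALSE
  fr <- compute_region_features(object_from_matrix(ring))
  expect_equal(unname(fr[c("F1_Area", "F2_FilledArea")]), c(8, 9))

  bar <- matrix(FALSE, 3, 12); bar[2, 2:11] <- TRUE
  fb <- compute_region_features(object_from_matrix(bar))
  expect_equal(unname(fb["F5_Extent"]), 1)
  expect_equal(unname(fb["F10_Orientation"]), 0)
  # moment-ellipse closed forms for a discrete 1 x 10 bar:
  # uxx = (10^2 - 1)/12 + 1/12 = 100/12, uyy = 1/12, uxy = 0,
  # major/minor = 2 sqrt(2) sqrt(uxx + uyy +/- (uxx - uyy))
  uxx <- 100 / 12; uyy <- 1 / 12
  expect_equal(unname(fb["F7_MajorAxisLength"]),
               2 * sqrt(2) * sqrt(uxx + uyy + (uxx - uyy)), tolerance = 1e-9)
  expect_equal(unname(fb["F8_MinorAxisLength"]),
               2 * sqrt(2) * sqrt(uxx + uyy - (uxx - uyy)), tolerance = 1e-9)
  expect_equal(unname(fb["F7_MajorAxisLength"]), 11.547, tolerance = 1e-4)
  expect_equal(unname(fb["F8_MinorAxisLength"]), 1.1547, tolerance = 1e-4)
  expect_equal(unname(fb["F3_ConvexArea"]), 10)
})

test_that("convex area counts lattice points in the hull (plus shape)", {
  plus <- matrix(FALSE, 11, 11)
  plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  f <- compute_region_features(object_from_matrix(plus))
  expect_equal(unname(f["F1_Area"]), 17)
  # hull is the diamond |x-6| + |y-6| <= 4: 41 lattice points
  expect_equal(unname(f["F3_ConvexArea"]), 41)
  expect_equal(unname(f["F4_Solidity"]), 17 / 41, tolerance = 1e-12)
})

test_that("skeletons of thin and solid shapes behave", {
  bar <- matrix(FALSE, 3, 12); bar[2, 2:11] <- TRUE
  sk <- skeletonize(bar)
  expect_gte(sum(sk), 8); expect_lte(sum(sk), 10)

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_identical(sum(skeletonize(single)), 1L)

  disk <- matrix(FALSE, 25, 25)
  ii <- expand.grid(r = 1:25, c = 1:25)
  disk[as.matrix(ii[(ii$r - 13)^2 + (ii$c - 13)^2 <= 100, ])] <- TRUE
  sk3 <- skeletonize(disk)
  expect_identical(length(connected_components(sk3)), 1L)
  expect_identical(count_holes(sk3), 0L)
  # skeleton never exceeds the object
  obj <- object_from_matrix(disk)
  expect_lte(sum(skeletonize(obj)), sum(disk))
})

test_that("skeleton end and branch points follow the neighbour rule", {
  line <- matrix(FALSE, 3, 12); line[2, 2:11] <- TRUE
  expect_identical(skeleton_points(line), c(NumEnd = 2L, NumBranch = 0L))

  plus <- matrix(FALSE, 11, 11)
  plus[6, 2:10] <- TRUE; plus[2:10, 6] <- TRUE
  expect_identical(skeleton_points(plus), c(NumEnd = 4L, NumBranch = 1L))

  ys <- matrix(FALSE, 12, 12)
  ys[7:11, 6] <- TRUE                          # stem below the junction
  for (k in 1:4) { ys[7 - k, 6 - k] <- TRUE; ys[7 - k, 6 + k] <- TRUE }
  expect_identical(unname(skeleton_points(ys)["NumBranch"]), 1L)
  expect_identical(unname(skeleton_points(ys)["NumEnd"]), 3L)
})

test_that("feature invariants hold across synthetic objects", {
  tab <- shared_training_table()
  expect_gt(nrow(tab), 150)
  expect_true(all(tab$F1_Area <= tab$F2_FilledArea + 1e-9))
  expect_true(all(tab$F2_FilledArea <= tab$F3_ConvexArea + 1e-9))
  expect_true(all(tab$F4_Solidity > 0 & tab$F4_Solidity <= 1 + 1e-12))
  expect_true(all(tab$F5_Extent > 0 & tab$F5_Extent <= 1 + 1e-12))
  expect_equal(tab$F6_EquivDiameter, 2 * sqrt(tab$F1_Area / pi), tolerance = 1e-12)
  expect_true(all(tab$F9_Eccentricity >= 0 & tab$F9_Eccentricity < 1))
  expect_true(all(tab$F8_MinorAxisLength <= tab$F7_MajorAxisLength + 1e-9))
  expect_true(all(tab$F10_Orientation > -90 & tab$F10_Orientation <= 90))
  expect_true(all(tab$F11_LengthSkelet <= tab$F1_Area))
  expect_true(all(tab$F12_NumEnd >= 0 & tab$F13_NumBranch >= 0))
})

test_that("features are translation invariant; orientation flips sign", {
  m <- matrix(FALSE, 30, 30)
  m[5:12, 4:9] <- TRUE; m[10:20, 8:11] <- TRUE
  f1 <- compute_features(object_from_matrix(m))$features
  shifted <- matrix(FALSE, 40, 40); shifted[11:40, 9:38] <- m[1:30, 1:30]
  f2 <- compute_features(object_from_matrix(shifted))$features
  expect_equal(f1, f2, tolerance = 1e-9)
  flipped <- m[nrow(m):1, ]
  f3 <- compute_region_features(object_from_matrix(flipped))
  expect_equal(unname(f3["F10_Orientation"]), -unname(f1["F10_Orientation"]),
               tolerance = 1e-9)
})

test_that("total foreground area is conserved in the feature table", {
  sc <- small_scene(300, seed = 11)
  mask <- segment_green(sc$image)
  tab <- extract_object_features(mask, resolution_mm = 0.6)
  expect_identical(as.integer(sum(tab$F1_Area)), sum(mask$values))
})
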