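const_roi <- function(value = 5, dims = c(4, 4, 4)) {
  list(image = image_volume(array(value, dims)),
       mask = array(TRUE, dims))
}

test_that("first-order statistics match hand computations", {
  roi <- const_roi(3)
  f <- intensity_features(roi$image, roi$mask)
  expect_equal(unname(f["intensity_mean"]), 3)
  expect_equal(unname(f["intensity_variance"]), 0)
  expect_equal(unname(f["intensity_skewness"]), 0)

  ## {1,1,2,2}: mean 1.5, population variance 0.25
  img <- image_volume(array(c(1, 1, 2, 2), c(4, 1, 1)))
  m <- array(TRUE, c(4, 1, 1))
  f2 <- intensity_features(img, m)
  expect_equal(unname(f2["intensity_mean"]), 1.5)
  expect_equal(unname(f2["intensity_variance"]), 0.25)
  expect_equal(unname(f2["intensity_skewness"]), 0)   # symmetric
})

test_that("histogram features of a constant region are degenerate", {
  roi <- const_roi(7)
  q <- quantize_roi(roi$image, roi$mask, 32)
  f <- histogram_features(q)
  expect_equal(unname(f["hist_entropy"]), 0)
  expect_equal(unname(f["hist_uniformity"]), 1)
  expect_equal(unname(f["hist_n_levels"]), 1)
})

test_that("IVH features follow the volume-fraction definition", {
  roi <- const_roi(4)
  f <- ivh_features(roi$image, roi$mask)
  expect_equal(unname(f["ivh_v10"]), 1)   # constant: all volume at any f
  expect_equal(unname(f["ivh_v90"]), 1)

  ## two-level ROI, half voxels each: fraction at the upper level = 0.5
  img <- image_volume(array(rep(c(0, 10), each = 8), c(16, 1, 1)))
  m <- array(TRUE, c(16, 1, 1))
  f2 <- ivh_features(img, m)
  expect_equal(unname(f2["ivh_v90"]), 0.5)
  ## monotone non-increasing IVH
  set.seed(4)
  img3 <- image_volume(array(rnorm(64), c(4, 4, 4)))
  f3 <- ivh_features(img3, array(TRUE, c(4, 4, 4)))
  v <- f3[c("ivh_v10", "ivh_v25", "ivh_v50", "ivh_v75", "ivh_v90")]
  expect_true(all(diff(v) <= 0))
  expect_gte(unname(f3["ivh_v10"] - f3["ivh_v90"]), 0)
})

test_that("morphology recovers volume, sphericity limit and degenerate masks", {
  ## 10x10x10 voxel cube at 1 mm iso = 1 cm^3
  m <- array(FALSE, c(14, 14, 14)); m[3:12, 3:12, 3:12] <- TRUE
  f <- morphology_features(m, c(1, 1, 1))
  expect_equal(unname(f["morph_volume_cm3"]), 1.0)
  expect_equal(unname(f["morph_voxel_count"]), 1000)
  ## max diameter = main diagonal of the 10-voxel cube (9 voxel steps)
  expect_equal(unname(f["morph_max_diameter_mm"]), sqrt(3 * 81))

  ## discretized balls: sphericity below 1 and increasing toward it
  sph <- vapply(c(4, 8, 12), function(r) {
    tv <- simulate_tumor_volume(c(r, r, r), "constant", seed = 1)
    unname(morphology_features(tv$mask)["morph_sphericity"])
  }, numeric(1))
  expect_true(all(sph < 1))
  expect_gt(sph[3], 0.97)
  expect_true(all(diff(sph) > 0))

  ## single voxel: volume = voxel volume, diameter 0
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  f1 <- morphology_features(m1, c(2, 2, 2))
  expect_equal(unname(f1["morph_volume_cm3"]), 8 / 1000)
  expect_equal(unname(f1["morph_max_diameter_mm"]), 0)
  expect_equal(unname(f1["morph_elongation"]), 1)
})

test_that("morphology is intensity-free and anisotropy-aware", {
  set.seed(5)
  m <- simulate_tumor_volume(c(4, 5, 6), "constant", seed = 2)$mask
  f1 <- morphology_features(m, c(1, 1, 2))
  f2 <- morphology_features(m, c(1, 1, 1))
  expect_equal(unname(f1["morph_volume_cm3"]),
               2 * unname(f2["morph_volume_cm3"]))
  expect_lt(unname(f1["morph_elongation"]), 1 + 1e-9)
})

test_that("LBP codes match hand encoding and histograms normalize", {
  ## constant image: all neighbors >= center -> 8 ones, uniform -> bin 8
  roi <- const_roi(1, c(5, 5, 1))
  f <- lbp_features(roi$image, roi$mask)
  expect_equal(unname(f["lbp_bin8"]), 1)
  expect_equal(sum(f), 1)

  ## hand-encoded single 3x3 patch: center 0, one neighbor 5, others -1
  ## -> one thresholded bit -> uniform pattern -> bin 1
  img3 <- array(-1, c(3, 3, 1)); img3[2, 2, 1] <- 0; img3[1, 1, 1] <- 5
  f3 <- lbp_features(image_volume(img3), array(TRUE, c(3, 3, 1)))
  expect_equal(unname(f3["lbp_bin1"]), 1)
  expect_equal(sum(f3), 1)

  ## alternating ring -> 8 transitions -> non-uniform bin 9
  img4 <- array(0, c(3, 3, 1))
  img4[1, 1, 1] <- img4[1, 3, 1] <- img4[3, 1, 1] <- img4[3, 3, 1] <- 5
  img4[2, 2, 1] <- 1
  f4 <- lbp_features(image_volume(img4), array(TRUE, c(3, 3, 1)))
  expect_equal(unname(f4["lbp_bin9"]), 1)

  expect_error(lbp_features(image_volume(array(0, c(2, 2, 1))),
                            array(TRUE, c(2, 2, 1))), "3x3")
})

test_that("extract_all returns the full finite manifest deterministically", {
  tv <- simulate_tumor_volume(c(5, 6, 4), "coarse", seed = 7)
  v <- extract_all(tv$image, tv$mask)
  manifest <- radiomic_manifest()
  expect_length(v, 102)
  expect_equal(names(v), manifest$name)
  expect_equal(sort(unique(attr(v, "family"))), sort(unique(manifest$family)))
  expect_length(unique(attr(v, "family")), 8)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_all(tv$image, tv$mask))
})

test_that("features are invariant to whole-voxel translation", {
  tv <- simulate_tumor_volume(c(4, 4, 5), "fine", seed = 9, margin = 5)
  d <- dim(tv$mask)
  shift <- function(a, k) {
    out <- array(0, d)
    out[(1 + k):d[1], , ] <- a[1:(d[1] - k), , ]
    out
  }
  img2 <- image_volume(shift(tv$image$data, 2), tv$image$spacing)
  msk2 <- shift(tv$mask, 2) > 0
  v1 <- extract_all(tv$image, tv$mask)
  v2 <- extract_all(img2, msk2)
  expect_equal(unname(v1), unname(v2), tolerance = 1e-10)
})

test_that("intensity features ignore intensities outside the mask", {
  tv <- simulate_tumor_volume(c(4, 4, 4), "fine", seed = 10)
  img2 <- tv$image
  img2$data[!tv$mask] <- img2$data[!tv$mask] + 500
  fam <- radiomic_manifest()
  keep <- fam$family %in% c("intensity", "histogram", "volumetric",
                            "morphologic")
  v1 <- extract_all(tv$image, tv$mask)
  v2 <- extract_all(img2, tv$mask)
  expect_equal(v1[fam$name[keep]], v2[fam$name[keep]])
})
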