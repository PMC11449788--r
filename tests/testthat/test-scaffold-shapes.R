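# Thresholding, 26-connected segmentation with border exclusion, and the
# nine-feature shape descriptors with their invariances.

test_that("probability thresholding keeps voxels at or above the cutoff", {
  u <- array(0.5, c(4, 4, 4))
  expect_true(all(threshold_probability(u, 0.2)))
  expect_false(any(threshold_probability(array(0.1, c(4, 4, 4)), 0.2)))
  # checkerboard of 0.1 / 0.9 at cutoff 0.5: exactly half kept
  cb <- array(0.1, c(4, 4, 4))
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  cb[idx[rowSums(idx) %% 2 == 0, ]] <- 0.9
  expect_equal(sum(threshold_probability(cb, 0.5)), 32)
  expect_error(threshold_probability(u, 1.2), class = "invalid_cutoff")
  expect_error(threshold_probability(array(2, c(2, 2, 2)), 0.5),
               class = "invalid_volume")
})

test_that("segmentation labels 26-connected components and flags the border", {
  m <- array(FALSE, c(12, 12, 12))
  m[3:5, 3:5, 3:5] <- TRUE
  m[8:10, 8:10, 8:10] <- TRUE
  seg <- segment_objects(m)
  expect_length(seg$objects, 2)
  expect_false(any(vapply(seg$objects, `[[`, logical(1), "border")))
  # cube with one face on the volume border is flagged
  mb <- array(FALSE, c(12, 12, 12))
  mb[1:3, 5:7, 5:7] <- TRUE
  expect_true(segment_objects(mb)$objects[[1]]$border)
  # two cubes sharing only a vertex are one object under 26-connectivity
  mv <- array(FALSE, c(12, 12, 12))
  mv[3:4, 3:4, 3:4] <- TRUE
  mv[5:6, 5:6, 5:6] <- TRUE
  expect_length(segment_objects(mv)$objects, 1)
  # empty mask
  expect_length(segment_objects(array(FALSE, c(4, 4, 4)))$objects, 0)
})

test_that("a digitized ball is spherical with a faithful surface estimate", {
  ball <- digitized_ball(20)
  f <- shape_features(ball, voxel_size = c(1, 1, 1))
  expect_lt(abs(f$sphericity - 1), 0.05)
  expect_lt(f$volume_ratio, 0.05)
  # surface and volume against closed forms
  expect_lt(abs(f$volume_nm3 - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.01)
  expect_lt(abs(f$surface_nm2 - 4 * pi * 20^2) / (4 * pi * 20^2), 0.05)
})

test_that("an exact digitized ellipsoid has near-zero volume ratio", {
  e <- digitized_ellipsoid(c(20, 12, 8))
  f <- shape_features(e, voxel_size = c(1, 1, 1))
  expect_lt(f$volume_ratio, 0.05)
})

test_that("moment invariants are stable under translation, rotation, scaling", {
  e <- digitized_ellipsoid(c(20, 12, 8))
  f0 <- shape_features(e, voxel_size = c(1, 1, 1))
  moments <- function(f) unlist(f[c("M1", "M2", "M3", "M4", "M5")])
  # translation: exact
  f_t <- shape_features(sweep(e, 2, c(7, -3, 11), "+"), voxel_size = c(1, 1, 1))
  expect_equal(moments(f_t), moments(f0), tolerance = 1e-12)
  # 90-degree axis permutations: exact
  f_r <- shape_features(e[, c(3, 1, 2)], voxel_size = c(1, 1, 1))
  expect_equal(moments(f_r), moments(f0), tolerance = 1e-12)
  # uniform 2x rescale: <= 2% drift (digitization only)
  e2 <- digitized_ellipsoid(c(40, 24, 16))
  f_s <- shape_features(e2, voxel_size = c(1, 1, 1))
  expect_lt(max(abs(moments(f_s) / moments(f0) - 1)), 0.02)
})

test_that("volume ratio grows monotonically as holes are carved", {
  e <- digitized_ellipsoid(c(16, 12, 8))
  ctr <- colMeans(e)
  vr <- numeric(3)
  for (i in 1:3) {
    hole_r <- c(0, 3, 5)[i]
    keep <- (e[, 1] - ctr[1] + 6)^2 + (e[, 2] - ctr[2])^2 +
      (e[, 3] - ctr[3])^2 > hole_r^2
    vr[i] <- shape_features(e[keep, ], voxel_size = c(1, 1, 1))$volume_ratio
  }
  expect_true(all(diff(vr) > 0))
})

test_that("volume converts by the voxel size and correction factor", {
  vox <- digitized_ball(4)
  n <- nrow(vox)
  f <- shape_features(vox, voxel_size = c(43, 43, 120), correction_factor = 1)
  expect_equal(f$volume_nm3, n * 43 * 43 * 120)
  # a 200-voxel object at factor 1 would give 200 x 221,880 nm^3
  expect_equal(200 * prod(c(43, 43, 120)), 44376000)
  f2 <- shape_features(vox, voxel_size = c(43, 43, 120),
                       correction_factor = 1.1)
  expect_equal(f2$volume_nm3, n * 221880 / 1.1^3)
  expect_equal(f2$surface_nm2, f$surface_nm2 / 1.1^2)
})

test_that("the feature vector has exactly nine entries", {
  f <- shape_features(digitized_ball(5), voxel_size = c(43, 43, 120))
  feats <- c("volume_nm3", "surface_nm2", "volume_ratio", "sphericity",
             "M1", "M2", "M3", "M4", "M5")
  expect_true(all(feats %in% names(f)))
  expect_length(feats, 9)
  expect_true(all(is.finite(unlist(f[feats]))))
})

test_that("degenerate (planar) objects are regularized and flagged", {
  plane <- as.matrix(expand.grid(x = 1:6, y = 1:6, z = 3))
  f <- shape_features(plane, voxel_size = c(1, 1, 1))
  expect_true(all(is.finite(unlist(f[c("M1", "M2", "M3", "M4", "M5")]))))
})

test_that("the volume-exclusion threshold reproduces the printed derivation", {
  th <- volume_exclusion_threshold()
  expect_equal(th$voxels, 2 * 200^2 * 500 / (43 * 43 * 120))
  expect_equal(round(th$voxels, 1), 180.3)
  expect_equal(th$threshold, 200)
})

test_that("the volume filter rejects below and retains at the threshold", {
  recs <- data.frame(label = 1:3, voxel_count = c(180, 200, 350))
  out <- volume_filter(recs, 200)
  expect_identical(out$voxel_count, c(200, 350))
  expect_equal(attr(out, "n_volume_excluded"), 1)
  expect_error(volume_filter(recs, 0), class = "invalid_threshold")
})

test_that("segmentation recovers generator truth objects exactly", {
  cfg <- sim_config(seed = 31, scaffolds = list(n_objects = 15L,
                                                vol_dim = c(160L, 160L, 56L)))
  sc <- gen_scaffolds(cfg)
  seg <- segment_objects(threshold_probability(sc$volume, 0.2))
  truth_counts <- sort(sc$truth$voxel_count[sc$truth$voxel_count > 0])
  # perforated templates may split into several 26-components; every truth
  # object must be covered by segmented voxels with identical total count
  expect_equal(sum(vapply(seg$objects, `[[`, integer(1), "voxel_count")),
               sum(truth_counts))
  expect_gte(length(seg$objects), sum(sc$truth$voxel_count > 0))
})
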