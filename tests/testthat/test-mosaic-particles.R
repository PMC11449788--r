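# Preprocessing, alignment, particle detection, colocalization, and
# spatial point-pattern statistics.

test_that("rolling-ball preprocessing removes flat background", {
  roi <- matrix(TRUE, 48, 48)
  flat <- matrix(7, 48, 48)
  out <- preprocess_synapse(list(flat, flat), roi)
  expect_true(all(out < 1e-9))
  # a single bright spot on a flat background survives within 5%
  spot <- render_spot_image(matrix(c(24, 24), 1), amplitude = 100,
                            psf_sd = 2, baseline = 10)
  out2 <- preprocess_synapse(list(spot), roi)
  peak <- max(spot) - 10            # rendered amplitude above the baseline
  expect_lt(abs(max(out2) - peak) / peak, 0.05)
  # all signal outside the ROI is cleared
  roi2 <- matrix(FALSE, 48, 48); roi2[1:10, 1:10] <- TRUE
  out3 <- preprocess_synapse(list(spot), roi2)
  expect_true(all(out3[!roi2] == 0))
  expect_lt(max(out3), 1)
  expect_error(preprocess_synapse(list(spot), matrix(TRUE, 10, 10)),
               class = "invalid_roi")
})

test_that("channel alignment recovers planted rigid transforms", {
  set.seed(42)
  roi <- matrix(FALSE, 48, 48); roi[8:40, 8:40] <- TRUE
  pts <- cbind(runif(8, 12, 36), runif(8, 12, 36))
  ch1 <- render_spot_image(pts)
  # identical channels: identity transform
  al0 <- align_channels(ch1, ch1, roi)
  expect_equal(unname(al0$shift), c(0, 0))
  expect_equal(al0$rotation_deg, 0)
  # planted shift of (3, 0): recovered as (-3, 0)
  ch2 <- matrix(0, 48, 48); ch2[4:48, ] <- ch1[1:45, ]
  al <- align_channels(ch1, ch2, roi)
  expect_equal(unname(al$shift), c(-3, 0))
  expect_gte(al$cor_after, al$cor_before)
  # planted 5-degree rotation about the ROI center: recovered within 1 degree
  ctr <- colMeans(which(roi, arr.ind = TRUE))
  ch3 <- synmorph:::rotate_about(ch1, 5, ctr)
  al2 <- align_channels(ch1, ch3, roi)
  expect_lte(abs(al2$rotation_deg - (-5)), 1)
  # flat channel: identity with warning
  expect_warning(align_channels(ch1, matrix(0, 48, 48), roi),
                 "flat channel")
})

test_that("particle detection resolves, merges, and measures spots", {
  # two spots 10 px apart: two particles within 0.5 px of truth
  pts <- matrix(c(19, 24, 29, 24), 2, byrow = TRUE)
  img <- render_spot_image(pts)
  pat <- detect_particles(img, pixel_size = 1)
  expect_equal(nrow(pat$points), 2)
  found <- pat$points[order(pat$points$x), c("x", "y")]
  expect_lt(max(abs(as.matrix(found) - pts)), 0.5)
  # the same spots 1 px apart merge into one particle
  img2 <- render_spot_image(matrix(c(23.5, 24, 24.5, 24), 2, byrow = TRUE))
  expect_equal(nrow(detect_particles(img2, pixel_size = 1)$points), 1)
  # empty image: no particles
  expect_equal(nrow(detect_particles(matrix(0, 32, 32))$points), 0)
  # empty mask: empty pattern
  expect_equal(nrow(detect_particles(img, matrix(FALSE, 48, 48))$points), 0)
  # marks are sensible
  expect_true(all(pat$points$area_nm2 > 0))
  expect_true(all(pat$points$total_int > 0))
})

test_that("particle summaries apply the dimensional normalization rules", {
  pts <- matrix(c(10, 10, 20, 20, 30, 30, 12, 30, 30, 12), 5, byrow = TRUE)
  img <- render_spot_image(pts, dm = c(40, 40))
  pat <- detect_particles(img, pixel_size = 25)
  expect_equal(nrow(pat$points), 5)
  s1 <- particle_summary(pat, correction_factor = 1)
  # density = count / mask area (40 x 40 px at 25 nm)
  expect_equal(s1$density_per_nm2, 5 / (1600 * 625))
  s2 <- particle_summary(pat, correction_factor = 1.1)
  expect_equal(s2$mean_area_nm2, s1$mean_area_nm2 / 1.21)
  expect_equal(s2$density_per_nm2, s1$density_per_nm2 * 1.21)
  expect_equal(s2$mean_total_int, s1$mean_total_int)
})

test_that("Manders coefficients match closed forms and stay in [0,1]", {
  ch <- matrix(runif(100), 10, 10)
  m <- matrix(FALSE, 10, 10); m[2:5, 2:5] <- TRUE
  expect_equal(as.numeric(manders(ch, ch, m, m)), c(1, 1))
  m2 <- matrix(FALSE, 10, 10); m2[7:9, 7:9] <- TRUE
  expect_equal(as.numeric(manders(ch, ch, m, m2)), c(0, 0))
  # uniform channel, second mask covering half of the first: M1 = 0.5
  u <- matrix(1, 10, 10)
  mh <- matrix(FALSE, 10, 10); mh[2:5, 2:3] <- TRUE
  expect_equal(as.numeric(manders(u, u, m, mh)[1]), 0.5)
  # swapping channels and masks swaps M1 and M2
  a <- matrix(runif(100), 10, 10); b <- matrix(runif(100), 10, 10)
  mm <- manders(a, b, m, mh); mm_sw <- manders(b, a, mh, m)
  expect_equal(unname(mm[1]), unname(mm_sw[2]))
  expect_true(all(mm >= 0 & mm <= 1))
  # zero denominator flags
  z <- manders(a, b, matrix(FALSE, 10, 10), mh)
  expect_true(attr(z, "flagged"))
})

test_that("NND profiles match the brute-force oracle and are monotone", {
  # collinear points at 0, 1, 3: mean NND1 = 4/3, mean NND2 = 8/3
  col3 <- cbind(x = c(0, 1, 3), y = 0)
  nn <- nnd_profile(col3, K = 2)
  expect_equal(nn$mean_nnd, c(4 / 3, 8 / 3))
  # regular grid with spacing d: NND1 = d
  gr <- as.matrix(expand.grid(x = (1:5) * 70, y = (1:5) * 70))
  expect_equal(nnd_profile(gr, K = 1)$mean_nnd, 70)
  # brute-force agreement on random patterns up to 50 points
  for (s in 1:3) {
    set.seed(s)
    xy <- cbind(x = runif(50, 0, 1000), y = runif(50, 0, 1000))
    nnp <- nnd_profile(xy, K = 10)
    expect_equal(nnp$mean_nnd, brute_force_nnd(xy, 10), tolerance = 1e-12)
    expect_true(all(diff(nnp$mean_nnd) >= 0))
  }
  # n <= K: computed to n - 1 with a flag
  small <- nnd_profile(col3, K = 5)
  expect_equal(nrow(small), 2)
  expect_true(attr(small, "flagged"))
  # correction factor divides distances
  expect_equal(nnd_profile(col3, K = 2, correction_factor = 2)$mean_nnd,
               c(2 / 3, 4 / 3))
})

test_that("the K estimator matches the two-point closed form without edge correction", {
  w <- list(type = "rect", xrange = c(0, 1), yrange = c(0, 1))
  pts <- cbind(x = c(0.3, 0.3), y = c(0.4, 0.9))   # distance 0.5
  rp <- ripley_csr(pts, w, r_max = 1, nr = 10, correction = "none")
  expect_equal(rp$K[rp$r < 0.5], rep(0, sum(rp$r < 0.5)))
  expect_equal(rp$K[rp$r >= 0.5], rep(1, sum(rp$r >= 0.5)))  # |W| = 1
  expect_true(all(diff(rp$K) >= 0))
  # fewer than two points: flagged NA
  r1 <- ripley_csr(cbind(x = 1, y = 1), w)
  expect_true(attr(r1, "flagged"))
  expect_true(is.na(r1$deviation))
})

test_that("the CSR deviation separates clustered from inhibited patterns", {
  win <- ellipse_window()
  set.seed(77)
  # clustered (Thomas-like): positive deviation
  parents <- csr_in_ellipse(5, win$center, win$semi * 0.7)
  off <- parents[sample.int(5, 60, replace = TRUE), ] +
    matrix(rnorm(120, 0, 40), 60, 2)
  rp_c <- ripley_csr(off, win)
  expect_gt(rp_c$deviation, 0)
  # hard-core: negative deviation
  hc <- matrix(NA_real_, 0, 2)
  while (nrow(hc) < 25) {
    cand <- csr_in_ellipse(1, win$center, win$semi)
    if (nrow(hc) == 0 ||
        min(sqrt((hc[, 1] - cand[1])^2 + (hc[, 2] - cand[2])^2)) >= 140)
      hc <- rbind(hc, cand)
  }
  rp_h <- ripley_csr(hc, win)
  expect_lt(rp_h$deviation, 0)
})

test_that("overlap-pair distances follow the documented pairing rules", {
  # identical masks: all pair distances zero
  lab <- matrix(0L, 20, 20); lab[3:5, 3:5] <- 1L; lab[12:14, 12:14] <- 2L
  ov <- overlap_pair_distances(lab, lab, pixel_size = 1)
  expect_equal(ov$pairs$distance_nm, c(0, 0))
  # two 2x2 regions overlapping by one pixel: one pair, center distance 2 px
  a <- matrix(0L, 24, 24); a[10:11, 10:11] <- 1L
  b <- matrix(0L, 24, 24); b[11:12, 11:12] <- 1L
  ov2 <- overlap_pair_distances(a, b, pixel_size = 1)
  expect_equal(nrow(ov2$pairs), 1)
  expect_equal(ov2$pairs$distance_nm, sqrt(2))
  # a region overlapping two partner regions yields two pairs
  c1 <- matrix(0L, 24, 24); c1[5:14, 5:8] <- 1L
  c2 <- matrix(0L, 24, 24); c2[5:6, 5:8] <- 1L; c2[13:14, 5:8] <- 2L
  ov3 <- overlap_pair_distances(c1, c2, pixel_size = 1)
  expect_equal(nrow(ov3$pairs), 2)
  # disjoint masks: flagged
  ov4 <- overlap_pair_distances(a, matrix(0L, 24, 24))
  expect_true(attr(ov4, "flagged"))
  # correction factor divides distances
  ov5 <- overlap_pair_distances(a, b, pixel_size = 1, correction_factor = 2)
  expect_equal(ov5$pairs$distance_nm, sqrt(2) / 2)
})
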