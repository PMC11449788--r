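# Embedding, CLARA + Gap clustering, pseudotime, composition tables.

make_feature_frame <- function(x) {
  colnames(x) <- c("volume_nm3", "surface_nm2", "volume_ratio", "sphericity",
                   "M1", "M2", "M3", "M4", "M5")[seq_len(ncol(x))]
  as.data.frame(x)
}

# positive-valued synthetic feature records with n rows
random_records <- function(n, seed = 1) {
  set.seed(seed)
  make_feature_frame(matrix(exp(rnorm(n * 9)), n, 9))
}

test_that("embedding is reproducible and invariant to duplication", {
  r <- random_records(40)
  e <- shape_embed(r)
  expect_equal(dim(e$scores), c(40L, 3L))
  # stored transform reproduces scores exactly
  expect_equal(unname(predict(e, r)), unname(e$scores), tolerance = 1e-12)
  # duplicating the records duplicates the scores
  e2 <- shape_embed(rbind(r, r))
  expect_equal(abs(unname(e2$scores[1:40, ])), abs(unname(e2$scores[41:80, ])),
               tolerance = 1e-12)
})

test_that("embedding reports degenerate inputs", {
  r <- random_records(30)
  r$volume_ratio <- 5
  expect_error(shape_embed(r), class = "zero_variance")
  expect_error(shape_embed(r, features = "nope"), class = "invalid_data")
  expect_error(shape_embed(random_records(5)), class = "invalid_data")
  # data in a 2-plane after transform: PC3 variance ~ 0
  set.seed(2)
  z <- matrix(exp(rnorm(60)), 30, 2)
  r2 <- make_feature_frame(cbind(z, z[, 1] * z[, 2],
                                 matrix(rep(z[, 1] * z[, 2]^2, 6), 30, 6) *
                                   matrix(rep(c(1, 2, 3, 4, 5, 6), each = 30), 30, 6)))
  e3 <- shape_embed(r2)
  expect_lt(e3$sdev[3] / e3$sdev[1], 1e-6)
})

test_that("two separated blobs at forced k = 2 recover the partition", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60 * 3, 0), 60, 3), matrix(rnorm(60 * 3, 10), 60, 3))
  cl <- shape_cluster(x, k_range = 2, gap_B = 10, seed = 1)
  expect_equal(cl$k, 2)
  truth <- rep(1:2, each = 60)
  agree <- max(mean(cl$clustering == truth), mean(cl$clustering == 3 - truth))
  expect_equal(agree, 1)
})

test_that("gap statistic selects k = 1 on unclustered data", {
  # identical points
  x0 <- matrix(1, 40, 3)
  cl0 <- shape_cluster(x0, k_range = 1:4, gap_B = 10, seed = 1)
  expect_equal(cl0$k, 1)
  # null calibration: uniform single-cluster data picks k = 1 in >= 90% of runs
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(runif(120 * 3), 120, 3)
    shape_cluster(x, k_range = 1:6, gap_B = 25, seed = s)$k
  }, numeric(1))
  expect_gte(mean(picks == 1), 0.9)
})

test_that("clusters are reordered by ascending medoid volume", {
  set.seed(9)
  centers <- c(0, 20, 40)
  x <- do.call(rbind, lapply(centers, function(c0)
    matrix(rnorm(40 * 3, c0), 40, 3)))
  vol <- x[, 1]    # volume proxy increases with the blob center
  cl <- shape_cluster(x, volumes = vol, k_range = 3, gap_B = 10, seed = 2)
  expect_equal(cl$k, 3)
  med_vol <- vol[cl$medoids]
  expect_true(all(diff(med_vol) > 0))
  expect_setequal(cl$order_map, 1:3)
  # cluster id increases with volume (ties in the 3-level id cap Spearman)
  expect_gt(cor(cl$clustering, vol, method = "spearman"), 0.9)
})

test_that("pseudotime orders collinear points and flips with cluster order", {
  set.seed(3)
  t <- sort(runif(120, 0, 10))
  x <- cbind(t, 0.5 * t, -0.25 * t) +
    matrix(rnorm(360, 0, 0.01), 120, 3)
  cl <- shape_cluster(x, volumes = t, k_range = 3, gap_B = 10, seed = 1)
  pt <- suppressWarnings(shape_pseudotime(x, cl))
  expect_equal(mean(pt$pseudotime), 0, tolerance = 1e-8)
  expect_equal(sd(pt$pseudotime), 1, tolerance = 1e-8)
  expect_gt(cor(pt$pseudotime, t, method = "spearman"), 0.99)
  # reversing the cluster order negates pseudotime (up to the projection)
  cl_rev <- cl
  cl_rev$clustering <- as.integer(cl$k + 1L - cl$clustering)
  cl_rev$medoids <- rev(cl$medoids)
  pt_rev <- suppressWarnings(shape_pseudotime(x, cl_rev))
  expect_lt(cor(pt$pseudotime, pt_rev$pseudotime), -0.99)
})

test_that("pseudotime recovers a planted curved continuum", {
  set.seed(13)
  t <- runif(300, 0, 2 * pi * 0.75)
  x <- cbind(5 * cos(t), 5 * sin(t), 0.5 * t) + matrix(rnorm(900, 0, 0.2), 300, 3)
  cl <- shape_cluster(x, volumes = t, k_range = 4, gap_B = 10, seed = 4)
  pt <- suppressWarnings(shape_pseudotime(x, cl))
  expect_gt(abs(cor(pt$pseudotime, t, method = "spearman")), 0.95)
})

test_that("composition tables conserve counts and keep zero cells", {
  cl <- rep(1:6, times = c(4, 4, 4, 4, 4, 4))
  g <- rep(c("WT", "KO"), 12)
  ct <- composition_table(cl, g)
  expect_equal(colSums(ct$counts), c(KO = 12, WT = 12))
  expect_true(all(abs(colSums(ct$proportions) - 1) < 1e-12))
  # an empty cluster in one group is retained as a zero cell
  ct2 <- composition_table(c(1, 1, 2), c("a", "a", "b"), k = 3)
  expect_equal(nrow(ct2$counts), 3)
  expect_equal(unname(ct2$counts[3, ]), c(0, 0))
  expect_equal(sum(ct2$counts), 3)
  expect_error(composition_table(c(1, NA), c("a", "b")),
               class = "invalid_label")
})

test_that("the fingerprint recovers the generator's morphology continuum", {
  recs <- list()
  for (i in 1:2) {
    cfg <- sim_config(seed = 200 + i)
    sc <- gen_scaffolds(cfg)
    seg <- segment_objects(threshold_probability(sc$volume, 0.2))
    tab <- scaffold_shape_table(seg, cfg$voxel_size, 1.0)
    lab_map <- vapply(seg$objects, function(o)
      sc$labels[o$voxels[1, 1], o$voxels[1, 2], o$voxels[1, 3]], integer(1))
    keep <- !vapply(seg$objects, `[[`, logical(1), "border")
    tab$true_class <- sc$truth$class_index[lab_map[keep]]
    recs[[i]] <- tab
  }
  recs <- volume_filter(do.call(rbind, recs))
  emb <- shape_embed(recs)
  cl <- shape_cluster(emb, volumes = recs$volume_nm3, k_range = 1:8,
                      gap_B = 25, seed = 1)
  tt <- table(cl$clustering, recs$true_class)
  modal_match <- sum(apply(tt, 1, max)) / sum(tt)
  expect_gte(modal_match, 0.8)
  pt <- suppressWarnings(shape_pseudotime(emb, cl))
  expect_gt(cor(pt$pseudotime, recs$volume_nm3, method = "spearman"), 0.9)
})
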