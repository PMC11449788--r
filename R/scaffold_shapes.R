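# 3D scaffold shape analysis: thresholding of probability maps, 26-connected
# segmentation with border exclusion, and the nine-feature shape descriptor
# set (volume, surface, volume ratio, sphericity, five second-moment
# invariants), with per-animal expansion normalization and the resolution-
# based volume exclusion filter.

#' Threshold a probability map
#'
#' Keeps voxels with probability greater than or equal to the cutoff
#' (probabilities below the cutoff are excluded). Default cutoffs used in
#' the pipeline are 0.2 for confocal probability maps and 0.5 for STED.
#'
#' @param volume 3D array with values in \[0, 1\].
#' @param cutoff probability cutoff in \[0, 1\].
#' @return logical 3D array (the binary mask).
#' @export
threshold_probability <- function(volume, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff < 0 || cutoff > 1)
    stop_synmorph("cutoff must lie in [0, 1]", "invalid_cutoff")
  if (min(volume) < 0 || max(volume) > 1)
    stop_synmorph("probability map values must lie in [0, 1]", "invalid_volume")
  volume >= cutoff
}

#' Segment a binary mask into 26-connected objects
#'
#' Labels 26-connected components of a 3D binary mask. Components touching
#' any face of the volume are flagged as border objects; these are excluded
#' from downstream feature extraction (but returned, so that filter
#' accounting can be logged).
#'
#' @param mask logical 3D array.
#' @return object of class `segmented_scaffolds`: list with `objects` (per
#'   object: `label`, `voxels` n x 3 index matrix, `voxel_count`, `border`)
#'   and `labels` (3D integer array, 0 = background).
#' @export
segment_objects <- function(mask) {
  dm <- dim(mask)
  fg <- which(mask)
  labels <- array(0L, dm)
  if (length(fg) == 0)
    return(structure(list(objects = list(), labels = labels, dim = dm),
                     class = "segmented_scaffolds"))

  ix <- ((fg - 1L) %% dm[1]) + 1L
  iy <- (((fg - 1L) %/% dm[1]) %% dm[2]) + 1L
  iz <- ((fg - 1L) %/% (dm[1] * dm[2])) + 1L
  pos <- array(0L, dm); pos[fg] <- seq_along(fg)

  # neighbor index (into fg) per 26-offset; 0 where neighbor is background
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbrs <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    o <- offs[k, ]
    ok <- ix + o[1] >= 1L & ix + o[1] <= dm[1] &
          iy + o[2] >= 1L & iy + o[2] <= dm[2] &
          iz + o[3] >= 1L & iz + o[3] <= dm[3]
    nb <- integer(length(fg))
    nb[ok] <- pos[fg[ok] + o[1] + o[2] * dm[1] + o[3] * dm[1] * dm[2]]
    nbrs[[k]] <- nb
  }

  # iterative minimum-label propagation with pointer jumping
  lab <- seq_along(fg)
  repeat {
    old <- lab
    for (k in seq_len(nrow(offs))) {
      nb <- nbrs[[k]]; has <- nb > 0L
      lab[has] <- pmin(lab[has], lab[nb[has]])
    }
    lab <- lab[lab]          # path compression
    if (identical(lab, old)) break
  }
  while (any(lab != lab[lab])) lab <- lab[lab]

  roots <- sort(unique(lab))
  comp <- match(lab, roots)
  labels[fg] <- comp

  on_border <- ix == 1L | ix == dm[1] | iy == 1L | iy == dm[2] |
               iz == 1L | iz == dm[3]
  border_comp <- sort(unique(comp[on_border]))

  objects <- lapply(seq_along(roots), function(c) {
    sel <- comp == c
    list(label = c,
         voxels = cbind(x = ix[sel], y = iy[sel], z = iz[sel]),
         voxel_count = sum(sel),
         border = c %in% border_comp)
  })
  structure(list(objects = objects, labels = labels, dim = dm),
            class = "segmented_scaffolds")
}

# surface area of a voxel set via the co-area formula on a Gaussian-smoothed
# indicator: A = sum |grad u| dV with u = G_sigma * chi. Validated to < 1%
# on digitized balls. Works in index (pixel) units.
coarea_surface <- function(voxels, sigma = 1) {
  pad <- ceiling(3 * sigma) + 2L
  lo <- apply(voxels, 2, min) - pad
  dm <- apply(voxels, 2, max) - lo + pad
  a <- array(0, dm)
  a[cbind(voxels[, 1] - lo[1], voxels[, 2] - lo[2], voxels[, 3] - lo[3])] <- 1
  u <- smooth3d(a, sigma)
  d1 <- dim(u)
  gx <- (u[c(2:d1[1], d1[1]), , ] - u[c(1, 1:(d1[1] - 1)), , ]) / 2
  gy <- (u[, c(2:d1[2], d1[2]), ] - u[, c(1, 1:(d1[2] - 1)), ]) / 2
  gz <- (u[, , c(2:d1[3], d1[3])] - u[, , c(1, 1:(d1[3] - 1))]) / 2
  sum(sqrt(gx^2 + gy^2 + gz^2))
}

#' Shape features of a segmented scaffold
#'
#' Computes the nine-feature shape descriptor of one object:
#' \itemize{
#'   \item `volume_nm3`: voxel count x voxel volume, divided by the cubed
#'     per-animal correction factor;
#'   \item `surface_nm2`: surface area in pixel units (co-area estimate on
#'     the smoothed indicator) x the squared xy pixel size, divided by the
#'     squared correction factor;
#'   \item `volume_ratio`: voxel-grid symmetric difference between the
#'     object and its moment-equivalent ellipsoid, relative to the object
#'     volume (0 for a perfect ellipsoid, growing with lobes/perforations);
#'   \item `sphericity`: \eqn{\pi^{1/3} (6V)^{2/3} / A} in pixel units;
#'   \item `M1..M5`: scale/translation/rotation-invariant functions of the
#'     normalized second central moment tensor
#'     \eqn{\eta = \mu_2 / \mu_{000}^{5/3}}: M1 = tr(\eqn{\eta}),
#'     M2 = second elementary symmetric function of its eigenvalues,
#'     M3 = det(\eqn{\eta}), M4 = M1^2/M2, M5 = M1^3/M3.
#' }
#' The moment-equivalent ellipsoid shares the object's centroid and second
#' central moments (solid-ellipsoid relation: semi-axes
#' \eqn{a_i = \sqrt{5 \lambda_i}}).
#'
#' @param voxels n x 3 integer matrix of voxel indices (one object).
#' @param voxel_size voxel size in nm (x, y, z).
#' @param correction_factor per-animal expansion correction factor
#'   (animal mean AZ-PSD distance / batch mean; dimensionless).
#' @param surface_sigma smoothing sigma (voxels) of the surface estimator.
#' @return named list with the nine features plus `voxel_count` and a
#'   `degenerate` flag (set when the moment tensor needed regularization).
#' @export
shape_features <- function(voxels, voxel_size = c(43, 43, 120),
                           correction_factor = 1, surface_sigma = 1) {
  voxels <- as.matrix(voxels)
  n <- nrow(voxels)
  if (n < 1) stop_synmorph("object must contain at least one voxel",
                           "invalid_object")
  check_positive(correction_factor, "correction_factor")
  cf <- correction_factor

  ctr <- colMeans(voxels)
  cenc <- sweep(voxels, 2, ctr)
  # second central moments of the voxel set; + 1/12 per voxel for the
  # within-voxel mass distribution (exact for unit cubes)
  mu2 <- crossprod(cenc) + diag(n / 12, 3)

  degenerate <- FALSE
  cov3 <- mu2 / n
  ev <- eigen(cov3, symmetric = TRUE)
  if (min(ev$values) < 1e-9) {
    degenerate <- TRUE
    cov3 <- cov3 + diag(1e-6 * max(ev$values, 1), 3)
    ev <- eigen(cov3, symmetric = TRUE)
  }

  eta <- (cov3 * n) / n^(5 / 3)
  lam <- eigen(eta, symmetric = TRUE, only.values = TRUE)$values
  M1 <- sum(lam)
  M2 <- lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3]
  M3 <- prod(lam)
  M4 <- M1^2 / M2
  M5 <- M1^3 / M3

  # moment-equivalent solid ellipsoid and voxel-grid symmetric difference
  semi <- sqrt(5 * ev$values)
  axes <- ev$vectors
  rng <- lapply(1:3, function(d) {
    lo <- floor(min(voxels[, d], ctr[d] - max(semi)) - 1)
    hi <- ceiling(max(voxels[, d], ctr[d] + max(semi)) + 1)
    lo:hi
  })
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  q <- sweep(g, 2, ctr) %*% axes
  in_ell <- (q[, 1] / semi[1])^2 + (q[, 2] / semi[2])^2 +
    (q[, 3] / semi[3])^2 <= 1
  key_obj <- paste(voxels[, 1], voxels[, 2], voxels[, 3])
  key_ell <- paste(g[in_ell, 1], g[in_ell, 2], g[in_ell, 3])
  n_int <- sum(key_ell %in% key_obj)
  volume_ratio <- (n - n_int + length(key_ell) - n_int) / n

  A_px <- coarea_surface(voxels, surface_sigma)
  sphericity <- pi^(1 / 3) * (6 * n)^(2 / 3) / A_px

  list(volume_nm3 = n * prod(voxel_size) / cf^3,
       surface_nm2 = A_px * voxel_size[1] * voxel_size[2] / cf^2,
       volume_ratio = volume_ratio,
       sphericity = sphericity,
       M1 = M1, M2 = M2, M3 = M3, M4 = M4, M5 = M5,
       voxel_count = n, degenerate = degenerate)
}

#' Shape-feature table of a segmented volume
#'
#' Applies [shape_features()] to every non-border object of a segmentation
#' and assembles the feature table with grouping metadata.
#'
#' @param seg a `segmented_scaffolds` object.
#' @param voxel_size,correction_factor passed to [shape_features()].
#' @param metadata optional named list (e.g. animal, genotype, region)
#'   replicated onto every row.
#' @return data frame with one row per analyzed object; attribute
#'   `n_border_excluded` reports how many objects were dropped at the
#'   border-exclusion step.
#' @export
scaffold_shape_table <- function(seg, voxel_size = c(43, 43, 120),
                                 correction_factor = 1, metadata = list()) {
  keep <- Filter(function(o) !o$border, seg$objects)
  rows <- lapply(keep, function(o) {
    f <- shape_features(o$voxels, voxel_size, correction_factor)
    cbind(data.frame(label = o$label), as.data.frame(f))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0))
  for (nm in names(metadata)) out[[nm]] <- metadata[[nm]]
  attr(out, "n_border_excluded") <- length(seg$objects) - length(keep)
  out
}

#' Resolution-based volume exclusion threshold
#'
#' The minimal analyzable object volume is a cuboid with edges of twice the
#' theoretical confocal resolution limit (2 x 200^2 x 500 nm^3), expressed
#' in voxels of the acquisition grid and rounded to the nearest hundred.
#' With 43 x 43 x 120 nm voxels this gives 180.3 voxels, rounded to 200.
#'
#' @param resolution_xy,resolution_z confocal resolution limits in nm.
#' @param voxel_size voxel size in nm.
#' @param round_to rounding granularity in voxels.
#' @return list with `voxels` (the exact ratio) and `threshold` (rounded).
#' @export
volume_exclusion_threshold <- function(resolution_xy = 200,
                                       resolution_z = 500,
                                       voxel_size = c(43, 43, 120),
                                       round_to = 100) {
  v <- 2 * resolution_xy^2 * resolution_z / prod(voxel_size)
  list(voxels = v, threshold = round(v / round_to) * round_to)
}

#' Filter shape records by voxel-count threshold
#'
#' Removes objects whose voxel count falls below the exclusion threshold
#' (default 200 voxels, from [volume_exclusion_threshold()]).
#'
#' @param records data frame with a `voxel_count` column.
#' @param threshold minimum voxel count retained (objects with
#'   `voxel_count < threshold` are rejected).
#' @return the filtered records; attribute `n_volume_excluded` reports the
#'   number of rejected objects.
#' @export
volume_filter <- function(records,
                          threshold = volume_exclusion_threshold()$threshold) {
  if (threshold < 1)
    stop_synmorph("threshold must be at least 1 voxel", "invalid_threshold")
  keep <- records$voxel_count >= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "n_volume_excluded") <- sum(!keep)
  out
}
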