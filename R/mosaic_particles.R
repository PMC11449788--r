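# Per-synapse 2D analysis of subsynaptic particles: rolling-ball background
# subtraction and maximum-intensity projection, rigid channel alignment by
# exhaustive correlation search, FindFoci-style particle detection
# (smoothing, local maxima, descending-intensity region growing, saddle
# merging), basic particle properties, Manders colocalization, k-nearest-
# neighbour distance profiles, Ripley's K with isotropic edge correction and
# the summed CSR-deviation scalar, and overlap-pair distances between the
# labeled particle masks of two channels.

# grayscale morphological filters with a disc structuring element;
# edges are replicated so the estimate has no border dip
gray_filter <- function(m, radius, fun) {
  dm <- dim(m)
  pad <- as.integer(radius)
  ri <- c(rep(1L, pad), seq_len(dm[1]), rep(dm[1], pad))
  ci <- c(rep(1L, pad), seq_len(dm[2]), rep(dm[2], pad))
  mp <- m[ri, ci]
  offs <- as.matrix(expand.grid(dx = -pad:pad, dy = -pad:pad))
  offs <- offs[offs[, 1]^2 + offs[, 2]^2 <= radius^2, , drop = FALSE]
  out <- NULL
  for (k in seq_len(nrow(offs))) {
    sh <- mp[pad + seq_len(dm[1]) + offs[k, 1],
             pad + seq_len(dm[2]) + offs[k, 2]]
    out <- if (is.null(out)) sh else fun(out, sh)
  }
  out
}

gray_opening <- function(m, radius) {
  gray_filter(gray_filter(m, radius, pmin), radius, pmax)
}

#' Preprocess a STED synapse stack
#'
#' Subtracts the rolling-ball background from every slice (grayscale
#' morphological opening with a disc structuring element of the given
#' radius), takes the maximum-intensity projection over slices, and clears
#' all pixels outside the synapse ROI.
#'
#' @param stack list of 2D matrices (slices) or a 3D array (x, y, slice).
#' @param roi logical matrix, the synapse ROI mask (same 2D dimensions).
#' @param ball_radius rolling-ball radius in pixels (default 10).
#' @return the background-subtracted, ROI-cleared projection matrix.
#' @export
preprocess_synapse <- function(stack, roi, ball_radius = 10) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack)) stack <- list(stack)
  dm <- dim(stack[[1]])
  if (!identical(dim(roi), dm))
    stop_synmorph("ROI dimensions do not match the image", "invalid_roi")

  sub <- lapply(stack, function(s) {
    bg <- gray_opening(s, ball_radius)
    pmax(s - bg, 0)
  })
  mip <- Reduce(pmax, sub)
  mip[!roi] <- 0
  mip
}

# bilinear rotation of a matrix about an arbitrary center (degrees,
# counter-clockwise in (row, col) coordinates); out-of-range -> 0
rotate_about <- function(img, theta_deg, center) {
  if (theta_deg == 0) return(img)
  th <- theta_deg * pi / 180
  dm <- dim(img)
  r <- matrix(rep(seq_len(dm[1]), dm[2]), dm[1], dm[2]) - center[1]
  c <- matrix(rep(seq_len(dm[2]), each = dm[1]), dm[1], dm[2]) - center[2]
  sr <- cos(th) * r + sin(th) * c + center[1]   # inverse mapping
  sc <- -sin(th) * r + cos(th) * c + center[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= dm[1] & ci >= 1 & ci <= dm[2]
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * val(r0, c0) + fr * (1 - fc) * val(r0 + 1, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) + fr * fc * val(r0 + 1, c0 + 1)
  matrix(out, dm[1], dm[2])
}

#' Rigidly align channel 2 onto channel 1
#'
#' Exhaustive search over integer translations (within `max_shift` pixels)
#' and rotations about the ROI centroid (within `max_rot` degrees, in
#' `rot_step` steps) maximizing the Pearson correlation of the two channels
#' inside the ROI. The identity transform is always a candidate, so the
#' correlation after alignment is never below the one before.
#'
#' @param ch1,ch2 2D intensity matrices of equal dimensions.
#' @param roi logical ROI mask.
#' @param max_shift,max_rot,rot_step search ranges (px, degrees, degrees).
#' @return list with `shift` (dx, dy applied to ch2), `rotation_deg`,
#'   `cor_before`, `cor_after`, and `ch2_aligned`.
#' @export
align_channels <- function(ch1, ch2, roi, max_shift = 10, max_rot = 10,
                           rot_step = 1) {
  dm <- dim(ch1)
  stopifnot(identical(dim(ch2), dm), identical(dim(roi), dm))
  v1 <- ch1[roi]
  if (sd(v1) == 0 || sd(ch2[roi]) == 0) {
    warning("flat channel inside ROI; returning identity transform")
    return(list(shift = c(0, 0), rotation_deg = 0,
                cor_before = NA_real_, cor_after = NA_real_,
                ch2_aligned = ch2))
  }
  idx <- which(roi, arr.ind = TRUE)
  ctr <- colMeans(idx)
  shifts <- as.matrix(expand.grid(sdx = -max_shift:max_shift,
                                  sdy = -max_shift:max_shift))
  # linear indices into the zero-padded rotated image, one column per shift
  prd <- dm[1] + 2 * max_shift
  lin <- outer(idx[, 1] + max_shift, shifts[, 1], "+") +
    (outer(idx[, 2] + max_shift, shifts[, 2], "+") - 1) * prd

  n <- length(v1); s1 <- sum(v1); ss1 <- sum(v1^2)
  best <- list(cor = -Inf)
  for (ang in seq(-max_rot, max_rot, by = rot_step)) {
    rot <- rotate_about(ch2, ang, ctr)
    padded <- matrix(0, prd, dm[2] + 2 * max_shift)
    padded[max_shift + seq_len(dm[1]), max_shift + seq_len(dm[2])] <- rot
    vals <- matrix(padded[lin], nrow = n)
    s2 <- colSums(vals); ss2 <- colSums(vals^2)
    s12 <- as.vector(crossprod(v1, vals))
    denom <- sqrt(pmax(n * ss1 - s1^2, 0) * pmax(n * ss2 - s2^2, 0))
    cors <- ifelse(denom > 0, (n * s12 - s1 * s2) / denom, -Inf)
    j <- which.max(cors)
    if (cors[j] > best$cor)
      best <- list(cor = cors[j], ang = ang, sdx = shifts[j, 1],
                   sdy = shifts[j, 2])
  }
  cor_before <- cor(v1, ch2[roi])
  rot <- rotate_about(ch2, best$ang, ctr)
  # reported shift is the translation applied to ch2 content
  dx <- -best$sdx; dy <- -best$sdy
  aligned <- matrix(0, dm[1], dm[2])
  src_r <- seq_len(dm[1]) - dx; src_c <- seq_len(dm[2]) - dy
  ok_r <- src_r >= 1 & src_r <= dm[1]; ok_c <- src_c >= 1 & src_c <= dm[2]
  aligned[ok_r, ok_c] <- rot[src_r[ok_r], src_c[ok_c]]
  list(shift = c(dx = unname(dx), dy = unname(dy)),
       rotation_deg = best$ang, cor_before = cor_before,
       cor_after = best$cor, ch2_aligned = aligned)
}

#' Detect subsynaptic particles (FindFoci-style)
#'
#' Gaussian pre-smoothing, local-maximum seeds above a background level,
#' descending-intensity region growing that assigns every above-background
#' pixel to a peak (recording saddle heights between touching regions), and
#' merging of peaks whose height above the connecting saddle is less than a
#' fraction of their height above background, or whose region is smaller
#' than a minimum size.
#'
#' @param image 2D intensity matrix.
#' @param mask logical matrix restricting the search (defaults to the whole
#'   image); typically the thresholded probability-map mask.
#' @param pixel_size pixel size in nm.
#' @param smooth_sd Gaussian pre-smoothing sigma in px (0 disables).
#' @param background background level; default is the mean intensity of the
#'   smoothed image inside the mask.
#' @param saddle_frac merge threshold: peaks are merged when
#'   `min peak height above saddle < saddle_frac * height above background`.
#' @param min_size minimum region size in px; smaller regions are merged
#'   into their strongest-saddle neighbour (or dropped if isolated).
#' @return object of class `point_pattern`: `points` (data frame: `x`, `y`
#'   in nm, `area_nm2`, `total_int`, `avg_int`), `labels` (labeled matrix),
#'   `pixel_size`, `mask_area_px`.
#' @export
detect_particles <- function(image, mask = NULL, pixel_size = 25,
                             smooth_sd = 1, background = NULL,
                             saddle_frac = 0.2, min_size = 4) {
  dm <- dim(image)
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  empty <- function() structure(
    list(points = data.frame(x = numeric(0), y = numeric(0),
                             area_nm2 = numeric(0), total_int = numeric(0),
                             avg_int = numeric(0)),
         labels = matrix(0L, dm[1], dm[2]), pixel_size = pixel_size,
         mask_area_px = sum(mask)), class = "point_pattern")
  if (!any(mask)) return(empty())

  im <- if (smooth_sd > 0) smooth2d(image, smooth_sd) else image
  bg <- background %||% mean(im[mask])
  consider <- mask & im > bg
  if (!any(consider)) return(empty())

  px <- which(consider)
  ord <- px[order(im[px], decreasing = TRUE)]
  lab <- matrix(0L, dm[1], dm[2])
  nreg <- 0L
  peak_h <- numeric(0)
  saddle <- matrix(-Inf, 0, 0)
  noff <- c(-1L, 1L, -dm[1], dm[1], -dm[1] - 1L, -dm[1] + 1L,
            dm[1] - 1L, dm[1] + 1L)
  for (p in ord) {
    r <- ((p - 1L) %% dm[1]) + 1L; cc <- ((p - 1L) %/% dm[1]) + 1L
    nb <- p + noff
    keep <- rep(TRUE, 8L)
    if (r == 1L) keep[c(1, 5, 7)] <- FALSE
    if (r == dm[1]) keep[c(2, 6, 8)] <- FALSE
    if (cc == 1L) keep[c(3, 5, 6)] <- FALSE
    if (cc == dm[2]) keep[c(4, 7, 8)] <- FALSE
    nb <- nb[keep]
    nl <- lab[nb]; nl <- nl[nl > 0L]
    if (length(nl) == 0L) {
      nreg <- nreg + 1L
      lab[p] <- nreg
      peak_h[nreg] <- im[p]
      if (nreg > 1L) {
        saddle <- rbind(cbind(saddle, -Inf), -Inf)
      } else saddle <- matrix(-Inf, 1, 1)
    } else {
      ul <- unique(nl)
      # assign to the label of the highest-intensity labeled neighbor
      nbl <- nb[lab[nb] > 0L]
      lab[p] <- lab[nbl[which.max(im[nbl])]]
      if (length(ul) > 1L) {
        for (a in seq_along(ul)) for (b in seq_along(ul)) if (a < b) {
          i <- ul[a]; j <- ul[b]
          if (im[p] > saddle[i, j]) {
            saddle[i, j] <- im[p]; saddle[j, i] <- im[p]
          }
        }
      }
    }
  }

  # merge by saddle rule and minimum size
  parent <- seq_len(nreg)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sizes <- tabulate(lab[lab > 0L], nreg)
  repeat {
    changed <- FALSE
    roots <- unique(vapply(seq_len(nreg), find, integer(1)))
    if (length(roots) > 1) {
      for (i in roots) for (j in roots) if (i < j && is.finite(saddle[i, j])) {
        h <- min(peak_h[i], peak_h[j])
        if ((h - saddle[i, j]) < saddle_frac * (h - bg) ||
            min(sizes[i], sizes[j]) < min_size) {
          lo <- if (peak_h[i] >= peak_h[j]) i else j
          hi <- if (lo == i) j else i
          parent[hi] <- lo
          sizes[lo] <- sizes[lo] + sizes[hi]
          peak_h[lo] <- max(peak_h[lo], peak_h[hi])
          saddle[lo, ] <- pmax(saddle[lo, ], saddle[hi, ])
          saddle[, lo] <- pmax(saddle[, lo], saddle[, hi])
          saddle[lo, lo] <- -Inf
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  fg <- which(lab > 0L)
  lab[fg] <- vapply(lab[fg], find, integer(1))
  # drop still-undersized isolated regions
  sz <- tabulate(lab[fg], nreg)
  small <- which(sz > 0 & sz < min_size)
  if (length(small)) lab[lab %in% small] <- 0L
  fg <- which(lab > 0L)
  if (length(fg) == 0L) return(empty())
  final <- sort(unique(lab[fg]))
  lab[fg] <- match(lab[fg], final)

  rows <- lapply(seq_along(final), function(i) {
    sel <- which(lab == i)
    r <- ((sel - 1L) %% dm[1]) + 1L; cc <- ((sel - 1L) %/% dm[1]) + 1L
    w <- image[sel]
    tot <- sum(w)
    wx <- if (tot > 0) sum((r - 0.5) * w) / tot else mean(r - 0.5)
    wy <- if (tot > 0) sum((cc - 0.5) * w) / tot else mean(cc - 0.5)
    data.frame(x = wx * pixel_size, y = wy * pixel_size,
               area_nm2 = length(sel) * pixel_size^2,
               total_int = tot, avg_int = tot / length(sel))
  })
  structure(list(points = do.call(rbind, rows), labels = lab,
                 pixel_size = pixel_size, mask_area_px = sum(mask)),
            class = "point_pattern")
}

#' Per-synapse basic particle properties
#'
#' Averages particle area and intensities over the synapse and derives the
#' particle density (count per mask area). Length-derived quantities are
#' corrected for local expansion: areas are divided by the squared
#' correction factor, densities multiplied by it squared; intensities are
#' left unchanged. Centering and scaling across the analysis set is applied
#' downstream, once all synapses are assembled.
#'
#' @param pattern a `point_pattern`.
#' @param correction_factor per-animal expansion correction factor.
#' @return one-row data frame: `n`, `mean_area_nm2`, `mean_total_int`,
#'   `mean_avg_int`, `density_per_nm2`, `flagged` (TRUE when the pattern is
#'   empty and the averages are undefined).
#' @export
particle_summary <- function(pattern, correction_factor = 1) {
  cf <- correction_factor
  if (pattern$mask_area_px <= 0)
    stop_synmorph("mask area is zero", "invalid_mask")
  area_nm2 <- pattern$mask_area_px * pattern$pixel_size^2
  pts <- pattern$points
  n <- nrow(pts)
  if (n == 0) {
    return(data.frame(n = 0L, mean_area_nm2 = NA_real_,
                      mean_total_int = NA_real_, mean_avg_int = NA_real_,
                      density_per_nm2 = 0, flagged = TRUE))
  }
  data.frame(n = n,
             mean_area_nm2 = mean(pts$area_nm2) / cf^2,
             mean_total_int = mean(pts$total_int),
             mean_avg_int = mean(pts$avg_int),
             density_per_nm2 = n / area_nm2 * cf^2,
             flagged = FALSE)
}

#' Manders colocalization coefficients
#'
#' M1 is the fraction of channel-1 intensity inside mask 1 that also lies
#' inside mask 2; M2 is the symmetric quantity for channel 2. Both lie in
#' \[0, 1\]; a zero denominator yields `NA` with a flag.
#'
#' @param ch1,ch2 aligned intensity matrices.
#' @param mask1,mask2 particle-support masks (logical, or labeled with
#'   0 = background).
#' @return named vector `c(M1, M2)`; attribute `flagged` marks undefined
#'   coefficients.
#' @export
manders <- function(ch1, ch2, mask1, mask2) {
  m1 <- mask1 > 0; m2 <- mask2 > 0
  d1 <- sum(ch1[m1]); d2 <- sum(ch2[m2])
  M1 <- if (d1 > 0) sum(ch1[m1 & m2]) / d1 else NA_real_
  M2 <- if (d2 > 0) sum(ch2[m1 & m2]) / d2 else NA_real_
  structure(c(M1 = M1, M2 = M2), flagged = is.na(M1) || is.na(M2))
}

#' Mean k-nearest-neighbour distances of a point pattern
#'
#' For every point, the Euclidean distances to its k nearest neighbours
#' (k = 1..K); means over points per k, divided by the expansion correction
#' factor. Means are non-decreasing in k.
#'
#' @param points `point_pattern`, data frame, or matrix with `x`, `y` in nm.
#' @param K highest neighbour rank; if the pattern has only n <= K points
#'   the profile is computed to k = n - 1 and flagged.
#' @param correction_factor per-animal expansion correction factor.
#' @return data frame with `k` and `mean_nnd` (nm); attribute `flagged`.
#' @export
nnd_profile <- function(points, K = 20, correction_factor = 1) {
  xy <- pattern_coords(points)
  n <- nrow(xy)
  if (n < 2) stop_synmorph("need at least two points", "invalid_data")
  flagged <- n <= K
  Ke <- min(K, n - 1)
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  sorted <- apply(d, 1, function(r) sort(r)[seq_len(Ke)])
  if (Ke == 1) sorted <- matrix(sorted, nrow = 1)
  structure(data.frame(k = seq_len(Ke),
                       mean_nnd = rowMeans(sorted) / correction_factor),
            flagged = flagged)
}

pattern_coords <- function(points) {
  if (inherits(points, "point_pattern")) points <- points$points
  points <- as.data.frame(points)
  if (all(c("x", "y") %in% colnames(points)))
    points <- points[, c("x", "y")]
  as.matrix(points[, 1:2])
}

window_area <- function(window) {
  switch(window$type,
         ellipse = pi * prod(window$semi),
         rect = diff(window$xrange) * diff(window$yrange),
         stop_synmorph("unknown window type", "invalid_window"))
}

window_inside <- function(window, x, y) {
  switch(window$type,
         ellipse = ((x - window$center[1]) / window$semi[1])^2 +
           ((y - window$center[2]) / window$semi[2])^2 <= 1,
         rect = x >= window$xrange[1] & x <= window$xrange[2] &
           y >= window$yrange[1] & y <= window$yrange[2])
}

#' Ripley's K function and CSR-deviation scalar
#'
#' Estimates K(r) on the ROI window up to `r_max` (default 500 nm = 20
#' pixels of 25 nm), with Ripley isotropic edge correction (the weight of a
#' point pair is the reciprocal fraction of the circle through the neighbour
#' that lies inside the window; computed numerically on the window). The
#' CSR-deviation scalar is the summed difference between the estimate and
#' the CSR expectation pi r^2, divided by the number of radii.
#'
#' @param points `point_pattern`, data frame, or matrix (`x`, `y`, nm).
#' @param window observation window: `list(type = "ellipse", center, semi)`
#'   or `list(type = "rect", xrange, yrange)`.
#' @param r_max maximum radius (same unit as the coordinates).
#' @param nr number of radii (evaluated at `r_max/nr, 2 r_max/nr, ...`).
#' @param correction `"isotropic"` or `"none"`.
#' @param n_angles angular resolution of the numeric boundary correction.
#' @return list with `r`, `K`, `theoretical` (pi r^2), and `deviation`;
#'   `NA` with a flag for patterns of fewer than two points.
#' @export
ripley_csr <- function(points, window, r_max = 500, nr = 20,
                       correction = c("isotropic", "none"), n_angles = 72) {
  correction <- match.arg(correction)
  xy <- pattern_coords(points)
  n <- nrow(xy)
  r <- seq(r_max / nr, r_max, length.out = nr)
  if (n < 2) {
    return(structure(list(r = r, K = rep(NA_real_, nr),
                          theoretical = pi * r^2, deviation = NA_real_),
                     flagged = TRUE))
  }
  A <- window_area(window)
  prs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- xy[prs[, 1], 1] - xy[prs[, 2], 1]
  dy <- xy[prs[, 1], 2] - xy[prs[, 2], 2]
  dij <- sqrt(dx^2 + dy^2)

  if (correction == "isotropic") {
    th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
    frac_inside <- function(cx, cy, rad) {
      # fraction of the circle (cx, cy, rad) inside the window
      px <- outer(rad, cos(th)) + cx
      py <- outer(rad, sin(th)) + cy
      rowMeans(matrix(window_inside(window, px, py), nrow = length(rad)))
    }
    w1 <- 1 / pmax(frac_inside(xy[prs[, 1], 1], xy[prs[, 1], 2], dij), 1e-6)
    w2 <- 1 / pmax(frac_inside(xy[prs[, 2], 1], xy[prs[, 2], 2], dij), 1e-6)
  } else {
    w1 <- w2 <- rep(1, length(dij))
  }
  K <- vapply(r, function(rr) {
    sel <- dij <= rr
    A / (n * (n - 1)) * sum(w1[sel] + w2[sel])
  }, numeric(1))
  structure(list(r = r, K = K, theoretical = pi * r^2,
                 deviation = sum(K - pi * r^2) / nr),
            flagged = FALSE)
}

#' Centre-of-mass distances of overlapping particle pairs
#'
#' Every labeled region in the first mask sharing at least one pixel with a
#' region in the second mask forms a colocalizing pair (a region overlapping
#' several partners contributes one pair per partner). The distance of a
#' pair is the Euclidean distance between the two regions' centres of mass,
#' divided by the expansion correction factor.
#'
#' @param mask1,mask2 labeled particle masks (integer matrices,
#'   0 = background), e.g. the `labels` of [detect_particles()].
#' @param pixel_size pixel size in nm.
#' @param correction_factor per-animal expansion correction factor.
#' @return list with `pairs` (label1, label2, distance_nm) and
#'   `mean_distance`; flagged `NA` when no pair overlaps.
#' @export
overlap_pair_distances <- function(mask1, mask2, pixel_size = 25,
                                   correction_factor = 1) {
  ov <- mask1 > 0 & mask2 > 0
  if (!any(ov)) {
    return(structure(list(pairs = data.frame(label1 = integer(0),
                                             label2 = integer(0),
                                             distance_nm = numeric(0)),
                          mean_distance = NA_real_), flagged = TRUE))
  }
  centroid <- function(mask, l) {
    sel <- which(mask == l)
    dm <- dim(mask)
    r <- ((sel - 1L) %% dm[1]) + 1L; cc <- ((sel - 1L) %/% dm[1]) + 1L
    c(mean(r - 0.5), mean(cc - 0.5)) * pixel_size
  }
  pr <- unique(data.frame(label1 = mask1[ov], label2 = mask2[ov]))
  pr <- pr[order(pr$label1, pr$label2), , drop = FALSE]
  pr$distance_nm <- vapply(seq_len(nrow(pr)), function(i) {
    c1 <- centroid(mask1, pr$label1[i]); c2 <- centroid(mask2, pr$label2[i])
    sqrt(sum((c1 - c2)^2)) / correction_factor
  }, numeric(1))
  rownames(pr) <- NULL
  structure(list(pairs = pr, mean_distance = mean(pr$distance_nm)),
            flagged = FALSE)
}
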