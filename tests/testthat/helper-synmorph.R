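# Fixture builders and tiny independent oracles used across the suite.

# two-Gaussian line profile sampled at the confocal pixel pitch
two_peak_trace <- function(separation, peak_sd = 30, amplitude = 100,
                           baseline = 5, noise_sd = 0, step = 43,
                           center = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- ceiling((separation + 700) / step) * step
  if (is.null(center)) center <- len / 2
  pos <- seq(0, len, by = step)
  mu <- c(center - separation / 2, center + separation / 2)
  int <- baseline +
    amplitude * exp(-(pos - mu[1])^2 / (2 * peak_sd^2)) +
    amplitude * exp(-(pos - mu[2])^2 / (2 * peak_sd^2))
  if (noise_sd > 0) int <- int + rnorm(length(pos), 0, noise_sd)
  data.frame(position = pos, intensity = int)
}

# digitized ball: voxel-center-inside test (the brute-force enumeration)
digitized_ball <- function(radius, center = NULL) {
  n <- ceiling(radius) * 2 + 5
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  g <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  keep <- (g[, 1] - center[1])^2 + (g[, 2] - center[2])^2 +
    (g[, 3] - center[3])^2 <= radius^2
  g[keep, , drop = FALSE]
}

digitized_ellipsoid <- function(semi, center = NULL) {
  n <- ceiling(max(semi)) * 2 + 5
  if (is.null(center)) center <- rep((n + 1) / 2, 3)
  g <- as.matrix(expand.grid(x = 1:n, y = 1:n, z = 1:n))
  keep <- ((g[, 1] - center[1]) / semi[1])^2 +
    ((g[, 2] - center[2]) / semi[2])^2 +
    ((g[, 3] - center[3]) / semi[3])^2 <= 1
  g[keep, , drop = FALSE]
}

# render Gaussian spots (no noise) on a dm[1] x dm[2] pixel grid
render_spot_image <- function(pts_px, dm = c(48, 48), amplitude = 100,
                              psf_sd = 2, baseline = 0) {
  xs <- matrix(rep(seq_len(dm[1]) - 0.5, dm[2]), dm[1], dm[2])
  ys <- matrix(rep(seq_len(dm[2]) - 0.5, each = dm[1]), dm[1], dm[2])
  img <- matrix(baseline, dm[1], dm[2])
  for (i in seq_len(nrow(pts_px)))
    img <- img + amplitude *
      exp(-((xs - pts_px[i, 1])^2 + (ys - pts_px[i, 2])^2) / (2 * psf_sd^2))
  img
}

# brute-force k-NN mean distances (independent of nnd_profile internals)
brute_force_nnd <- function(xy, K) {
  n <- nrow(xy)
  means <- numeric(K)
  all_sorted <- sapply(seq_len(n), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    sort(d[-i])[seq_len(K)]
  })
  if (K == 1) all_sorted <- matrix(all_sorted, nrow = 1)
  rowMeans(all_sorted)
}

# uniform points in an elliptical window (for CSR oracles)
csr_in_ellipse <- function(n, center, semi) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    x <- runif(2 * n, center[1] - semi[1], center[1] + semi[1])
    y <- runif(2 * n, center[2] - semi[2], center[2] + semi[2])
    k <- ((x - center[1]) / semi[1])^2 + ((y - center[2]) / semi[2])^2 <= 1
    out <- rbind(out, cbind(x[k], y[k]))
  }
  out[seq_len(n), , drop = FALSE]
}

ellipse_window <- function(center = c(800, 800), semi = c(650, 500)) {
  list(type = "ellipse", center = center, semi = semi)
}
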