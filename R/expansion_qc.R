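# Expansion quality control: AZ-PSD peak distances from line profiles across
# side-view synapses, per-animal correction factors, batch normalization and
# the macroscopic (gel-level) expansion factor. The AZ-PSD distance acts as a
# local expansion ruler: after ~10x expansion the two protein bands sit
# roughly 500 nm apart, and animal-to-animal differences in that distance are
# divided out of every downstream length-derived measurement.

#' Measure the AZ-PSD peak distance of a line profile
#'
#' Fits a polynomial through the intensity profile, locates its local maxima
#' on a fine grid, keeps the two highest, and refines each peak position by a
#' local log-quadratic fit to the baseline-subtracted raw samples (exact for
#' Gaussian-shaped peaks). Returns the distance between the two refined peak
#' positions along the line.
#'
#' The measurement is invariant to adding a constant baseline and to uniform
#' intensity scaling.
#'
#' @param trace data frame with columns `position` (nm, strictly increasing,
#'   at least 20 samples) and `intensity` (non-negative).
#' @param degree polynomial degree for peak detection (default 8).
#' @param refine_halfwidth half-width in nm of the window used for the local
#'   log-quadratic refinement around each detected peak.
#' @return the AZ-PSD distance in nm, with attribute `peaks` holding the two
#'   refined peak positions.
#' @export
measure_az_psd <- function(trace, degree = 8, refine_halfwidth = 90) {
  pos <- trace$position; int <- trace$intensity
  if (length(pos) < 20)
    stop_synmorph("profile must contain at least 20 samples", "invalid_trace")
  if (any(diff(pos) <= 0))
    stop_synmorph("positions must be strictly increasing", "invalid_trace")

  ctr <- mean(pos); scl <- sd(pos)
  ps <- (pos - ctr) / scl
  fit <- lm(int ~ poly(ps, degree))
  grid <- seq(min(pos), max(pos), length.out = 2000)
  yv <- as.vector(predict(fit, newdata = data.frame(ps = (grid - ctr) / scl)))
  locmax <- which(diff(sign(diff(yv))) == -2) + 1L
  if (length(locmax) < 2)
    stop_synmorph("fewer than two local maxima in fitted profile",
                  "measurement_failure")
  best2 <- locmax[order(yv[locmax], decreasing = TRUE)[1:2]]
  # both retained maxima must be dominant peaks, not fit ripples
  y0 <- min(int)
  if ((yv[best2[2]] - y0) < 0.2 * (yv[best2[1]] - y0))
    stop_synmorph("second peak is not dominant (single-peak trace?)",
                  "measurement_failure")
  top2 <- sort(grid[best2])

  base <- min(int)
  refine <- function(px) {
    w <- which(abs(pos - px) <= refine_halfwidth)
    yi <- int[w] - base
    if (length(w) < 3 || any(yi <= 0)) return(px)
    q <- lm(log(yi) ~ pos[w] + I(pos[w]^2))
    cf <- coef(q)
    if (!is.finite(cf[3]) || cf[3] >= 0) return(px)
    v <- -cf[2] / (2 * cf[3])
    if (!is.finite(v) || abs(v - px) > refine_halfwidth) px else unname(v)
  }
  peaks <- vapply(top2, refine, numeric(1))
  structure(abs(diff(peaks)), peaks = peaks)
}

#' Summarize AZ-PSD distances into correction factors
#'
#' Averages distances per animal, defines the batch mean as the mean of its
#' member animals' means, normalizes raw distances to the batch mean, and
#' derives each animal's correction factor as animal mean / batch mean. The
#' correction factor divides downstream length-derived measurements (lengths
#' by the factor, areas by its square, volumes by its cube).
#'
#' @param distances data frame with columns `distance` (nm), `animal`,
#'   `batch`.
#' @return a list of class `expansion_summary` with elements `animals`
#'   (animal, batch, n, mean_distance, correction_factor), `batches`
#'   (batch, mean_distance), and `normalized` (the input with a
#'   `normalized_distance` column).
#' @export
summarize_expansion <- function(distances) {
  d <- data.frame(distance = as.numeric(distances$distance),
                  animal = as.character(distances$animal),
                  batch = as.character(distances$batch),
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0 || any(!is.finite(d$distance)))
    stop_synmorph("distances must be non-empty and finite", "invalid_data")
  if (any(table(d$animal) < 1))
    stop_synmorph("every animal needs at least one distance", "invalid_data")

  animals <- do.call(rbind, lapply(split(d, d$animal), function(s) {
    data.frame(animal = s$animal[1], batch = s$batch[1], n = nrow(s),
               mean_distance = mean(s$distance), stringsAsFactors = FALSE)
  }))
  rownames(animals) <- NULL
  batches <- do.call(rbind, lapply(split(animals, animals$batch), function(s) {
    data.frame(batch = s$batch[1], mean_distance = mean(s$mean_distance),
               stringsAsFactors = FALSE)
  }))
  rownames(batches) <- NULL
  animals$correction_factor <- animals$mean_distance /
    batches$mean_distance[match(animals$batch, batches$batch)]
  d$normalized_distance <- d$distance /
    batches$mean_distance[match(d$batch, batches$batch)]

  structure(list(animals = animals, batches = batches, normalized = d),
            class = "expansion_summary")
}

#' Macroscopic linear expansion factor
#'
#' Ratio of post- to pre-expansion line measurements of a photographed gel.
#'
#' @param pre,post lengths in the same unit, both strictly positive.
#' @return post / pre.
#' @export
macroscopic_expansion_factor <- function(pre, post) {
  check_positive(pre, "pre"); check_positive(post, "post")
  post / pre
}

#' Measure all profiles of a generated or imported set
#'
#' Applies [measure_az_psd()] to every trace, flags and drops traces where
#' peak detection fails.
#'
#' @param profiles list as returned by [gen_profiles()] (or any list with a
#'   `traces` data frame holding `profile_id`, `position`, `intensity`,
#'   `animal`, `batch`).
#' @param degree polynomial degree passed to [measure_az_psd()].
#' @return data frame with one row per successfully measured profile:
#'   `profile_id`, `animal`, `batch`, `distance`; failed profiles are
#'   reported in attribute `failed`.
#' @export
measure_profiles <- function(profiles, degree = 8) {
  tr <- profiles$traces
  ids <- unique(tr$profile_id)
  rows <- vector("list", length(ids)); failed <- character(0)
  for (i in seq_along(ids)) {
    s <- tr[tr$profile_id == ids[i], ]
    dst <- tryCatch(measure_az_psd(s[, c("position", "intensity")], degree = degree),
                    synmorph_error = function(e) NA_real_)
    if (is.na(dst)) { failed <- c(failed, ids[i]); next }
    rows[[i]] <- data.frame(profile_id = ids[i], animal = s$animal[1],
                            batch = s$batch[1], distance = as.numeric(dst),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}
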