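# Synthetic-data generator. Emulates the three input data kinds of the
# pipeline with known ground truth: (a) 1D line profiles across side-view
# synapses (two Gaussian peaks = AZ and PSD bands), (b) 3D probability maps
# of postsynaptic scaffolds drawn from a morphology continuum (small spheres
# -> ellipsoids -> lobed -> large perforated scaffolds), sampled on the
# anisotropic 43 x 43 x 120 nm voxel grid, and (c) per-synapse two-channel
# 2D STED mosaics at 25 nm pixels (CSR / Thomas-clustered / hard-core point
# processes, optionally cross-channel coupled at a fixed offset).
# Identical configuration (including seed) yields identical output.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [gen_profiles()], [gen_scaffolds()] and [gen_mosaics()]. Defaults encode
#' the study conditions: 43 x 43 x 120 nm confocal voxels, 25 nm STED
#' pixels, two monomer batches with mean AZ-PSD separations of 536.7 and
#' 510.4 nm, 3 animals per batch with 60 profiles each, and a six-class
#' scaffold morphology continuum.
#'
#' @param seed integer master seed; all generator randomness derives from it.
#' @param voxel_size confocal voxel size in nm (x, y, z).
#' @param sted_pixel_size STED pixel size in nm.
#' @param profiles,scaffolds,mosaics named lists overriding individual
#'   defaults of the respective generator (see the generator documentation).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, voxel_size = c(43, 43, 120),
                       sted_pixel_size = 25, profiles = list(),
                       scaffolds = list(), mosaics = list()) {
  check_positive(voxel_size, "voxel_size")
  check_positive(sted_pixel_size, "sted_pixel_size")

  prof <- utils::modifyList(list(
    batches = data.frame(batch = c("A", "B"),
                         separation = c(536.7, 510.4),
                         stringsAsFactors = FALSE),
    n_animals_per_batch = 3L,
    n_profiles_per_animal = 60L,
    animal_sd = 4,          # nm, animal-level spread of the true separation
    peak_sd = 30,           # nm, width of AZ / PSD bands
    amplitude = 100,
    baseline = 5,
    noise_sd = 2,           # additive Gaussian noise (2% of amplitude)
    step = voxel_size[1]    # sampling step along the line, nm
  ), profiles)
  if (!is.null(profiles$batches)) prof$batches <- profiles$batches
  if (any(!is.finite(prof$batches$separation)) || any(prof$batches$separation <= 0))
    stop_synmorph("profile peak separation must be strictly positive",
                  "invalid_config")
  if (any(prof$batches$separation <= 4 * prof$peak_sd))
    stop_synmorph("peak separation must exceed 4 x peak sd", "invalid_config")

  scaf <- utils::modifyList(list(
    n_objects = 80L,
    vol_dim = c(288L, 288L, 72L),
    classes = default_scaffold_classes(),
    border_fraction = 0.05,
    prob_fg = c(0.75, 0.98),   # probability values inside objects
    prob_bg = c(0, 0.08),      # background probability values
    margin_nm = 30,            # clearance between object bounding spheres
    max_retries = 200L
  ), scaffolds)
  # replace (not merge) structured fields supplied by the user
  if (!is.null(scaffolds$classes)) scaf$classes <- scaffolds$classes
  check_positive(scaf$vol_dim, "scaffolds$vol_dim")

  mos <- utils::modifyList(list(
    n_synapses = 12L,
    n_points = 40L,
    process = "csr",           # csr | thomas | hardcore
    thomas = list(n_parents = 5L, sd_nm = 60),
    hardcore_nm = 100,
    img_dim = c(64L, 64L),
    roi_semi_px = c(26, 20),
    psf_sd_px = 2,
    amplitude = 100,
    baseline = 2,
    poisson = TRUE,
    support_radius_px = 2,
    channel2 = list(mode = "independent", offset_nm = 50, fraction = 1,
                    n_points = 40L),
    max_retries = 5000L
  ), mosaics)
  if (mos$amplitude <= 0)
    stop_synmorph("mosaic spot amplitude must be positive", "invalid_config")

  structure(list(seed = as.integer(seed), voxel_size = voxel_size,
                 sted_pixel_size = sted_pixel_size, profiles = prof,
                 scaffolds = scaf, mosaics = mos),
            class = "sim_config")
}

#' Default scaffold morphology continuum
#'
#' Six template classes of increasing volume and complexity: two sphere
#' classes spanning the volume-exclusion threshold, an ellipsoid class, two
#' lobed classes (unions of offset ellipsoids) and a perforated class (a
#' flattened ellipsoid with holes), mirroring the continuum from small
#' spherical to large perforated postsynaptic scaffolds.
#'
#' @return list of class definitions used by [gen_scaffolds()].
#' @export
default_scaffold_classes <- function() {
  list(
    list(name = "sphere_small", type = "sphere", semi_nm = c(230, 230, 230),
         jitter = 0.10),
    list(name = "sphere_large", type = "sphere", semi_nm = c(340, 340, 340),
         jitter = 0.06),
    list(name = "ellipsoid", type = "ellipsoid", semi_nm = c(560, 340, 220),
         jitter = 0.06),
    list(name = "lobed2", type = "lobed", semi_nm = c(640, 420, 260),
         n_lobes = 2L, lobe_offset = 1.15, jitter = 0.06),
    list(name = "lobed3", type = "lobed", semi_nm = c(740, 500, 290),
         n_lobes = 3L, lobe_offset = 1.2, jitter = 0.06),
    list(name = "perforated", type = "perforated", semi_nm = c(900, 650, 300),
         n_holes = 3L, hole_frac = 0.45, jitter = 0.06)
  )
}

#' Generate synthetic AZ-PSD line profiles
#'
#' Each trace is the sum of two Gaussian peaks (the AZ and PSD bands) on a
#' constant baseline with additive Gaussian noise, sampled at the confocal
#' pixel pitch along the line. True separations are drawn per animal around
#' the batch mean.
#'
#' @param config a [sim_config()].
#' @return list with `traces` (long data frame: `profile_id`, `position`,
#'   `intensity`, `animal`, `batch`) and `truth` (one row per profile with
#'   the true peak separation and peak positions).
#' @export
gen_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$profiles
  set.seed(derive_seed(config$seed, 1L))

  traces <- list(); truth <- list(); id <- 0L
  for (b in seq_len(nrow(p$batches))) {
    batch <- p$batches$batch[b]; sep_b <- p$batches$separation[b]
    for (a in seq_len(p$n_animals_per_batch)) {
      animal <- sprintf("%s%d", batch, a)
      sep_a <- sep_b + rnorm(1, 0, p$animal_sd)
      line_len <- ceiling((sep_a + 700) / p$step) * p$step
      pos <- seq(0, line_len, by = p$step)
      for (j in seq_len(p$n_profiles_per_animal)) {
        id <- id + 1L
        ctr <- line_len / 2 + runif(1, -p$step / 2, p$step / 2)
        mu <- c(ctr - sep_a / 2, ctr + sep_a / 2)
        int <- p$baseline +
          p$amplitude * exp(-(pos - mu[1])^2 / (2 * p$peak_sd^2)) +
          p$amplitude * exp(-(pos - mu[2])^2 / (2 * p$peak_sd^2)) +
          rnorm(length(pos), 0, p$noise_sd)
        pid <- sprintf("prof_%04d", id)
        traces[[id]] <- data.frame(profile_id = pid, position = pos,
                                   intensity = int, animal = animal,
                                   batch = batch, stringsAsFactors = FALSE)
        truth[[id]] <- data.frame(profile_id = pid, animal = animal,
                                  batch = batch, true_separation = sep_a,
                                  peak1 = mu[1], peak2 = mu[2],
                                  stringsAsFactors = FALSE)
      }
    }
  }
  list(traces = do.call(rbind, traces), truth = do.call(rbind, truth))
}

# --- scaffold templates -----------------------------------------------------

# membership test of template `cls` (scaled by s, rotated by R, centered at 0)
# for points pts (n x 3, nm, already centered); returns logical
template_inside <- function(pts, cls, s, R) {
  q <- pts %*% R                    # rotate into template frame
  semi <- cls$semi_nm * s
  inside_ell <- function(q, c0, semi) {
    ((q[, 1] - c0[1]) / semi[1])^2 + ((q[, 2] - c0[2]) / semi[2])^2 +
      ((q[, 3] - c0[3]) / semi[3])^2 <= 1
  }
  if (cls$type %in% c("sphere", "ellipsoid")) {
    inside_ell(q, c(0, 0, 0), semi)
  } else if (cls$type == "lobed") {
    ins <- rep(FALSE, nrow(q))
    off <- cls$lobe_offset * semi[1]
    for (l in seq_len(cls$n_lobes)) {
      ang <- 2 * pi * (l - 1) / cls$n_lobes
      c0 <- c(cos(ang), sin(ang), 0) * off * 0.6
      ins <- ins | inside_ell(q, c0, semi * 0.75)
    }
    ins
  } else if (cls$type == "perforated") {
    ins <- inside_ell(q, c(0, 0, 0), semi)
    for (h in seq_len(cls$n_holes)) {
      ang <- 2 * pi * (h - 1) / cls$n_holes + pi / 5
      c0 <- c(cos(ang), sin(ang), 0) * semi[1] * 0.45
      hole <- semi * cls$hole_frac
      ins <- ins & !inside_ell(q, c0, c(hole[1], hole[2], semi[3] * 2))
    }
    ins
  } else stop_synmorph(paste("unknown template type:", cls$type),
                       "invalid_config")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform over rotations
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a synthetic scaffold probability map
#'
#' Places non-overlapping objects drawn from the morphology continuum into a
#' 3D volume in physical nm coordinates, samples them on the anisotropic
#' voxel grid, and emits a probability map (foreground voxels get high
#' probabilities, background low) together with per-object ground truth.
#' A configurable fraction of objects is deliberately placed across the
#' volume border.
#'
#' @param config a [sim_config()].
#' @return list with `volume` (3D array of probabilities in \[0,1\]),
#'   `truth` (object id, class, centroid in nm, voxel count, border flag)
#'   and `labels` (3D integer array of true object labels).
#' @export
gen_scaffolds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$scaffolds; vx <- config$voxel_size
  set.seed(derive_seed(config$seed, 2L))

  dm <- as.integer(sc$vol_dim)
  extent <- dm * vx
  n <- sc$n_objects
  cls_idx <- if (!is.null(sc$class_weights)) {
    sample(seq_along(sc$classes), n, replace = TRUE,
           prob = sc$class_weights)
  } else rep_len(seq_along(sc$classes), n)[sample.int(n)]
  border <- runif(n) < sc$border_fraction

  centers <- matrix(NA_real_, n, 3)
  radii <- numeric(n); scales <- numeric(n); rots <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- sc$classes[[cls_idx[i]]]
    s <- exp(rnorm(1, 0, cls$jitter %||% 0.1))
    Rbound <- max(cls$semi_nm) * s *
      (if (cls$type == "lobed") (0.6 * cls$lobe_offset + 0.75) else 1)
    ok <- FALSE
    for (try in seq_len(sc$max_retries)) {
      if (border[i]) {
        ctr <- runif(3, Rbound, extent - Rbound)
        ax <- sample.int(3, 1)
        ctr[ax] <- if (runif(1) < 0.5) runif(1, 0, 0.3 * Rbound) else
          extent[ax] - runif(1, 0, 0.3 * Rbound)
      } else {
        ctr <- runif(3, Rbound + sc$margin_nm, extent - Rbound - sc$margin_nm)
      }
      if (i == 1 || all(sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - ctr)^2)) >
                        Rbound + radii[seq_len(i - 1)] + sc$margin_nm)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop_synmorph(
      sprintf("could not place object %d without overlap after %d retries",
              i, sc$max_retries), "placement_error")
    centers[i, ] <- ctr; radii[i] <- Rbound; scales[i] <- s
    rots[[i]] <- random_rotation()
  }

  labels <- array(0L, dm)
  vol <- array(runif(prod(dm), sc$prob_bg[1], sc$prob_bg[2]), dm)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- sc$classes[[cls_idx[i]]]
    Rb <- radii[i]
    ir <- lapply(1:3, function(d) {
      lo <- max(1L, floor((centers[i, d] - Rb) / vx[d]))
      hi <- min(dm[d], ceiling((centers[i, d] + Rb) / vx[d]) + 1L)
      lo:hi
    })
    g <- as.matrix(expand.grid(x = ir[[1]], y = ir[[2]], z = ir[[3]]))
    pts <- sweep(sweep(g - 0.5, 2, vx, "*"), 2, centers[i, ], "-")
    ins <- template_inside(pts, cls, scales[i], rots[[i]])
    touches <- FALSE
    if (any(ins)) {
      gi <- g[ins, , drop = FALSE]
      lin <- gi[, 1] + (gi[, 2] - 1L) * dm[1] + (gi[, 3] - 1L) * dm[1] * dm[2]
      labels[lin] <- i
      vol[lin] <- runif(length(lin), sc$prob_fg[1], sc$prob_fg[2])
      touches <- any(gi == 1L) || any(sweep(gi, 2, dm, "==") )
    }
    truth[[i]] <- data.frame(
      object_id = i, class = cls$name, class_index = cls_idx[i],
      cx = centers[i, 1], cy = centers[i, 2], cz = centers[i, 3],
      scale = scales[i], voxel_count = sum(ins),
      border = touches, stringsAsFactors = FALSE)
  }
  list(volume = vol, labels = labels, truth = do.call(rbind, truth),
       voxel_size = vx)
}

# --- mosaics ----------------------------------------------------------------

inside_ellipse <- function(x, y, ctr, semi) {
  ((x - ctr[1]) / semi[1])^2 + ((y - ctr[2]) / semi[2])^2 <= 1
}

sample_in_ellipse <- function(n, ctr, semi) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 8
    x <- runif(m, ctr[1] - semi[1], ctr[1] + semi[1])
    y <- runif(m, ctr[2] - semi[2], ctr[2] + semi[2])
    keep <- inside_ellipse(x, y, ctr, semi)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

gen_points <- function(m, ctr_nm, semi_nm) {
  n <- m$n_points
  if (m$process == "csr") {
    sample_in_ellipse(n, ctr_nm, semi_nm)
  } else if (m$process == "thomas") {
    par <- sample_in_ellipse(m$thomas$n_parents, ctr_nm, semi_nm)
    pts <- matrix(NA_real_, 0, 2)
    while (nrow(pts) < n) {
      pid <- sample.int(nrow(par), n, replace = TRUE)
      cand <- par[pid, , drop = FALSE] + matrix(rnorm(2 * n, 0, m$thomas$sd_nm), n, 2)
      keep <- inside_ellipse(cand[, 1], cand[, 2], ctr_nm, semi_nm)
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    pts[seq_len(n), , drop = FALSE]
  } else if (m$process == "hardcore") {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < n) {
      tries <- tries + 1L
      if (tries > m$max_retries)
        stop_synmorph("hard-core pattern not placeable: too many points for radius",
                      "placement_error")
      cand <- sample_in_ellipse(1, ctr_nm, semi_nm)
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= m$hardcore_nm)
        pts <- rbind(pts, cand)
    }
    pts
  } else stop_synmorph(paste("unknown point process:", m$process),
                       "invalid_config")
}

render_spots <- function(pts_px, dm, amp, psf_sd, baseline) {
  img <- matrix(baseline, dm[1], dm[2])
  if (nrow(pts_px) == 0) return(img)
  xs <- matrix(rep(seq_len(dm[1]) - 0.5, dm[2]), dm[1], dm[2])
  ys <- matrix(rep(seq_len(dm[2]) - 0.5, each = dm[1]), dm[1], dm[2])
  for (i in seq_len(nrow(pts_px))) {
    img <- img + amp * exp(-((xs - pts_px[i, 1])^2 + (ys - pts_px[i, 2])^2) /
                             (2 * psf_sd^2))
  }
  img
}

#' Generate synthetic two-channel subsynaptic particle mosaics
#'
#' For each synapse, draws channel-1 particle coordinates from a chosen
#' point process (CSR, Thomas-clustered, or hard-core) inside an elliptical
#' ROI, generates channel-2 points either independently or paired to
#' channel-1 points at a fixed offset distance (random direction), renders
#' both channels as Gaussian spots with optional Poisson noise, and emits
#' ROI masks, labeled spot-support masks, true coordinates and the pairing
#' table.
#'
#' @param config a [sim_config()].
#' @return list with one element per synapse (`ch1`, `ch2`, `roi`,
#'   `support1`, `support2`, image matrices / masks), plus `truth` (long
#'   data frame of true coordinates in nm) and `pairs` (pairing table).
#' @export
gen_mosaics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$mosaics; px <- config$sted_pixel_size
  set.seed(derive_seed(config$seed, 3L))

  dm <- as.integer(m$img_dim)
  ctr_px <- dm / 2; semi_px <- m$roi_semi_px
  ctr_nm <- ctr_px * px; semi_nm <- semi_px * px

  xs <- matrix(rep(seq_len(dm[1]) - 0.5, dm[2]), dm[1], dm[2])
  ys <- matrix(rep(seq_len(dm[2]) - 0.5, each = dm[1]), dm[1], dm[2])
  roi <- inside_ellipse(xs, ys, ctr_px, semi_px)

  synapses <- vector("list", m$n_synapses)
  truth <- list(); pairs <- list()
  for (s in seq_len(m$n_synapses)) {
    p1 <- gen_points(m, ctr_nm, semi_nm)
    c2 <- m$channel2
    if (identical(c2$mode, "paired")) {
      n1 <- nrow(p1)
      is_paired <- runif(n1) < c2$fraction
      p2 <- matrix(NA_real_, 0, 2); pr <- list()
      for (i in which(is_paired)) {
        repeat {
          ang <- runif(1, 0, 2 * pi)
          cand <- p1[i, ] + c2$offset_nm * c(cos(ang), sin(ang))
          if (inside_ellipse(cand[1], cand[2], ctr_nm, semi_nm)) break
        }
        p2 <- rbind(p2, cand)
        pr[[length(pr) + 1L]] <- data.frame(synapse = s, id1 = i,
                                            id2 = nrow(p2),
                                            offset_nm = c2$offset_nm)
      }
      n_extra <- round((1 - c2$fraction) * (c2$n_points %||% n1))
      if (n_extra > 0) p2 <- rbind(p2, sample_in_ellipse(n_extra, ctr_nm, semi_nm))
      if (length(pr)) pairs[[length(pairs) + 1L]] <- do.call(rbind, pr)
    } else {
      p2 <- sample_in_ellipse(c2$n_points %||% m$n_points, ctr_nm, semi_nm)
    }

    render_one <- function(pts) {
      img <- render_spots(pts / px, dm, m$amplitude, m$psf_sd_px, m$baseline)
      if (isTRUE(m$poisson)) img <- matrix(rpois(length(img), img), dm[1], dm[2])
      img
    }
    support_mask <- function(pts) {
      lab <- matrix(0L, dm[1], dm[2])
      if (nrow(pts) == 0) return(lab)
      for (i in seq_len(nrow(pts))) {
        sel <- (xs - pts[i, 1] / px)^2 + (ys - pts[i, 2] / px)^2 <=
          m$support_radius_px^2
        lab[sel] <- i
      }
      lab
    }

    synapses[[s]] <- list(ch1 = render_one(p1), ch2 = render_one(p2),
                          roi = roi, support1 = support_mask(p1),
                          support2 = support_mask(p2), synapse = s)
    truth[[length(truth) + 1L]] <- rbind(
      data.frame(synapse = s, channel = 1L, id = seq_len(nrow(p1)),
                 x = p1[, 1], y = p1[, 2]),
      data.frame(synapse = s, channel = 2L, id = seq_len(nrow(p2)),
                 x = p2[, 1], y = p2[, 2]))
  }
  list(synapses = synapses, truth = do.call(rbind, truth),
       pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
       roi = roi, window = list(type = "ellipse", center = ctr_nm,
                                semi = semi_nm),
       pixel_size = px)
}
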