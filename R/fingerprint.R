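# Shape fingerprinting: log/center/scale embedding of the nine-feature
# records into the first three principal components, CLARA partitional
# clustering with Gap-statistic selection of the cluster number, cluster
# reordering into a running sequence (ascending medoid volume), and
# principal-curve pseudotime as an ordinal proxy for synaptic maturity.

#' Embed shape records into PC1-3
#'
#' Log-transforms each feature (with a per-feature offset epsilon = 1e-6 of
#' the feature's smallest positive value, so that exact zeros such as a
#' vanishing volume ratio stay finite), centers and scales to unit variance,
#' and projects onto the first three principal components. The stored
#' transform reproduces the scores exactly via [predict.shape_embedding()].
#'
#' @param records data frame holding the feature columns.
#' @param features feature column names (default: the nine shape features).
#' @param log_transform apply the log step (disable for data that is already
#'   on a symmetric scale).
#' @return object of class `shape_embedding` with `scores` (n x 3),
#'   `rotation`, `center`, `scale`, `eps` and `sdev` (all PC standard
#'   deviations).
#' @export
shape_embed <- function(records,
                        features = c("volume_nm3", "surface_nm2",
                                     "volume_ratio", "sphericity",
                                     "M1", "M2", "M3", "M4", "M5"),
                        log_transform = TRUE) {
  miss <- setdiff(features, colnames(records))
  if (length(miss))
    stop_synmorph(paste("missing feature column(s):",
                        paste(miss, collapse = ", ")), "invalid_data")
  x <- as.matrix(records[, features, drop = FALSE])
  if (nrow(x) < 10)
    stop_synmorph("need at least 10 records to embed", "invalid_data")

  eps <- rep(0, ncol(x))
  if (log_transform) {
    eps <- apply(x, 2, function(v) {
      pos <- v[v > 0]
      if (length(pos)) 1e-6 * min(pos) else 1e-6
    })
    x <- log(sweep(x, 2, eps, "+"))
  }
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  if (any(scl == 0))
    stop_synmorph(paste("zero-variance feature(s) after transform:",
                        paste(features[scl == 0], collapse = ", ")),
                  "zero_variance")
  z <- scale(x, center = ctr, scale = scl)
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  ncomp <- min(3L, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 center = ctr, scale = scl, eps = eps,
                 features = features, log_transform = log_transform,
                 sdev = pc$sdev),
            class = "shape_embedding")
}

#' @rdname shape_embed
#' @param object a `shape_embedding`.
#' @param newdata data frame with the original feature columns.
#' @param ... unused.
#' @export
predict.shape_embedding <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  if (object$log_transform) x <- log(sweep(x, 2, object$eps, "+"))
  z <- scale(x, center = object$center, scale = object$scale)
  z %*% object$rotation
}

clara_clustering <- function(x, k, samples = 50, sampsize = NULL) {
  if (k == 1) return(rep(1L, nrow(x)))
  ss <- min(nrow(x), sampsize %||% (40 + k))
  cluster::clara(x, k, metric = "euclidean", samples = samples,
                 sampsize = ss, pamLike = TRUE, rngR = TRUE)$clustering
}

#' Cluster an embedding with CLARA and Gap-statistic model selection
#'
#' Runs CLARA (repeated subsampled k-medoid search, 50 subsamples of size
#' 40 + k, best total dissimilarity kept) for each candidate k, computes the
#' Gap statistic against `gap_B` reference datasets drawn uniformly over the
#' PCA-aligned bounding box of the data, selects k by the firstSEmax rule,
#' and reorders the selected clusters into a running sequence of ascending
#' medoid volume.
#'
#' @param embedding a `shape_embedding` (or a plain score matrix).
#' @param volumes per-object volumes used to order clusters (ascending
#'   medoid volume); defaults to the first PC score.
#' @param k_range candidate cluster numbers (must satisfy n >= 2 * max k).
#' @param gap_B number of Gap reference datasets.
#' @param seed integer seed for the subsampling and reference draws.
#' @param samples number of CLARA subsamples.
#' @return object of class `cluster_model`: `k`, `clustering` (1..k, ordered
#'   labels), `medoids` (row indices into the data, in label order), `gap`
#'   (candidate k, gap value, SE), `order_map`.
#' @export
shape_cluster <- function(embedding, volumes = NULL, k_range = 1:10,
                          gap_B = 50, seed = NULL, samples = 50) {
  x <- if (inherits(embedding, "shape_embedding")) embedding$scores else
    as.matrix(embedding)
  n <- nrow(x); kmax <- max(k_range)
  if (n < 2 * kmax)
    stop_synmorph("need at least 2 x max(k_range) observations",
                  "invalid_data")
  if (!is.null(seed)) set.seed(seed)

  if (all(apply(x, 2, sd) == 0)) {
    # all points identical: one trivial cluster
    return(structure(list(k = 1L, clustering = rep(1L, n), medoids = 1L,
                          gap = data.frame(k = 1L, gap = NA_real_,
                                           SE = NA_real_),
                          order_map = 1L, seed = seed),
                     class = "cluster_model"))
  }

  gs <- cluster::clusGap(x, FUNcluster = function(x, k)
    list(cluster = clara_clustering(x, k, samples = samples)),
    K.max = kmax, B = gap_B, spaceH0 = "scaledPCA", verbose = FALSE)
  tab <- as.data.frame(gs$Tab)
  sel <- intersect(seq_len(kmax), k_range)
  k <- sel[cluster::maxSE(tab$gap[sel], tab$SE.sim[sel],
                          method = "firstSEmax")]

  if (k == 1) {
    clustering <- rep(1L, n)
    # medoid of the whole set: minimizer of summed distances (chunked)
    tot <- vapply(seq_len(n), function(i)
      sum(sqrt(colSums((t(x) - x[i, ])^2))), numeric(1))
    med <- which.min(tot)
  } else {
    cl <- cluster::clara(x, k, metric = "euclidean", samples = samples,
                         sampsize = min(n, 40 + k), pamLike = TRUE,
                         rngR = TRUE, medoids.x = FALSE)
    clustering <- cl$clustering
    med <- cl$i.med
  }

  ord_val <- if (is.null(volumes)) x[med, 1] else volumes[med]
  order_map <- order(ord_val)            # old label at new position
  relabel <- match(seq_len(k), order_map)  # old label -> new label
  structure(list(k = k, clustering = as.integer(relabel[clustering]),
                 medoids = med[order_map],
                 gap = data.frame(k = seq_len(kmax), gap = tab$gap,
                                  SE = tab$SE.sim),
                 order_map = order_map, seed = seed),
            class = "cluster_model")
}

# project points x (n x d) onto polyline P (m x d); returns arc-length
# position and squared distance of each projection
project_polyline <- function(x, P) {
  n <- nrow(x); m <- nrow(P)
  seg <- diff(P)                      # (m-1) x d
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, n); best_lam <- numeric(n)
  for (i in seq_len(m - 1)) {
    if (seglen[i] == 0) next
    v <- seg[i, ]
    w <- sweep(x, 2, P[i, ])
    t <- pmin(pmax((w %*% v) / sum(v^2), 0), 1)
    d2 <- rowSums((w - t %*% t(v))^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lam[upd] <- cum[i] + t[upd] * seglen[i]
  }
  list(lambda = best_lam, dist2 = best_d2)
}

#' Principal-curve pseudotime
#'
#' Fits a smooth principal curve through the embedding, initialized on the
#' polyline through the ordered cluster medoids and refined by iterating
#' project -> smooth-against-arc-length -> reproject until the mean squared
#' projection distance stabilizes. Each object's pseudotime is the
#' arc-length of its projection, oriented to increase with cluster order,
#' then centered and scaled to mean 0 / sd 1.
#'
#' @param embedding a `shape_embedding` (or score matrix).
#' @param model a `cluster_model` with ordered clusters.
#' @param span lowess span (fraction of points) of the coordinate smoother.
#' @param max_iter,tol iteration limit and relative-change tolerance; if not
#'   converged a warning is issued and the last iterate returned.
#' @param n_control number of polyline control points kept per iteration.
#' @return object of class `pseudotime_assignment`: `pseudotime` (centered,
#'   scaled), `lambda` (raw arc length), `curve` (control points),
#'   `converged`, `iterations`.
#' @export
shape_pseudotime <- function(embedding, model, span = 0.2, max_iter = 30,
                             tol = 1e-4, n_control = 100) {
  x <- if (inherits(embedding, "shape_embedding")) embedding$scores else
    as.matrix(embedding)
  P <- x[model$medoids, , drop = FALSE]
  if (nrow(P) < 2) P <- rbind(P, P + 1e-8)   # single cluster: degenerate seed

  prev <- Inf; converged <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    pr <- project_polyline(x, P)
    msd <- mean(pr$dist2)
    if (is.finite(prev) && abs(prev - msd) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE; break
    }
    prev <- msd
    ord <- order(pr$lambda)
    lam_s <- pr$lambda[ord]
    newP <- sapply(seq_len(ncol(x)), function(d)
      lowess(lam_s, x[ord, d], f = span)$y)
    keep <- unique(round(seq(1, nrow(newP), length.out = min(n_control, nrow(newP)))))
    P <- newP[keep, , drop = FALSE]
  }
  if (!converged) warning("principal curve did not converge; returning last iterate")

  pr <- project_polyline(x, P)
  lambda <- pr$lambda
  # orient along the cluster sequence
  if (stats::cor(lambda, model$clustering, method = "spearman") < 0)
    lambda <- max(lambda) - lambda
  ps <- as.numeric(scale(lambda))
  structure(list(pseudotime = ps, lambda = lambda, curve = P,
                 converged = converged, iterations = it),
            class = "pseudotime_assignment")
}

#' Cluster-composition contingency table
#'
#' Cross-tabulates cluster identities against group labels, retaining empty
#' clusters as zero cells, and derives per-group proportions (columns sum
#' to 1).
#'
#' @param cluster_id integer cluster labels in 1..k.
#' @param group group labels (genotype, brain region, ...), one per object.
#' @param k total number of clusters (defaults to `max(cluster_id)`).
#' @return list with `counts` (k x groups) and `proportions`.
#' @export
composition_table <- function(cluster_id, group, k = max(cluster_id)) {
  if (length(cluster_id) != length(group))
    stop_synmorph("cluster_id and group must have equal length", "invalid_data")
  if (any(is.na(group)) || any(is.na(cluster_id)))
    stop_synmorph("unknown (missing) label", "invalid_label")
  cl <- factor(cluster_id, levels = seq_len(k))
  counts <- table(cluster = cl, group = factor(group))
  props <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  list(counts = unclass(counts), proportions = unclass(props))
}
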