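#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm predict coef prcomp sd var quantile rnorm runif rpois
#'   pnorm pchisq p.adjust chisq.test wilcox.test aov lowess cor dist rbinom
#'   setNames complete.cases poly
#' @importFrom utils head read.csv write.csv
NULL

# condition helper: all package errors carry a class so callers can test for them
stop_synmorph <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "synmorph_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_synmorph(sprintf("'%s' must be strictly positive and finite", name),
                  "invalid_config")
  }
  invisible(x)
}

# separable Gaussian smoothing of a 2D matrix (replicate-edge padding)
gauss_kernel <- function(sigma) {
  k <- max(1L, ceiling(3 * sigma))
  x <- (-k):k
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  w <- gauss_kernel(sigma)
  k <- (length(w) - 1L) / 2L
  sm_dim <- function(a, d) {
    n <- dim(a)[d]
    out <- array(0, dim(a))
    for (i in seq_along(w)) {
      idx <- pmin(pmax(seq_len(n) + (i - k - 1L), 1L), n)
      out <- out + w[i] * (if (d == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE])
    }
    out
  }
  sm_dim(sm_dim(m, 1L), 2L)
}

# separable Gaussian smoothing of a 3D array; sigma per axis in voxel units
smooth3d <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  dm <- dim(a)
  for (d in 1:3) {
    if (sigma[d] <= 0) next
    w <- gauss_kernel(sigma[d])
    k <- (length(w) - 1L) / 2L
    out <- array(0, dm)
    for (i in seq_along(w)) {
      idx <- pmin(pmax(seq_len(dm[d]) + (i - k - 1L), 1L), dm[d])
      out <- out + w[i] * switch(d,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    a <- out
  }
  a
}

# deterministic per-task seed derived from a master seed, kept inside .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587L) + 1L
}
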