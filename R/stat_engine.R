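# Statistical layer: chi-square composition tests with residual post-hocs,
# semi-parametric MANOVA via the modified ANOVA-type statistic (MATS) with a
# parametric bootstrap, mixed-design repeated-measures ANOVA, rank-sum tests,
# and multiplicity corrections. Every test returns a "synmorph_test" object
# with statistic, p-value and (where requested) a post-hoc table.

new_test_result <- function(statistic, p_value, df = NA_real_, posthoc = NULL,
                            alpha = 0.05, method = "", meta = list()) {
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 posthoc = posthoc, alpha = alpha, method = method,
                 meta = meta),
            class = "synmorph_test")
}

#' @export
print.synmorph_test <- function(x, ...) {
  cat(x$method, "\n")
  st <- x$statistic
  cat(sprintf("  %s = %.4g", names(st)[1], st[[1]]))
  if (!is.na(x$df[1])) cat(sprintf(", df = %s", paste(x$df, collapse = ", ")))
  cat(sprintf(", p = %.4g (alpha = %g)\n", x$p_value, x$alpha))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc:\n")
    print(head(x$posthoc, 12), row.names = FALSE)
  }
  invisible(x)
}

#' Multiplicity correction
#'
#' Bonferroni or Benjamini-Hochberg adjustment of a vector of p-values,
#' capped at 1 and monotone in the usual step-up/step-down sense.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"BH"`.
#' @param m number of tests (defaults to `length(p)`).
#' @return adjusted p-values, same length as `p`.
#' @export
adjust_p <- function(p, method = c("bonferroni", "BH"), m = length(p)) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_synmorph("p-values must lie in [0, 1]", "invalid_pvalues")
  }
  p.adjust(p, method = if (method == "BH") "BH" else "bonferroni", n = m)
}

#' Chi-square test of independence with residual post-hocs
#'
#' Pearson chi-square test (no continuity correction) on a k x g contingency
#' table, with per-cell standardized residuals, their two-sided normal
#' p-values Bonferroni-corrected over all cells, and optionally pairwise
#' column (group) tests with Bonferroni correction.
#'
#' @param table non-negative integer matrix, at least 2 x 2.
#' @param pairwise if `TRUE`, additionally run chi-square tests on every pair
#'   of columns, Bonferroni-corrected across pairs.
#' @param alpha significance level recorded in the result.
#' @return a `synmorph_test`; `$posthoc` holds the cell-residual table, and
#'   `$meta$pairwise` the pairwise column tests if requested.
#' @export
chisq_independence <- function(table, pairwise = FALSE, alpha = 0.05) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop_synmorph("contingency table must be at least 2 x 2", "invalid_table")
  if (any(table < 0) || any(abs(table - round(table)) > 1e-8))
    stop_synmorph("contingency table must hold non-negative counts", "invalid_table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_synmorph("contingency table has a zero marginal", "zero_marginal")

  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  stdres <- ht$stdres     # (O - E) / sqrt(E (1 - row prop)(1 - col prop))
  p_cell <- 2 * pnorm(-abs(stdres))
  p_cell_adj <- pmin(p_cell * length(table), 1)
  cells <- data.frame(
    row = rep(rownames(table) %||% seq_len(nrow(table)), ncol(table)),
    col = rep(colnames(table) %||% seq_len(ncol(table)), each = nrow(table)),
    observed = as.vector(table), expected = as.vector(ht$expected),
    std_residual = as.vector(stdres),
    p_raw = as.vector(p_cell), p_adj = as.vector(p_cell_adj),
    stringsAsFactors = FALSE)
  cells$adjustment <- "bonferroni"

  meta <- list()
  if (pairwise) {
    cols <- colnames(table) %||% as.character(seq_len(ncol(table)))
    prs <- utils::combn(ncol(table), 2)
    pw <- data.frame(
      comparison = apply(prs, 2, function(j) paste(cols[j], collapse = " vs ")),
      statistic = NA_real_, df = NA_real_, p_raw = NA_real_,
      stringsAsFactors = FALSE)
    for (i in seq_len(ncol(prs))) {
      h <- suppressWarnings(chisq.test(table[, prs[, i]], correct = FALSE))
      pw$statistic[i] <- unname(h$statistic)
      pw$df[i] <- unname(h$parameter)
      pw$p_raw[i] <- h$p.value
    }
    pw$p_adj <- adjust_p(pw$p_raw, "bonferroni")
    pw$adjustment <- "bonferroni"
    meta$pairwise <- pw
  }

  new_test_result(c("X-squared" = unname(ht$statistic)), ht$p.value,
                  df = unname(ht$parameter), posthoc = cells, alpha = alpha,
                  method = "Pearson chi-square test of independence",
                  meta = meta)
}

# MATS statistic for grouped multivariate data.
# means: a x p matrix of group means; covs: list of a p x p covariances;
# n: group sizes. Q = N (C ybar)' (C D C')^{-1} (C ybar) with C = H (x) I_p,
# H = [I_{a-1}, -1] the full-rank contrast for equal group means, and D the
# diagonal of N * blockdiag(S_i / n_i). The full-rank contrast form equals
# the projection form and is exactly invariant under per-variable rescaling.
mats_statistic <- function(means, covs, n) {
  a <- nrow(means); p <- ncol(means); N <- sum(n)
  ybar <- as.vector(t(means))                       # group-major stacking
  dvec <- unlist(lapply(seq_len(a), function(i) N * diag(covs[[i]]) / n[i]))
  H <- cbind(diag(a - 1), -1)
  Cm <- kronecker(H, diag(p))
  Cy <- Cm %*% ybar
  M <- Cm %*% (dvec * t(Cm))                        # C D C'
  drop(N * crossprod(Cy, solve(M, Cy)))
}

group_stats <- function(x, g) {
  lv <- levels(g)
  means <- do.call(rbind, lapply(lv, function(l)
    colMeans(x[g == l, , drop = FALSE])))
  covs <- lapply(lv, function(l) {
    xi <- x[g == l, , drop = FALSE]
    stats::cov(xi)
  })
  n <- as.vector(table(g))
  list(means = means, covs = covs, n = n)
}

#' Semi-parametric one-way MANOVA (modified ANOVA-type statistic)
#'
#' Multi-group comparison of multivariate means without assuming multivariate
#' normality or covariance homogeneity. The test statistic is the modified
#' ANOVA-type statistic (MATS)
#' \deqn{Q_N = N \bar y^\top T (T \hat D_N T)^+ T \bar y}
#' where \eqn{\bar y} stacks the group mean vectors, \eqn{T} is the
#' projection onto the contrast space of "all group means equal", and
#' \eqn{\hat D_N} is the diagonal of the estimated covariance of
#' \eqn{\sqrt N \bar y}. The p-value comes from a parametric bootstrap: each
#' replicate draws group-wise samples from centered multivariate normals with
#' the groups' empirical covariance matrices and recomputes the statistic.
#'
#' @param data numeric matrix or data frame (observations x variables).
#' @param groups factor (or coercible) of group labels, one per row.
#' @param B number of bootstrap replicates (default 999).
#' @param seed optional integer seed for the bootstrap.
#' @param exclude character vector of variable names to drop before testing
#'   (e.g. moment invariants that duplicate information in another moment).
#' @param posthoc if `TRUE`, univariate pairwise group comparisons per
#'   variable (two-group MATS, i.e. Welch-type t squared, with its own
#'   parametric bootstrap) Bonferroni-corrected across comparisons.
#' @param alpha significance level recorded in the result.
#' @return a `synmorph_test` with the MATS value, bootstrap p-value, and an
#'   optional post-hoc table.
#' @export
mats_manova <- function(data, groups, B = 999, seed = NULL, exclude = NULL,
                        posthoc = FALSE, alpha = 0.05) {
  x <- as.matrix(data)
  if (!is.null(exclude)) {
    keep <- setdiff(colnames(x), exclude)
    x <- x[, keep, drop = FALSE]
  }
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2)
    stop_synmorph("need at least two groups", "invalid_groups")
  if (any(table(g) < 2))
    stop_synmorph("need at least two observations per group", "invalid_groups")
  if (ncol(x) < 1) stop_synmorph("no variables left to test", "invalid_data")

  gs <- group_stats(x, g)
  zero_var <- which(vapply(gs$covs, function(S) any(diag(S) <= 0), logical(1)))
  if (length(zero_var)) {
    bad <- unique(unlist(lapply(gs$covs, function(S) colnames(x)[diag(S) <= 0])))
    stop_synmorph(paste0("zero-variance variable(s): ",
                         paste(bad, collapse = ", ")), "zero_variance")
  }
  # the statistic is exactly scale-invariant; standardize per variable for
  # numerical conditioning (features span many orders of magnitude)
  x <- scale(x, center = FALSE, scale = apply(x, 2, sd))
  gs <- group_stats(x, g)
  Q <- mats_statistic(gs$means, gs$covs, gs$n)

  if (!is.null(seed)) set.seed(seed)
  chols <- lapply(gs$covs, chol)
  p <- ncol(x); a <- nlevels(g)
  Qboot <- vapply(seq_len(B), function(b) {
    means_b <- matrix(0, a, p)
    covs_b <- vector("list", a)
    for (i in seq_len(a)) {
      zi <- matrix(rnorm(gs$n[i] * p), gs$n[i], p) %*% chols[[i]]
      means_b[i, ] <- colMeans(zi)
      covs_b[[i]] <- stats::cov(zi)
    }
    mats_statistic(means_b, covs_b, gs$n)
  }, numeric(1))
  pval <- mean(Qboot >= Q)

  ph <- NULL
  if (posthoc) {
    lv <- levels(g); prs <- utils::combn(length(lv), 2)
    rows <- list()
    for (j in seq_len(p)) for (i in seq_len(ncol(prs))) {
      g1 <- lv[prs[1, i]]; g2 <- lv[prs[2, i]]
      x1 <- x[g == g1, j]; x2 <- x[g == g2, j]
      m <- c(mean(x1), mean(x2)); v <- c(var(x1), var(x2)); nn <- c(length(x1), length(x2))
      q <- (m[1] - m[2])^2 / (v[1] / nn[1] + v[2] / nn[2])
      qb <- vapply(seq_len(B), function(b) {
        z1 <- rnorm(nn[1], 0, sqrt(v[1])); z2 <- rnorm(nn[2], 0, sqrt(v[2]))
        (mean(z1) - mean(z2))^2 / (var(z1) / nn[1] + var(z2) / nn[2])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = colnames(x)[j] %||% as.character(j),
        comparison = paste(g1, "vs", g2),
        statistic = q, p_raw = mean(qb >= q), stringsAsFactors = FALSE)
    }
    ph <- do.call(rbind, rows)
    ph$p_adj <- adjust_p(ph$p_raw, "bonferroni")
    ph$adjustment <- "bonferroni"
  }

  new_test_result(c(MATS = Q), pval, posthoc = ph, alpha = alpha,
                  method = "Semi-parametric one-way MANOVA (MATS, parametric bootstrap)",
                  meta = list(B = B, seed = seed,
                              variables = colnames(x), groups = levels(g)))
}

#' Mixed-design (repeated-measures) ANOVA
#'
#' One between-subject factor (group) and one within-subject factor (e.g.
#' neighbour rank k), balanced within subjects. Reports the F test for the
#' between-group effect from the subject stratum, and per-level pairwise
#' group comparisons with Benjamini-Hochberg correction.
#'
#' @param data data frame in long format.
#' @param subject,within,group,value column names in `data`.
#' @param posthoc if `TRUE`, per within-level pairwise Welch t-tests between
#'   groups, BH-adjusted across all comparisons.
#' @param alpha significance level recorded in the result.
#' @return a `synmorph_test` with the group F statistic and p-value.
#' @export
rm_anova <- function(data, subject = "subject", within = "within",
                     group = "group", value = "value", posthoc = TRUE,
                     alpha = 0.05) {
  d <- data.frame(subject = as.factor(data[[subject]]),
                  within = as.factor(data[[within]]),
                  group = as.factor(data[[group]]),
                  value = as.numeric(data[[value]]))
  # drop subjects missing any within level
  tab <- table(d$subject, d$within)
  complete <- rownames(tab)[apply(tab > 0, 1, all)]
  if (length(complete) < nlevels(d$subject)) {
    warning(sprintf("dropping %d subject(s) with missing within-levels",
                    nlevels(d$subject) - length(complete)))
    d <- droplevels(d[d$subject %in% complete, ])
  }
  if (nlevels(d$group) < 2)
    stop_synmorph("fewer than two groups with complete within-levels",
                  "invalid_groups")

  fit <- aov(value ~ group * within + Error(subject / within), data = d)
  s <- summary(fit)
  # between-group effect lives in the subject stratum
  subj_tab <- s[["Error: subject"]][[1]]
  i <- grep("^group", trimws(rownames(subj_tab)))[1]
  Fv <- subj_tab[i, "F value"]; pv <- subj_tab[i, "Pr(>F)"]
  df <- c(subj_tab[i, "Df"], subj_tab[nrow(subj_tab), "Df"])

  ph <- NULL
  if (posthoc && nlevels(d$group) >= 2) {
    lv <- levels(d$group); prs <- utils::combn(length(lv), 2)
    rows <- list()
    for (k in levels(d$within)) for (i2 in seq_len(ncol(prs))) {
      x1 <- d$value[d$within == k & d$group == lv[prs[1, i2]]]
      x2 <- d$value[d$within == k & d$group == lv[prs[2, i2]]]
      pr <- if (sd(c(x1, x2)) == 0) 1 else
        tryCatch(stats::t.test(x1, x2)$p.value, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        within = k, comparison = paste(lv[prs[, i2]], collapse = " vs "),
        p_raw = pr, stringsAsFactors = FALSE)
    }
    ph <- do.call(rbind, rows)
    ph$p_adj <- adjust_p(ph$p_raw, "BH")
    ph$adjustment <- "BH"
  }

  new_test_result(c("F" = unname(Fv)), unname(pv), df = df, posthoc = ph,
                  alpha = alpha,
                  method = "Mixed-design repeated-measures ANOVA (between-group effect)")
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact p-value for small samples without ties, normal approximation with
#' tie correction otherwise (the standard behaviour of [stats::wilcox.test]).
#'
#' @param x,y numeric samples.
#' @param alpha significance level recorded in the result.
#' @return a `synmorph_test` with the rank-sum statistic W and p-value.
#' @export
rank_sum <- function(x, y, alpha = 0.05) {
  if (length(x) < 1 || length(y) < 1)
    stop_synmorph("both samples must be non-empty", "invalid_data")
  ht <- suppressWarnings(wilcox.test(x, y))
  new_test_result(c(W = unname(ht$statistic)), min(ht$p.value, 1),
                  alpha = alpha, method = "Two-sample Wilcoxon rank-sum test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
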