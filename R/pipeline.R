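# End-to-end orchestration: simulate -> expansion QC -> scaffold shapes ->
# fingerprint -> particles -> statistics, with plain-text outputs, filter
# accounting and a reproducible run directory. TIFF and CSV round-trip
# helpers live here as well.

#' Read / write multi-page TIFF stacks
#'
#' 16-bit grayscale multi-page TIFF I/O. `write_stack` stores a 3D array
#' (or list of matrices) of non-negative integers; `read_stack` returns the
#' identical integer array.
#'
#' @param x 3D integer array (x, y, slice) or list of matrices, values in
#'   0..65535.
#' @param path file path.
#' @return `read_stack`: 3D integer array with the stored values.
#' @export
write_stack <- function(x, path) {
  if (is.list(x)) x <- simplify2array(x)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  if (min(x) < 0 || max(x) > 65535)
    stop_synmorph("stack values must lie in 0..65535", "format_error")
  pages <- lapply(seq_len(dim(x)[3]), function(i) x[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop_synmorph(
                      sprintf("cannot read TIFF '%s': %s", path,
                              conditionMessage(e)), "format_error"))
  if (is.matrix(pages)) pages <- list(pages)
  simplify2array(pages)
}

#' Read / write analysis tables
#'
#' CSV round-trip helpers: numeric columns are written with 17 significant
#' digits so that write -> read reproduces values exactly.
#'
#' @param x data frame.
#' @param path file path.
#' @return `read_table_csv`: the data frame.
#' @export
write_table_csv <- function(x, path) {
  y <- as.data.frame(x)
  for (j in seq_along(y)) {
    if (is.numeric(y[[j]]) && !is.integer(y[[j]]))
      y[[j]] <- sprintf("%.17g", y[[j]])
  }
  write.csv(y, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Default end-to-end run configuration
#'
#' Problem sizes are deliberately modest (a demonstration run finishes in
#' about a minute); all thresholds carry the pipeline defaults: probability
#' cutoff 0.2 (confocal) / 0.5 (STED), 200-voxel volume exclusion, 10 px
#' rolling ball, 500 nm Ripley radius, alpha 0.01 for the shape MANOVA and
#' 0.05 for the particle analyses.
#'
#' @param seed master seed (required; every stochastic stage derives its
#'   seed from it).
#' @return a named list, the `config` argument of [run_pipeline()].
#' @export
default_run_config <- function(seed) {
  list(
    seed = seed,
    genotypes = c("WT", "KO"),
    regions = c("STR", "SENS"),
    n_objects = 60,                 # scaffolds per condition
    prob_cutoff = 0.2,
    volume_threshold = volume_exclusion_threshold()$threshold,
    k_range = 1:8,
    gap_B = 25,
    n_synapses = 8,                 # mosaics per genotype
    n_points = 30,                  # true particles per synapse
    hardcore_nm = 140,              # WT: ordered (hard-core) mosaic
    nnd_K = 6,
    r_max = 500,
    mats_B = 199,
    alpha_shape = 0.01,
    alpha_particles = 0.05,
    # KO scaffolds shift toward the small/spherical end of the continuum
    class_weights = list(WT = c(1, 1, 1.2, 1.2, 1.2, 1.2),
                         KO = c(1.6, 1.6, 1.2, 0.8, 0.6, 0.5))
  )
}

#' Run the full synthetic-data pipeline
#'
#' Executes all stages in dependency order on generated data: AZ-PSD
#' profile QC, scaffold segmentation and shape features, PCA / CLARA /
#' pseudotime fingerprinting with composition statistics, particle and
#' point-pattern analysis, and the statistical layer. Writes CSV tables, a
#' log with filter accounting, a config snapshot and a plain-text report to
#' `out_dir`. Reruns with the same configuration produce byte-identical
#' numeric tables.
#'
#' @param out_dir output directory (created if needed).
#' @param config list from [default_run_config()].
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, config) {
  if (is.null(config$seed))
    stop_synmorph("config must provide a seed for the stochastic stages",
                  "invalid_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  cat("", file = logf)
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  writeLines(deparse(config), file.path(out_dir, "config.txt"))

  ## stage 1: expansion QC ---------------------------------------------------
  cfg_prof <- sim_config(seed = config$seed)
  prof <- gen_profiles(cfg_prof)
  dist_tab <- measure_profiles(prof)
  qc <- summarize_expansion(dist_tab)
  write_table_csv(dist_tab, file.path(out_dir, "azpsd_distances.csv"))
  write_table_csv(qc$animals, file.path(out_dir, "expansion_summary.csv"))
  batch_test <- rank_sum(dist_tab$distance[dist_tab$batch == qc$batches$batch[1]],
                         dist_tab$distance[dist_tab$batch == qc$batches$batch[2]])
  log_line("expansion QC: %d profiles measured, %d failed",
           nrow(dist_tab), length(attr(dist_tab, "failed")))
  cf <- setNames(qc$animals$correction_factor, qc$animals$animal)

  ## stage 2: scaffold shapes ------------------------------------------------
  conditions <- expand.grid(genotype = config$genotypes,
                            region = config$regions,
                            stringsAsFactors = FALSE)
  records <- list()
  for (i in seq_len(nrow(conditions))) {
    gt <- conditions$genotype[i]; rg <- conditions$region[i]
    animal <- qc$animals$animal[(i - 1) %% nrow(qc$animals) + 1]
    ccfg <- sim_config(seed = derive_seed(config$seed, 100 + i),
                       scaffolds = list(n_objects = config$n_objects,
                                        class_weights = config$class_weights[[gt]]))
    sc <- gen_scaffolds(ccfg)
    mask <- threshold_probability(sc$volume, config$prob_cutoff)
    seg <- segment_objects(mask)
    tab <- scaffold_shape_table(seg, voxel_size = ccfg$voxel_size,
                                correction_factor = unname(cf[animal]),
                                metadata = list(genotype = gt, region = rg,
                                                animal = animal))
    n_border <- attr(tab, "n_border_excluded")
    tab <- volume_filter(tab, config$volume_threshold)
    n_vol <- attr(tab, "n_volume_excluded")
    log_line("scaffolds %s/%s: %d objects in = %d border + %d volume + %d analyzed",
             gt, rg, length(seg$objects), n_border, n_vol, nrow(tab))
    stopifnot(length(seg$objects) == n_border + n_vol + nrow(tab))
    records[[i]] <- tab
  }
  records <- do.call(rbind, records)
  write_table_csv(records, file.path(out_dir, "shape_records.csv"))

  ## stage 3: fingerprint ----------------------------------------------------
  emb <- shape_embed(records)
  cl <- shape_cluster(emb, volumes = records$volume_nm3,
                      k_range = config$k_range, gap_B = config$gap_B,
                      seed = derive_seed(config$seed, 200))
  pt <- shape_pseudotime(emb, cl)
  scores <- data.frame(emb$scores, cluster = cl$clustering,
                       pseudotime = pt$pseudotime,
                       genotype = records$genotype, region = records$region)
  write_table_csv(scores, file.path(out_dir, "fingerprint_scores.csv"))
  write_table_csv(cl$gap, file.path(out_dir, "gap_curve.csv"))

  comp <- composition_table(cl$clustering, records$genotype, k = cl$k)
  chisq <- chisq_independence(comp$counts, alpha = config$alpha_shape)
  feat <- cbind(records[, c("volume_nm3", "surface_nm2", "volume_ratio",
                            "sphericity", "M1", "M2", "M3", "M4", "M5")],
                pseudotime = pt$pseudotime)
  manova <- mats_manova(feat, records$genotype, B = config$mats_B,
                        seed = derive_seed(config$seed, 201),
                        exclude = c("M2", "M3", "M4"),
                        alpha = config$alpha_shape)
  log_line("fingerprint: k = %d selected; chi-square X2 = %.3f; MATS = %.3f",
           cl$k, chisq$statistic, manova$statistic)

  ## stage 4: particles ------------------------------------------------------
  part_rows <- list(); nnd_rows <- list(); dev_rows <- list(); ov_rows <- list()
  for (gt in config$genotypes) {
    mcfg <- sim_config(seed = derive_seed(config$seed,
                                          300 + match(gt, config$genotypes)),
                       mosaics = list(
                         n_synapses = config$n_synapses,
                         n_points = config$n_points,
                         process = if (gt == "WT") "hardcore" else "csr",
                         hardcore_nm = config$hardcore_nm,
                         channel2 = list(mode = "paired",
                                         offset_nm = if (gt == "WT") 50 else 80,
                                         fraction = 1)))
    mos <- gen_mosaics(mcfg)
    for (s in seq_along(mos$synapses)) {
      syn <- mos$synapses[[s]]
      pat1 <- detect_particles(syn$ch1, syn$roi, pixel_size = mos$pixel_size)
      pat2 <- detect_particles(syn$ch2, syn$roi, pixel_size = mos$pixel_size)
      sm <- particle_summary(pat1)
      sm$genotype <- gt; sm$synapse <- paste0(gt, "_", s)
      mm <- manders(syn$ch1, syn$ch2, pat1$labels, pat2$labels)
      sm$M1 <- mm[["M1"]]; sm$M2 <- mm[["M2"]]
      part_rows[[length(part_rows) + 1L]] <- sm
      if (nrow(pat1$points) > config$nnd_K) {
        nn <- nnd_profile(pat1, K = config$nnd_K)
        nnd_rows[[length(nnd_rows) + 1L]] <-
          data.frame(synapse = sm$synapse, genotype = gt, nn)
      }
      if (nrow(pat1$points) > 2) {
        rp <- ripley_csr(pat1, mos$window, r_max = config$r_max)
        dev_rows[[length(dev_rows) + 1L]] <-
          data.frame(synapse = sm$synapse, genotype = gt,
                     deviation = rp$deviation)
      }
      ov <- overlap_pair_distances(pat1$labels, pat2$labels,
                                   pixel_size = mos$pixel_size)
      if (!attr(ov, "flagged"))
        ov_rows[[length(ov_rows) + 1L]] <-
          data.frame(synapse = sm$synapse, genotype = gt,
                     mean_pair_nm = ov$mean_distance)
    }
  }
  particles <- do.call(rbind, part_rows)
  nnd_tab <- do.call(rbind, nnd_rows)
  dev_tab <- do.call(rbind, dev_rows)
  ov_tab <- do.call(rbind, ov_rows)
  write_table_csv(particles, file.path(out_dir, "particles.csv"))
  write_table_csv(nnd_tab, file.path(out_dir, "nnd.csv"))
  write_table_csv(dev_tab, file.path(out_dir, "csr_deviation.csv"))
  write_table_csv(ov_tab, file.path(out_dir, "overlap_pairs.csv"))
  log_line("particles: %d synapses analyzed", nrow(particles))

  ## stage 5: particle statistics -------------------------------------------
  basic_vars <- c("mean_area_nm2", "mean_total_int", "mean_avg_int",
                  "density_per_nm2")
  ok <- !particles$flagged & complete.cases(particles[, basic_vars])
  basic_scaled <- scale(particles[ok, basic_vars])
  part_manova <- mats_manova(basic_scaled, particles$genotype[ok],
                             B = config$mats_B,
                             seed = derive_seed(config$seed, 400),
                             alpha = config$alpha_particles)
  nnd_test <- rm_anova(nnd_tab, subject = "synapse", within = "k",
                       group = "genotype", value = "mean_nnd",
                       alpha = config$alpha_particles)
  dev_test <- rank_sum(dev_tab$deviation[dev_tab$genotype == config$genotypes[1]],
                       dev_tab$deviation[dev_tab$genotype == config$genotypes[2]],
                       alpha = config$alpha_particles)

  ## report ------------------------------------------------------------------
  rep_path <- file.path(out_dir, "report.txt")
  con <- file(rep_path, "w")
  w <- function(...) writeLines(sprintf(...), con)
  w("synmorph pipeline report (seed %d)", config$seed)
  w("")
  w("[expansion QC] batches: %s",
    paste(sprintf("%s = %.1f nm", qc$batches$batch, qc$batches$mean_distance),
          collapse = ", "))
  w("[expansion QC] batch comparison rank-sum: W = %g, p = %.4g",
    batch_test$statistic, batch_test$p_value)
  w("[fingerprint] selected k = %d clusters", cl$k)
  w("[fingerprint] cluster composition chi-square: X2 = %.3f, df = %d, p = %.4g",
    chisq$statistic, chisq$df, chisq$p_value)
  w("[fingerprint] shape MANOVA: MATS = %.3f, p = %.4g (alpha %.2g)",
    manova$statistic, manova$p_value, config$alpha_shape)
  w("[particles] basic-property MANOVA: MATS = %.3f, p = %.4g",
    part_manova$statistic, part_manova$p_value)
  w("[particles] NND RM-ANOVA group effect: F = %.3f, p = %.4g",
    nnd_test$statistic, nnd_test$p_value)
  w("[particles] CSR-deviation rank-sum: W = %g, p = %.4g",
    dev_test$statistic, dev_test$p_value)
  close(con)

  invisible(list(qc = qc, records = records, cluster = cl, pseudotime = pt,
                 composition = comp, chisq = chisq, manova = manova,
                 particles = particles, nnd = nnd_tab,
                 nnd_test = nnd_test, dev_test = dev_test,
                 part_manova = part_manova, batch_test = batch_test))
}
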