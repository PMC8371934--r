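# Reproducible simulation studies used to calibrate and validate the
# estimators: EM-vs-grid recombination agreement, sliding-window error
# correction efficiency, permutation-threshold type-I error, and QTL
# parameter recovery. These run at desk scale (minutes on one CPU) and
# are exercised by the test suite and the acceptance script.

#' EM vs grid-search agreement on random two-locus tables
#'
#' Draws random F2 two-locus class-count tables (r uniform in
#' (0.01, 0.49), n individuals 50-200, multinomial classes) and compares
#' [estimate_rf_em()] with the brute-force [rf_grid_mle()].
#'
#' @param n_tables number of random tables (default 1000).
#' @param seed RNG seed.
#' @param step oracle grid step.
#' @return list: `max_abs_diff`, per-table `diff`, `r_true`.
#' @export
rf_oracle_benchmark <- function(n_tables = 1000, seed = 1, step = 1e-4) {
  set.seed(seed)
  diffs <- numeric(n_tables)
  r_true <- runif(n_tables, 0.01, 0.49)
  for (i in seq_len(n_tables)) {
    n_ind <- sample(50:200, 1)
    p <- .f2_class_probs(r_true[i])
    cnt <- matrix(rmultinom(1, n_ind, as.numeric(p)), 3, 3)
    cnt_list <- list(AA = cnt[1, 1], AH = cnt[1, 2], AB = cnt[1, 3],
                     HA = cnt[2, 1], HH = cnt[2, 2], HB = cnt[2, 3],
                     BA = cnt[3, 1], BH = cnt[3, 2], BB = cnt[3, 3])
    cnt_list <- lapply(cnt_list, function(x) matrix(as.numeric(x), 1, 1))
    em <- .em_rf_core(cnt_list)$r[1, 1]
    grid <- rf_grid_mle(cnt, step = step)
    diffs[i] <- abs(em - grid)
  }
  list(max_abs_diff = max(diffs), diff = diffs, r_true = r_true)
}

#' Sliding-window correction efficiency on injected isolated errors
#'
#' Simulates a clean F2 genotype matrix, flips isolated random calls at
#' `error_rate`, applies [window_correct()], and measures the error rate
#' against the truth before and after correction.
#'
#' @param n_ind individuals (default 120).
#' @param n_markers total markers (default 2000, split over
#'   `n_chrom` chromosomes).
#' @param n_chrom chromosomes (default 2).
#' @param chrom_cM chromosome length (default 100).
#' @param error_rate isolated-flip rate (default 0.02).
#' @param window correction window (default 15).
#' @param seed RNG seed.
#' @return list: `pre_error_rate`, `post_error_rate`, `reduction`
#'   (fraction of injected errors removed).
#' @export
correction_benchmark <- function(n_ind = 120, n_markers = 2000,
                                 n_chrom = 2, chrom_cM = 100,
                                 error_rate = 0.02, window = 15,
                                 seed = 1) {
  cfg <- sim_config(n_chromosomes = n_chrom, chrom_length_cM = chrom_cM,
                    n_individuals = n_ind,
                    marker_density = n_markers / (n_chrom * chrom_cM),
                    miscall_run_rate = 0, missing_rate = 0,
                    qtl_spec = data.frame(trait = character(),
                                          chrom = integer(),
                                          pos_cM = numeric(),
                                          add = numeric(), dom = numeric(),
                                          pve = numeric()),
                    trait_corr = matrix(1, 1, 1,
                                        dimnames = list("L", "L")),
                    trait_mean = c(L = 0), trait_sd = c(L = 1),
                    seed = seed)
  sim <- simulate_f2(cfg)
  truth <- sim$truth$genotypes
  obs <- truth
  set.seed(seed + 1L)
  flip <- matrix(runif(length(obs)) < error_rate, nrow(obs), ncol(obs))
  if (any(flip)) {
    cur <- obs[flip]
    obs[flip] <- vapply(cur, function(cc) sample(setdiff(CODE_LEVELS, cc), 1),
                        "")
  }
  gm <- geno_matrix(sim$geno$markers, obs)
  reps <- structure(list(markers = cbind(gm$markers,
                                         end_bp = gm$markers$pos,
                                         n_markers = 1L),
                         codes = gm$codes), class = "rep_markers")
  corrected <- window_correct(reps, window)
  pre <- mean(gm$codes != truth, na.rm = TRUE)
  post <- mean(corrected$codes != truth, na.rm = TRUE)
  list(pre_error_rate = pre, post_error_rate = post,
       reduction = 1 - post / pre)
}

# small single-trait map simulation reused by the calibration studies:
# build bins + spaced map from a clean simulated chromosome set
.sim_small_map <- function(n_chrom, chrom_cM, density, n_ind, qtl_spec,
                           seed, min_group_size = 50) {
  cfg <- sim_config(n_chromosomes = n_chrom, chrom_length_cM = chrom_cM,
                    n_individuals = n_ind, marker_density = density,
                    miscall_run_rate = 0, missing_rate = 0,
                    qtl_spec = qtl_spec,
                    trait_corr = matrix(1, 1, 1, dimnames = list("L", "L")),
                    trait_mean = c(L = 0), trait_sd = c(L = 1),
                    seed = seed)
  sim <- simulate_f2(cfg)
  bins <- build_bins(structure(list(
    markers = cbind(sim$geno$markers, end_bp = sim$geno$markers$pos,
                    n_markers = 1L),
    codes = sim$geno$codes), class = "rep_markers"))
  map <- space_map(group_bins(bins, lod_threshold = 6,
                              min_group_size = min_group_size))
  list(sim = sim, map = map)
}

#' Empirical type-I error of the permutation LOD threshold
#'
#' On a fixed simulated null map, draws `n_reps` independent standard
#' normal phenotypes; for each, computes its own permutation threshold
#' (`n_perm` permutations at level `alpha`) and records whether the
#' phenotype's genome-wide maximum interval-mapping LOD exceeds it. The
#' exceedance frequency estimates the genome-wide type-I error.
#'
#' @param n_reps null replicates (default 200).
#' @param n_perm permutations per replicate (default 200).
#' @param alpha nominal level (default 0.05).
#' @param n_ind individuals (default 120).
#' @param seed RNG seed.
#' @return list: `type1_error`, `n_reps`, `threshold_mean`.
#' @export
calibrate_type1_error <- function(n_reps = 200, n_perm = 200,
                                  alpha = 0.05, n_ind = 120, seed = 1) {
  empty_qtl <- data.frame(trait = character(), chrom = integer(),
                          pos_cM = numeric(), add = numeric(),
                          dom = numeric(), pve = numeric())
  sm <- .sim_small_map(n_chrom = 1, chrom_cM = 100, density = 1,
                       n_ind = n_ind, qtl_spec = empty_qtl, seed = seed)
  map <- sm$map
  keep <- rep(TRUE, n_ind)
  design <- .scan_design(map, keep, step = 1)
  n <- n_ind
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  set.seed(seed + 1L)
  exceed <- logical(n_reps)
  thr_sum <- 0
  for (rep_i in seq_len(n_reps)) {
    y <- rnorm(n)
    Y <- cbind(y, vapply(seq_len(n_perm), function(i) sample(y), y))
    sy2 <- colSums(Y^2)
    rss0 <- sy2 - n * colMeans(Y)^2
    maxlod <- rep(0, n_perm + 1L)
    for (q in design$Q) {
      rss1 <- pmax(sy2 - colSums(crossprod(q, Y)^2), 1e-12)
      maxlod <- pmax(maxlod, n / 2 * log10(rss0 / rss1))
    }
    thr <- sort(maxlod[-1])[k]
    exceed[rep_i] <- maxlod[1] > thr
    thr_sum <- thr_sum + thr
  }
  list(type1_error = mean(exceed), n_reps = n_reps,
       threshold_mean = thr_sum / n_reps)
}

#' QTL parameter recovery under the study conditions
#'
#' Repeatedly simulates one 100 cM chromosome carrying a single QTL with
#' target PVE, builds the bin map, scans by interval mapping with a
#' permutation threshold, and records the detected peak position error
#' (relative to the map position of the bin nearest the true QTL) and
#' the estimated peak-marker PVE.
#'
#' @param n_reps replicates (default 200).
#' @param pve target QTL PVE (default 0.40).
#' @param qtl_cM true QTL position (default 47.3 cM of 100).
#' @param n_ind individuals (default 120).
#' @param n_perm permutations for the per-replicate threshold
#'   (default 100).
#' @param seed RNG seed.
#' @return list: `detected` (fraction), `median_abs_peak_error_cM`,
#'   `median_pve`, per-replicate vectors `peak_error_cM`, `pve_hat`.
#' @export
qtl_recovery_study <- function(n_reps = 200, pve = 0.40, qtl_cM = 47.3,
                               n_ind = 120, n_perm = 100, seed = 1) {
  qtl_spec <- data.frame(trait = "L", chrom = 1, pos_cM = qtl_cM,
                         add = 1, dom = 0, pve = pve)
  peak_err <- rep(NA_real_, n_reps)
  pve_hat <- rep(NA_real_, n_reps)
  for (rep_i in seq_len(n_reps)) {
    sm <- .sim_small_map(n_chrom = 1, chrom_cM = 100, density = 1,
                         n_ind = n_ind, qtl_spec = qtl_spec,
                         seed = seed + rep_i)
    map <- sm$map; sim <- sm$sim
    thr <- permutation_threshold(map, sim$pheno, "L", n_perm = n_perm,
                                 alpha = 0.05, seed = seed + rep_i,
                                 step = 1)
    scan <- scan_im(map, sim$pheno, "L", step = 1, threshold = thr)
    calls <- call_qtls(scan, map, sim$pheno)
    if (!nrow(calls)) next
    # truth in map coordinates: the bin containing the marker nearest
    # the simulated QTL position
    mk <- which.min(abs(sim$truth$marker_cM - qtl_cM))
    mk_id <- rownames(sim$geno$codes)[mk]
    tabm <- map$table
    bin_row <- which(tabm$start_bp <= sim$geno$markers$pos[mk] &
                       tabm$end_bp >= sim$geno$markers$pos[mk])
    true_cM <- if (length(bin_row)) tabm$cM[bin_row[1]] else
      tabm$cM[which.min(abs(tabm$start_bp - sim$geno$markers$pos[mk]))]
    best <- which.max(calls$peak_lod)
    peak_err[rep_i] <- abs(calls$peak_cM[best] - true_cM)
    pve_hat[rep_i] <- calls$pve[best]
  }
  det <- !is.na(peak_err)
  list(detected = mean(det),
       median_abs_peak_error_cM = median(peak_err[det]),
       median_pve = median(pve_hat[det]),
       peak_error_cM = peak_err, pve_hat = pve_hat)
}

#' Published sesame seed-coat-color QTL table
#'
#' The 17 seed-coat-color QTLs (L/a/b colorimeter indices) reported for
#' the Yuzhi DS899 x JS012 F2 population, with flanking-marker names and
#' cM positions per linkage group. Used to exercise the
#' interval-consolidation logic on in-study data.
#' @return data frame trait, lg, qtl, left_marker, left_cM,
#'   right_marker, right_cM, pve, peak_lod, methods.
#' @export
sesame_qtl_table <- function() {
  read.delim(system.file("extdata", "sesame_seedcoat_qtls.tsv",
                         package = "binmapqtl"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Published sesame superdense linkage-map summary
#'
#' Per-linkage-group length, bin count, marker count, gap count and
#' largest gap of the published sesame map, plus (as attributes
#' `prior_markers` / `prior_bins`) the marker and bin counts of the
#' previous-generation sesame map used for fold-increase comparisons.
#' @return data frame lg, length_cM, n_bins, n_markers,
#'   avg_interval_cM, n_gaps, largest_gap_cM.
#' @export
sesame_map_table <- function() {
  df <- read.delim(system.file("extdata", "sesame_linkage_map.tsv",
                               package = "binmapqtl"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "prior_markers") <- 30193L
  attr(df, "prior_bins") <- 3041L
  df
}
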