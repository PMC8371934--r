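test_that("redundant markers collapse by spacing and compatibility", {
  # two identical markers 50 bp apart merge; 150 bp apart do not
  gm <- gm_from_strings(c("AAHB", "AAHB"), pos = c(1000L, 1050L))
  expect_equal(nrow(collapse_redundant(gm)$codes), 1)
  gm2 <- gm_from_strings(c("AAHB", "AAHB"), pos = c(1000L, 1150L))
  expect_equal(nrow(collapse_redundant(gm2)$codes), 2)
  # missing-tolerant redundancy: consensus fills the missing call
  gm3 <- gm_from_strings(c("AAHB", "A-HB", "AAHB"),
                         pos = c(1000L, 1050L, 1099L))
  reps <- collapse_redundant(gm3)
  expect_equal(nrow(reps$codes), 1)
  expect_equal(unname(reps$codes[1, ]), c("A", "A", "H", "B"))
  expect_equal(reps$markers$n_markers, 3L)
  # conflicting marker breaks the run
  gm4 <- gm_from_strings(c("AAHB", "ABHB"), pos = c(1000L, 1050L))
  expect_equal(nrow(collapse_redundant(gm4)$codes), 2)
})

test_that("collapse agrees with a brute-force run-enumeration oracle", {
  set.seed(8)
  for (rep_i in 1:20) {
    m <- 40
    codes <- matrix(sample(c("A", "H", "B", NA), m * 6, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)), m, 6)
    colnames(codes) <- sprintf("I%d", 1:6)
    pos <- cumsum(sample(c(30L, 60L, 120L), m, replace = TRUE))
    gm <- geno_matrix(data.frame(contig = "C01", pos = pos), codes)
    got <- collapse_redundant(gm, min_gap_bp = 100)
    runs <- collapse_oracle(gm$codes, gm$markers$pos, 100)
    expect_equal(nrow(got$codes), length(runs))
    expect_equal(got$markers$n_markers, lengths(runs))
    expect_equal(got$markers$pos,
                 vapply(runs, function(r) gm$markers$pos[r[1]], 1L))
  }
})

test_that("window correction restores isolated flips and respects ties", {
  # one isolated flip inside 15 identical codes
  v <- rep("A", 15); v[8] <- "B"
  gm <- gm_from_strings(vapply(v, function(x) x, ""))
  out <- window_correct(rep_from_gm(gm), 15)
  expect_equal(unname(out$codes[, 1]), rep("A", 15))
  expect_equal(attr(out, "n_corrected"), 1L)
  # a clean two-segment vector (one crossover) is left untouched
  v2 <- c(rep("A", 10), rep("H", 10))
  gm2 <- gm_from_strings(v2)
  out2 <- window_correct(rep_from_gm(gm2), 15)
  expect_equal(unname(out2$codes[, 1]), v2)
  # 7 A vs 7 B around a missing center: tie, stays missing
  v3 <- c(rep("A", 7), "-", rep("B", 7))
  gm3 <- gm_from_strings(v3)
  out3 <- window_correct(rep_from_gm(gm3), 15)
  expect_true(is.na(out3$codes[8, 1]))
  expect_error(window_correct(rep_from_gm(gm3), 14), "odd")
})

test_that("window correction matches the majority-vote oracle and is idempotent", {
  set.seed(15)
  for (rep_i in 1:10) {
    m <- 60
    v <- rep(c("A", "H"), each = m / 2)
    flip <- sample(m, 4)
    v[flip] <- sample(c("A", "H", "B"), 4, replace = TRUE)
    v[sample(m, 3)] <- NA
    codes <- matrix(v, m, 1, dimnames = list(NULL, "I1"))
    gm <- geno_matrix(data.frame(contig = "C01", pos = seq_len(m) * 1000L),
                      codes)
    out <- window_correct(rep_from_gm(gm), 15)
    expect_equal(unname(out$codes[, 1]), unname(window_oracle(v, 15)))
  }
  # idempotence on isolated-error fixtures
  v <- rep("A", 40); v[20] <- "B"
  gm <- gm_from_strings(vapply(v, identity, ""))
  once <- window_correct(rep_from_gm(gm), 15)
  twice <- window_correct(once, 15)
  expect_identical(once$codes, twice$codes)
})

test_that("bins merge adjacent redundant representatives and account markers", {
  gm <- gm_from_strings(c("AAHB", "AAHB", "ABHB"),
                        pos = c(1000L, 500000L, 900000L))
  reps <- rep_from_gm(gm)
  bins <- build_bins(reps)
  expect_equal(nrow(bins$bins), 2)     # no spacing constraint at this stage
  expect_equal(bins$bins$n_markers, c(2L, 1L))
  # vectors differing at one individual stay separate
  gm2 <- gm_from_strings(c("AAHB", "AHHB"))
  expect_equal(nrow(build_bins(rep_from_gm(gm2))$bins), 2)
  # member counts flow through collapse -> bins (17 underlying markers)
  strs <- c(rep("AAHB", 9), rep("AAHB", 8))
  pos <- c(1000L + seq_len(9) * 10L, 600000L + seq_len(8) * 10L)
  gm3 <- gm_from_strings(strs, pos = pos)
  reps3 <- collapse_redundant(gm3)
  expect_equal(nrow(reps3$codes), 2)
  bins3 <- build_bins(reps3)
  expect_equal(nrow(bins3$bins), 1)
  expect_equal(bins3$bins$n_markers, 17L)
  expect_equal(bins3$bins$start_bp, min(pos))
  expect_equal(bins3$bins$end_bp, max(pos))
})

test_that("segregation-distortion filter drops bins below the count thresholds", {
  mk <- function(nA, nH, nB, nMiss = 0) {
    c(rep("A", nA), rep("H", nH), rep("B", nB), rep(NA, nMiss))
  }
  codes <- rbind(mk(30, 60, 30), mk(19, 70, 31), mk(31, 39, 30, 20),
                 mk(30, 60, 19, 11))
  colnames(codes) <- sprintf("I%03d", seq_len(ncol(codes)))
  gm <- geno_matrix(data.frame(contig = "C01", pos = (1:4) * 1e6L), codes)
  bins <- build_bins(rep_from_gm(gm))
  kept <- filter_distorted(bins)
  expect_equal(nrow(kept$bins), 1)
  expect_equal(kept$bins$nA, 30)
  log <- attr(kept, "removal_log")
  expect_equal(nrow(log), 3)
  expect_setequal(log$reason, c("nA", "nH", "nB"))
})

test_that("counts are conserved through the bin pipeline", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_cM = 50,
                    n_individuals = 120, marker_density = 2,
                    site_cluster_size = 3, miscall_run_rate = 0.1,
                    missing_rate = 0.03, qtl_spec = default_qtl_spec()[0, ],
                    seed = 31)
  sim <- simulate_f2(cfg)
  reps <- collapse_redundant(sim$geno)
  corr <- window_correct(reps)
  bins <- build_bins(corr)
  n_markers <- nrow(sim$geno$codes)
  expect_lte(nrow(bins$bins), nrow(reps$codes))
  expect_lte(nrow(reps$codes), n_markers)
  expect_equal(sum(reps$markers$n_markers), n_markers)
  expect_equal(sum(bins$bins$n_markers), n_markers)
  b <- bins$bins
  expect_true(all(b$nA + b$nH + b$nB + b$nMissing == 120))
})

test_that("correction removes the bulk of injected isolated errors", {
  cb <- correction_benchmark(n_ind = 120, n_markers = 2000, seed = 17)
  expect_lt(cb$post_error_rate, 0.1 * cb$pre_error_rate)
})
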