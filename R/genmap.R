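# Linkage map construction on bins: pairwise recombination fractions by
# EM over the phase-ambiguous double-heterozygote class, single-linkage
# grouping at a LOD threshold, physical-order bin ordering, Kosambi
# spacing, and map statistics.

# F2 two-locus (coupling) genotype class probabilities as a function of r.
# Rows locus 1 = A,H,B; cols locus 2 = A,H,B.
.f2_class_probs <- function(r) {
  matrix(c((1 - r)^2 / 4, r * (1 - r) / 2, r^2 / 4,
           r * (1 - r) / 2, ((1 - r)^2 + r^2) / 2, r * (1 - r) / 2,
           r^2 / 4, r * (1 - r) / 2, (1 - r)^2 / 4),
         3, 3, byrow = TRUE, dimnames = list(CODE_LEVELS, CODE_LEVELS))
}

# log-likelihood of a 3x3 count table at r (0*log(0) := 0)
.f2_loglik <- function(r, n) {
  p <- .f2_class_probs(r)
  sum(n[n > 0] * log(p[n > 0]))
}

# vectorized EM over 9 pairwise count matrices (all same dim).
# Returns list(r, lod, n_informative).
.em_rf_core <- function(cnt, max_iter = 500, tol = 1e-8) {
  N <- Reduce(`+`, cnt)
  # recombinant gametes contributed by each class (HH handled in E-step)
  fixed <- cnt$AH + cnt$HA + cnt$HB + cnt$BH + 2 * (cnt$AB + cnt$BA)
  r <- array(0.25, dim = dim(N))
  for (it in seq_len(max_iter)) {
    w <- r^2 / ((1 - r)^2 + r^2)     # P(double recombinant | HH)
    r_new <- (fixed + 2 * cnt$HH * w) / (2 * N)
    r_new <- pmin(pmax(r_new, 1e-9), 0.5)
    if (max(abs(r_new - r), na.rm = TRUE) < tol) { r <- r_new; break }
    r <- r_new
  }
  # LOD = log10 L(r) - log10 L(0.5), term-wise over the 9 classes
  ll <- function(rr) {
    out <- array(0, dim = dim(N))
    probs <- list(
      AA = (1 - rr)^2 / 4, AH = rr * (1 - rr) / 2, AB = rr^2 / 4,
      HA = rr * (1 - rr) / 2, HH = ((1 - rr)^2 + rr^2) / 2,
      HB = rr * (1 - rr) / 2,
      BA = rr^2 / 4, BH = rr * (1 - rr) / 2, BB = (1 - rr)^2 / 4)
    for (k in names(cnt)) {
      term <- cnt[[k]] * log(probs[[k]])
      term[cnt[[k]] == 0] <- 0
      out <- out + term
    }
    out
  }
  lod <- (ll(r) - ll(array(0.5, dim = dim(N)))) / log(10)
  lod <- pmax(lod, 0)
  list(r = r, lod = lod, n_informative = N)
}

# 9 pairwise class-count matrices for all bin pairs via indicator
# cross-products
.pairwise_counts <- function(codes) {
  IA <- (!is.na(codes) & codes == "A") + 0
  IH <- (!is.na(codes) & codes == "H") + 0
  IB <- (!is.na(codes) & codes == "B") + 0
  list(AA = tcrossprod(IA, IA), AH = tcrossprod(IA, IH),
       AB = tcrossprod(IA, IB), HA = tcrossprod(IH, IA),
       HH = tcrossprod(IH, IH), HB = tcrossprod(IH, IB),
       BA = tcrossprod(IB, IA), BH = tcrossprod(IB, IH),
       BB = tcrossprod(IB, IB))
}

#' Pairwise recombination fractions and linkage LODs for a set of bins
#'
#' Computes, for every pair of code vectors (rows of `codes`), the
#' maximum-likelihood recombination fraction by EM and the linkage LOD
#' against independence (r = 0.5), using complete cases only.
#'
#' @param codes markers/bins x individuals code matrix.
#' @return list of matrices `r`, `lod`, `n_informative`.
#' @export
pairwise_rf <- function(codes) {
  .em_rf_core(.pairwise_counts(codes))
}

#' EM estimate of the recombination fraction between two markers
#'
#' Standard F2 codominant maximum-likelihood estimator: recombinant
#' gametes are counted directly for the eight unambiguous two-locus
#' classes while the phase-ambiguous double-heterozygote class is
#' fractionally assigned in the E-step with weight
#' r^2 / ((1-r)^2 + r^2). Starts at r = 0.25 and stops at |dr| < 1e-8 or
#' 500 iterations. The LOD is log10 L(r-hat) - log10 L(0.5).
#'
#' @param codesA,codesB per-individual codes (A/H/B/NA) at the two
#'   markers.
#' @return list with `r`, `lod`, `n_informative`.
#' @export
estimate_rf_em <- function(codesA, codesB) {
  keep <- !is.na(codesA) & !is.na(codesB)
  if (sum(keep) < 2)
    stop("fewer than 2 individuals informative at both markers")
  n <- table(factor(codesA[keep], CODE_LEVELS),
             factor(codesB[keep], CODE_LEVELS))
  cnt <- list(AA = n[1, 1], AH = n[1, 2], AB = n[1, 3],
              HA = n[2, 1], HH = n[2, 2], HB = n[2, 3],
              BA = n[3, 1], BH = n[3, 2], BB = n[3, 3])
  cnt <- lapply(cnt, function(x) matrix(as.numeric(x), 1, 1))
  res <- .em_rf_core(cnt)
  list(r = res$r[1, 1], lod = res$lod[1, 1],
       n_informative = res$n_informative[1, 1])
}

#' Grid-search maximum-likelihood recombination fraction
#'
#' Brute-force reference estimator: evaluates the F2 two-locus
#' log-likelihood of a 3x3 class-count table on a fixed grid of r values
#' and returns the argmax. Serves as an independent check of
#' [estimate_rf_em()].
#'
#' @param n 3x3 count table (rows locus 1 A/H/B, cols locus 2 A/H/B).
#' @param step grid step (default 1e-4).
#' @return the grid MLE of r.
#' @export
rf_grid_mle <- function(n, step = 1e-4) {
  grid <- seq(step, 0.5, by = step)
  n <- as.numeric(n)
  pos <- n > 0
  ll <- vapply(grid, function(r) {
    p <- as.numeric(.f2_class_probs(r))
    sum(n[pos] * log(p[pos]))
  }, 0)
  grid[which.max(ll)]
}

#' Kosambi map distance from a recombination fraction
#'
#' d = 25 ln((1 + 2r) / (1 - 2r)) centimorgans. Values of r at or above
#' 0.5 - 1e-6 are capped there with a warning (the function diverges at
#' 0.5).
#'
#' @param r recombination fraction(s) in \[0, 0.5\].
#' @return distance(s) in cM.
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0)) stop("negative recombination fraction")
  cap <- 0.5 - 1e-6
  if (any(r >= cap)) {
    warning("recombination fraction(s) capped at 0.5 - 1e-6")
    r <- pmin(r, cap)
  }
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi function
#'
#' r = tanh(d / 50) / 2; maps a cM distance back to a recombination
#' fraction.
#' @param d distance(s) in cM.
#' @return recombination fraction(s).
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("negative distance")
  0.5 * tanh(d / 50)
}

#' Group bins into linkage groups by single-linkage LOD clustering
#'
#' Bins joined by any pairwise linkage LOD at or above `lod_threshold`
#' fall into one group (single linkage over the LOD graph). Groups whose
#' bins carry fewer than `min_group_size` underlying SNP/InDel markers
#' are discarded with a message. Within each group, bins are ordered by
#' physical position (contig appearance order, then bp) -- the markers
#' are genome-anchored, so de novo ordering is not attempted.
#'
#' @param bins a `bin_set` (typically after [filter_distorted()]).
#' @param lod_threshold linkage LOD separating groups (default 12).
#' @param min_group_size minimum underlying marker count per retained
#'   group (default 100).
#' @return a `genetic_map`: `table` data frame (bin_id, group, contig,
#'   start_bp, end_bp, n_markers, cM = NA until [space_map()]) plus the
#'   aligned `codes` matrix.
#' @export
group_bins <- function(bins, lod_threshold = 12, min_group_size = 100) {
  b <- bins$bins
  B <- nrow(b)
  pr <- pairwise_rf(bins$codes)
  adj <- !is.na(pr$lod) & pr$lod >= lod_threshold
  diag(adj) <- FALSE
  comp <- integer(B); cur <- 0L
  for (i in seq_len(B)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i; comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- tapply(b$n_markers, factor(comp, seq_len(cur)), sum)
  keep_groups <- which(sizes >= min_group_size)
  if (length(keep_groups) < cur)
    message(cur - length(keep_groups),
            " group(s) with fewer than ", min_group_size,
            " markers discarded")
  keep <- comp %in% keep_groups
  b <- b[keep, , drop = FALSE]
  comp <- match(comp[keep], keep_groups)   # renumber 1..G
  codes <- bins$codes[keep, , drop = FALSE]
  lev <- unique(b$contig)
  o <- order(comp, match(b$contig, lev), b$start_bp)
  tab <- data.frame(bin_id = b$bin_id, group = comp,
                    contig = b$contig, start_bp = b$start_bp,
                    end_bp = b$end_bp, n_markers = b$n_markers,
                    cM = rep(NA_real_, nrow(b)),
                    stringsAsFactors = FALSE)[o, ]
  rownames(tab) <- NULL
  structure(list(table = tab, codes = codes[o, , drop = FALSE]),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  g <- x$table
  cat(sprintf("genetic_map: %d bins (%d markers) in %d linkage group(s)%s\n",
              nrow(g), sum(g$n_markers), length(unique(g$group)),
              if (all(is.na(g$cM))) " [not yet spaced]"
              else sprintf(", total %.2f cM",
                           sum(tapply(g$cM, g$group, max)))))
  invisible(x)
}

#' Assign Kosambi cM positions within each linkage group
#'
#' The first bin of each group sits at 0 cM; each subsequent position
#' adds the Kosambi distance of the EM recombination fraction between
#' adjacent bins.
#'
#' @param map a `genetic_map` from [group_bins()].
#' @return the map with the `cM` column filled.
#' @export
space_map <- function(map) {
  tab <- map$table
  for (g in unique(tab$group)) {
    idx <- which(tab$group == g)
    cm <- numeric(length(idx))
    if (length(idx) > 1) {
      for (j in seq_len(length(idx) - 1L)) {
        est <- tryCatch(
          estimate_rf_em(map$codes[idx[j], ], map$codes[idx[j + 1L], ]),
          error = function(e) stop("adjacent bins ", tab$bin_id[idx[j]],
                                   " / ", tab$bin_id[idx[j + 1L]],
                                   " share no informative individuals"))
        cm[j + 1L] <- cm[j] + kosambi_cM(est$r)
      }
    }
    tab$cM[idx] <- cm
  }
  map$table <- tab
  map
}

#' Map statistics per linkage group and in total
#'
#' Length, bin and marker counts, mean adjacent-bin interval (computed as
#' length / (bins - 1)), number of gaps at or above `gap_threshold` cM,
#' and largest gap, per group and summed/maximized overall; plus the
#' derived densities (bins per cM, markers per cM, markers per bin).
#'
#' @param map a spaced `genetic_map`.
#' @param gap_threshold gap-size threshold in cM (default 5).
#' @return list with `per_group` data frame and `totals` list.
#' @export
map_stats <- function(map, gap_threshold = 5) {
  tab <- map$table
  if (all(is.na(tab$cM))) stop("map not spaced; run space_map() first")
  per <- do.call(rbind, lapply(unique(tab$group), function(g) {
    cm <- sort(tab$cM[tab$group == g])
    gaps <- diff(cm)
    data.frame(group = g,
               length_cM = max(cm),
               n_bins = length(cm),
               n_markers = sum(tab$n_markers[tab$group == g]),
               mean_interval_cM = if (length(cm) > 1)
                 max(cm) / (length(cm) - 1) else NA_real_,
               n_gaps = sum(gaps >= gap_threshold),
               largest_gap_cM = if (length(gaps)) max(gaps) else 0)
  }))
  totals <- list(length_cM = sum(per$length_cM),
                 n_bins = sum(per$n_bins),
                 n_markers = sum(per$n_markers),
                 n_gaps = sum(per$n_gaps),
                 largest_gap_cM = max(per$largest_gap_cM))
  totals <- c(totals, map_density(totals$n_bins, totals$n_markers,
                                  totals$length_cM))
  list(per_group = per, totals = totals)
}

#' Marker-density arithmetic for a map summary
#'
#' Bins per cM, markers per cM and markers per bin from map totals;
#' usable directly on published map summary tables.
#'
#' @param n_bins,n_markers,length_cM map totals.
#' @return list with `bins_per_cM`, `markers_per_cM`, `markers_per_bin`.
#' @export
map_density <- function(n_bins, n_markers, length_cM) {
  list(bins_per_cM = n_bins / length_cM,
       markers_per_cM = n_markers / length_cM,
       markers_per_bin = n_markers / n_bins)
}

#' Write the spaced map and its statistics as TSV
#' @param map a spaced `genetic_map`.
#' @param path map TSV (bin_id, group, cM, contig, start_bp, end_bp,
#'   n_markers).
#' @export
write_map_tsv <- function(map, path) {
  tab <- map$table[, c("bin_id", "group", "cM", "contig", "start_bp",
                       "end_bp", "n_markers")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
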