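# Bin-map construction: the four-step cleanup pipeline applied to the
# coded marker matrix before linkage mapping.
#   (1) collapse_redundant : merge consecutive redundant markers < 100 bp
#                            apart into representative markers
#   (2) window_correct     : 15-marker sliding-window majority correction
#   (3) build_bins         : merge adjacent redundant representatives
#   (4) filter_distorted   : drop bins with distorted segregation
#
# "Redundant" tolerates missing data: two code vectors are redundant when
# they agree at every individual where both are non-missing, so that
# low-coverage missingness does not shatter true bins.

# TRUE if code vector y is compatible with consensus x
.compatible <- function(x, y) !any(x != y, na.rm = TRUE)

#' Collapse consecutive redundant markers into representative markers
#'
#' Scans each contig left to right and merges maximal runs of markers that
#' are pairwise redundant (agree wherever both are non-missing) and whose
#' adjacent members lie closer than `min_gap_bp`. The representative code
#' per individual is the run consensus: missing entries are filled by the
#' run's non-missing value, and a (theoretical) conflict degrades to
#' missing.
#'
#' @param gm a [geno_matrix()].
#' @param min_gap_bp adjacent markers at or beyond this spacing always
#'   start a new representative (default 100 bp).
#' @return a `rep_markers` object: `markers` data frame (contig, pos = bp
#'   of first member, end_bp, n_markers) plus the consensus `codes`
#'   matrix.
#' @export
collapse_redundant <- function(gm, min_gap_bp = 100) {
  stopifnot(inherits(gm, "geno_matrix"))
  m <- gm$markers
  codes <- gm$codes
  nI <- ncol(codes)
  out_info <- list(); out_codes <- list(); k <- 0L
  for (ct in unique(m$contig)) {
    rows <- which(m$contig == ct)
    cons <- codes[rows[1], ]
    start_bp <- m$pos[rows[1]]; end_bp <- start_bp; n_mem <- 1L
    flush <- function() {
      k <<- k + 1L
      out_info[[k]] <<- data.frame(contig = ct, pos = start_bp,
                                   end_bp = end_bp, n_markers = n_mem,
                                   stringsAsFactors = FALSE)
      out_codes[[k]] <<- cons
    }
    for (i in rows[-1]) {
      v <- codes[i, ]
      if (m$pos[i] - end_bp < min_gap_bp && .compatible(cons, v)) {
        fill <- is.na(cons) & !is.na(v)
        cons[fill] <- v[fill]
        end_bp <- m$pos[i]; n_mem <- n_mem + 1L
      } else {
        flush()
        cons <- v; start_bp <- m$pos[i]; end_bp <- start_bp; n_mem <- 1L
      }
    }
    flush()
  }
  info <- do.call(rbind, out_info)
  cm <- do.call(rbind, out_codes)
  rownames(cm) <- sprintf("%s-%d", info$contig, info$pos)
  colnames(cm) <- colnames(codes)
  rownames(info) <- NULL
  structure(list(markers = info, codes = cm), class = "rep_markers")
}

#' @export
print.rep_markers <- function(x, ...) {
  cat(sprintf("rep_markers: %d representatives covering %d markers\n",
              nrow(x$codes), sum(x$markers$n_markers)))
  invisible(x)
}

# windowed counts of code k (1..3) for one individual's code vector on
# one contig; centered window of w markers, shrunk at the edges
.window_counts <- function(idx_mat, w) {
  m <- nrow(idx_mat)
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(m) - h, 1L)
  hi <- pmin(seq_len(m) + h, m)
  cs <- rbind(0, apply(idx_mat, 2, cumsum))
  cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
}

#' Sliding-window genotype correction
#'
#' Single, non-iterative pass over each contig: for every marker and
#' individual the centered window of `window` representatives (shrunk at
#' contig edges) is inspected. If a strict majority (> half of the
#' non-missing window entries) supports one code, a disagreeing
#' non-missing center is replaced and a missing center is imputed; ties
#' leave the code unchanged. All decisions are taken on the input state,
#' so the pass is order-independent and conservative about genuine
#' crossover boundaries.
#'
#' @param reps a `rep_markers` object (or a [geno_matrix()]).
#' @param window odd window size in markers (default 15).
#' @return object of the same class with corrected codes; attributes
#'   `"n_corrected"` (non-missing calls changed) and `"n_imputed"`
#'   (missing calls filled).
#' @export
window_correct <- function(reps, window = 15) {
  if (window %% 2L == 0L) stop("window must be odd")
  codes <- reps$codes
  contig <- reps$markers$contig
  n_corrected <- 0L; n_imputed <- 0L
  for (ct in unique(contig)) {
    rows <- which(contig == ct)
    sub <- codes[rows, , drop = FALSE]
    cA <- .window_counts((!is.na(sub) & sub == "A") + 0, window)
    cH <- .window_counts((!is.na(sub) & sub == "H") + 0, window)
    cB <- .window_counts((!is.na(sub) & sub == "B") + 0, window)
    nonmiss <- cA + cH + cB
    maxc <- pmax(cA, cH, cB)
    strict <- 2 * maxc > nonmiss & nonmiss > 0
    maj <- matrix("A", nrow(sub), ncol(sub))
    maj[cH == maxc] <- "H"   # unique when strict majority holds
    maj[cB == maxc] <- "B"
    maj[cA == maxc] <- "A"
    change <- strict & (is.na(sub) | sub != maj)
    n_imputed <- n_imputed + sum(change & is.na(sub))
    n_corrected <- n_corrected + sum(change & !is.na(sub))
    sub[change] <- maj[change]
    codes[rows, ] <- sub
  }
  out <- reps
  out$codes <- codes
  attr(out, "n_corrected") <- n_corrected
  attr(out, "n_imputed") <- n_imputed
  out
}

#' Group adjacent redundant representatives into bins
#'
#' Maximal runs of adjacent representatives (within a contig) whose
#' corrected code vectors are redundant become one bin; member marker
#' counts are summed and the per-bin genotype counts are taken on the
#' consensus vector. No physical-distance constraint applies at this
#' stage.
#'
#' @param reps corrected `rep_markers` (output of [window_correct()]).
#' @return a `bin_set`: `bins` data frame (bin_id, contig, start_bp,
#'   end_bp, n_markers, nA, nH, nB, nMissing) plus the consensus `codes`
#'   matrix.
#' @export
build_bins <- function(reps) {
  # reuse the run-merging machinery with no spacing constraint
  gm_like <- structure(list(
    markers = data.frame(contig = reps$markers$contig,
                         pos = reps$markers$pos),
    codes = reps$codes), class = "geno_matrix")
  runs <- collapse_redundant(gm_like, min_gap_bp = Inf)
  # re-attribute member counts and physical spans from the representatives
  idx <- factor(rep(seq_len(nrow(runs$markers)), runs$markers$n_markers),
                levels = seq_len(nrow(runs$markers)))  # run per representative
  n_markers <- as.integer(tapply(reps$markers$n_markers, idx, sum))
  end_bp <- as.integer(tapply(reps$markers$end_bp, idx, max))
  codes <- runs$codes
  bins <- data.frame(
    bin_id = rownames(codes),
    contig = runs$markers$contig,
    start_bp = runs$markers$pos,
    end_bp = end_bp,
    n_markers = n_markers,
    nA = rowSums(codes == "A", na.rm = TRUE),
    nH = rowSums(codes == "H", na.rm = TRUE),
    nB = rowSums(codes == "B", na.rm = TRUE),
    nMissing = rowSums(is.na(codes)),
    stringsAsFactors = FALSE)
  rownames(bins) <- NULL
  structure(list(bins = bins, codes = codes), class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins containing %d markers on %d contig(s)\n",
              nrow(x$bins), sum(x$bins$n_markers),
              length(unique(x$bins$contig))))
  invisible(x)
}

#' Filter bins with distorted segregation
#'
#' Removes a bin when its consensus genotype counts fall below the
#' thresholds: fewer than `min_hom` A plants, fewer than `min_hom` B
#' plants, or fewer than `min_het` H plants. The defaults (20/20/40)
#' correspond to requiring at least 80 informative individuals at the
#' ideal 1:2:1 ratio in a 120-plant F2.
#'
#' @param bins a `bin_set`.
#' @param min_hom minimum count of each homozygote class.
#' @param min_het minimum count of heterozygotes.
#' @return the filtered `bin_set`; removal reasons in attribute
#'   `"removal_log"` (data frame bin_id, reason).
#' @export
filter_distorted <- function(bins, min_hom = 20, min_het = 40) {
  b <- bins$bins
  low_a <- b$nA < min_hom
  low_b <- b$nB < min_hom
  low_h <- b$nH < min_het
  drop <- low_a | low_b | low_h
  reason <- character(sum(drop))
  if (any(drop)) {
    reason <- apply(cbind(low_a, low_b, low_h)[drop, , drop = FALSE], 1,
                    function(z) paste(c("nA", "nB", "nH")[z], collapse = "+"))
  }
  out <- structure(list(bins = b[!drop, , drop = FALSE],
                        codes = bins$codes[!drop, , drop = FALSE]),
                   class = "bin_set")
  rownames(out$bins) <- NULL
  attr(out, "removal_log") <- data.frame(bin_id = b$bin_id[drop],
                                         reason = reason,
                                         stringsAsFactors = FALSE)
  out
}
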