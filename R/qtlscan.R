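# QTL scanning on the spaced bin map: Haley-Knott regression of the
# phenotype on conditional QTL genotype probabilities, for interval
# mapping (IM) and composite interval mapping (CIM, with cofactor
# markers excluded inside a window around the test position), with
# permutation-based genome-wide significance thresholds.

# genotype transition matrix along an F2 chromosome (no interference):
# entry [i, j] = P(genotype j at the right locus | genotype i at the
# left locus) for recombination fraction r, genotypes A/H/B
.f2_trans <- function(r) {
  matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
           r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
           r^2, 2 * r * (1 - r), (1 - r)^2),
         3, 3, byrow = TRUE, dimnames = list(CODE_LEVELS, CODE_LEVELS))
}

# numeric additive/dominance codes from A/H/B
.code_num <- function(codes) {
  xa <- c(A = 1, H = 0, B = -1)[codes]
  xd <- c(A = 0, H = 1, B = 0)[codes]
  cbind(xa = unname(xa), xd = unname(xd))
}

#' Conditional F2 QTL genotype probabilities at a map position
#'
#' For each individual, the probability of QTL genotype AA/AH/BB at
#' `position` given the observed codes at the flanking bins, using
#' Kosambi-inverted recombination fractions and no-interference Markov
#' transitions along the chromosome. A missing flank is marginalized
#' (one-sided conditioning; with both flanks missing the 1:2:1 prior is
#' returned). At a bin position the probabilities reduce to the
#' indicator of that bin's code.
#'
#' @param map a spaced `genetic_map`.
#' @param group linkage group id.
#' @param position cM position within the group's span.
#' @return n x 3 matrix with columns `pAA`, `pAH`, `pBB`; rows sum to 1.
#' @export
genotype_probs_f2 <- function(map, group, position) {
  tab <- map$table
  idx <- which(tab$group == group)
  if (!length(idx)) stop("group not in map")
  cm <- tab$cM[idx]
  if (position < min(cm) - 1e-9 || position > max(cm) + 1e-9)
    stop("position outside the group's cM span")
  l <- max(which(cm <= position + 1e-9))
  r <- min(which(cm >= position - 1e-9))
  prior <- c(0.25, 0.5, 0.25)
  codesL <- factor(map$codes[idx[l], ], CODE_LEVELS)
  codesR <- factor(map$codes[idx[r], ], CODE_LEVELS)
  KL <- .f2_trans(kosambi_inv(max(position - cm[l], 0)))
  KR <- .f2_trans(kosambi_inv(max(cm[r] - position, 0)))
  n <- ncol(map$codes)
  # left factor: row of KL for the left code, prior if missing
  Lpart <- matrix(prior, n, 3, byrow = TRUE)
  okL <- !is.na(codesL)
  Lpart[okL, ] <- KL[as.integer(codesL[okL]), , drop = FALSE]
  # right factor: column of KR for the right code, neutral if missing
  Rpart <- matrix(1, n, 3)
  okR <- !is.na(codesR)
  Rpart[okR, ] <- t(KR)[as.integer(codesR[okR]), , drop = FALSE]
  # both flanks present: chain conditional KL[l,q] * KR[q,r]; left-only:
  # KL[l,q] (Rpart neutral); right-only: prior(q) * KR[q,r]; none: prior
  p <- Lpart * Rpart
  p <- p / rowSums(p)
  colnames(p) <- c("pAA", "pAH", "pBB")
  rownames(p) <- colnames(map$codes)
  p
}

# cM grid over one group: seq(0, max, step) plus the terminal bin
.group_grid <- function(cm_max, step) {
  g <- seq(0, cm_max, by = step)
  if (cm_max - g[length(g)] > 1e-9) g <- c(g, cm_max)
  g
}

# scan design: per grid position the thin-QR of [1, xa, xd] restricted
# to the phenotyped individuals. Returns list(grid=df(group, cM), Q=list).
.scan_design <- function(map, keep, step) {
  tab <- map$table
  grid <- do.call(rbind, lapply(unique(tab$group), function(g) {
    data.frame(group = g, cM = .group_grid(max(tab$cM[tab$group == g]), step))
  }))
  Q <- vector("list", nrow(grid))
  X <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- genotype_probs_f2(map, grid$group[i], grid$cM[i])[keep, , drop = FALSE]
    Xi <- cbind(1, p[, "pAA"] - p[, "pBB"], p[, "pAH"])
    qr_i <- qr(Xi)
    Q[[i]] <- qr.Q(qr_i)[, seq_len(qr_i$rank), drop = FALSE]
    X[[i]] <- Xi
  }
  list(grid = grid, Q = Q, X = X, keep = keep)
}

# LOD profile for one phenotype vector given a scan design
.design_lod <- function(design, y) {
  n <- length(y)
  sy2 <- sum(y^2)
  rss0 <- sum((y - mean(y))^2)
  vapply(design$Q, function(q) {
    rss1 <- max(sy2 - sum(crossprod(q, y)^2), 1e-12)
    max(n / 2 * log10(rss0 / rss1), 0)
  }, 0)
}

# matched phenotype vector for a trait; names = individual ids
.match_pheno <- function(map, pheno, trait) {
  if (!trait %in% names(pheno)) stop("trait not in phenotype table: ", trait)
  y <- setNames(pheno[[trait]], pheno$id)
  ids <- colnames(map$codes)
  y <- y[ids]
  names(y) <- ids
  y
}

#' Interval mapping scan (Haley-Knott regression)
#'
#' At each grid position the phenotype is regressed on the additive
#' (pAA - pBB) and dominance (pAH) expected-genotype predictors;
#' LOD = (n/2) log10(RSS0 / RSS1). Individuals with a missing phenotype
#' are dropped for that trait only.
#'
#' @param map a spaced `genetic_map`.
#' @param pheno phenotype data frame with an `id` column.
#' @param trait phenotype column to scan.
#' @param step walk step in cM (default 1).
#' @param threshold optional LOD significance threshold to attach (see
#'   [permutation_threshold()]).
#' @return a `qtl_scan` data frame (trait, group, cM, lod, method) with
#'   attributes `threshold` and `step`.
#' @export
scan_im <- function(map, pheno, trait, step = 1, threshold = NULL) {
  y <- .match_pheno(map, pheno, trait)
  keep <- !is.na(y)
  if (sum(keep) < 10) stop("fewer than 10 phenotyped individuals")
  design <- .scan_design(map, keep, step)
  lod <- .design_lod(design, y[keep])
  out <- data.frame(trait = trait, group = design$grid$group,
                    cM = design$grid$cM, lod = lod,
                    method = "IM", stringsAsFactors = FALSE)
  structure(out, class = c("qtl_scan", "data.frame"),
            threshold = threshold, step = step)
}

#' Permutation-based genome-wide LOD threshold
#'
#' Permutes the phenotype against whole genotype rows (preserving the
#' marker correlation structure), rescans, and returns the
#' `(1 - alpha)` quantile of the per-permutation maximum LOD, taken as
#' the `ceiling((1 - alpha) * n_perm)`-th order statistic. Deterministic
#' given `seed`.
#'
#' @inheritParams scan_im
#' @param n_perm number of permutations (default 1000; < 100 warns).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed RNG seed.
#' @return the LOD threshold (numeric scalar).
#' @export
permutation_threshold <- function(map, pheno, trait, n_perm = 1000,
                                  alpha = 0.05, seed = 1, step = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations")
  y <- .match_pheno(map, pheno, trait)
  keep <- !is.na(y)
  if (sum(keep) < 10) stop("fewer than 10 phenotyped individuals")
  y <- y[keep]
  design <- .scan_design(map, keep, step)
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), y)
  sy2 <- sum(y^2)
  rss0 <- sum((y - mean(y))^2)
  n <- length(y)
  maxlod <- rep(0, n_perm)
  for (q in design$Q) {
    rss1 <- pmax(sy2 - colSums(crossprod(q, Y)^2), 1e-12)
    maxlod <- pmax(maxlod, n / 2 * log10(rss0 / rss1))
  }
  k <- max(1L, ceiling((1 - alpha) * n_perm))
  sort(maxlod)[k]
}

#' Forward selection of cofactor markers for CIM
#'
#' Adds bin markers (an additive + dominance predictor pair each) by
#' greatest residual-sum-of-squares reduction, stopping when the BIC no
#' longer improves or `max_cofactors` is reached. Missing marker codes
#' are mean-imputed in the design.
#'
#' @inheritParams scan_im
#' @param max_cofactors maximum number of cofactor markers (default 5).
#' @return data frame of selected bins (bin_id, group, cM); zero rows if
#'   nothing improves the criterion.
#' @export
select_cofactors <- function(map, pheno, trait, max_cofactors = 5) {
  y <- .match_pheno(map, pheno, trait)
  keep <- !is.na(y)
  y <- y[keep]
  n <- length(y)
  tab <- map$table
  Xmk <- lapply(seq_len(nrow(tab)), function(i) {
    x <- .code_num(map$codes[i, keep])
    for (j in 1:2) x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    x
  })
  selected <- integer(0)
  Z <- matrix(1, n, 1)
  rss_cur <- sum((y - mean(y))^2)
  bic_cur <- n * log(rss_cur / n) + ncol(Z) * log(n)
  if (max_cofactors < 1) return(tab[integer(0), c("bin_id", "group", "cM")])
  repeat {
    cand <- setdiff(seq_len(nrow(tab)), selected)
    rss <- vapply(cand, function(i) {
      fit <- .lm.fit(cbind(Z, Xmk[[i]]), y)
      sum(fit$residuals^2)
    }, 0)
    best <- cand[which.min(rss)]
    bic_new <- n * log(min(rss) / n) + (ncol(Z) + 2) * log(n)
    if (bic_new >= bic_cur - 1e-8) break
    selected <- c(selected, best)
    Z <- cbind(Z, Xmk[[best]])
    bic_cur <- bic_new
    if (length(selected) >= max_cofactors) break
  }
  out <- tab[selected, c("bin_id", "group", "cM")]
  rownames(out) <- NULL
  out
}

#' Cofactors active at a test position
#'
#' The CIM design at a position excludes every cofactor lying within
#' `window` cM of it on the same linkage group.
#' @param cofactors data frame from [select_cofactors()].
#' @param group,position test position.
#' @param window exclusion window in cM.
#' @return logical vector: which cofactors remain in the design.
#' @export
active_cofactors <- function(cofactors, group, position, window) {
  if (!nrow(cofactors)) return(logical(0))
  !(cofactors$group == group & abs(cofactors$cM - position) < window)
}

#' Composite interval mapping scan
#'
#' As [scan_im()] but with the selected cofactor markers as covariates in
#' both the null and the full model, excluding any cofactor within
#' `window` cM of the test position. With no cofactors the scan equals
#' interval mapping on the same grid.
#'
#' @inheritParams scan_im
#' @param cofactors data frame from [select_cofactors()].
#' @param step walk step in cM (default 2).
#' @param window cofactor exclusion window in cM (default 10).
#' @return a `qtl_scan` data frame with method `"CIM"`.
#' @export
scan_cim <- function(map, pheno, trait, cofactors, step = 2, window = 10,
                     threshold = NULL) {
  y <- .match_pheno(map, pheno, trait)
  keep <- !is.na(y)
  if (sum(keep) < 10) stop("fewer than 10 phenotyped individuals")
  yk <- y[keep]
  n <- length(yk)
  cof_idx <- match(cofactors$bin_id, map$table$bin_id)
  Zall <- lapply(cof_idx, function(i) {
    x <- .code_num(map$codes[i, keep])
    for (j in 1:2) x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
    x
  })
  design <- .scan_design(map, keep, step)
  lod <- numeric(nrow(design$grid))
  for (i in seq_len(nrow(design$grid))) {
    act <- active_cofactors(cofactors, design$grid$group[i],
                            design$grid$cM[i], window)
    Z <- do.call(cbind, c(list(matrix(1, n, 1)), Zall[act]))
    rss0 <- sum(.lm.fit(Z, yk)$residuals^2)
    rss1 <- max(sum(.lm.fit(cbind(Z, design$X[[i]][, -1, drop = FALSE]),
                            yk)$residuals^2), 1e-12)
    lod[i] <- max(n / 2 * log10(rss0 / rss1), 0)
  }
  out <- data.frame(trait = trait, group = design$grid$group,
                    cM = design$grid$cM, lod = lod,
                    method = "CIM", stringsAsFactors = FALSE)
  structure(out, class = c("qtl_scan", "data.frame"),
            threshold = threshold, step = step)
}

#' Call QTLs from a thresholded scan
#'
#' Each maximal contiguous run of grid positions with LOD above the
#' attached threshold yields one QTL: the peak is the argmax, the
#' left/right markers are the nearest bins bounding the region, and the
#' PVE (V_G / V_P) is the coefficient of determination of the
#' additive + dominance regression at the bin marker nearest the peak.
#' QTL names are auto-generated as `qSC<trait><group>.<k>`.
#'
#' @param scan a `qtl_scan` with a `threshold` attribute (or `threshold`
#'   supplied here).
#' @param map the spaced `genetic_map` the scan was run on.
#' @param pheno phenotype data frame.
#' @param threshold optional LOD threshold overriding the attribute.
#' @return data frame of QTL calls (possibly zero rows): trait, group,
#'   name, left_marker, left_cM, right_marker, right_cM, peak_cM,
#'   peak_lod, pve, method.
#' @export
call_qtls <- function(scan, map, pheno, threshold = NULL) {
  thr <- threshold %||% attr(scan, "threshold")
  if (is.null(thr)) stop("no LOD threshold attached to the scan")
  trait <- scan$trait[1]
  y <- .match_pheno(map, pheno, trait)
  tab <- map$table
  calls <- list()
  for (g in unique(scan$group)) {
    sg <- scan[scan$group == g, , drop = FALSE]
    above <- sg$lod > thr
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    k <- 0L
    bins_g <- tab[tab$group == g, , drop = FALSE]
    rows_g <- which(tab$group == g)
    for (j in which(rl$values)) {
      k <- k + 1L
      reg <- sg[starts[j]:ends[j], , drop = FALSE]
      peak_i <- which.max(reg$lod)
      peak_cM <- reg$cM[peak_i]
      left_ok <- which(bins_g$cM <= reg$cM[1] + 1e-9)
      right_ok <- which(bins_g$cM >= reg$cM[nrow(reg)] - 1e-9)
      li <- if (length(left_ok)) max(left_ok) else 1L
      ri <- if (length(right_ok)) min(right_ok) else nrow(bins_g)
      near <- which.min(abs(bins_g$cM - peak_cM))
      xn <- .code_num(map$codes[rows_g[near], ])
      cc <- complete.cases(xn) & !is.na(y)
      pve <- if (sum(cc) > 3) {
        fit <- .lm.fit(cbind(1, xn[cc, , drop = FALSE]), y[cc])
        max(0, min(1, 1 - sum(fit$residuals^2) /
                     sum((y[cc] - mean(y[cc]))^2)))
      } else NA_real_
      calls[[length(calls) + 1L]] <- data.frame(
        trait = trait, group = g,
        name = sprintf("qSC%s%d.%d", trait, g, k),
        left_marker = bins_g$bin_id[li], left_cM = bins_g$cM[li],
        right_marker = bins_g$bin_id[ri], right_cM = bins_g$cM[ri],
        peak_cM = peak_cM, peak_lod = max(reg$lod), pve = pve,
        method = scan$method[1], stringsAsFactors = FALSE)
    }
  }
  if (!length(calls)) {
    return(data.frame(trait = character(), group = integer(),
                      name = character(), left_marker = character(),
                      left_cM = numeric(), right_marker = character(),
                      right_cM = numeric(), peak_cM = numeric(),
                      peak_lod = numeric(), pve = numeric(),
                      method = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
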