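# shared fixture builders: tiny code matrices and simulated crosses

# geno_matrix from code strings ("AAHB-" per marker, "-" = missing)
gm_from_strings <- function(strs, contig = "C01", pos = NULL) {
  codes <- do.call(rbind, lapply(strsplit(strs, ""), function(x) {
    x[x == "-"] <- NA_character_
    x
  }))
  if (is.null(pos)) pos <- seq_len(length(strs)) * 1000L
  colnames(codes) <- sprintf("I%02d", seq_len(ncol(codes)))
  geno_matrix(data.frame(contig = contig, pos = pos), codes)
}

# promote a geno_matrix to single-member representative markers
rep_from_gm <- function(gm) {
  structure(list(markers = cbind(gm$markers, end_bp = gm$markers$pos,
                                 n_markers = 1L),
                 codes = gm$codes), class = "rep_markers")
}

# single-trait config for small crosses
one_trait_config <- function(n_chrom = 1, len = 100, n_ind = 120,
                             density = 1, qtl = NULL, seed = 1, ...) {
  qtl <- qtl %||% data.frame(trait = character(), chrom = integer(),
                             pos_cM = numeric(), add = numeric(),
                             dom = numeric(), pve = numeric())
  sim_config(n_chromosomes = n_chrom, chrom_length_cM = len,
             n_individuals = n_ind, marker_density = density,
             miscall_run_rate = 0, missing_rate = 0, qtl_spec = qtl,
             trait_corr = matrix(1, 1, 1, dimnames = list("L", "L")),
             trait_mean = c(L = 0), trait_sd = c(L = 1), seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force redundant-run collapse: candidate joins a run only if it is
# compatible with EVERY member and lies within the gap of the previous one
collapse_oracle <- function(codes, pos, min_gap) {
  compat <- function(x, y) !any(x != y, na.rm = TRUE)
  runs <- list()
  members <- 1L
  for (i in seq_len(nrow(codes))[-1]) {
    ok_gap <- pos[i] - pos[members[length(members)]] < min_gap
    ok_cmp <- all(vapply(members, function(m) compat(codes[m, ], codes[i, ]),
                         TRUE))
    if (ok_gap && ok_cmp) members <- c(members, i)
    else { runs[[length(runs) + 1L]] <- members; members <- i }
  }
  runs[[length(runs) + 1L]] <- members
  runs
}

# majority-vote oracle for one individual's code vector
window_oracle <- function(v, w) {
  h <- (w - 1L) %/% 2L
  out <- v
  for (i in seq_along(v)) {
    win <- v[max(1, i - h):min(length(v), i + h)]
    win <- win[!is.na(win)]
    if (!length(win)) next
    tab <- table(win)
    if (max(tab) * 2 > length(win)) {
      m <- names(tab)[which.max(tab)]
      out[i] <- m
    }
  }
  out
}
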