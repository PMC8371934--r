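#' Configuration for a synthetic F2 intercross
#'
#' Defines the study conditions emulated by [simulate_f2()]: a 13-chromosome
#' genome, 120 F2 individuals, dense biallelic markers fixed for opposite
#' alleles in the parents, correlated low-coverage miscall runs in which
#' short stretches of true heterozygotes are called as one homozygote,
#' uniform missingness, a small number of QTLs per seed-coat-color index
#' (L/a/b) with per-QTL target phenotypic variance explained (PVE), and
#' correlated residuals across the three indices.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM genetic length of each chromosome (cM); recycled.
#' @param n_individuals number of F2 individuals.
#' @param marker_density marker sites per cM.
#' @param site_cluster_size markers emitted per site; members of a cluster
#'   lie within `cluster_span_bp` of each other and share the site's
#'   genotype, emulating the redundant local markers that the collapsing
#'   step merges.
#' @param cluster_span_bp physical span (bp) of a marker cluster.
#' @param bp_per_cM physical-to-genetic scale used to place markers on the
#'   (synthetic) physical axis.
#' @param miscall_run_rate probability that a maximal run of true
#'   heterozygotes receives a homozygous miscall run.
#' @param miscall_run_length mean length (markers) of a miscall run
#'   (geometric).
#' @param missing_rate per-call missing probability.
#' @param qtl_spec data frame with columns `trait`, `chrom`, `pos_cM`,
#'   `add`, `dom`, `pve`: QTL positions, the shape of their
#'   additive/dominance effects (rescaled internally so each QTL attains
#'   its target `pve` under 1:2:1 genotype frequencies), and per-QTL PVE.
#' @param trait_corr correlation matrix of the residuals across traits;
#'   row/column names define the trait set.
#' @param trait_mean,trait_sd location/scale used to put phenotypes on a
#'   colorimeter-like scale.
#' @param seed integer seed; fixes all outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 13,
                       chrom_length_cM = 120,
                       n_individuals = 120,
                       marker_density = 2,
                       site_cluster_size = 1,
                       cluster_span_bp = 60,
                       bp_per_cM = 2e5,
                       miscall_run_rate = 0.15,
                       miscall_run_length = 5,
                       missing_rate = 0.05,
                       qtl_spec = default_qtl_spec(),
                       trait_corr = default_trait_corr(),
                       trait_mean = c(L = 40, a = 5.5, b = 10),
                       trait_sd = c(L = 8.4, a = 2.7, b = 4.3),
                       seed = 1L) {
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  for (r in c(miscall_run_rate, missing_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  trait_corr <- as.matrix(trait_corr)
  if (!isSymmetric(unname(trait_corr)))
    stop("trait_corr must be symmetric")
  if (min(eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop("trait_corr must be positive-definite")
  traits <- rownames(trait_corr) %||% names(trait_mean)
  if (is.null(traits)) stop("trait_corr must carry trait names")
  dimnames(trait_corr) <- list(traits, traits)
  if (nrow(qtl_spec)) {
    need <- c("trait", "chrom", "pos_cM", "add", "dom", "pve")
    if (!all(need %in% names(qtl_spec)))
      stop("qtl_spec needs columns: ", paste(need, collapse = ", "))
    if (!all(qtl_spec$trait %in% traits))
      stop("qtl_spec traits must appear in trait_corr")
    if (any(qtl_spec$chrom > n_chromosomes))
      stop("qtl_spec chromosome beyond n_chromosomes")
    if (any(qtl_spec$pos_cM > chrom_length_cM[qtl_spec$chrom]))
      stop("QTL position beyond chromosome end")
    tot <- tapply(qtl_spec$pve, qtl_spec$trait, sum)
    if (any(tot >= 1)) stop("per-trait total PVE must be < 1")
  }
  structure(list(
    n_chromosomes = n_chromosomes, chrom_length_cM = chrom_length_cM,
    n_individuals = n_individuals, marker_density = marker_density,
    site_cluster_size = site_cluster_size, cluster_span_bp = cluster_span_bp,
    bp_per_cM = bp_per_cM, miscall_run_rate = miscall_run_rate,
    miscall_run_length = miscall_run_length, missing_rate = missing_rate,
    qtl_spec = qtl_spec, trait_corr = trait_corr, traits = traits,
    trait_mean = trait_mean[traits], trait_sd = trait_sd[traits],
    seed = as.integer(seed)), class = "sim_config")
}

#' Default QTL layout for the seed-coat-color simulation
#'
#' One to three QTLs per colorimeter index with PVEs up to 0.30, a shared
#' major locus on chromosome 9 (mirroring a QTL hotspot), and dominance
#' pushing L towards the dark-parent value (F1 seeds dark).
#' @return data frame with columns trait, chrom, pos_cM, add, dom, pve.
#' @export
default_qtl_spec <- function() {
  data.frame(
    trait = c("L", "L", "a", "a", "a", "b", "b", "b"),
    chrom = c(9, 3, 9, 5, 6, 9, 3, 5),
    pos_cM = c(25, 45, 25, 21, 80, 25, 44, 21),
    add   = c(1, 1, -1, -1, -1, 1, 1, 1),
    dom   = c(-1, -0.5, 0.5, 0, 0, -1, 0, 0),
    pve   = c(0.30, 0.10, 0.25, 0.08, 0.08, 0.25, 0.10, 0.08))
}

#' Default residual correlation of the L/a/b colorimeter indices
#' @return 3x3 correlation matrix.
#' @export
default_trait_corr <- function() {
  m <- matrix(c(1, -0.3, 0.6,
                -0.3, 1, -0.2,
                0.6, -0.2, 1), 3, 3,
              dimnames = list(c("L", "a", "b"), c("L", "a", "b")))
  m
}

# one gamete from an F1: allele (0 = parent-1, 1 = parent-2) at each
# queried cM position; crossovers Poisson(length/100), positions uniform,
# no interference
.sim_gamete <- function(len_cM, pos_cM) {
  n_xo <- rpois(1L, len_cM / 100)
  xo <- if (n_xo > 0) sort(runif(n_xo, 0, len_cM)) else numeric(0)
  start <- sample.int(2L, 1L) - 1L
  list(alleles = (start + findInterval(pos_cM, xo)) %% 2L, xo = xo)
}

#' Simulate an F2 intercross with low-coverage genotyping artifacts
#'
#' Generates error-free true genotypes via a no-interference crossover
#' model, an observed genotype matrix with homozygous miscall runs applied
#' to true heterozygous stretches plus uniform missingness, and phenotypes
#' composed of QTL additive/dominance effects plus correlated residual
#' noise. Effects are rescaled so that, in expectation under 1:2:1
#' genotype frequencies, each QTL explains its target fraction of the
#' phenotypic variance; the residual variance is then `1 - sum(pve)` on
#' the standardized scale.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `f2_sim` with elements `truth` (true codes,
#'   marker cM positions, QTL genotypes, crossover points), `geno` (the
#'   observed [geno_matrix()]), `pheno` (data frame `id`, one column per
#'   trait), and `config`.
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nI <- config$n_individuals
  ids <- sprintf("F2_%03d", seq_len(nI))
  contigs <- sprintf("C%02d", seq_len(config$n_chromosomes))

  # marker layout: sites at random cM positions, optionally emitted as
  # tight physical clusters of identical markers
  layout <- vector("list", config$n_chromosomes)
  for (ch in seq_len(config$n_chromosomes)) {
    len <- config$chrom_length_cM[ch]
    n_sites <- max(2L, round(len * config$marker_density))
    site_cM <- sort(runif(n_sites, 0, len))
    k <- config$site_cluster_size
    site_bp <- pmax(1L, round(site_cM * config$bp_per_cM))
    if (k > 1) {
      off <- replicate(n_sites,
                       c(0, sort(sample.int(config$cluster_span_bp, k - 1L))))
      bp <- as.integer(rep(site_bp, each = k) + as.vector(off))
    } else {
      bp <- as.integer(site_bp)
    }
    layout[[ch]] <- list(
      site_cM = site_cM,
      site_of_marker = rep(seq_len(n_sites), each = k),
      bp = bp)
  }

  qtl <- config$qtl_spec
  qtl_by_chrom <- if (nrow(qtl)) split(seq_len(nrow(qtl)), qtl$chrom) else list()

  n_markers_chr <- vapply(layout, function(l) length(l$bp), 1L)
  n_markers <- sum(n_markers_chr)
  true_codes <- matrix(NA_character_, n_markers, nI)
  qtl_codes <- if (nrow(qtl)) matrix(NA_character_, nrow(qtl), nI) else NULL
  crossovers <- vector("list", nI)

  marker_rows <- split(seq_len(n_markers),
                       rep(seq_len(config$n_chromosomes), n_markers_chr))
  for (i in seq_len(nI)) {
    xo_i <- vector("list", config$n_chromosomes)
    for (ch in seq_len(config$n_chromosomes)) {
      l <- layout[[ch]]
      q_idx <- qtl_by_chrom[[as.character(ch)]]
      pos_all <- c(l$site_cM, if (length(q_idx)) qtl$pos_cM[q_idx])
      g1 <- .sim_gamete(config$chrom_length_cM[ch], pos_all)
      g2 <- .sim_gamete(config$chrom_length_cM[ch], pos_all)
      geno <- g1$alleles + g2$alleles   # 0/1/2 = A/H/B
      ns <- length(l$site_cM)
      true_codes[marker_rows[[ch]], i] <-
        CODE_LEVELS[geno[l$site_of_marker] + 1L]
      if (length(q_idx))
        qtl_codes[q_idx, i] <- CODE_LEVELS[geno[ns + seq_along(q_idx)] + 1L]
      xo_i[[ch]] <- sort(c(g1$xo, g2$xo))
    }
    crossovers[[i]] <- xo_i
  }

  markers <- data.frame(
    contig = rep(contigs, n_markers_chr),
    pos = unlist(lapply(layout, `[[`, "bp")),
    stringsAsFactors = FALSE)
  marker_cM <- unlist(lapply(layout, function(l) l$site_cM[l$site_of_marker]))
  rownames(true_codes) <- sprintf("%s-%d", markers$contig, markers$pos)
  colnames(true_codes) <- ids

  # observed matrix: miscall runs on true-H stretches, then missingness
  obs <- true_codes
  if (config$miscall_run_rate > 0) {
    p_geo <- 1 / max(config$miscall_run_length, 1)
    for (i in seq_len(nI)) {
      for (ch in seq_len(config$n_chromosomes)) {
        rows <- marker_rows[[ch]]
        v <- obs[rows, i]
        rl <- rle(v)
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1L
        hr <- which(rl$values == "H")
        for (h in hr) {
          if (runif(1) >= config$miscall_run_rate) next
          run_len <- rl$lengths[h]
          st <- sample.int(run_len, 1L)
          ln <- min(rgeom(1L, p_geo) + 1L, run_len - st + 1L)
          idx <- rows[(starts[h] + st - 1L):(starts[h] + st + ln - 2L)]
          obs[idx, i] <- sample(c("A", "B"), 1L)
        }
      }
    }
  }
  if (config$missing_rate > 0) {
    obs[matrix(runif(length(obs)) < config$missing_rate,
               nrow(obs), ncol(obs))] <- NA_character_
  }

  # phenotypes: rescale each QTL's effects to hit its target PVE, unit
  # phenotypic variance, then shift/scale to the colorimeter ranges
  traits <- config$traits
  pheno <- data.frame(id = ids, stringsAsFactors = FALSE)
  pve_tot <- setNames(numeric(length(traits)), traits)
  if (nrow(qtl)) {
    for (t in traits) pve_tot[t] <- sum(qtl$pve[qtl$trait == t])
  }
  res_sd <- sqrt(1 - pve_tot)
  Sigma <- config$trait_corr * (res_sd %o% res_sd)
  E <- MASS::mvrnorm(nI, mu = rep(0, length(traits)), Sigma = Sigma)
  E <- matrix(E, nrow = nI, dimnames = list(NULL, traits))
  for (t in traits) {
    g <- numeric(nI)
    rows_t <- which(qtl$trait == t)
    for (q in rows_t) {
      code <- qtl_codes[q, ]
      xa <- c(A = 1, H = 0, B = -1)[code]
      xd <- c(A = 0, H = 1, B = 0)[code]
      s2 <- qtl$add[q]^2 / 2 + qtl$dom[q]^2 / 4
      cq <- sqrt(qtl$pve[q] / s2)
      g <- g + cq * (qtl$add[q] * xa + qtl$dom[q] * (xd - 0.5))
    }
    pheno[[t]] <- unname(config$trait_mean[t] +
                           config$trait_sd[t] * (g + E[, t]))
  }

  gm <- geno_matrix(markers, obs)
  truth <- list(genotypes = true_codes, marker_cM = marker_cM,
                qtl_spec = qtl, qtl_codes = qtl_codes,
                crossovers = crossovers)
  structure(list(truth = truth, geno = gm, pheno = pheno, config = config),
            class = "f2_sim")
}

#' @export
print.f2_sim <- function(x, ...) {
  cat(sprintf("F2 simulation: %d individuals, %d markers on %d chromosomes, %d QTL rows\n",
              ncol(x$geno$codes), nrow(x$geno$codes),
              x$config$n_chromosomes, nrow(x$config$qtl_spec)))
  invisible(x)
}

#' Simulate gene models, parent-genotyped variants and DEG tables
#'
#' Builds the annotation-side fixtures for the candidate-gene screen:
#' non-overlapping gene models on the simulated chromosomes, a variant
#' table in which each planted candidate gene carries one high-impact
#' variant homozygous-alternate in the black parent and reference in both
#' white lines, and per-stage (5/10/15/20/25 DAF) differential-expression
#' tables in which planted candidates are DEGs at one or more late stages
#' but not at 5 DAF. Every non-planted gene is a decoy violating exactly
#' one screen condition (not co-segregating, not high-impact, DEG at the
#' control stage, or no late DEG), cycling over the four flavors.
#'
#' @param config a [sim_config()] object (chromosome layout and seed).
#' @param n_genes total genes to place.
#' @param n_planted_candidates genes that must survive the full screen.
#' @param stages differential-expression stages in days after flowering.
#' @return list with elements `genes`, `cds` (CDS parts), `variants`,
#'   `deg`, `planted` (gene ids), `stages`.
#' @export
simulate_annotation <- function(config, n_genes, n_planted_candidates,
                                stages = c(5, 10, 15, 20, 25)) {
  stopifnot(inherits(config, "sim_config"))
  if (n_planted_candidates > n_genes)
    stop("n_planted_candidates must be <= n_genes")
  set.seed(config$seed + 1000L)
  contigs <- sprintf("C%02d", seq_len(config$n_chromosomes))
  chrom_bp <- pmax(1e6, round(config$chrom_length_cM * config$bp_per_cM))

  non_stop <- setdiff(names(Biostrings::GENETIC_CODE),
                      c("TAA", "TAG", "TGA"))
  genes <- list(); cds_parts <- list(); cds_seqs <- character(n_genes)
  cursor <- setNames(rep(50000L, config$n_chromosomes), contigs)
  for (g in seq_len(n_genes)) {
    ch <- ((g - 1L) %% config$n_chromosomes) + 1L
    gid <- sprintf("gene%04d", g)
    n_ex <- sample(1:3, 1L)
    ex_cds <- 3L * sample(100:400, n_ex)           # exon CDS lengths (bp)
    introns <- if (n_ex > 1) sample(200:800, n_ex - 1L) else integer(0)
    start <- cursor[ch]
    if (start + sum(ex_cds) + sum(introns) > chrom_bp[ch] - 1000)
      stop("gene placement exceeds chromosome; reduce n_genes")
    ex_start <- integer(n_ex); ex_end <- integer(n_ex); p <- start
    for (e in seq_len(n_ex)) {
      ex_start[e] <- p; ex_end[e] <- p + ex_cds[e] - 1L
      p <- ex_end[e] + 1L + (if (e < n_ex) introns[e] else 0L)
    }
    end <- ex_end[n_ex]
    cursor[ch] <- end + sample(15000:30000, 1L)
    strand <- if (g <= n_planted_candidates) "+" else sample(c("+", "-"), 1L)
    L <- sum(ex_cds)
    body <- paste(sample(non_stop, L / 3L - 2L, replace = TRUE), collapse = "")
    cds_seqs[g] <- paste0("ATG", body, "TAA")
    genes[[g]] <- data.frame(gene_id = gid, contig = contigs[ch],
                             start = start, end = end, strand = strand,
                             annotation = sprintf("hypothetical protein %s", gid),
                             stringsAsFactors = FALSE)
    cds_parts[[g]] <- data.frame(gene_id = gid, contig = contigs[ch],
                                 start = ex_start, end = ex_end,
                                 strand = strand, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  genes$cds_seq <- cds_seqs
  cds <- do.call(rbind, cds_parts)

  planted <- genes$gene_id[seq_len(n_planted_candidates)]
  decoys <- setdiff(genes$gene_id, planted)
  decoy_flavor <- setNames(rep_len(c("not_coseg", "not_high", "deg_at_control",
                                     "no_late_deg"), length(decoys)), decoys)

  # variants: a frameshift insertion mid-CDS per gene that needs one;
  # decoys of flavor "not_high" get a missense SNP instead
  high_of <- function(gid, coseg, high) {
    row <- genes[genes$gene_id == gid, ]
    parts <- cds[cds$gene_id == gid, ]
    pos <- parts$start[1] + 30L
    # base at pos on the + strand equals the CDS base for "+" genes
    off <- pos - parts$start[1] + 1L
    refb <- substr(row$cds_seq, off, off)
    if (row$strand == "-") refb <- chartr("ACGT", "TGCA", refb)
    if (high) {
      alt <- paste0(refb, "A"); effect <- "frameshift_variant"; imp <- "HIGH"
    } else {
      alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
      effect <- "missense_variant"; imp <- "MODERATE"
    }
    data.frame(contig = row$contig, pos = pos, ref = refb, alt = alt,
               gene_id = gid, effect = effect, impact = imp,
               gt_black = "1/1",
               gt_white = if (coseg) "0/0" else "1/1",
               gt_ref = "0/0",
               ann = sprintf("%s|%s|%s|%s", alt, effect, imp, gid),
               stringsAsFactors = FALSE)
  }
  var_rows <- list()
  for (gid in planted) var_rows[[gid]] <- high_of(gid, coseg = TRUE, high = TRUE)
  for (gid in decoys) {
    fl <- decoy_flavor[gid]
    var_rows[[gid]] <- switch(fl,
      not_coseg = high_of(gid, coseg = FALSE, high = TRUE),
      not_high = high_of(gid, coseg = TRUE, high = FALSE),
      high_of(gid, coseg = TRUE, high = TRUE))
  }
  variants <- do.call(rbind, var_rows); rownames(variants) <- NULL

  # DEG tables: flat baseline everywhere, then the role-specific pattern
  deg <- expand.grid(gene_id = genes$gene_id, stage = stages,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  deg$log2fc <- rnorm(nrow(deg), 0, 0.3)
  deg$padj <- runif(nrow(deg), 0.2, 1)
  set_deg <- function(gid, stage, up = TRUE) {
    i <- deg$gene_id == gid & deg$stage == stage
    deg$log2fc[i] <<- (if (up) 1 else -1) * (1.5 + rexp(sum(i), 1))
    deg$padj[i] <<- 10^-runif(sum(i), 3, 8)
  }
  late <- setdiff(stages, stages[1])
  for (gid in planted) {
    for (s in sample(late, sample(1:3, 1L))) set_deg(gid, s, runif(1) < 0.5)
  }
  for (gid in decoys) {
    fl <- decoy_flavor[gid]
    if (fl %in% c("not_coseg", "not_high")) {
      set_deg(gid, sample(late, 1L))
    } else if (fl == "deg_at_control") {
      set_deg(gid, stages[1]); set_deg(gid, sample(late, 1L))
    } # no_late_deg: baseline only
  }

  list(genes = genes, cds = cds, variants = variants, deg = deg,
       planted = planted, decoy_flavor = decoy_flavor, stages = stages)
}
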