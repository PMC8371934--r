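# Candidate-gene screen inside the consolidated qSC physical segments:
# genes must carry at least one high-impact variant co-segregating with
# the seed-coat-color contrast (homozygous-alternate in the black
# parent, reference in both white lines) AND be differentially expressed
# at one or more late seed-development stages but not at the control
# stage (5 DAF).

# variant effects regarded as high impact
HIGH_IMPACT_EFFECTS <- c("frameshift_variant", "stop_gained", "stop_lost",
                         "start_lost", "splice_acceptor_variant",
                         "splice_donor_variant", "exon_loss_variant")

#' Genes overlapping physical segments
#'
#' Returns the genes whose span overlaps any segment by at least 1 bp
#' (deduplicated). Genes on contigs absent from the segments are skipped
#' silently.
#'
#' @param genes data frame gene_id, contig, start, end (1-based
#'   inclusive).
#' @param segments data frame contig, start_bp, end_bp (e.g. from
#'   [to_physical()]).
#' @return the overlapping subset of `genes`.
#' @export
genes_in_segments <- function(genes, segments) {
  if (!nrow(genes) || !nrow(segments)) return(genes[integer(0), ])
  gr <- GenomicRanges::GRanges(genes$contig,
                               IRanges::IRanges(genes$start, genes$end))
  sr <- GenomicRanges::GRanges(segments$contig,
                               IRanges::IRanges(segments$start_bp,
                                                segments$end_bp))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, sr))
  out <- genes[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# diploid GT string -> dosage for the three reference lines
.line_dosage <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & grepl("^[0-9]+[/|][0-9]+$", gt)
  parts <- strsplit(gt[ok], "[/|]")
  out[ok] <- as.integer(vapply(parts, `[`, "", 1L)) +
    as.integer(vapply(parts, `[`, "", 2L))
  out
}

#' Screen variants co-segregating with the seed-coat-color contrast
#'
#' Keeps variants at which the black parent is homozygous for the
#' non-reference allele while both white lines (the white parent and the
#' white reference-genome line) are homozygous reference. A missing
#' genotype in any of the three lines removes the variant
#' (conservative). Progeny genotypes play no role.
#'
#' @param variants variant data frame.
#' @param black,white,reference column names holding the diploid GT
#'   strings of the black parent, the white parent, and the white
#'   reference line.
#' @return the co-segregating subset of `variants`.
#' @export
coseg_screen <- function(variants, black = "gt_black", white = "gt_white",
                         reference = "gt_ref") {
  db <- .line_dosage(variants[[black]])
  dw <- .line_dosage(variants[[white]])
  dr <- .line_dosage(variants[[reference]])
  keep <- !is.na(db) & !is.na(dw) & !is.na(dr) &
    db == 2L & dw == 0L & dr == 0L
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse impact classes from ANN-style annotation strings
#'
#' Reads the standard functional-annotation field dialect
#' `Allele|Annotation|Impact|Gene...` and returns the effect label and
#' impact class (high/moderate/low/modifier) per record.
#' @param ann character vector of annotation strings.
#' @return data frame effect, impact.
#' @export
ann_impact <- function(ann) {
  parts <- strsplit(ann, "|", fixed = TRUE)
  data.frame(
    effect = vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, ""),
    impact = tolower(vapply(parts, function(p) if (length(p) >= 3) p[3] else NA_character_, "")),
    stringsAsFactors = FALSE)
}

# CDS-relative position of a genomic position for a gene model
# (parts: data frame start, end sorted ascending; strand "+"/"-")
.cds_offset <- function(pos, parts, strand) {
  lens <- parts$end - parts$start + 1L
  if (strand == "+") {
    before <- c(0L, cumsum(lens))[-(nrow(parts) + 1L)]
    for (e in seq_len(nrow(parts))) {
      if (pos >= parts$start[e] && pos <= parts$end[e])
        return(before[e] + pos - parts$start[e] + 1L)
    }
  } else {
    ord <- rev(seq_len(nrow(parts)))
    before <- c(0L, cumsum(lens[ord]))[-(nrow(parts) + 1L)]
    for (k in seq_along(ord)) {
      e <- ord[k]
      if (pos >= parts$start[e] && pos <= parts$end[e])
        return(before[k] + parts$end[e] - pos + 1L)
    }
  }
  NA_integer_
}

.revcomp1 <- function(b) chartr("ACGT", "TGCA", b)

#' Minimal variant effect classifier
#'
#' Built-in effect caller for a single variant against one gene model:
#' CDS indels with length not a multiple of 3 are frameshifts (high);
#' SNPs creating a stop codon are stop_gained, destroying the start or a
#' stop codon start_lost / stop_lost (all high); variants within 2 bp of
#' an intron boundary are splice_acceptor/splice_donor (high); deletions
#' removing a whole exon are exon_loss (high); synonymous SNPs are low,
#' missense moderate, and non-genic variants modifier. UTR/regulatory
#' classes are not modeled (modifier-class handling is pass-through).
#'
#' @param variant list or one-row data frame with contig, pos, ref, alt.
#' @param gene list or one-row data frame with contig, start, end,
#'   strand.
#' @param cds data frame of the gene's CDS parts (start, end), sorted by
#'   start.
#' @param cds_seq the spliced coding sequence (sense strand, 5'->3').
#' @return data frame effect, impact.
#' @export
classify_impact <- function(variant, gene, cds, cds_seq) {
  eff <- function(effect, impact) data.frame(effect = effect,
                                             impact = impact,
                                             stringsAsFactors = FALSE)
  pos <- variant$pos; ref <- variant$ref; alt <- variant$alt
  if (variant$contig != gene$contig || pos < gene$start || pos > gene$end)
    return(eff("intergenic_variant", "modifier"))
  if (nchar(cds_seq) %% 3L != 0L)
    warning("CDS length not a multiple of 3 for ", gene$gene_id %||% "gene")
  parts <- cds[order(cds$start), , drop = FALSE]
  strand <- gene$strand
  is_del <- nchar(ref) > nchar(alt)
  is_ins <- nchar(alt) > nchar(ref)
  if (is_del) {
    # VCF anchor base: deleted span is pos+1 .. pos+nchar(ref)-1
    del_s <- pos + 1L; del_e <- pos + nchar(ref) - 1L
    whole <- any(parts$start >= del_s & parts$end <= del_e)
    if (whole) return(eff("exon_loss_variant", "high"))
    in_cds <- any(del_e >= parts$start & del_s <= parts$end)
    if (in_cds) {
      n_del <- sum(vapply(seq_len(nrow(parts)), function(e) {
        max(0, min(del_e, parts$end[e]) - max(del_s, parts$start[e]) + 1)
      }, 0))
      return(if (n_del %% 3 != 0) eff("frameshift_variant", "high")
             else eff("inframe_deletion", "moderate"))
    }
  }
  in_exon <- any(pos >= parts$start & pos <= parts$end)
  if (!in_exon) {
    # intronic: within 2 bp of an exon boundary is a splice site
    for (e in seq_len(nrow(parts) - 1L)) {
      int_s <- parts$end[e] + 1L; int_e <- parts$start[e + 1L] - 1L
      if (pos < int_s || pos > int_e) next
      at5 <- pos <= int_s + 1L   # first 2 intron bases (donor on + strand)
      at3 <- pos >= int_e - 1L
      if (at5) return(eff(if (strand == "+") "splice_donor_variant"
                          else "splice_acceptor_variant", "high"))
      if (at3) return(eff(if (strand == "+") "splice_acceptor_variant"
                          else "splice_donor_variant", "high"))
      return(eff("intron_variant", "modifier"))
    }
    return(eff("intron_variant", "modifier"))
  }
  if (is_ins) {
    n_ins <- nchar(alt) - nchar(ref)
    return(if (n_ins %% 3L != 0L) eff("frameshift_variant", "high")
           else eff("inframe_insertion", "moderate"))
  }
  if (is_del) return(eff("inframe_deletion", "moderate"))  # edge: anchor in exon, span intronic
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    return(eff("missense_variant", "moderate"))  # complex substitution
  cpos <- .cds_offset(pos, parts, strand)
  base_new <- if (strand == "+") alt else .revcomp1(alt)
  codon_i <- (cpos - 1L) %/% 3L + 1L
  within <- (cpos - 1L) %% 3L + 1L
  old_codon <- substr(cds_seq, 3L * (codon_i - 1L) + 1L, 3L * codon_i)
  new_codon <- old_codon
  substr(new_codon, within, within) <- base_new
  code <- Biostrings::GENETIC_CODE
  old_aa <- unname(code[old_codon]); new_aa <- unname(code[new_codon])
  n_codons <- nchar(cds_seq) %/% 3L
  if (codon_i == 1L && new_codon != "ATG")
    return(eff("start_lost", "high"))
  if (old_aa != "*" && new_aa == "*")
    return(eff("stop_gained", "high"))
  if (old_aa == "*" && new_aa != "*")
    return(eff("stop_lost", "high"))
  if (old_aa == new_aa) return(eff("synonymous_variant", "low"))
  eff("missense_variant", "moderate")
}

#' Effect classification for a variant table
#'
#' Uses pre-annotated ANN-style strings when an `ann` column (or
#' `effect`/`impact` columns) is present; otherwise applies the built-in
#' caller [classify_impact()] against the supplied gene models.
#'
#' @param variants variant data frame (contig, pos, ref, alt, gene_id).
#' @param genes gene table with `cds_seq` (needed only for the built-in
#'   caller).
#' @param cds CDS part table (needed only for the built-in caller).
#' @return `variants` with `effect` and `impact` columns filled.
#' @export
variant_effects <- function(variants, genes = NULL, cds = NULL) {
  if (all(c("effect", "impact") %in% names(variants))) {
    variants$impact <- tolower(variants$impact)
    return(variants)
  }
  if ("ann" %in% names(variants)) {
    ai <- ann_impact(variants$ann)
    variants$effect <- ai$effect
    variants$impact <- ai$impact
    return(variants)
  }
  if (is.null(genes) || is.null(cds))
    stop("no annotation column; gene models and CDS parts required")
  res <- lapply(seq_len(nrow(variants)), function(i) {
    gid <- variants$gene_id[i]
    g <- genes[genes$gene_id == gid, , drop = FALSE]
    if (!nrow(g)) return(data.frame(effect = "intergenic_variant",
                                    impact = "modifier"))
    classify_impact(variants[i, ], g, cds[cds$gene_id == gid, , drop = FALSE],
                    g$cds_seq)
  })
  res <- do.call(rbind, res)
  variants$effect <- res$effect
  variants$impact <- res$impact
  variants
}

#' Stage-wise differential-expression flags
#'
#' A gene is flagged DEG at a stage when its adjusted p-value is below
#' `padj_cut` and |log2 fold change| exceeds `lfc_cut`; a missing
#' gene-stage record means not DEG.
#'
#' @param deg data frame gene_id, stage, log2fc, padj (one record per
#'   gene per stage).
#' @param padj_cut FDR-adjusted p-value cutoff (default 0.05).
#' @param lfc_cut |log2 fold change| cutoff (default 1).
#' @param stages stages to tabulate (default the stages present).
#' @return logical matrix genes x stages.
#' @export
deg_flags <- function(deg, padj_cut = 0.05, lfc_cut = 1, stages = NULL) {
  if (any(deg$padj < 0 | deg$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  if (anyDuplicated(deg[, c("gene_id", "stage")]))
    stop("duplicate gene-stage records")
  stages <- stages %||% sort(unique(deg$stage))
  genes <- unique(deg$gene_id)
  flags <- matrix(FALSE, length(genes), length(stages),
                  dimnames = list(genes, as.character(stages)))
  hit <- !is.na(deg$padj) & !is.na(deg$log2fc) &
    deg$padj < padj_cut & abs(deg$log2fc) > lfc_cut
  idx <- cbind(match(deg$gene_id, genes),
               match(deg$stage, stages))
  ok <- hit & !is.na(idx[, 2])
  flags[idx[ok, , drop = FALSE]] <- TRUE
  flags
}

#' Screen candidate genes by variant and expression evidence
#'
#' A gene passes when it carries at least one co-segregating high-impact
#' variant AND is DEG at one or more of the case stages AND is not DEG
#' at the control stage. Evidence is recorded for every input gene,
#' passing or not.
#'
#' @param genes gene table restricted to the qSC segments (gene_id at
#'   minimum).
#' @param coseg_high_variants co-segregating variant table with `impact`
#'   filled (only rows with impact "high" count).
#' @param flags DEG flag matrix from [deg_flags()].
#' @param control_stage stage used as control (default 5).
#' @param case_stages late stages (default 10/15/20/25).
#' @return data frame gene_id, n_coseg_high, deg_control, deg_stages,
#'   passes.
#' @export
screen_candidates <- function(genes, coseg_high_variants, flags,
                              control_stage = 5,
                              case_stages = c(10, 15, 20, 25)) {
  hv <- coseg_high_variants[tolower(coseg_high_variants$impact) == "high", ,
                            drop = FALSE]
  n_high <- table(factor(hv$gene_id, levels = genes$gene_id))
  ctl <- as.character(control_stage)
  cs <- as.character(case_stages)
  cs <- cs[cs %in% colnames(flags)]
  get_flag <- function(gid, st) {
    if (gid %in% rownames(flags) && st %in% colnames(flags))
      flags[gid, st] else FALSE
  }
  ev <- do.call(rbind, lapply(genes$gene_id, function(gid) {
    late <- vapply(cs, function(st) get_flag(gid, st), TRUE)
    data.frame(gene_id = gid,
               n_coseg_high = as.integer(n_high[gid]),
               deg_control = get_flag(gid, ctl),
               deg_stages = paste(cs[late], collapse = ","),
               passes = as.integer(n_high[gid]) >= 1L && any(late) &&
                 !get_flag(gid, ctl),
               stringsAsFactors = FALSE)
  }))
  rownames(ev) <- NULL
  ev
}

#' Venn-style counts for the candidate screen
#' @param evidence output of [screen_candidates()].
#' @return list: genes with co-segregating high-impact variants, genes
#'   passing the DEG filter (late DEG, not at control), and the
#'   intersection (the candidates).
#' @export
candidate_summary <- function(evidence) {
  deg_ok <- nchar(evidence$deg_stages) > 0 & !evidence$deg_control
  list(n_high_impact = sum(evidence$n_coseg_high >= 1),
       n_deg_filtered = sum(deg_ok),
       n_candidates = sum(evidence$passes))
}
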