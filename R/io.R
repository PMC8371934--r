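#' Write a minimal GT-only VCF for a simulated cross
#'
#' Emits parents plus progeny as a biallelic, GT-only VCF. Parent 1 (the
#' "A" parent) is homozygous reference at every marker and parent 2
#' homozygous alternate, matching the informative-site convention of the
#' coding stage. Coordinates are 1-based as in VCF.
#'
#' @param sim an `f2_sim` object from [simulate_f2()].
#' @param path output file.
#' @param parent1,parent2 sample names for the two parents.
#' @return `path`, invisibly.
#' @export
write_sim_vcf <- function(sim, path, parent1 = "P1", parent2 = "P2") {
  gm <- sim$geno
  ids <- colnames(gm$codes)
  gt_of <- c(A = "0/0", H = "0/1", B = "1/1")
  prog <- matrix(gt_of[gm$codes], nrow(gm$codes), ncol(gm$codes))
  prog[is.na(gm$codes)] <- "./."
  n <- nrow(gm$markers)
  refalt <- matrix(c("A", "G"), n, 2, byrow = TRUE)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", parent1, parent2, ids), collapse = "\t"),
    paste(gm$markers$contig, gm$markers$pos,
          rownames(gm$codes), refalt[, 1], refalt[, 2], ".", "PASS", ".",
          "GT", "0/0", "1/1",
          apply(prog, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write/read a phenotype table (one row per individual)
#' @param pheno data frame with an `id` column plus one column per trait.
#' @param path TSV file.
#' @return `path` ([write_pheno_tsv()]) or the phenotype data frame.
#' @export
write_pheno_tsv <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @param average_replicates if `TRUE` and ids repeat, replicate rows are
#'   averaged per individual (colorimeter replicates).
#' @export
read_pheno_tsv <- function(path, average_replicates = TRUE) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  ph <- read.delim(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(ph)) stop("phenotype table needs an 'id' column")
  if (average_replicates && anyDuplicated(ph$id)) {
    num <- vapply(ph, is.numeric, TRUE)
    ag <- aggregate(ph[num], by = list(id = ph$id), FUN = mean)
    ph <- ag[match(unique(ph$id), ag$id), , drop = FALSE]
    rownames(ph) <- NULL
  }
  ph
}

#' Write the simulation truth as JSON (test oracle)
#' @param sim an `f2_sim` object.
#' @param path output JSON file.
#' @export
write_truth_json <- function(sim, path) {
  tr <- sim$truth
  jsonlite::write_json(list(
    marker_id = rownames(tr$genotypes),
    marker_cM = tr$marker_cM,
    genotypes = apply(tr$genotypes, 2, function(col) {
      col[is.na(col)] <- "-"; paste(col, collapse = "")
    }),
    qtl_spec = tr$qtl_spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write/read the coded A/H/B marker matrix as TSV
#'
#' Rows are markers (id `contig-pos`), columns individuals, symbols
#' `A`/`H`/`B`/`-`.
#' @param gm a [geno_matrix()].
#' @param path TSV file.
#' @export
write_geno_tsv <- function(gm, path) {
  m <- gm$codes
  m[is.na(m)] <- "-"
  df <- data.frame(marker = rownames(m), contig = gm$markers$contig,
                   pos = gm$markers$pos, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  codes <- as.matrix(df[, -(1:3), drop = FALSE])
  codes[codes == "-"] <- NA_character_
  rownames(codes) <- df$marker
  geno_matrix(df[, c("contig", "pos")], codes)
}

#' Write simulated gene models as GFF3
#'
#' Emits gene, mRNA and CDS features (1-based inclusive coordinates) for
#' the output of [simulate_annotation()].
#' @param ann a [simulate_annotation()] result.
#' @param path output GFF3 file.
#' @export
write_gff3 <- function(ann, path) {
  g <- ann$genes; cds <- ann$cds
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    parts <- cds[cds$gene_id == gid, , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;product=%s",
              g$contig[i], g$start[i], g$end[i], g$strand[i], gid, gid,
              gsub("[;=]", "_", g$annotation[i])),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$contig[i], g$start[i], g$end[i], g$strand[i], gid, gid),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
              parts$contig, parts$start, parts$end, parts$strand, gid, gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Returns gene spans and CDS parts using `rtracklayer` for parsing.
#' @param path GFF3 file.
#' @return list with data frames `genes` (gene_id, contig, start, end,
#'   strand, annotation) and `cds` (gene_id, contig, start, end, strand).
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  gene <- df[df$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = as.character(gene$ID),
    contig = as.character(gene$seqnames),
    start = gene$start, end = gene$end,
    strand = as.character(gene$strand),
    annotation = if ("product" %in% names(gene))
      as.character(gene$product) else NA_character_,
    stringsAsFactors = FALSE)
  cdsr <- df[df$type == "CDS", , drop = FALSE]
  parent <- vapply(cdsr$Parent, function(p) as.character(p)[1], "")
  cds <- data.frame(
    gene_id = sub("\\.t1$", "", parent),
    contig = as.character(cdsr$seqnames),
    start = cdsr$start, end = cdsr$end,
    strand = as.character(cdsr$strand), stringsAsFactors = FALSE)
  list(genes = genes, cds = cds)
}

#' Write/read per-stage differential-expression tables
#' @param deg data frame gene_id, stage, log2fc, padj.
#' @param dir output directory; one `deg_stage<stage>.tsv` per stage.
#' @return written paths / combined data frame.
#' @export
write_deg_tables <- function(deg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in sort(unique(deg$stage))) {
    p <- file.path(dir, sprintf("deg_stage%02d.tsv", s))
    write.table(deg[deg$stage == s, ], p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_deg_tables
#' @param paths DEG TSV files to combine.
#' @export
read_deg_tables <- function(paths) {
  do.call(rbind, lapply(paths, read.delim, stringsAsFactors = FALSE))
}

#' Write/read the parent-genotyped variant table
#' @param variants variant data frame (see [simulate_annotation()]).
#' @param path TSV file.
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
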