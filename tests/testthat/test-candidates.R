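test_that("gene-segment overlap uses the 1 bp rule and skips absent contigs", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                      contig = c("C1", "C1", "C1", "C9"),
                      start = c(100L, 995L, 2000L, 100L),
                      end = c(500L, 1005L, 3000L, 500L))
  segments <- data.frame(contig = "C1", start_bp = 400L, end_bp = 1000L)
  hit <- genes_in_segments(genes, segments)
  expect_setequal(hit$gene_id, c("g1", "g2"))   # g2 overlaps by boundary
  one_bp <- data.frame(contig = "C1", start_bp = 500L, end_bp = 500L)
  expect_equal(genes_in_segments(genes, one_bp)$gene_id, "g1")
})

test_that("co-segregation keeps black-unique homozygous-alternate variants only", {
  v <- data.frame(contig = "C1", pos = 1:5, ref = "A", alt = "G",
                  gene_id = sprintf("g%d", 1:5),
                  gt_black = c("1/1", "1/1", "0/1", "1/1", "1/1"),
                  gt_white = c("0/0", "1/1", "0/0", "0/0", "./."),
                  gt_ref = c("0/0", "0/0", "0/0", "0/1", "0/0"))
  kept <- coseg_screen(v)
  expect_equal(kept$gene_id, "g1")
  # invariant to any progeny columns tacked on
  v$F2_001 <- "0/1"
  expect_equal(coseg_screen(v)$gene_id, "g1")
})

test_that("the minimal effect caller classifies indels, splice and stop changes", {
  gene <- data.frame(gene_id = "g", contig = "C1", start = 101L,
                     end = 400L, strand = "+")
  cds <- data.frame(start = c(101L, 301L), end = c(200L, 400L))
  # CDS: 200 bp total... make it 201 bp? keep multiple of 3: 100+100=200 no.
  cds <- data.frame(start = c(101L, 302L), end = c(200L, 400L))  # 100+99=199
  cds <- data.frame(start = c(101L, 301L), end = c(199L, 401L))  # 99+101=200
  cds <- data.frame(start = c(101L, 301L), end = c(199L, 402L))  # 99+102=201
  set.seed(3)
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  cds_seq <- paste0("ATG", paste(sample(non_stop, 65, TRUE), collapse = ""),
                    "TAA")
  gene$end <- 402L
  v <- function(pos, ref, alt) list(contig = "C1", pos = pos, ref = ref,
                                    alt = alt)
  # 2 bp deletion inside CDS -> frameshift
  r <- classify_impact(v(150, "AGG", "A"), gene, cds, cds_seq)
  expect_equal(r$effect, "frameshift_variant"); expect_equal(r$impact, "high")
  # 3 bp deletion -> inframe (moderate)
  r <- classify_impact(v(150, "AGGC", "A"), gene, cds, cds_seq)
  expect_equal(r$impact, "moderate")
  # 1 bp insertion -> frameshift
  r <- classify_impact(v(150, "A", "AT"), gene, cds, cds_seq)
  expect_equal(r$effect, "frameshift_variant")
  # deletion removing a whole exon -> exon loss
  r <- classify_impact(v(250, paste(rep("A", 160), collapse = ""), "A"),
                       gene, cds, cds_seq)
  expect_equal(r$effect, "exon_loss_variant"); expect_equal(r$impact, "high")
  # splice donor (first 2 intron bases on + strand)
  r <- classify_impact(v(200, "A", "G"), gene, cds, cds_seq)
  expect_equal(r$effect, "splice_donor_variant")
  r <- classify_impact(v(300, "A", "G"), gene, cds, cds_seq)
  expect_equal(r$effect, "splice_acceptor_variant")
  # deep intron -> modifier
  r <- classify_impact(v(250, "A", "G"), gene, cds, cds_seq)
  expect_equal(r$impact, "modifier")
  # outside the gene -> modifier
  r <- classify_impact(v(50, "A", "G"), gene, cds, cds_seq)
  expect_equal(r$effect, "intergenic_variant")
  # start codon disruption
  r <- classify_impact(v(102, substr(cds_seq, 2, 2), "C"), gene, cds, cds_seq)
  expect_equal(r$effect, "start_lost"); expect_equal(r$impact, "high")
  # stop codon destruction (last codon TAA; genomic 400..402)
  r <- classify_impact(v(401, "A", "C"), gene, cds, cds_seq)
  expect_equal(r$effect, "stop_lost")
})

test_that("SNP classification agrees with whole-CDS translation on every substitution", {
  # brute-force oracle: mutate the full CDS, translate with Biostrings,
  # and classify from the protein change
  set.seed(9)
  cfg <- one_trait_config(n_chrom = 2, len = 60, seed = 9)
  ann <- simulate_annotation(cfg, 10, 2)
  code <- Biostrings::GENETIC_CODE
  for (gi in seq_len(nrow(ann$genes))) {
    g <- ann$genes[gi, ]
    parts <- ann$cds[ann$cds$gene_id == g$gene_id, , drop = FALSE]
    seq <- g$cds_seq
    # sample CDS positions (full enumeration on the first two genes)
    cps <- if (gi <= 2) seq_len(min(nchar(seq), 60)) else
      sample(nchar(seq), 15)
    for (cp in cps) {
      # genomic position of CDS offset cp
      lens <- parts$end - parts$start + 1L
      if (g$strand == "+") {
        cum <- cumsum(lens); e <- which(cp <= cum)[1]
        gpos <- parts$start[e] + (cp - c(0L, cum)[e] - 1L)
      } else {
        ord <- rev(seq_len(nrow(parts))); cum <- cumsum(lens[ord])
        k <- which(cp <= cum)[1]; e <- ord[k]
        gpos <- parts$end[e] - (cp - c(0L, cum)[k] - 1L)
      }
      oldb_cds <- substr(seq, cp, cp)
      oldb_gen <- if (g$strand == "+") oldb_cds else
        chartr("ACGT", "TGCA", oldb_cds)
      for (nb in setdiff(c("A", "C", "G", "T"), oldb_gen)) {
        got <- classify_impact(list(contig = g$contig, pos = gpos,
                                    ref = oldb_gen, alt = nb),
                               g, parts, seq)
        nb_cds <- if (g$strand == "+") nb else chartr("ACGT", "TGCA", nb)
        mut <- seq
        substr(mut, cp, cp) <- nb_cds
        aa_old <- as.character(Biostrings::translate(
          Biostrings::DNAString(seq)))
        aa_new <- as.character(Biostrings::translate(
          Biostrings::DNAString(mut)))
        ci <- (cp - 1) %/% 3 + 1
        expected <- if (ci == 1 && substr(mut, 1, 3) != "ATG") "start_lost"
          else if (substr(aa_old, ci, ci) != "*" &&
                     substr(aa_new, ci, ci) == "*") "stop_gained"
          else if (substr(aa_old, ci, ci) == "*" &&
                     substr(aa_new, ci, ci) != "*") "stop_lost"
          else if (aa_new == aa_old) "synonymous_variant"
          else "missense_variant"
        expect_equal(got$effect, expected,
                     info = sprintf("%s cds %d -> %s", g$gene_id, cp, nb))
      }
    }
  }
})

test_that("ANN-style annotation strings map straight to impact classes", {
  ai <- ann_impact(c("G|stop_gained|HIGH|gene1|x|y",
                     "T|missense_variant|MODERATE|gene2",
                     "A|synonymous_variant|LOW|gene3"))
  expect_equal(ai$effect, c("stop_gained", "missense_variant",
                            "synonymous_variant"))
  expect_equal(ai$impact, c("high", "moderate", "low"))
})

test_that("DEG flags apply both cutoffs and reject duplicates", {
  deg <- data.frame(gene_id = rep("g1", 3), stage = c(5, 10, 15),
                    log2fc = c(1.2, 0.8, 3.0), padj = c(0.04, 0.04, 0.06))
  f <- deg_flags(deg)
  expect_true(f["g1", "5"])      # padj 0.04, |lfc| 1.2 -> DEG
  expect_false(f["g1", "10"])    # fails fold-change
  expect_false(f["g1", "15"])    # fails FDR
  expect_error(deg_flags(rbind(deg, deg[1, ])), "duplicate")
  expect_error(deg_flags(transform(deg, padj = c(-0.1, 0.5, 0.5))),
               "padj")
})

test_that("the screen passes exactly genes with variant plus late-DEG evidence", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"))
  vars <- data.frame(gene_id = c("g1", "g2", "g3"),
                     impact = c("high", "high", "moderate"))
  flags <- matrix(FALSE, 3, 5,
                  dimnames = list(c("g1", "g2", "g3"),
                                  c("5", "10", "15", "20", "25")))
  flags["g1", "15"] <- TRUE                 # late only -> passes
  flags["g2", c("5", "15")] <- TRUE         # also at control -> fails
  flags["g3", "20"] <- TRUE                 # no high-impact variant -> fails
  ev <- screen_candidates(genes, vars, flags)
  expect_equal(ev$passes, c(TRUE, FALSE, FALSE))
  expect_equal(ev$n_coseg_high, c(1L, 1L, 0L))
  # monotone: dropping a condition never shrinks the passing set
  pass_full <- ev$passes
  no_ctrl <- ev$n_coseg_high >= 1 & nchar(ev$deg_stages) > 0
  no_var <- nchar(ev$deg_stages) > 0 & !ev$deg_control
  expect_true(all(pass_full <= no_ctrl))
  expect_true(all(pass_full <= no_var))
})

test_that("the full screen isolates planted candidates from decoys", {
  cfg <- one_trait_config(n_chrom = 2, len = 60, seed = 5)
  ann <- simulate_annotation(cfg, 25, 5)
  segs <- data.frame(contig = c("C01", "C02"), start_bp = 1L,
                     end_bp = 15000000L)
  in_seg <- genes_in_segments(ann$genes, segs)
  coseg <- coseg_screen(ann$variants)
  flags <- deg_flags(ann$deg)
  ev <- screen_candidates(in_seg, coseg, flags)
  expect_setequal(ev$gene_id[ev$passes], ann$planted)
  # brute-force per-gene evaluation of the three conditions
  for (i in seq_len(nrow(ev))) {
    gid <- ev$gene_id[i]
    c1 <- any(coseg$gene_id == gid & tolower(coseg$impact) == "high")
    c2 <- any(flags[gid, c("10", "15", "20", "25")])
    c3 <- !flags[gid, "5"]
    expect_equal(ev$passes[i], c1 && c2 && c3, info = gid)
  }
  vsum <- candidate_summary(ev)
  expect_equal(vsum$n_candidates, 5)
})
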