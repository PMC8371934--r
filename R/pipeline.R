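#' Configuration for the full mapping pipeline
#'
#' File paths plus every numeric parameter of the stages, at the study's
#' settings by default: 100 bp redundancy spacing, 15-marker correction
#' window, 20/20/40 segregation-distortion thresholds, linkage LOD 12,
#' 100-marker minimum group size, 1 cM IM walk step, 2 cM CIM step with
#' a 10 cM cofactor window, 1,000 permutations at alpha 0.05, 5 cM gap
#' threshold, 2 cM cluster gap, DEG cutoffs padj < 0.05 and |log2FC| > 1
#' with 5 DAF as the control stage.
#'
#' @param vcf joint-called VCF of parents + progeny.
#' @param pheno phenotype TSV (id, one column per trait).
#' @param gff optional GFF3 gene models (candidate screen).
#' @param variants optional parent-genotyped variant TSV (candidate
#'   screen).
#' @param deg_files optional per-stage DEG TSVs (candidate screen).
#' @param parent1,parent2 VCF sample names of the A ("white") and B
#'   ("black") parent.
#' @param traits traits to scan (default: all phenotype columns).
#' @param min_gap_bp,window,min_hom,min_het,lod_threshold,min_group_size
#'   bin-map and grouping parameters.
#' @param im_step,cim_step,cim_window,max_cofactors,n_perm,alpha scan
#'   parameters.
#' @param gap_threshold,cluster_gap interval parameters (cM).
#' @param padj_cut,lfc_cut,control_stage,case_stages DEG screen
#'   parameters.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` list; overrides of the defaults are
#'   recorded in attribute `"overrides"`.
#' @export
pipeline_config <- function(vcf, pheno, gff = NULL, variants = NULL,
                            deg_files = NULL,
                            parent1 = "P1", parent2 = "P2",
                            traits = NULL,
                            min_gap_bp = 100, window = 15,
                            min_hom = 20, min_het = 40,
                            lod_threshold = 12, min_group_size = 100,
                            im_step = 1, cim_step = 2, cim_window = 10,
                            max_cofactors = 5, n_perm = 1000, alpha = 0.05,
                            gap_threshold = 5, cluster_gap = 2,
                            padj_cut = 0.05, lfc_cut = 1,
                            control_stage = 5,
                            case_stages = c(10, 15, 20, 25),
                            seed = 1L) {
  cfg <- as.list(environment())
  defaults <- formals(pipeline_config)
  param_names <- setdiff(names(defaults),
                         c("vcf", "pheno", "gff", "variants", "deg_files",
                           "parent1", "parent2", "traits", "seed"))
  overrides <- param_names[vapply(param_names, function(p) {
    !identical(cfg[[p]], eval(defaults[[p]]))
  }, TRUE)]
  structure(cfg, class = "pipeline_config", overrides = overrides)
}

#' Run the complete analysis
#'
#' Executes coding -> binning -> map construction -> per-trait QTL scans
#' (IM and CIM with permutation thresholds) -> interval consolidation ->
#' candidate screen -> phenotype summary, writing every stage output
#' plus a JSON run manifest (parameters, seed, per-stage record counts)
#' into `out_dir`. Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results (map,
#'   scans, qtls, intervals, segments, candidates, phenotype summary,
#'   manifest).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("binmapqtl")),
                   seed = config$seed,
                   parameters = config[!(names(config) %in%
                                           c("vcf", "pheno", "gff", "variants",
                                             "deg_files"))],
                   overrides = attr(config, "overrides"),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # coding
  if (!file.exists(config$vcf))
    stop("pipeline stage 'coding' failed: VCF not found: ", config$vcf,
         call. = FALSE)
  if (is.null(config$pheno) || !file.exists(config$pheno))
    stop("pipeline stage 'phenostats/qtlscan' failed: phenotype file not found: ",
         config$pheno %||% "<missing>", call. = FALSE)
  vs <- stage("coding", read_cross_vcf(config$vcf, config$parent1,
                                       config$parent2))
  inf <- stage("coding", select_informative_sites(vs))
  gm <- stage("coding", code_genotypes(inf))
  write_geno_tsv(gm, file.path(out_dir, "genotypes_abh.tsv"))
  note("coding", sites_in = nrow(vs$sites), informative = nrow(inf$sites),
       filter_log = as.list(attr(inf, "filter_log")))

  # binning
  reps <- stage("binning", collapse_redundant(gm, config$min_gap_bp))
  corr <- stage("binning", window_correct(reps, config$window))
  bins <- stage("binning", build_bins(corr))
  kept <- stage("binning", filter_distorted(bins, config$min_hom,
                                            config$min_het))
  bt <- kept$bins
  bt_codes <- apply(kept$codes, 1, function(r) {
    r[is.na(r)] <- "-"; paste(r, collapse = "")
  })
  write.table(cbind(bt, consensus = bt_codes),
              file.path(out_dir, "bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("binning", markers_in = nrow(gm$codes),
       representatives = nrow(reps$codes),
       corrected_calls = attr(corr, "n_corrected"),
       imputed_calls = attr(corr, "n_imputed"),
       bins = nrow(bins$bins), bins_kept = nrow(kept$bins),
       bins_distorted = nrow(bins$bins) - nrow(kept$bins))

  # genetic map
  map <- stage("genmap", group_bins(kept, config$lod_threshold,
                                    config$min_group_size))
  map <- stage("genmap", space_map(map))
  write_map_tsv(map, file.path(out_dir, "map.tsv"))
  ms <- map_stats(map, config$gap_threshold)
  write.table(ms$per_group, file.path(out_dir, "map_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  note("genmap", groups = length(unique(map$table$group)),
       bins = nrow(map$table), total_cM = ms$totals$length_cM)

  # phenotypes
  ph <- stage("phenostats", read_pheno_tsv(config$pheno))
  traits <- config$traits %||% setdiff(names(ph)[vapply(ph, is.numeric, TRUE)],
                                       "id")
  psum <- stage("phenostats", summarize_phenotypes(ph, traits))
  write.table(psum$summary, file.path(out_dir, "phenotype_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.csv(psum$correlation, file.path(out_dir, "phenotype_correlation.csv"))
  note("phenostats", individuals = nrow(ph), traits = length(traits))

  # QTL scans per trait
  scans <- list(); qtls <- list()
  for (ti in seq_along(traits)) {
    t <- traits[ti]
    seed_t <- config$seed + 100L * ti
    thr <- stage("qtlscan", permutation_threshold(
      map, ph, t, n_perm = config$n_perm, alpha = config$alpha,
      seed = seed_t, step = config$im_step))
    s_im <- stage("qtlscan", scan_im(map, ph, t, step = config$im_step,
                                     threshold = thr))
    cof <- stage("qtlscan", select_cofactors(map, ph, t,
                                             config$max_cofactors))
    s_cim <- stage("qtlscan", scan_cim(map, ph, t, cof,
                                       step = config$cim_step,
                                       window = config$cim_window,
                                       threshold = thr))
    q_im <- stage("qtlscan", call_qtls(s_im, map, ph))
    q_cim <- stage("qtlscan", call_qtls(s_cim, map, ph))
    scans[[t]] <- rbind(as.data.frame(s_im), as.data.frame(s_cim))
    qtls[[t]] <- rbind(q_im, q_cim)
    jsonlite::write_json(list(trait = t, threshold = thr,
                              n_perm = config$n_perm,
                              alpha = config$alpha),
                         file.path(out_dir, sprintf("threshold_%s.json", t)),
                         auto_unbox = TRUE, digits = NA)
  }
  scan_tab <- do.call(rbind, scans)
  qtl_tab <- do.call(rbind, qtls)
  rownames(scan_tab) <- rownames(qtl_tab) <- NULL
  write.table(scan_tab, file.path(out_dir, "scans.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(qtl_tab, file.path(out_dir, "qtls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("qtlscan", traits = length(traits), qtls = nrow(qtl_tab))

  # interval consolidation
  segments <- NULL; merged <- NULL; clustered <- NULL
  if (nrow(qtl_tab)) {
    merged <- stage("intervals", merge_overlapping(qtl_intervals(qtl_tab)))
    clustered <- stage("intervals", cluster_adjacent(merged,
                                                     config$cluster_gap))
    segments <- do.call(rbind, lapply(seq_len(nrow(clustered)), function(i) {
      stage("intervals", to_physical(clustered[i, ], map))
    }))
    write.table(merged, file.path(out_dir, "intervals_merged.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(clustered, file.path(out_dir, "intervals_qsc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_segments_bed(segments, file.path(out_dir, "qsc_segments.bed"))
  }
  note("intervals", qtls_in = nrow(qtl_tab),
       merged = if (is.null(merged)) 0L else nrow(merged),
       qsc = if (is.null(clustered)) 0L else nrow(clustered))

  # candidate screen (only when annotation inputs are configured)
  candidates <- NULL
  if (!is.null(config$gff) && !is.null(config$variants) &&
      !is.null(config$deg_files) && !is.null(segments)) {
    gene_models <- stage("candidates", read_gff_genes(config$gff))
    vars <- stage("candidates", read_variants_tsv(config$variants))
    deg <- stage("candidates", read_deg_tables(config$deg_files))
    in_seg <- stage("candidates", genes_in_segments(gene_models$genes,
                                                    segments))
    coseg <- stage("candidates", coseg_screen(vars))
    coseg <- stage("candidates", variant_effects(coseg))
    coseg <- coseg[coseg$gene_id %in% in_seg$gene_id, , drop = FALSE]
    flags <- stage("candidates", deg_flags(deg, config$padj_cut,
                                           config$lfc_cut))
    candidates <- stage("candidates", screen_candidates(
      in_seg, coseg, flags, config$control_stage, config$case_stages))
    write.table(candidates, file.path(out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    vsum <- candidate_summary(candidates)
    jsonlite::write_json(vsum, file.path(out_dir, "candidate_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("candidates", genes_in_segments = nrow(in_seg),
         coseg_high = sum(tolower(coseg$impact) == "high"),
         candidates = sum(candidates$passes))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(map = map, scans = scan_tab, qtls = qtl_tab,
                 intervals = clustered, segments = segments,
                 candidates = candidates, pheno_summary = psum,
                 manifest = manifest))
}
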