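#' Coded A/H/B genotype matrix
#'
#' Container for coded genotype calls: a marker table (contig, 1-based bp
#' position) and a markers x individuals character matrix with values
#' `"A"` (parent-1 homozygote), `"H"` (heterozygote), `"B"` (parent-2
#' homozygote) or `NA` (missing). Markers are sorted by contig (order of
#' appearance) and position.
#'
#' @param markers data frame with columns `contig` and `pos`.
#' @param codes character matrix, one row per marker, one column per
#'   individual.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(markers, codes) {
  codes <- as.matrix(codes)
  if (nrow(markers) != nrow(codes))
    stop("markers and codes disagree in marker count")
  bad <- !is.na(codes) & !(codes %in% CODE_LEVELS)
  if (any(bad)) stop("codes must be A, H, B or NA")
  lev <- unique(markers$contig)
  o <- order(match(markers$contig, lev), markers$pos)
  markers <- markers[o, c("contig", "pos"), drop = FALSE]
  codes <- codes[o, , drop = FALSE]
  rownames(markers) <- NULL
  rownames(codes) <- sprintf("%s-%d", markers$contig, markers$pos)
  structure(list(markers = markers, codes = codes), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d individuals on %d contig(s); %.1f%% missing\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$markers$contig)),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

# diploid GT string -> alt-allele dosage (0/1/2), NA if missing;
# multiallelic (allele index > 1) -> NA_integer_ handled by caller
.gt_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & grepl("^[0-9]+[/|][0-9]+$", gt)
  parts <- strsplit(gt[ok], "[/|]")
  a1 <- as.integer(vapply(parts, `[`, "", 1L))
  a2 <- as.integer(vapply(parts, `[`, "", 2L))
  d <- a1 + a2
  d[a1 > 1 | a2 > 1] <- NA_integer_  # third allele: degrade to missing
  out[ok] <- d
  out
}

#' Read joint-called genotypes for parents and progeny from a VCF
#'
#' Extracts the GT field only. Multiallelic records are skipped with a
#' warning (A/H/B coding is defined for biallelic sites only).
#'
#' @param path VCF file (plain text or gzipped).
#' @param parent1,parent2 sample names of the two inbred parents; parent 1
#'   is the "A" parent, parent 2 the "B" parent.
#' @return a `variant_sites` list: `sites` data frame (contig, pos, ref,
#'   alt, p1, p2 dosages) and `progeny` dosage matrix (sites x progeny).
#' @export
read_cross_vcf <- function(path, parent1, parent2) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!all(c(parent1, parent2) %in% samples))
    stop("parent samples not found in VCF")
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  prog_names <- setdiff(samples, c(parent1, parent2))
  dos <- apply(gt, 2, .gt_dosage)
  sites <- data.frame(contig = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      p1 = dos[, parent1], p2 = dos[, parent2],
                      stringsAsFactors = FALSE)
  progeny <- dos[, prog_names, drop = FALSE]
  lev <- unique(sites$contig)
  o <- order(match(sites$contig, lev), sites$pos)
  structure(list(sites = sites[o, , drop = FALSE],
                 progeny = progeny[o, , drop = FALSE]),
            class = "variant_sites")
}

#' Keep sites informative for A/H/B coding
#'
#' Retains sites at which both parents are non-missing, homozygous, and
#' fixed for different alleles; all other sites (heterozygous or missing
#' parent, monomorphic between parents) cannot be phase-assigned in the
#' cross and are dropped.
#'
#' @param vs a `variant_sites` object from [read_cross_vcf()].
#' @return a filtered `variant_sites` object; the number of removals per
#'   reason is attached as attribute `"filter_log"`.
#' @export
select_informative_sites <- function(vs) {
  stopifnot(inherits(vs, "variant_sites"))
  s <- vs$sites
  if (is.unsorted(order(match(s$contig, unique(s$contig)), s$pos)))
    stop("sites must be sorted by contig and position")
  missing_parent <- is.na(s$p1) | is.na(s$p2)
  het_parent <- !missing_parent & (s$p1 == 1L | s$p2 == 1L)
  monomorphic <- !missing_parent & !het_parent & s$p1 == s$p2
  keep <- !(missing_parent | het_parent | monomorphic)
  out <- structure(list(sites = s[keep, , drop = FALSE],
                        progeny = vs$progeny[keep, , drop = FALSE]),
                   class = "variant_sites")
  attr(out, "filter_log") <- c(missing_parent = sum(missing_parent),
                               het_parent = sum(het_parent),
                               monomorphic = sum(monomorphic),
                               kept = sum(keep))
  out
}

#' Code progeny genotypes as A/H/B relative to the parents
#'
#' At each informative site a progeny call equal to parent 1's homozygote
#' is coded `A`, equal to parent 2's `B`, heterozygous `H`; missing or
#' inconsistent calls (an allele absent from both parents) degrade to
#' missing and are counted in the attached `"coding_log"`.
#'
#' @param vs informative `variant_sites` (see
#'   [select_informative_sites()]).
#' @return a [geno_matrix()].
#' @export
code_genotypes <- function(vs) {
  stopifnot(inherits(vs, "variant_sites"))
  s <- vs$sites
  if (any(is.na(s$p1) | is.na(s$p2) | s$p1 == 1L | s$p2 == 1L |
            s$p1 == s$p2))
    stop("sites not filtered; run select_informative_sites() first")
  prog <- vs$progeny
  codes <- matrix(NA_character_, nrow(prog), ncol(prog),
                  dimnames = dimnames(prog))
  obs <- !is.na(prog)
  codes[obs & prog == 1L] <- "H"
  codes[obs & prog == s$p1] <- "A"   # p1 recycles down columns
  codes[obs & prog == s$p2] <- "B"
  n_missing <- sum(is.na(prog))
  n_inconsistent <- sum(!is.na(prog) & is.na(codes))
  gm <- geno_matrix(s[, c("contig", "pos")], codes)
  attr(gm, "coding_log") <- c(missing = n_missing,
                              inconsistent = n_inconsistent)
  gm
}
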