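---
title: "Bin maps and seed-coat-color QTLs in an F2 cross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bin maps and seed-coat-color QTLs in an F2 cross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binmapqtl)
```

## The problem

Seed coat color in sesame segregates as a quantitative trait. In an F2
population derived from a white-seeded and a black-seeded inbred parent,
each plant's seed coat is measured with a colorimeter as three indices:
*L* (luminosity, −100 black to 100 white), *a* (−60 green to +60 red) and
*b* (−60 blue to +60 yellow). Low-coverage whole-genome resequencing of
the parents and the F2 plants yields hundreds of thousands of biallelic
SNP/InDel genotypes, which — after aggressive cleanup — support a
superdense genetic bin map, QTL scans for the three indices, and a
variant-plus-expression screen for candidate genes inside the QTL
intervals. `binmapqtl` implements that entire chain as testable,
file-to-file stages, together with a simulator that generates crosses
with the same statistical structure so every stage can be validated
against a known truth.

## Genotype coding

Joint-called genotypes are coded relative to the parents: the homozygote
of parent 1 becomes `A`, of parent 2 `B`, and the heterozygote `H`. Only
sites where both parents are non-missing, homozygous, and fixed for
different alleles are informative; others cannot be phase-assigned in an
F2 and are dropped. A progeny call carrying an allele absent from both
parents degrades to missing rather than raising an error — with
low-coverage joint calling such records are expected noise, and the
correction stage downstream is designed to absorb them.

## Bin-map construction

Low-coverage calling produces two characteristic artifacts: missing
genotypes, and short runs of true heterozygotes miscalled as one
homozygote (with one or two reads per site, only one haplotype is
observed). The cleanup pipeline has four stages, each a pure function of
its input:

1. **Redundant-marker collapsing** (`collapse_redundant()`). Maximal runs
   of consecutive markers that are *redundant* and lie closer than
   `min_gap_bp` (default 100 bp) apart merge into one representative
   marker. Two code vectors are treated as redundant when they agree at
   every individual where both are non-missing; requiring exact equality
   instead would let random missingness shatter truly redundant runs,
   which at these coverages would defeat the purpose of the step. The
   representative's code is the run consensus, so the step also imputes
   within-run missingness.
2. **Sliding-window correction** (`window_correct()`). For each
   individual, each marker is compared with the strict majority
   (more than half of the non-missing entries) of its centered
   15-marker window, shrunk at contig edges. A disagreeing call is
   replaced and a missing call imputed; ties change nothing. The pass is
   single and non-iterative, with every decision taken on the *input*
   state: this makes the operator deterministic and order-independent,
   and deliberately conservative — iterating to convergence would risk
   smoothing away genuine crossovers, which single-pass strict majority
   protects because windows straddling a true crossover are mixed.
3. **Bin construction** (`build_bins()`). Adjacent representatives with
   redundant corrected vectors merge into bins with no distance
   constraint; a bin is the unit of mapping, and its marker count
   accumulates through both merging stages.
4. **Segregation-distortion filtering** (`filter_distorted()`). A bin is
   removed when its consensus counts fall below 20 `A`, 20 `B`, or 40
   `H` plants. The three conditions combine by OR: the thresholds
   correspond to demanding at least 80 informative plants at the ideal
   1:2:1 ratio in a 120-plant F2, and a bin failing any one class is
   unreliable for linkage. Whether the conditions should instead apply
   jointly is genuinely ambiguous; OR is the stricter reading and is the
   package's choice, with both thresholds exposed as parameters.

## Recombination fractions, grouping and map distances

For two codominant F2 loci in coupling, the nine two-locus genotype
classes have probabilities that are polynomials in the recombination
fraction $r$; eight classes count recombinant gametes unambiguously,
while the double heterozygote mixes the parental-phase and
recombinant-phase configurations. `estimate_rf_em()` maximizes the
likelihood by EM, fractionally assigning the double heterozygotes with
weight $r^2 / ((1-r)^2 + r^2)$ in each E-step. The EM starts at
$r = 0.25$, stops at $|\Delta r| < 10^{-8}$ or 500 iterations, and is
validated in the test suite against a brute-force grid search of the
same likelihood on a $10^{-4}$ grid (`rf_grid_mle()`), which is kept
deliberately independent of the EM code path. The linkage LOD is
$\log_{10} L(\hat r) - \log_{10} L(0.5)$.

Bins join a linkage group by single-linkage clustering over pairs with
LOD ≥ 12 (`group_bins()`); groups carrying fewer than 100 underlying
markers are discarded as unanchorable fragments. Within a group, bins
are ordered by physical position: the markers are genome-anchored, so de
novo ordering adds nothing here and an external ordering engine is out
of scope by design.

Adjacent-bin distances use the Kosambi mapping function
$d = 25 \ln\!\big((1+2r)/(1-2r)\big)$ cM, which partially accounts for
crossover interference; positions accumulate from 0 at the first bin
(`space_map()`). Since the function diverges at $r = 0.5$, estimates at
or above $0.5 - 10^{-6}$ are capped there with a warning. `map_stats()`
reports per-group length, bin and marker counts, gaps ≥ 5 cM and the
largest gap. The mean adjacent-bin interval is computed as
length/(bins − 1); published map summaries sometimes print a
per-group "average interval" column that is not reproducible as any
simple ratio of the same row, so this package defines the quantity
explicitly rather than targeting such a column.

## QTL scans

Interval mapping regresses the phenotype at each grid position on the
expected additive ($p_{AA} - p_{BB}$) and dominance ($p_{AH}$)
predictors, the Haley–Knott approximation to the full mixture
likelihood. Conditional QTL genotype probabilities come from the
no-interference Markov chain along the chromosome with
Kosambi-inverted recombination fractions; a missing flank is
marginalized against the 1:2:1 prior, and at a bin the probabilities
collapse to the indicator of the observed code. Haley–Knott is chosen
over mixture-EM because it is deterministic, fast enough for
permutation thresholds, exactly checkable against single-marker
regression at bin positions, and adequate at the effect sizes of
interest (PVE roughly 0.05–0.4); at very large effects and sparse maps
it mildly underestimates the residual mixture variance, which is a
known and accepted property of the approximation.

The LOD is $(n/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$. Genome-wide
significance uses permutation thresholds: phenotypes are permuted
against whole genotype rows — preserving the marker correlation
structure — and the $(1-\alpha)$ quantile of the per-permutation maximum
LOD is taken as the $\lceil (1-\alpha) \, n_\mathrm{perm} \rceil$-th
order statistic (1,000 permutations at $\alpha = 0.05$ by default). The
walk step is 1 cM for IM and 2 cM for composite interval mapping, which
adds forward-selected cofactor markers (BIC stop, at most 5 by default)
as covariates and excludes any cofactor within 10 cM of the test
position.

A called QTL is a maximal super-threshold run of grid positions; its
boundaries are the nearest flanking bin markers, and its PVE
($V_G/V_P$) is the coefficient of determination of the
additive-plus-dominance regression at the bin marker nearest the peak —
the peak-marker convention, which slightly understates the PVE of a QTL
falling midway between bins but needs no model beyond the scan itself.

## Interval consolidation

Per-trait QTLs from multiple scans overlap heavily; consolidation
proceeds in two steps. `merge_overlapping()` deduplicates identical
boundary intervals and merges intervals that overlap as *half-open*
ranges `[start, end)`. Half-open is the only convention under which
endpoint-touching intervals remain distinct — which is what keeps
adjacent but separately supported QTL intervals apart — while genuinely
overlapping ones merge. The single wrinkle is a zero-length interval
(a QTL whose two flanking markers print at the same cM): as a half-open
set it would be empty, so a point interval is absorbed by any interval
whose closed range contains it, and otherwise stands alone.
`cluster_adjacent()` then chains intervals separated by at most 2 cM
into spanning "qSC" hotspot intervals. The 2 cM default reconstructs
the observed hotspot-merging behavior (a 1.66 cM gap is bridged, larger
gaps never are); because the underlying rule is not stated anywhere,
the tolerance is an exposed parameter rather than a constant. All cM
arithmetic runs on integer hundredths, since the boundaries are
2-decimal printed values and float equality would otherwise decide
merges.

`to_physical()` projects an interval to the bp span of its member bins,
one segment per contig, and writes BED (0-based half-open) alongside
the 1-based inclusive TSVs.

## Candidate screen

Genes overlapping a qSC segment by ≥ 1 bp are screened on two axes.
First, the gene must carry at least one *co-segregating high-impact*
variant: homozygous-alternate in the black parent and homozygous
reference in both white lines (a missing genotype disqualifies the
variant — conservative), with an effect in the high-impact set
(frameshift, stop gained/lost, start lost, splice acceptor/donor, exon
loss). Effects come either from pre-annotated ANN-style strings or from
the built-in minimal caller, which handles CDS SNPs via the codon
table, indel frame arithmetic, ±2 bp splice sites and whole-exon
deletions, and deliberately models no UTR/regulatory classes —
modifier-class variants pass through unused. Second, the gene must be
differentially expressed (padj < 0.05 and |log2FC| > 1) at one or more
of the late seed-development stages (10/15/20/25 DAF) *and not* at the
5 DAF control stage, the stage before pigment accumulation begins. A
candidate's variant is required to lie in a screened gene, not
necessarily inside the segment itself, matching the gene-set framing of
the screen. Evidence is recorded for non-passing genes too, so the
screen is auditable.

## The simulator: what it emulates, and what it does not

`simulate_f2()` emulates the study conditions: 13 chromosomes, 120 F2
individuals, dense biallelic markers fixed for opposite alleles in the
parents, 1–4 QTLs per colorimeter index with PVE up to ~0.40, mutually
correlated L/a/b residuals, homozygous miscall runs applied to true
heterozygous stretches, and uniform missingness. Meiosis draws a
Poisson(length/100) number of crossovers per gamete with uniform
positions and no interference — standard, simple, and consistent with
additive map distances; the Kosambi function is then only approximately
the inverse of the meiosis model at long range, which is acceptable
because the correctness tests work on short intervals. Phenotypes are
built on a standardized scale: each QTL's additive/dominance effect
pair is rescaled so that, under exact 1:2:1 frequencies, the locus
contributes its target PVE ($\sigma^2_q = a^2/2 + d^2/4$ after
centering dominance), the residual variance is $1-\sum q$, and
residuals are drawn with the configured cross-trait correlation before
shifting to colorimeter-like means and SDs. This closed-form scaling is
verified by Monte-Carlo in the tests. Defaults place a shared major
locus on chromosome 9 plus smaller loci on chromosomes 3, 5 and 6, with
dominance pushing *L* toward the dark parent (F1 seeds are dark).

The true miscall-run rate and missingness of real low-coverage data are
not published quantities; the defaults (15% of heterozygous runs hit,
mean run length 5 markers, 5% missing) are plausible for ~1× coverage
and are configuration, not claims about any particular dataset.

The simulator does not model read-level noise, base-calling error,
reference bias, segregation distortion of biological origin, or linkage
between the annotation fixtures and the genetic map's QTL positions
(planted candidate genes are placed by coordinate, not by linkage). A
passing pipeline on simulated data therefore demonstrates the
*statistical machinery* — coding, correction, mapping, scanning,
screening — under the stated noise model, not robustness to artifacts
outside it.

`simulate_annotation()` builds the annotation-side fixtures: placed,
non-overlapping gene models written as GFF3; one high-impact
co-segregating variant per planted candidate; and per-stage DEG tables
where planted candidates are DEG at ≥ 1 late stage and clean at 5 DAF.
Every decoy violates exactly one screen condition (cycling over:
variant not co-segregating, variant only moderate-impact, DEG also at
the control stage, no late DEG), so the screen's conditions are each
individually load-bearing in the end-to-end test.

## Numerical choices and degenerate inputs

* EM: start 0.25, tolerance $10^{-8}$, 500 iterations, $\hat r$ clamped
  to $[10^{-9}, 0.5]$; LOD floored at 0.
* Window correction requires an odd window and a *strict* majority;
  exact ties (e.g. 7 A vs 7 B around a missing center) change nothing.
* Permutation quantile: order statistic
  $\lceil(1-\alpha)n_\mathrm{perm}\rceil$, so $\alpha = 1$ degenerates
  to the minimum of the permutation maxima.
* Scans guard RSS ratios with a $10^{-12}$ floor so a perfect fit
  yields a large finite LOD instead of dividing by zero.
* Multiallelic VCF records are skipped with a warning; a third allele
  in a progeny call degrades to missing.
* A constant phenotype column flags its correlations as undefined
  rather than erroring; Shapiro–Wilk is skipped outside 3–5000
  observations.
* Zero-noise simulation reproduces the truth bit-for-bit, and a fixed
  seed fixes every simulator output exactly.

## Calibration studies and problem sizes

Four built-in studies (exercised by the test suite and
`scripts/acceptance.R`) quantify the estimators at the study's
population size of 120 individuals, at sizes chosen to finish in
minutes on one CPU: EM-vs-grid agreement on 1,000 random tables;
correction efficiency on a 120 × 2,000-marker chromosome pair with 2%
injected isolated flips; permutation-threshold type-I error over 200
null replicates of 200 permutations each on a 100 cM chromosome; and
QTL parameter recovery over 200 replicates of a single PVE-0.40 locus,
scanned with per-replicate permutation thresholds. The recovery study
measures the peak error against the map position of the bin containing
the marker nearest the true QTL, because simulated truth lives in true
cM while scans live in estimated map cM.

## Known limitations

* Only IM and CIM scans are provided; inclusive/genome-wide composite
  variants of interval mapping are not reimplemented, and the
  consolidation logic is designed to work from the two provided scans.
* Marker order is taken from the genome anchoring; misassembled contigs
  would propagate into the map untouched.
* The correction operator trusts strict local majorities; adjacent
  conflicting errors inside one window can survive (and its idempotence
  guarantee applies to isolated-error fixtures).
* PVE at the peak marker is a single-locus $R^2$; linked QTLs inflate
  each other's apparent PVE.
* The built-in effect caller covers the high-impact classes and common
  coding classes only; for anything richer, feed pre-annotated ANN
  strings.
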