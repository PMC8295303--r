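---
title: "Methods: reduced-accessibility regions, TAD co-occurrence and contact mining"
author: "chromRCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reduced-accessibility regions, TAD co-occurrence and contact mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

chromRCA implements an integrative chromatin analysis for a two-condition
design (control vs. a knockout that removes local thyroid-hormone
activation in the liver). Its object of study is the **region of reduced
chromatin accessibility (RCA)**: an open-chromatin ATAC-seq peak present in
the control that has no overlapping peak in the knockout. Around this call
the package links five kinds of evidence:

1. **Genomic annotation** of RCAs against a gene model, yielding
   promoter RCAs (p-RCAs, within 200 bp of a TSS) and intergenic RCAs
   (i-RCAs).
2. **Chromatin-state classification** of RCAs from H3K4me3/H3K4me1/ATAC
   signal, with CTCF/cohesin sub-typing of insulators.
3. **Expression coupling**: p-RCAs paired with downregulated genes within
   5 kb.
4. **DNA hypermethylation sites (H-sites)**: their embedding in
   knockout-specific H3K9me3 domains (HH-sites), thyroid-receptor flanking,
   chromosome-density correlations and distance-bracket profiles.
5. **3D genome context**: co-occurrence of p-RCAs and i-RCAs inside the
   same TAD, and mining of significant Hi-C contacts whose promoter-side
   anchor (*area-1*) lies within 1 kb of a p-RCA, profiling the distal
   anchor (*area-2*) for nearby i-RCAs and H-sites.

All coordinates are consumed as BED (0-based, half-open) and held
internally as `GRanges`; distances are edge-to-edge gaps in bp, zero when
intervals overlap. Strand is carried but ignored by overlap and distance
logic — only TSS definition is strand-aware.

# Stage-by-stage model and parameters

## RCA detection

`subtract_condition(control, case)` retains whole control peaks with no
case peak overlapping by at least `min_overlap_bp` (default 1). The call is
peak-level presence/absence, not base-pair subtraction: the quantity of
interest is "open regions unique to a condition", so truncating peaks would
manufacture fragments with no biological identity.

## Annotation

Two promoter windows coexist deliberately: 200 bp around the TSS for
RCA/ATAC genomic annotation, and 1 kb for methylation-site promoter calls.
Both live in `annotation_config()` and every stage names which one it uses.
Labels follow the precedence promoter > exon > intron > intergenic, so each
interval gets exactly one label and category counts always sum to the input
size. A "negative RNA-seq region" for a downregulated gene is
operationalized as the gene body: the upstream expression analysis defines
no sub-gene coverage-dip coordinates, and the gene body is the coarsest
proxy that cannot misplace the signal. Fold changes are signed ratios
(negative = lower in the knockout); tables stating ratios in (0,1) are
converted on load. Downregulation uses strict thresholds: |fold| > 1.2 and
p < 0.05.

## TPM and classification

Signals over RCA regions are normalized as transcripts-per-kilobase-million
**over the RCA region set itself** (not genome-wide bins): per track,
`TPM_i = (c_i / L_i_kb) / sum_j (c_j / L_j_kb) * 1e6`, so each track sums
to 1e6. Users wanting genome-wide normalization can substitute their own
table. Classification is a total function with literal strict inequalities:

* gate: `max(TPM_H3K4me3, TPM_H3K4me1) > 4` — exactly 4 fails;
* within the gate, ratio `TPM_H3K4me3 / TPM_H3K4me1`: > 1.5 promoter,
  < 0.67 enhancer, otherwise weak promoter (ties at 1.5 and 0.67 are
  intermediate); a zero denominator is treated as an infinite ratio
  (promoter) and logged;
* below the gate: ATAC > H3K4me1 is an insulator, otherwise weak insulator
  (equality falls to weak). The ATAC signal is TPM-normalized the same way
  so the comparison is unit-consistent.

Insulator-class regions are sub-typed CAC (overlap ≥1 CTCF and ≥1 Rad21
peak), CNC (Rad21 only) or neither; a CTCF-only insulator is "neither".

## Proximity profiles

`anchored_matrix()` is the numeric core of anchor-centered heat-maps: rows
are anchors (mouse-style chromosome display order chr1..9, chrX, chr10..19
when the genome looks mouse-like), columns are offset bins over
±halfwidth. Matrix binning uses interval **midpoints** (peaks are centered)
while `bracket_histogram()` uses **edge-to-edge** nearest distances; the
mix is deliberate, matching how each display is defined. With an even
number of bins there is no center bin: a zero offset falls in the first bin
right of center, and an offset of exactly +halfwidth clamps into the last
bin. Default brackets (1, 5, 50, 500, 1000 kbp) reconstruct the distance
classes used across the published distance figures and are fully
configurable. Bracket counts plus the no-neighbor count always equal the
number of queries; distance 0 goes to the first bracket, closed on the
left.

## Association statistics

Chromosome densities are features per Mbp. Correlations are Spearman with
average ranks for ties; the two-sided p-value uses the exact null
distribution for n ≤ 12 without ties (exact enumeration below n = 10,
AS 89 above) and the t-approximation otherwise. No multiple-comparison
adjustment is applied, matching the source analysis.

TAD membership is any-overlap (≥1 bp): a feature spanning two adjacent
TADs counts for both, the permissive literal reading; `type = "within"`
offers containment semantics. The 2×2 test is the **uncorrected** Pearson
chi-squared, `N(ad − bc)² / ((a+b)(c+d)(a+c)(b+d))`: on the published TAD
contingency totals (3,538 TADs; 472 with p-RCAs; 677 with i-RCAs; 278 with
both) the uncorrected statistic gives 556.5 — the printed 557 — while the
Yates-corrected one gives 553.6, which fixes the convention. A companion
test printed alongside the gene-restricted TAD analysis (counts 51/131/81)
is not reproducible from its printed counts under any stated total, so the
package does not attempt it.

## Hi-C mining

Contacts are consumed as BEDPE, deduplicated by coordinate identity and
canonically oriented (anchor-1 midpoint left). Separation is
midpoint-to-midpoint; the filter keeps intra-chromosomal pairs with
1 kb ≤ separation ≤ 10 Mb, both bounds inclusive, and is idempotent.
Either anchor may match a p-RCA ("within 1 kb" = edge distance ≤ 1000 bp
against the anchor interval, nearest p-RCA reported), so a contact matching
at both anchors yields two area-1 hits; `both_anchors = FALSE` restricts to
anchor 1. Area-2 neighborhoods use the strictly-exclusive "< 50 kb"
wording for counts while nearest distances are reported as-is.

# The synthetic-data generator

`simulate_chromatin()` emits every input the pipeline reads, with a YAML
ground-truth manifest, from a single integer seed driving one documented
RNG stream (same seed ⇒ byte-identical files). Its defaults are the study
conditions the rest of the package is tested against:

* a mouse-like genome of 20 chromosomes × 60 Mbp, partitioned into TADs of
  0.6–1.4 Mbp (mean 1 Mbp);
* per-TAD (p-RCA, i-RCA) indicator flags drawn from a 2×2 joint with
  margins 0.20/0.30 and odds ratio 9.6 — the odds ratio implied by the
  published TAD table is ≈9.58;
* 154 planted p-RCA:gene pairs over 146 downregulated genes (eight genes
  carry two promoter RCAs, straddling the TSS), each pair's promoter RCA
  within 150 bp of the TSS;
* one planted Hi-C contact per paired p-RCA: the promoter-side anchor
  overlaps or nearly overlaps the p-RCA, the distal anchor sits at a
  lognormal separation (meanlog `log(324000) − 0.32`, sdlog 0.8, truncated
  to 1 kb–2.4 Mb, targeting a mean of ~324 kbp) with an i-RCA planted
  2–20 kb away;
* 400 p-RCAs and 600 i-RCAs in total, 34 insulator-class regions typed
  30 CAC / 4 CNC plus 16 weak insulators, engineered per-region signal
  counts that provably classify to their planted state;
* 400 H-sites scattered around i-RCAs (Gaussian sd 27.5 kb, giving a mean
  absolute offset of ~22 kb; 15% uniform noise), 40 of them embedded in
  knockout-unique H3K9me3 domains (HH-sites), 25 coinciding with
  normally-demethylated control sites; 69 T3-bound and 7 unoccupied
  thyroid-receptor flanking occasions within 10 kb of HH-sites;
* 500 genes (32% downregulated, 40 upregulated), 500 contacts (planted +
  intra-chromosomal noise, 10 inter-chromosomal and 5 sub-kb decoys that
  the filter must drop), background ATAC/H3K9me3/CTCF/Rad21/uTR peaks.

Placement is rejection-sampled against interval registries with spacing
margins chosen so that every planted association is recoverable *exactly*:
noise contact anchors stay >2 kb from any p-RCA, non-paired p-RCAs stay
>12 kb from downregulated gene bodies, competing i-RCAs stay >60 kb from
planted distal anchors, H-sites are ≥2.5 kb apart and HH candidates are
isolated by >22 kb so a flanking TR peak can never straddle two sites.
TADs are a non-overlapping partition (real TADs can nest — a documented
simplification), features never overlap within a set, and the generator
asserts that its engineered signal table reproduces the planted classes
before writing anything.

What the generator does **not** emulate: read-level noise, peak-shape
variation, fragment-level Hi-C noise, nested/overlapping TADs, copy-number
or mappability artifacts, and correlated replicate structure. Passing
recovery tests therefore demonstrates the correctness of the interval
logic and statistics under the planted model, not robustness to upstream
peak-calling error on real data.

`null_resample()` calibrates the TAD test: with odds ratio forced to 1 it
draws the per-TAD flag table directly from the independence joint and
applies the chi-squared test. Drawing the table rather than placing and
re-scanning intervals is sound because the generator's construction makes
the interval-level table identical to the flag-level table; it is also what
keeps 2,000 replicates near-instant.

# Numerical and degenerate-input choices

* BED parsing rejects `start ≥ end` and out-of-bounds intervals with the
  offending line number; unknown chromosomes are skipped with a warning by
  default, escalated to an error under `strict = TRUE`.
* `filter_by_score` is strictly greater-than (the published peak filter is
  −log10 p > 2) and errors on missing scores rather than guessing.
* An all-zero signal track makes TPM undefined and is an error, not a
  silent zero.
* A degenerate 2×2 margin (any zero row/column total) is an error; a zero
  off-diagonal product flags the odds ratio as infinite with a warning.
* Zero-variance density vectors make rank correlation undefined → error.
* Ties in `nearest_distance` resolve to the first subject in sorted order;
  only the distance is contract-guaranteed.

# Problem sizes

The shipped tests run the generator at its default scale (≈1,200 TADs,
1,050 RCA regions, 500 contacts, 500 genes, ~4,500 background peaks),
50 randomized oracle instances of 50–300 features, 2,000 null replicates
for the calibration check, and full-enumeration Spearman verification at
n = 8. These sizes were chosen so the whole suite exercises every code
path at comfortably interactive speed while keeping all planted-recovery
guarantees exact.

# Known limitations

* The published genome-wide totals (1,508 H-sites, 8,031 RCAs, 1,551
  p-RCAs, 2,426 i-RCAs, 988 areas-1, …) require the original sequencing
  data and are not reproduced here; the synthetic bundle reproduces the
  *structure*, at desk scale, with exact ground truth instead. (The source
  also prints both 8,031 and 8,052 for the same RCA total; the package
  reports whatever its subtraction yields and does not arbitrate.)
* Whether the published area-1 mining matched one anchor or both is not
  stated; both-anchor matching is the default, with a flag to restrict.
* The gene-body proxy for reduced-expression regions can overstate pairing
  distance for long genes whose expression dip is internal.
* Spearman p-values at n = 10–12 use AS 89 rather than full enumeration.
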