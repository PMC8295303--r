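# chromRCA

Integrative interval analysis of chromatin accessibility loss. chromRCA is
an R package for a two-condition epigenomic design in which a perturbation
(here, liver-specific loss of type 2 deiodinase, which removes local
thyroid-hormone activation) leaves a permanent mark on the chromatin of the
adult animal. It links, stage by stage:

* **RCAs** — regions of reduced chromatin accessibility: control ATAC-seq
  peaks with no overlapping knockout peak (`subtract_condition`);
* **genomic annotation** of RCAs into promoter (p-RCA, TSS ± 200 bp),
  exon, intron and intergenic (i-RCA) classes;
* **chromatin states** from H3K4me3/H3K4me1/ATAC TPM over the RCA set —
  promoter / weak promoter / enhancer / insulator / weak insulator — with
  CTCF+cohesin (CAC) vs cohesin-only (CNC) insulator sub-typing;
* **expression**: p-RCAs paired with downregulated genes (>1.2-fold,
  p < 0.05) within 5 kb;
* **DNA hypermethylation sites (H-sites)**: embedding in knockout-specific
  H3K9me3 (HH-sites), thyroid-receptor flanking counts, per-chromosome
  density correlations (Spearman), anchored density matrices and
  distance-bracket histograms;
* **3D context**: TAD-level co-occurrence of p-RCAs and i-RCAs tested with
  the uncorrected Pearson chi-squared,

  chi² = N (ad − bc)² / [(a+b)(c+d)(a+c)(b+d)],

  and mining of significant Hi-C contacts (1 kb ≤ separation ≤ 10 Mb) for
  promoter-anchored *area-1* coordinates (within 1 kb of a p-RCA) and
  their distal *area-2* partners' i-RCA/H-site neighborhoods (< 50 kb).

A seeded synthetic-data generator (`simulate_chromatin`) plants all of this
structure — TAD co-occurrence with a prescribed odds ratio, p-RCA:gene
pairs, promoter-anchored contacts with lognormal separations, clustered
H-sites, insulator typing — and writes a ground-truth manifest, so every
stage is verifiable end-to-end without any external sequencing data.

## Worked example

```r
library(chromRCA)

sim <- simulate_chromatin(sim_config(seed = 1), "sim_out")
cfg <- pipeline_config(inputs = sim$paths[setdiff(names(sim$paths), "manifest")])
s   <- run_pipeline(cfg, "run_out")

s$pairing
#> $n_pairs
#> [1] 154
#> $n_genes
#> [1] 146
#> $n_prcas
#> [1] 154

s$insulator_types
#> $CAC
#> [1] 30
#> $CNC
#> [1] 4
#> $neither
#> [1] 0

s$tad$chi2
#> [1] 229.9600
s$contacts$mean_separation_bp
#> [1] 335621.6
```

Reading the output: the pipeline re-detected all 1,050 planted RCAs,
annotated 400 as promoter and 650 as intergenic, paired 154 promoter RCAs
with 146 downregulated genes at ≤5 kb (the planted pairing, recovered
exactly), typed the 34 insulator-class regions as 30 CAC + 4 CNC, found
every planted promoter-anchored Hi-C contact (mean anchor separation
~336 kb against a planted target of ~324 kb), and rejected independence of
p-RCA/i-RCA TAD membership (chi² ≈ 230 on 1,215 synthetic TADs, planted
odds ratio 9.6). The full report bundle (`run_out/`) contains per-stage
TSV/BED tables, a `summary.yaml`, and a `log.txt` recording every
threshold and input checksum.

Applying the published TAD contingency totals directly:

```r
chi_square_2x2(cooccurrence_table(278, 194, 399, 2667))
#> $chi2
#> [1] 556.544
#> $p
#> [1] 4.747002e-123
#> $odds_ratio
#> [1] 9.578405
```

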