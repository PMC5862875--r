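# mmcap — integrative targeted-capture mutation analysis for multiple myeloma

Multiple myeloma is driven by three kinds of genomic lesion at once: copy
number variants (hyperdiploidy, arm-level gains/losses), immunoglobulin
heavy-chain (IGH) and MYC translocations, and somatic point mutations in
genes such as *NRAS*, *KRAS*, *FAM46C*, *TP53*, *DIS3*, and *IGLL5*. A
single capture panel (~3.3 Mb over ~465 genes plus tiled IGH/MYC/IGL loci,
tumor/normal pairs at ~100×) can assay all three — but only with analysis
tuned hard against false positives. `mmcap` is that analysis layer, for
bioinformaticians working with myeloma (or similar) capture panels:

* **CNV calling** from per-probe log2 tumor/normal depth ratios
  `r = log2(t/n) − m`: recursive binary segmentation, then a Gaussian-
  mixture noise model fit to each sample's ratios — the component with
  mean nearest 0 defines a diploid noise band `μ_d ± z_{1−α/2}·σ_d`, and a
  segment is called only if its mean lies outside the band *and* its tail
  probability under `N(μ_d, σ_d/√n_probes)` is below α. Clonal landmarks:
  single-copy gain at `log2(3/2) = 0.58`, single-copy loss at
  `log2(1/2) = −1`. Arm events need ≥60% arm coverage; hyperdiploidy is
  scored from whole-chromosome gains of odd chromosomes.
* **Translocation filtering** by minimal-evidence thresholds on split
  reads (SR) and discordant pairs (PE): exhaustive lexicographic grid
  search maximizing precision then recall, returning the provably
  componentwise-minimal optimal triple `(min_sr, min_pe, min_total)`; a
  panel-of-normals mode returns minimal thresholds passing **zero**
  normal-sample candidates (used for MYC, where FISH truth is absent).
  Classification into t(11;14), t(4;14), t(8;14), …, MYC-ITX/CTX and
  1 Mb breakpoint gene annotation included.
* **Variant analyses**: the high-confidence filter (drop silent/intronic/
  intergenic/flanking, IGH-locus, and germline-flagged calls), exact-key
  run-to-run matching with VAF concordance (R²), binomial read-count
  downsampling with a depth-vs-yield saturation curve, and diploid-locus
  VAF clonality summaries.
* **Integrative statistics**: samples × features mutation matrix across
  all three lesion types (composites like RAS = KRAS ∪ NRAS recomputed as
  ORs), Tukey-fence hypermutator exclusion, pairwise co-occurrence/
  exclusivity by exact one-sided Fisher (hypergeometric tail sums), the
  AID c-signature one-sided exact binomial test on WRCY/RGYW motifs,
  upper-fence expression outliers, and in-repo Kaplan–Meier, log-rank,
  and binary-covariate Cox (Breslow/Newton) progression analysis.
* **A seeded synthetic-cohort generator** for every input the pipeline
  consumes (NB depths with planted clonal CNVs, Poisson SV support,
  Bernoulli mutation matrices with planted log-odds interactions, WRCY
  sequences with planted AID mutations, exponential survival with a
  planted hazard ratio), used by the validation suite and the demo
  pipeline.

## Worked example

```r
library(mmcap)

cfg <- pipeline_config(seed = 1)           # 20-sample demo cohort
res <- run_pipeline(cfg, "demo_run")       # writes all stage outputs

res$sv$thresholds
#> SV thresholds: sr >= 5, pe >= 0, sr+pe >= 0 (precision 1, recall 1)
res$sv$normal_panel
#> SV thresholds: sr >= 4, pe >= 0, sr+pe >= 0 (precision NA, recall NA)
table(res$hyperdiploidy$hyperdiploid)
#> FALSE  TRUE
#>    15     5
res$aid
#> # A tibble: 1 × 4
#>   n_mutations n_at_motif background_p  p_value
#> 1          40         32        0.143 2.30e-20
res$cox
#> Cox proportional hazards (mutant vs other): HR = 1.81 (95% CI 0.43-7.68),
#>   p = 0.419, n = 20 (11 events)
```

Reading the output: the SV tuner found that requiring 5 supporting split
reads separates planted true translocations from artifacts perfectly on
this cohort (precision 1 at recall 1); the panel-of-normals filter needed
`sr >= 4` to exclude every normal-sample call. Five of twenty samples were
flagged hyperdiploid. The AID test saw 32 of 40 planted mutations at
hotspot motifs against a 14% background motif fraction — overwhelming
enrichment. The Cox fit recovers the planted hazard ratio direction, with
the wide confidence interval a 20-sample cohort deserves; at n = 5000 the
estimate lands within ±0.1 of the planted 1.46 (see the acceptance
script). Each run directory also contains every table as TSV/BED/BEDPE, a
resolved-config snapshot, a structured log, and an md5 manifest —
re-running the same config reproduces identical checksums.

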