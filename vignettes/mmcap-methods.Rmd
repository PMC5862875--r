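---
title: "Methods: integrative targeted-capture mutation analysis for myeloma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative targeted-capture mutation analysis for myeloma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mmcap is the analysis layer for a multiple-myeloma (MM) targeted-capture
sequencing panel: roughly 3.3 Mb of probes over ~465 MM-relevant genes plus
unbiased tiling of the IGH, MYC, and immunoglobulin lambda loci, sequenced
as tumor/normal pairs to ~100x. From the aligned-and-called upstream
products (per-probe depths, translocation candidates with read support,
merged multi-caller variant tables) it derives copy-number calls,
high-precision translocation calls, filtered somatic variants, and the
integrative statistics that tie the three mutation types together. This
vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-cohort generator does and does not emulate.

## Copy number from depth ratios

For probe $i$ with tumor depth $t_i$ and matched-normal depth $n_i$, the
copy-number signal is

$$r_i = \log_2\frac{\max(t_i,\varepsilon)}{\max(n_i,\varepsilon)} - m,$$

where $m$ is the per-sample median of the uncorrected ratios over unmasked
autosomal probes, so the diploid baseline sits at 0. A clonal single-copy
gain (3 copies vs 2) sits at $\log_2(3/2)=0.58$ and a clonal heterozygous
loss at $\log_2(1/2)=-1$; with tumor purity $p$ and total copy number $c$
the expected ratio is $\log_2\!\big(p\,c/2 + (1-p)\big)$. The pseudo-count
is a *floor* ($\varepsilon = 0.5$), not an additive offset: it only
matters when a tumor depth is exactly zero, and it leaves the clonal
landmarks exact at nonzero counts. Probes whose normal depth falls below
`min_normal_depth = 10` are masked everywhere (normalization,
segmentation, noise model): a shallow normal makes the ratio mostly noise.
Sex chromosomes are excluded from the normalization median (and from
hyperdiploidy scoring) because their baseline depends on patient sex, not
tumor ploidy.

### Segmentation

Tracks are segmented by recursive binary splitting within each
(chromosome arm, sample): the probe maximizing the two-sample
$t$-statistic between left and right means is accepted as a breakpoint
when the statistic exceeds `stat_threshold = 5` and both sides keep
`min_probes = 10` probes. The threshold is calibrated against the maximum
of ~500 dependent $t$-statistics under the null
($\sqrt{2\log 500}\approx 3.5$, plus margin for the recursion), so flat
arms stay unsplit with high probability while a 30-probe shift of 0.2 or
more is found essentially always. Segmenting within arms (arms are
contiguous, so the union still partitions the chromosome) means every
segment maps to one arm, which the arm-event arithmetic below relies on.
This segmentation is the package's own replacement for external
depth-ratio segmenters and is validated by planted-breakpoint recovery,
not output compatibility.

### The diploid noise model

The central filtering idea is to estimate how noisy *diploid* probes are
and discard any segment whose mean could plausibly arise from that noise.
Per sample, a univariate Gaussian mixture with $K = 1..3$ components is
fit by EM to the pooled per-probe ratios (restarts from k-means++-style
seeds; the log-likelihood is non-decreasing per iteration; component
standard deviations are floored at $10^{-4}$ with a warning on degenerate
data). $K$ is chosen by BIC, and the component whose mean is nearest 0 is
the diploid one — copy-altered probes land in the other components. The
noise band is $\mu_d \pm z_{1-\alpha/2}\sigma_d$ with $\alpha = 0.05$.

Fitting probes (rather than segment means) per sample trades a small
dependence bias for far more observations and per-sample adaptivity; with
~100x depth and ~11% depth CV the per-probe ratio noise is
$\sigma_d \approx 0.2$, so the default band is roughly $\pm 0.4$ — wide
enough that low-purity events are deliberately left uncalled rather than
risk false positives.

A segment becomes a CNV call only if (a) its mean lies outside the band
and (b) the two-sided tail probability of its mean under
$N(\mu_d, \sigma_d/\sqrt{n_{\text{probes}}})$ is below $\alpha$. Retained
segments get states from fixed cut-points bracketing the clonal landmarks
with margin for purity below 1: $\le -1.6$ homozygous loss, below the
band loss, above the band gain, $\ge 1.0$ amplification. Raising $\alpha$
never removes a call retained at a lower $\alpha$ (the filter is monotone).

### Arm events and hyperdiploidy

An arm is called gained/lost when retained segments of that sign cover at
least `min_arm_fraction = 0.6` of its usable probes. Hyperdiploidy is
scored as the number of odd chromosomes among {3, 5, 7, 9, 11, 15, 19,
21} whose every panel-covered arm is gained (acrocentric chromosomes have
only a q arm, so a q gain counts); two or more trisomies flag the sample
as hyperdiploid. The two-trisomy threshold is deliberately permissive for
a ~100x panel: it is a screen, not a karyotype.

## Translocation filtering

Candidates arrive with split-read (`sr`) and discordant-pair (`pe`)
support. The filter family is three minimum-evidence thresholds
`(min_sr, min_pe, min_total)`; tuning is an exhaustive, exact grid search
(evaluated with 3-D suffix sums over the support lattice, so the full
integer grid up to the observed maxima + 1 is cheap). The objective is
lexicographic — maximize precision against the truth labels, then recall —
matching a validation setting where false positives are costlier than
misses. Two deliberate choices:

* precision over an empty call set is treated as invalid, not 1.0, which
  removes the degenerate "filter everything" optimum;
* among optima, the returned triple is the lexicographically smallest in
  the order `(min_total, min_pe, min_sr)`. Any componentwise-smaller
  optimum would precede it in that order, so the returned triple is
  provably componentwise-minimal — the least aggressive filter achieving
  the optimum. Truth labels are validated per candidate against
  sample-level truth classes, the granularity at which FISH validates.

Where no truth labels exist (MYC rearrangements), a panel of normals
substitutes: `tune_normal_panel()` returns minimal thresholds under which
*zero* normal-sample candidates survive (a guarantee by construction, on
every input), tie-broken toward retaining the most tumor candidates.
Classification into canonical classes — t(11;14), t(4;14), t(8;14),
t(6;14), t(14;20), t(14;16), t(14;22), MYC-ITX/CTX — is a pure lookup of
breakpoints against a region table; intra-chromosomal MYC events need at
least 100 kb of separation (configurable) to rule out local noise.
Breakpoints are annotated with genes within 1 Mb, sorted by distance.

## Variant filtering and depth analyses

The high-confidence filter drops silent/intronic/intergenic/flanking
calls, anything inside IGH (somatic hypermutation territory), and
anything germline-flagged by any caller; each dropped call carries its
first failing rule, and the filter is idempotent. Run-to-run matching
uses the exact key (sample, chrom, pos, ref, alt) — indel normalization
is assumed upstream; no position fuzzing. VAF concordance is the squared
Pearson correlation over shared variants (identical vectors report 1 even
when degenerate-constant; fewer than 3 pairs report missing).

Downsampling thins `ref_count`/`alt_count` binomially and recomputes VAF.
The yield curve applies a configurable detection rule (default
`alt_count >= 4` and `VAF >= 5%`; upstream discovery pipelines rarely
state their criterion, so this one is explicit and reported in output
metadata) at each fraction and reports the fraction beyond which every
marginal gain stays below 2%. Clonality summaries restrict variants to
loci without an overlapping non-neutral CNV call and report per-gene VAF
quantiles; all quantiles in the package use linear interpolation between
order statistics (R type 7), which matters when quartiles are quoted.

## Integrative statistics

The mutation matrix is binary samples x features: SNV gene features
require a non-synonymous call (missense, nonsense, frameshift, splice);
CNV arm features come from arm events plus an HRD flag; translocation
features from the classified classes; composites (RAS = KRAS | NRAS) are
recomputed ORs, never stored. Mutation burden is calls per Mb of panel.
Hypermutators are removed by the upper Tukey fence $Q_3 + 3\,\mathrm{IQR}$
on burden — an automated stand-in for the by-eye exclusion such analyses
usually make; any number of samples may be dropped.

Pairwise co-occurrence/exclusivity uses Fisher's exact test computed as
hypergeometric tail sums in both one-sided directions; a pair is flagged
when either tail drops below $\alpha$. Raw p-values are primary (matching
how such matrices are usually reported); a Benjamini-Hochberg column over
the two-sided p accompanies them. Because the two directional rejections
are disjoint and the discrete Fisher tails are conservative, the flag's
null rejection rate at mutation frequencies around 20% and $n \approx 95$
sits close to $\alpha$ itself, which the calibration suite checks
empirically. Degenerate tables (a zero margin) report both tails as 1 and
a missing odds ratio; zero-variance features are skipped with a message.

The AID (activation-induced cytidine deaminase) signature test counts
variants that are C→T/G at the C of a WRCY motif (or G→A/C at the G of an
RGYW motif on the reverse strand; W=A/T, R=A/G, Y=C/T; overlapping motifs
all count) and compares against a one-sided exact binomial null. The
background probability is the motif fraction among all C/G positions in
the footprint — the natural null for "where would a C/G mutation land if
motifs didn't matter". A per-trinucleotide background is a reasonable
alternative; the motif-fraction null is the package's documented choice
and is configurable by supplying a different footprint.

Expression outliers use the upper fence $Q_3 + 1.5\,\mathrm{IQR}$ only —
the biological question is overexpression of translocation partners.

Progression analysis ships its own estimators so the exact-oracle tests
exercise the code that runs: the Kaplan-Meier product-limit curve (equal
to the empirical survival function under no censoring), the two-group
log-rank test, and a single-binary-covariate Cox fit maximizing the
Breslow partial likelihood by Newton iteration (closed-form score and
information for a binary covariate; Wald confidence interval). Breslow
tie handling keeps the likelihood a smooth one-parameter function. A
group with no events makes the hazard ratio non-estimable and is reported
as such, never as a number. The mutant/wild-type contrast is
locale-independent (C-order sort, with an explicit `"mutant"` label
preferred).

## The synthetic cohort generator

The generator produces every input the pipeline consumes, under one root
seed fanned out into named substreams (`substream_seed()`), so any stage
can be reproduced in isolation and identical configurations are
byte-identical end to end.

* **Depths**: negative binomial per probe. Defaults are the study
  conditions the package targets: 95 pairs, mean tumor depth 104x, mean
  normal depth 107x. Dispersion defaults to 0.002, i.e. ~11% depth CV at
  104x — a realistic post-normalization capture panel; capture depth is
  overdispersed relative to Poisson, and the noise filter must be
  exercised against that. Tumor means scale with
  $p\,c/2 + (1-p)$ over planted clonal events.
* **Purity**: a single scalar per tumor (default 0.8, a typical
  CD138-sorted marrow aspirate); the cohort model is clonal-only, so no
  subclonal copy-number mixtures exist to estimate.
* **SV candidates**: true calls placed in IGH/partner windows, artifacts
  anywhere, both with Poisson support (defaults 20 vs 1 per read class) —
  the simplest model making the precision/recall trade-off nontrivial.
  Normal-sample artifacts emulate the recurrent false calls a panel of
  normals removes.
* **Mutation matrices**: independent samples; interacting feature pairs
  drawn from the 2x2 joint matching both marginals and a requested
  log-odds (Plackett construction; infeasible combinations error with the
  feasible bound).
* **AID sequences**: random sequence with planted WRCY motifs at a target
  density; AID-type mutations at motif C/Gs, the remainder uniform over
  *non-motif* C/G positions so the mutation universe matches the binomial
  test's background.
* **Survival**: exponential event times with rate
  $\lambda_0\,\mathrm{HR}^x$ and independent exponential censoring.

What it does **not** emulate: GC/mappability bias, read-level artifacts
(no FASTQ/BAM), subclonal structure, caller-specific error profiles, or
real breakpoint microhomology. Green tests therefore demonstrate that the
*statistical machinery* is correct and calibrated under its stated model,
not that the models capture every artifact of real capture data.

## Validation problem sizes

The shipped validation suite uses: exhaustive Fisher-vs-enumeration over
all 2x2 tables with $n \le 40$; 100 random tuner instances of up to 60
candidates against a brute-force grid oracle; 100 random 10 kb sequences
for the motif scan; GMM recovery at $n = 2000$ over 20 fits; Cox recovery
of HR 1.46 at $n = 5000$; CNV event recovery over 50 one-sample cohorts
of 1000 probes (events of 30+ probes, purity 0.6-0.95, depth 500x with
dispersion 0.001, i.e. per-probe ratio noise ~0.11); Fisher calibration
over 2000 cohorts of $n = 95$; log-rank uniformity over 500 replicates;
1000 panel-of-normals trials; and a 20-sample demo pipeline run twice for
checksum-identity. These sizes give the estimators enough data that the
stated tolerances reflect method error, not Monte-Carlo noise.

## Known limitations

* No allele-specific copy number (the panel lacks SNP probes by design)
  and no purity/ploidy joint estimation; low-purity events are filtered,
  not rescued.
* Threshold tuning optimizes on the tuning cohort itself; with few truth
  samples the achieved precision/recall are optimistic (no
  cross-validation, mirroring the validation-cohort setting).
* The Fisher direction flag controls each direction at $\alpha$
  marginally; users wanting strict familywise control should use the BH
  column.
* The AID test conditions on the observed mutation count and footprint;
  it does not model selection on the mutated sites.
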