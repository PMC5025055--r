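---
title: "Triangulating transcription-factor targets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating transcription-factor targets: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A transcription factor (TF) such as E2F1 is suspected of driving the
expression difference between two groups of primary cell lines — here
called group A (SGA, small-for-gestational-age derived) and group B
(AGA, appropriate-for-gestational-age derived), three lines per group.
No single assay settles the question: differential expression says
*which* genes differ, a knockdown says which genes *depend* on the TF,
and ChIP signal says where the TF *sits*. `tritarget` implements the
triangulation of all three:

1. **Basal contrast** — two-group differential expression (A vs B) on
   RNA-seq counts.
2. **Knockdown contrast** — paired control/knockdown differential
   expression per cell line (siRNA against the TF).
3. **Promoter binding** — input-normalized ChIP signal scored in a
   ±2 kb window around each TSS, tiered into low / moderate / high
   binding, plus consensus peak calls and promoter motif content.

A gene that is up in group A, down upon knockdown, and bound at its
promoter is a direct, activating TF target. The package also ships a
synthetic-data generator that plants all of these signals with a known
truth table, so the entire chain is testable without any external
download.

# Expression analysis

## Filtering

Genes enter the analysis universe when their CPM
(count / library size × 10⁶) exceeds 1 in at least 3 of the 6 samples
(`cpm_filter()`). The filter is strict (`> 1`), monotone in counts, and
uses raw column-sum library sizes.

## The differential tests

`de_test()` offers two methods.

**`nb_exact` (default).** The generator's model — and the standard
model for RNA-seq counts — is negative binomial. With only three
samples per group, per-gene variance estimates are so noisy that a
plain location test is either insensitive (after multiplicity
adjustment) or badly anti-conservative (raw p with a fold-change
filter). The matched test conditions on each gene's total count: with a
dispersion φ shared across genes, the group-A sum given the total
follows a negative hypergeometric law that is free of the gene's mean.
The two-sided p-value sums all splits no more probable than the
observed one. Two supporting estimates are involved:

* **Size factors.** Counts are first equalized by median-of-ratios
  size factors (the median, across genes, of each sample's ratio to
  the per-gene geometric mean). Column sums are *not* used here: when
  planted fold changes are asymmetric in magnitude (4× up adds more
  reads than 4× down removes), column sums are biased by ~10% and
  shift every null gene. The median of ratios is insensitive to a
  minority of changed genes.
* **Common dispersion.** φ is estimated once, by conditional maximum
  likelihood: given a gene's within-group total, the within-group
  counts are Dirichlet-multinomial with concentration 1/φ, so the
  conditional likelihood is free of all gene means and can be
  maximized in one dimension. There is *no* per-gene dispersion and no
  shrinkage toward a trend — empirical-Bayes moderation is deliberately
  out of scope.

For the **paired design** the same machinery yields a conditional
beta-binomial score test: under the null, the treated count given a
pair's total is beta-binomial(total, 1/φ, 1/φ); the centred counts are
pooled over pairs and normal-approximated. This keeps the paired
analysis sensitive at three to six pairs, where a paired t-test on
log-CPM differences (df 2–5) cannot clear a BH threshold across
thousands of genes.

**`lcpm`.** Welch's t-test (two-group) or the paired t-test on per-pair
differences, computed on log2(CPM + 0.5). Retained because it is the
simplest transparent reference and is useful for data that are not
count-like.

In both methods the reported effect size is the difference of mean
log2(CPM + 0.5); the pseudocount 0.5 avoids −∞ at zero counts. A gene
**passes** when |log2FC| ≥ log2(1.3) ≈ 0.38 — the boundary is
inclusive, since "a cutoff of 1.3" does not specify strictness — and
the chosen criterion (raw p for the basal contrast, BH FDR for the
knockdown contrast; both α = 0.05 by default) is met. Degenerate
(constant) genes receive p = 1 rather than an error.

## Set summaries and triangulation

`venn_summarize()` performs exact two-set algebra; exclusive
percentages are rounded half-up to one decimal (so 306/846 prints as
36.2%). `quadrant_classify()` places each gene by the sign pattern of
its basal and knockdown log2 fold changes; a gene is assigned to a
quadrant only when both axes are significant and both |log2FC| ≥ 0.38
(inclusive). `quadrant_enrichment()` then asks, per quadrant, whether
assigned genes concentrate there. The 2×2 construction is genuinely
under-specified in the source material; the package pins one:

    [ assigned & in quadrant,     assigned & elsewhere;
      unassigned with signs in the quadrant's sector,  other unassigned ]

i.e. the sign pattern of the jointly-significant genes is compared
against the sign pattern of the background. This null is exercised by a
dedicated type-I simulation (rejection rate at α = 0.05 within
[0.02, 0.09] under no coupling — Fisher's exactness makes it mildly
conservative).

# ChIP signal analysis

## SES input normalization

`ses_scale_factor()` implements signal extraction scaling: sort bins by
increasing ChIP value, find the split point k* maximizing the absolute
gap between the cumulative ChIP fraction and cumulative input fraction,
and return input-mass/ChIP-mass over bins 1..k*. The split point
separates background (where ChIP and input should agree) from
enrichment. When every k ties (e.g. ChIP and input are proportional)
the largest k is used, which covers the whole background and gives the
natural answers: factor 1 for identical tracks, 0.5 for ChIP = 2 ×
input. `normalize_track()` then computes per-bin
log2((chip·factor + 1)/(input + 1)) by default; a linear-ratio mode is
available (see "Decisions on open points").

## Promoter scores, group scaling, tiers

The promoter score of a gene for one sample is the **maximum**
normalized track value over bins intersecting the inclusive window
[TSS − 2000, TSS + 2000], clipped at contig edges (`tss_score()`).
Group means are arithmetic means over each group's samples.

Because library depth and IP efficiency differ between groups, a single
multiplicative factor is estimated and applied to the target group
(`group_scale_scores()`): the exponentiated median, over genes positive
in both groups, of log(mean_ref) − log(mean_target). The median makes
the estimate robust to the minority of genuinely differential
promoters; after scaling the median per-gene log-ratio is exactly zero,
and the two directed factors are exact inverses. The factor is reported
in the run log.

Binding tiers partition the overall mean score: low (< 2), moderate
(2 ≤ s ≤ 4), high (> 4) — `assign_tier()` reproduces this boundary
behaviour exactly (1.99 → low, 2.0 and 4.0 → moderate, 4.01 → high).

## Consensus peaks and annotation

`consensus_peaks()` merges per-sample peak calls by single-linkage on
≥ 1 bp overlap, drops merged regions supported by fewer than 2 distinct
samples, scores survivors by the maximum normalized intensity within
the region, and ranks them (descending intensity, genomic coordinate as
the deterministic tie-break; the top 500 are kept for motif work).
Support counts distinct samples, not peak records, so two fragmented
calls from one sample do not fake reproducibility.
`annotate_peaks()` classifies each summit as promoter (±2 kb of a TSS),
gene body, or intergenic, and reports the signed distance to the
nearest TSS oriented in the transcription direction (negative =
upstream).

# Association statistics

All exact tests use the **minimum-likelihood two-sided convention**:
the p-value sums all outcomes whose null probability does not exceed
that of the observation (with the customary 1 + 10⁻⁷ slack against
floating-point ties). This matches the convention of R's
`fisher.test`/`binom.test` and is verified in the test suite both ways:
against brute-force enumeration oracles and against the stats
functions.

* `fisher_exact_2x2()` — hypergeometric enumeration; sample odds ratio
  ad/bc.
* `binomial_sign_test()` — for scatter comparisons of paired
  intensities; ties are dropped by the caller before testing and their
  count is reported.
* `wilcoxon_group_compare()` — paired signed-rank by default (exact
  null distribution for n ≤ 25 without ties, tie-corrected normal
  approximation otherwise); unpaired rank-sum mode available.
* `bh_adjust()` — the Benjamini–Hochberg step-up from its definition.

`motif_family_enrichment()` screens each motif by Fisher on
[positive-set genes with a promoter hit, without; negative with,
without], then collapses to families with the dual correction
`corrected_p = min(best_p × n_motifs, median_p)` capped at 1 — the
Bonferroni branch protects small families, the median branch large
ones — followed by BH across families. `binding_vs_deg_association()`
tests preferential promoter binding between up- and downregulated
genes. `category_crosstab()` stacks binding-tier composition across
expression categories (S>A / S<A / S=A / UN × down / up / none) and
runs a headline Fisher on {moderate, high} vs {low} between two chosen
categories — which cells form that 2×2 is configurable because the
source summary does not fully specify it.

# The synthetic generator

`sim_config()` fixes the study conditions; the defaults *are* the
simulated experiment, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 2000 | genes, in 10 kb slots on two contigs |
| `n_per_group` | 3 | cell lines per group (3 SGA vs 3 AGA) |
| `nb_dispersion` | 0.05 | NB dispersion, constant across genes |
| `frac_deg` | 0.1 | planted DEGs, half up / half down in group A |
| `deg_fold` | 4 | planted linear fold change |
| `frac_e2f1_target` | 0.5 | fraction of group-A-up DEGs that are direct targets |
| `kd_fold` | 3 | target repression in the knockdown member of a pair |
| `peak_amp_by_tier` | 0 / 350 / 1550 | bump summit amplitude over background 50 |
| `background_rate` | 50 | Poisson background signal per 50 bp bin |
| `hist_boost` | 2 | histone amplitude multiplier in group A at up-target genes |

Gene means are log-normal (median 200, log-sd 1) — mean 200 at
dispersion 0.05 is a comfortably expressed gene, and the spread
exercises the CPM filter and the low-count tail. The amplitudes map
tiers onto the normalized-score partition: with background 50, a
moderate bump reaches log2((50+350)/50) ≈ 3 ∈ (2, 4] and a high bump
log2((50+1550)/50) = 5 > 4, with Poisson noise leaving comfortable
margins on both sides. Bumps are symmetric triangles over ±500 bp —
the shape is irrelevant to a max-in-window score, and a triangle keeps
its maximum at the summit. Peaks are emitted at planted bumps with
±100 bp per-sample jitter and 10% per-sample dropout, plus 5%
sample-specific noise peaks that the consensus step must remove. Motif
hits are planted within ±1.9 kb of motif-bearing TSSs; each of the
four E2F-family motifs hits such a promoter independently with
probability 0.7 (family members share similar consensus sequences, so
one true site matches several of them), and four background families
(SP, NFY, CTCF, AP1) hit 10% of promoters at random.

One RNG stream per output family (annotation / counts / tracks /
motifs) is derived from the master seed, so regenerating one artifact
never shifts the others; identical configurations are byte-identical
on disk.

**What the generator does not emulate** — and therefore what green
tests do *not* establish about real data: read-level artifacts
(mapping, duplicates, GC and fragment-length effects), gene–gene
correlation, per-gene dispersion trends, broad or asymmetric binding
domains, co-factor motifs co-occurring with the planted family, and
partial knockdown heterogeneity between lines. Recovery results here
validate the *machinery*, not field performance.

# Decisions on open points

* **Tier-threshold units.** The printed thresholds (2, 4) are applied
  to the normalized track value in its default log2-ratio units (the
  cited normalizer defaults to log2); a linear-ratio mode is one
  option away (`track_mode = "ratio"`), in which case thresholds should
  be supplied on that scale.
* **Scoring before scaling.** Per-sample promoter scores are computed
  on raw normalized tracks and the group factor is applied afterwards;
  scaling a max-in-window score and taking the max of a scaled track
  commute for a positive factor, and this order keeps single-sample
  scores interpretable.
* **Which knockdown contrast identifies targets.** The pooled paired
  design over all six lines (six pairs) is the primary target
  identification; the per-group three-pair analyses feed the Venn
  comparison. Per-group analyses at three pairs have little power
  without moderation — their near-empty intersection on synthetic data
  is a documented limitation, not a defect.
* **Quadrant and crosstab 2×2 constructions** — pinned as described
  above, configurable where the source is silent.
* **Wilcoxon pairing.** Intensity comparisons between groups are
  paired per gene by default (each gene contributes its two group
  means); the unpaired mode is exposed.
* **Basal criterion.** The basal contrast uses raw p < 0.05 plus the
  fold-change cutoff, the knockdown contrast BH FDR < 0.05 — both as
  stated for the respective analyses; either criterion can be selected
  for either design. Planted-truth recovery is assessed under the FDR
  criterion, the appropriate choice when a discovery list's error rate
  is the quantity of interest.

# Numerical conventions

Coordinates are 1-based closed inside R (the GRanges convention);
BED-family formats are converted at I/O (a minus-strand gene occupying
0-based [1000, 3000) has its TSS at 1-based 3000). All window
boundaries are inclusive. Percentages print half-up to one decimal.
Pseudocounts: 0.5 on CPM before log2; 1 on both numerator and
denominator of track ratios. SES ties resolve to the largest split
point; consensus ranking ties resolve by genomic coordinate; all
outputs are written with fixed formatting so identical runs are
byte-identical.

# Problem sizes used by the validation suite

The packaged checks run: oracle equivalence on ~1,050 random small
instances (tables ≤ 30, n ≤ 25, BH lists ≤ 12, plus 200 100-bin SES
tracks); planted-truth recovery on 50 generator seeds at the default
2,000-gene scale; type-I control of the quadrant test on 200 null
simulations of 400 genes; and byte-level determinism on paired
150-gene pipeline runs. These sizes were chosen to give stable
empirical rates (binomial standard errors of a few percent) on a
single CPU.

# Limitations

The package implements neither read alignment, peak calling, nor de
novo motif discovery — it consumes their standard outputs (bedGraph,
narrowPeak, motif position tables). Dispersion is modelled as a single
shared constant; data with strong mean–dispersion trends deserve a
dedicated DE package. The group-bias scaling assumes the majority of
promoters are non-differential, as does median-of-ratios
normalization; designs where most genes change violate both.
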