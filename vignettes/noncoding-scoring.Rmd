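---
title: "Scoring non-coding variants with a gene-partitioned boosting bundle"
author: "ncvscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring non-coding variants with a gene-partitioned boosting bundle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Most causal variants in unresolved Mendelian cases are expected outside
coding sequence, where effect prediction is hardest. `ncvscore` implements
a supervised scorer for non-coding single-nucleotide variants (SNVs): a
gradient-boosted tree classifier trained to discriminate curated
pathogenic non-coding SNVs from presumed-benign common SNVs, with a score
equal to the predicted positive-class probability. The pathogenic signal
the features capture is purifying selection — long-term interspecies
conservation, recent human sequence constraint, gene-level intolerance —
plus the local sequence context and splice-altering potential of the
position.

Three design elements carry most of the statistical weight:

* **Gene-partitioned hold-out.** Genes, not variants, are the unit of
  generalization: variants of one gene share features and would leak
  between training and test if split naively. All protein-coding genes are
  dealt into $k = 10$ partitions; the bundle trains $k$ models, model $j$
  blind to partition $j$, and any variant is scored by the model blind to
  its gene. A hard gate (`assert_no_leakage`) re-verifies the exclusion
  before every fit.
* **Region- and partition-matched negatives.** Scores must not simply
  re-discover *where* a variant lies. Each positive is paired with
  `ratio = 10` negatives from the same region type (upstream, 5'UTR,
  intronic, 3'UTR, downstream, intergenic) and the same gene partition, so
  the classifier must separate classes within region strata.
* **Per-gene caps.** At most one positive and one negative per gene
  prevents a handful of heavily reported genes from dominating the
  training distribution. The negative-side cap is enforced globally
  across the table; when a small pool makes that unsatisfiable for some
  positive, the cap is relaxed for that positive only (still one negative
  per gene within its pairing group, every pool variant used at most
  once), and the relaxation is recorded in the sampling metadata — the
  exact 1:10 ratio is never silently abandoned.

## Region typing

The canonical transcript model per gene (single transcript by design;
collapsing isoforms is the data producer's job) defines, strand-aware:
exonic-within-CDS = coding (excluded); exonic 5'/3' of the CDS = 5'UTR /
3'UTR; intra-span non-exonic = intronic; within 1 kb outside the span =
upstream / downstream; otherwise intergenic up to a 10 kb cap, beyond
which variants are unscorable. The 1 kb windows and 10 kb cap are
package defaults (common annotator practice), configurable per call.
When several genes could claim a position the precedence is coding >
5'UTR > 3'UTR > intronic > upstream > downstream > intergenic, then
smaller distance to the span, then lexicographic gene id — the coding
sentinel outranks everything because a position inside any gene's CDS
exon is not a non-coding variant. Assignment is deterministic and tiles
the line: a scan across a toy gene shows every position receiving exactly
one label with boundaries exactly at the geometry.

## Curation

Clinical-assertion records (ClinVar/HGMD-like TSVs) pass six ordered
filters; each is a pure predicate, so the surviving set is
order-independent while the telescoping report is order-defined.
"Conflicting annotations" is operationalized strictly: pooled over all
sources per variant, any co-occurrence of a pathogenic-side assertion
with a benign-side *or uncertain* one drops the variant; additionally at
least one pathogenic-side assertion must be present (a record with only
benign assertions is not a pathogenic candidate at all). "Evidence of
homozygosity" defaults to any homozygote (`max_homozygotes = 0`), and the
frequency gate to 0.1%; "common" negatives default to allele frequency
at least 1% and "rare" ones to at most 0.1% — the cutoffs are
configurable and logged, since they are conventions rather than
constants of the method.

## The 58-feature schema

Four categories, 58 slots, 26 flagged as new relative to a
first-generation scorer: interspecies conservation (16; per-clade
phastCons/phyloP-style plus large-alignment 241-mammal/43-primate slots),
human constraint (16; context tolerance and frequency-spectrum summaries
plus constraint z-scores for nine major subpopulations and one global),
gene level (16; including `loeuf`, the loss-of-function
observed/expected upper bound), and sequence context (10: GC and CpG
content, the 6-way region one-hot, and the splice-delta maxima at variant
and position level). Slot names other than the structurally required ones
are **provisional placeholders**: they fix the category structure and
counts, and real deployments bind them to concrete annotation tracks via
the `annotation_source` contract (tabular lookups; declared feature
subsets must be disjoint across sources — overlap is a setup error, not a
runtime surprise). Missing values are passed to the trees natively and
never imputed: boosted trees route missing observations, and inventing an
imputation model would add assumptions the scorer does not need.

GC/CpG use a 101-bp window by default (odd, configurable): GC is counted
over non-N bases, CpG over dinucleotide positions, so truncated
chromosome-end windows adjust their denominators. The splice maxima
collapse four delta scores (acceptor/donor gain/loss) per alt to a
variant-level max, and over all alts at the position to a position-level
max.

## Synthetic data: what it emulates, and what it does not

`synth_config()` defaults describe the study conditions the package
targets: 765 pathogenic SNVs, one per disease gene (a 900-gene universe,
85% disease-flagged), a region mix of 61/133/475/77/9/10 across
upstream/5'UTR/intronic/3'UTR/downstream/intergenic, a 1:10 design ratio
and 10 partitions. Gene models are laid out with 25–40 kb gaps on 22
chromosomes with realistic-order exon/intron sizes; variants are placed
inside their intended region's actual coordinates, so the generator and
`classify_region` must agree — an integration property the tests assert
exactly.

Features are unit-variance Gaussians: benign variants centred at the
per-region baseline shift (`region_bias`, default +0.5 SD in the 5'UTR to
emulate the benign score inflation observed there), pathogenic variants
shifted additionally by `d[category]` (default 1 SD — moderate,
deliberately imperfect separation). Features with a [0, 1] domain are
passed through the normal CDF, a monotone map that respects the domain
while preserving separation. A `fraction_splice_driven` (default 0.2) of
positives carries its signal mainly in the splice slots (near-1 maxima,
other shifts damped to 30%), giving the splice added-value analysis a
true positive control. Missingness is applied per category (default 5%
for the three conservation-style categories).

Two points matter for interpreting test results. First, `d` and
`fraction_splice_driven` are *independent* signal channels: the
zero-signal null used in the effect-size sweep sets both to zero, while
the spike-in and bias analyses keep the splice channel on. Second, the
generator is deliberately simple — independent Gaussian features, no
linkage structure, no mutation-rate heterogeneity, no realistic
allele-frequency spectrum, per-variant rather than per-gene gene-level
features. Passing tests therefore demonstrate that the machinery is
correct and recovers planted structure, not that the defaults predict
real-data performance.

## Training and scoring

XGBoost with binary log-loss; defaults: up to 500 rounds, early stopping
after 25 stagnant rounds on a 10% *gene-grouped* held-in validation split
(so even the early-stopping split cannot leak genes), learning rate 0.05,
depth 6, row/column subsampling 0.8, positive-class weight 1 — the 1:10
imbalance is part of the design and left unreweighted. All values are
serialized with the bundle; `nthread = 1` gives bit-reproducible fits and
is the default, with multithreading available at a documented
reproducibility caveat. Variants in genes absent from the partition map
are scored by the arithmetic mean of the k models and flagged
`model_index = "mean"` — the symmetric choice when no blind model is
identifiable.

## Evaluation conventions

* **AUROC** is the rank statistic (probability a random positive outranks
  a random negative, ties half-credited), identical to the trapezoidal
  area and invariant under monotone transforms.
* **AUPR** is average precision as a step sum over distinct thresholds
  (ties grouped into one step), not an interpolated trapezoid — tie-robust
  and exactly checkable against a step-enumeration oracle.
* **Rank tests** use exact enumeration for small tie-free samples
  (combined n ≤ 12, or ≤ 12 non-zero differences) and the
  tie-/continuity-corrected normal approximation otherwise; zero
  differences in the signed-rank test are discarded, and all-zero input
  returns statistic 0, p = 1 with a warning.
* **Spike-in percentiles** use the midrank form
  $100\,(b + t/2)/(n + 1)$ with the inserted variant excluded from its
  background (hence the $+1$); the naive $100\,b/n$ form is available by
  flag. The convention avoids hard 0/100 saturation and is monotone in
  the inserted score.
* **Gene rank percentiles** in the splice added-value analysis are
  $100\,r/(G+1)$ with midrank ties over $G$ genes.
* Single-class regions in the stratified report yield NA metrics with a
  warning rather than disappearing, so region counts always sum to the
  global row.

## Problem sizes used by the test and acceptance suites

The suites run entirely on synthetic data at desk scale, chosen so the
full run stays lightweight while estimates remain stable: the
structural checks use the full default study (765 positives, 7650
matched negatives); the bundle-structure check uses 220 genes / 100
positives at k = 10 (about 1100 rows); the effect-size sweep uses 150
genes / 100 positives at k = 5 across d in {0, 0.5, 1, 2, 3}; the
spike-in check uses 100 insertions in 20 individuals with 2000-score
backgrounds. Measured behavior at those sizes: chance-level held-out
AUROC (0.46) at zero signal, AUROC 0.99 at d = 1, 1.0 at d = 3, spike-in
paired p far below 0.01 at d = 1.

## Known limitations

Real annotation tracks are out of scope by design: the package ships the
lookup contract and synthetic stand-ins, not genome-wide data. One
canonical transcript per gene means isoform-dependent region boundaries
are not represented. The per-gene region-bias analysis conditions on the
5'UTR as the inflated reference region; with very few common variants per
gene its medians get noisy (singletons are flagged, not dropped). Scores
are raw classifier probabilities, not calibrated clinical quantities, and
are meant as one input to diagnostic prioritization rather than a
stand-alone decision rule.
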