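# ncvscore

Supervised pathogenicity scoring of **non-coding single-nucleotide
variants** (SNVs) in monogenic Mendelian disease, built around a
leakage-free, gene-partitioned gradient-boosting design.

Whole-genome sequencing resolves only a minority of suspected Mendelian
cases, and most of the genome — and a growing share of reported causal
variants — is non-coding. `ncvscore` is for method developers and
bioinformaticians who want a fully testable, end-to-end implementation of
this class of scorer: every stage from gene-model parsing to evaluation
runs on synthetic data generated by the package itself, with no external
downloads.

## The method

1. **Region typing.** Each SNV is assigned to one gene and one of six
   non-coding region types — upstream, 5′UTR, intronic, 3′UTR, downstream,
   intergenic — from a canonical transcript model (strand-aware; CDS-exonic
   positions are excluded as coding).
2. **Curation.** Clinical-assertion records pass six high-confidence
   filters (SNV-only, scorable region, no conflicting assertions pooled
   across sources, monogenic Mendelian inheritance only, no homozygotes and
   population allele frequency ≤ 0.1%, deduplication) to form the positive
   set.
3. **Gene partitioning.** Protein-coding genes are split into *k* = 10
   partitions, stratified by chromosome and by the presence of curated
   pathogenic variants; within every stratum cell the partition counts
   differ by at most 1.
4. **Matched training set.** At most one positive per gene; each positive
   is paired with 10 negatives drawn from the same partition and the same
   region type (at most one negative per gene, with a recorded per-positive
   relaxation when small pools make that global cap unsatisfiable), giving
   an exact global 1:10 ratio.
5. **Model bundle.** *k* XGBoost classifiers (binary log-loss; 58-feature
   input over four categories — interspecies conservation, human
   constraint, gene-level conservation, sequence context including two
   splice-delta maxima). Model *j* never sees partition *j*'s genes, and a
   hard leakage gate verifies this before every fit, so every variant can
   be scored by a model blind to its gene. The score is the predicted
   positive-class probability
   `s(x) = P(pathogenic | x) ∈ [0, 1]`.
6. **Evaluation.** Region-stratified AUROC (rank statistic, ties
   half-credited) and AUPR (average precision); per-gene region-bias
   analysis against the inflated 5′UTR benign background;
   within-individual spike-in rank percentiles
   `100 · (#below + ½·#ties) / (n + 1)` with paired one-sided Wilcoxon
   tests; and a splice added-value comparison of gene rank percentiles
   between a raw splice score and the model score.

## Worked example

```r
library(ncvscore)

cfg <- synth_config(n_genes = 150, n_positives = 100,
                    fraction_disease_genes = 0.75,
                    n_pool_per_gene = 40, d = 1, seed = 301)
res <- run_synthetic_pipeline(cfg, k = 5)
res$report[, c("region", "n_pathogenic", "n_benign",
               "score_auroc", "score_aupr")]
```

```
       region n_pathogenic n_benign score_auroc score_aupr
       <char>        <int>    <int>       <num>      <num>
1:     global          100     1000   0.9914200  0.9430369
2:   upstream            8       80   0.9953125  0.9659091
3:       UTR5           18      180   0.9941358  0.9671679
4:   intronic           62      620   0.9979969  0.9853033
5:       UTR3           10      100   1.0000000  1.0000000
6: downstream            1       10   1.0000000  1.0000000
7: intergenic            1       10   1.0000000  1.0000000
```

The table mirrors the package's cross-validation report: every variant was
scored by the bundle model blind to its gene's partition, then
discrimination between the 100 pathogenic and 1000 matched benign variants
is reported globally and per region. At a one-standard-deviation feature
shift (`d = 1`) the bundle separates the classes almost perfectly
(global AUROC 0.99), despite the benign score-inflation bias the generator
injects into the 5′UTR.

A shell front end over the same functions lives at `inst/cli/ncvscore`
(subcommands `synth`, `curate`, `partition`, `build-train`, `annotate`,
`train`, `score`, `evaluate`, `run-all`), e.g.

```sh
Rscript inst/cli/ncvscore run-all --synthetic --seed 7 --out runs/demo
```

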