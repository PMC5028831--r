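# ovitx

Comparative bulk RNA-seq analysis for two-breed livestock muscle studies —
the complete downstream pipeline from a gene-level count matrix to validated
differentially expressed genes (DEGs), functional enrichment, interaction
and co-expression networks, and qPCR confirmation.

The motivating design is a comparison of longissimus muscle transcriptomes
between two sheep breeds (Qianhua Mutton Merino, QHMM, and Small Tail Han,
STH; three biological replicates each), but every stage is generic for any
two-condition, small-n bulk RNA-seq comparison.

## What it computes

1. **Quantification** — mapping-summary arithmetic (mapped and
   unique-mapped rates), RPKM values
   (`RPKM = 10^9 C / (N L)`), and upper-quartile size factors
   (`s_j = Q75_j / geomean(Q75)`, computed on nonzero counts) with the
   normalized counts they imply.
2. **Differential expression** — a two-condition empirical-Bayes
   negative-binomial/Beta mixture, written from scratch. Each gene is
   either equally expressed (EE; one Beta(α, β_EE) prior on the shared NB
   probability parameter, pooled over all samples) or differentially
   expressed (DE; independent per-group priors sharing α). The Beta-NB
   marginal is closed-form; an EM algorithm estimates the mixing
   proportion `p_DE` and hyperparameters; the per-gene posterior DE
   probability drives a posterior FDR (cumulative mean of `1 − PP` over
   the ranked genes). DEG call rule: `|log2FC| > 0.585` (a 1.5-fold
   change) and `FDR < 0.05`. Dispersion is handled by marginalizing the
   per-gene likelihood over an empirically fitted log-normal dispersion
   prior (Gauss–Hermite quadrature) — essential for calibration at n = 3.
3. **Enrichment** — one-sided hypergeometric (Fisher) tests of DEG sets
   (all / up / down) against GO-namespace and pathway gene sets, raw
   `P < 0.05` filter, top-15 reports, BH q-values reported for
   transparency.
4. **Ontology graph** — ancestor closure of the significant GO terms
   ("GO-trees"), exported as GraphML/DOT; focus-term selection by name
   pattern with the associated DEG panel.
5. **Networks** — pathway-act (induced interaction subgraph of significant
   pathways; degree centrality), gene-act (typed KEGG-style relations
   restricted to DEGs), and per-group Pearson co-expression networks with
   BH-FDR edge selection and signed edges; hub discovery by an own-coded
   k-core decomposition (iterative minimum-degree peeling).
6. **qPCR validation** — 2^−ΔΔCt relative quantification against a
   housekeeping reference, Welch t-test on per-animal ΔCt, and sign
   concordance with the RNA-seq fold changes.
7. **Synthetic data** — a fully ground-truth-labelled generator emulating
   the two-breed design (NB counts at 13–16 M reads/sample, planted DE
   fractions and effect sizes straddling the 1.5-fold threshold, planted
   co-expression modules with a target correlation, planted enriched
   terms, Ct plates consistent with expression), so the whole pipeline is
   testable offline.

## Worked example

```r
library(ovitx)

cfg <- sim_config(n_genes = 2000, seed = 42)   # two breeds, 3 + 3 replicates
sim <- simulate_counts(cfg)
de  <- de_test(sim$counts)                     # UQ-normalize + EB mixture
de
#> de_result (STH vs QHMM): 2000 genes, 42 up, 46 down
de$model
#> eb_model: p_de=0.0796 alpha=0.796 beta=(63, 112, 85.8) converged in 14 iter

head(subset(de$table, call != "none"), 5)
#>      gene mean_QHMM mean_STH log2fc      fdr call
#> 7  G00007      1068      103 -3.378 9.46e-05 down
#> 8  G00008      3573     1789 -0.998 4.83e-02 down
#> 22 G00022       943      315 -1.581 3.13e-02 down
#> 35 G00035       873      153 -2.509 2.11e-03 down
#> 46 G00046      2148      531 -2.017 2.34e-04 down
```

`p_de = 0.0796` is the estimated fraction of DE genes (0.1 was planted; at
n = 3 some small effects are undetectable). Of the 88 genes called, 84 were
genuinely planted — an observed FDR of 0.045 at the nominal 0.05. Fold
changes are STH relative to QHMM, so `down` means lower expression in STH.

Mapping-summary arithmetic on the bundled fixture:

```r
ms <- read_mapping_summary(system.file("extdata", "mapping_summary.tsv",
                                       package = "ovitx"))
head(mapping_rates(ms), 3)
#>   sample mapped_rate unique_rate
#> 1     A1       0.925       0.877
#> 2     A2       0.912       0.853
#> 3     A3       0.921       0.872
```

## Command line

```sh
Rscript -e 'ovitx::ovitx_cli()' simulate --out sim --n-genes 2000 --seed 1
Rscript -e 'ovitx::ovitx_cli()' run \
  --counts sim/counts.tsv --design sim/design.tsv \
  --annotation sim/annotation.gmt --hierarchy sim/hierarchy.tsv \
  --relations sim/relations.tsv --qpcr sim/qpcr.tsv --out results/
```

`run` writes RPKM and DE tables (TSV), enrichment reports, GO-tree
GraphML/DOT, SIF + GraphML networks with k-core numbers, the RQ table, and
a checksum manifest; reruns with the same seed are byte-identical.
Subcommands `de`, `enrich`, `network`, `qpcr` run single stages; a YAML
config (`--config`) can replace the flags. `--coexpr-samples pooled` and
`--edge-alpha` relax the per-group co-expression networks, which are
near-empty at n = 3 by statistical necessity (|r| > 0.997 is needed for a
raw p < 0.05 at df = 1).

## Vignette

`vignettes/ovitx-methods.Rmd` documents the model, its assumptions, all
tunable thresholds, what the synthetic generator does and does not emulate,
and the numerical design decisions.
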