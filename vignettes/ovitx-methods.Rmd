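---
title: "ovitx: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ovitx: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ovitx implements the downstream analysis of a two-condition bulk RNA-seq
comparison with few biological replicates — the setting of livestock muscle
transcriptomics, where two breeds are compared with three animals each.
This vignette documents the statistical models, their assumptions, the
tunable parameters, and the design decisions taken where the design was
genuinely open. It states no empirical result that the package's test suite
does not itself compute.

## Quantification

**Mapping summary.** Rates are simple ratios of read counts
(`mapped_rate = mapped/all`, `unique_rate = unique/all`), reported at three
decimals. The bookkeeping identity `mapped + unmapped = all_reads` is
enforced exactly; `unique + repeat ≈ mapped` is only checked within a
100-read tolerance, because published summaries are known to disagree by a
handful of reads (the bundled fixture itself is off by 12–13 reads in three
samples).

**RPKM.** `RPKM_gj = 10^9 · C_gj / (N_j · L_g)`. The denominator `N_j` is
the within-matrix column sum by default, so the pipeline is self-contained
when no aligner report is available; aligner-reported totals can be passed
as an override. Both choices appear in practice and the source study does
not say which it used.

**Upper-quartile normalization.** `s_j = Q75_j / geomean(Q75)`, with the
75th percentile taken over each sample's *nonzero* counts
(linear-interpolation quantiles, R type 7). Factors are normalized to
geometric mean 1 rather than to a reference sample, for symmetry between
the two groups. Normalized counts are `C_gj / s_j`; their per-group means
are the "normalized counts" reported next to fold changes. Note that this
normalization fixes relative, not absolute, scale: multiplying one sample's
counts by `c` rescales every normalized column by `c^{1/J}`, leaving all
expression ratios and fold changes invariant.

## Differential expression

### Model

For gene *g*, normalized counts `X_gj` follow a negative binomial with size
`r_g` and probability parameter `q`, with a conjugate Beta prior on `q`.
Integrating `q` out gives the closed-form Beta-NB marginal for any sample
set *S* sharing one `q`:

```
log f(S) = Σ_{j∈S} log C(x_j + r_j − 1, x_j)
         + log B(α + Σ r_j, β + Σ x_j) − log B(α, β)
```

Two hypotheses per gene: **EE** (one `q` pooled over all samples, prior
Beta(α, β_EE)) and **DE** (independent `q1`, `q2` per group, priors
Beta(α, β_DE1), Beta(α, β_DE2) sharing α). The prior mixing proportion
`p_DE` and the four hyperparameters are estimated by EM:

* **E-step** — posterior DE probability from the marginal ratio.
* **M-step** — `p_DE` as the mean posterior (exact); hyperparameters by
  bounded quasi-Newton (`optim`/L-BFGS-B) on log-parameterized values in
  `[10^-3, 10^3]`, a few iterations per EM step from a warm start
  (generalized EM, so the observed-data log-likelihood trace is
  non-decreasing, which the tests assert).
* Initialization `p_DE = 0.2, α = 0.4, β = 1`; convergence when the
  relative change of `p_DE` falls below `tol = 1e-4`; `max_iter = 50`,
  with a loud warning (never silence) on non-convergence.

### Dispersion: the decisive numerical choice

With three replicates per group the within-group variance has four degrees
of freedom, and any per-gene point estimate of the NB dispersion produces
confidently wrong posteriors: genes whose variance is underestimated by
chance become false positives, and (if one shrinks aggressively) genes with
genuinely high dispersion do too. We verified both failure modes on
simulation, and that the same EM machinery with *oracle* dispersions is
well calibrated — the miscalibration is entirely dispersion-estimation
noise.

The pipeline therefore marginalizes over dispersion. A log-normal prior for
the excess dispersion `φ` (`Var = μ + φμ²`) is fitted from all genes: the
central value and spread of `log φ̂` are moment-matched, subtracting the
chi-square sampling noise `trigamma(d/2)` of the 4-df estimates. The
Beta-NB marginals of both hypotheses are then averaged over a 7-node
Gauss–Hermite discretization of this prior (Gauss–Hermite rather than
equal-probability bins because the *upper tail* of the prior is what
protects against false positives). Each gene's own replicates weight the
grid through the likelihood, so tight genes keep their power while
apparently-tight-but-truly-noisy genes are discounted.

Point-dispersion alternatives remain available and exported:
`estimate_size_params` (raw pooled-within-group method of moments,
`r = mean²/max(var − mean, 1e-8)`, capped at `1e8`) and
`moderate_size_params` (one-sided limma-style squeeze with prior df from
trigamma matching), and `em_fit(r = ...)` accepts any per-gene size vector.
"Pooled" variance always means pooled *within-group* variance: using the
cross-group variance absorbs the group difference into dispersion and
collapses the mixture to `p_DE = 0` (verified numerically).

### Calls and FDR

Ranking genes by posterior DE probability, the FDR of calling the top *k*
is the cumulative mean of `1 − PP`; the call set is the largest *k* with
FDR strictly below the 0.05 target, and a gene's reported FDR is that of
the smallest call set containing it. This is the soft-threshold
(posterior-probability) FDR native to the empirical-Bayes formulation; BH
on tail p-values is deliberately *not* used here (it is used for
correlation edges, below). The DEG rule is `|log2FC| > 0.585 ∧ FDR < 0.05`,
both strict; `2^0.585 = 1.5` at one decimal, i.e. a 1.5-fold threshold.
Fold changes are `log2(mean2/mean1)` of normalized group means, group 2
being the test breed; a pseudo-count of 1 is added to both means when
either is zero, and genes zero in every sample are excluded with a log
message. Report rounding: fold changes one decimal, FDR two significant
digits.

## Enrichment

One-sided hypergeometric over-representation per term
(`P = Σ_{i≥k} C(K,i)C(N−K,n−i)/C(N,n)`), computed for the all/up/down DEG
subsets. The universe is the expressed background (genes with nonzero total
count in the matrix), not the whole annotation — an expression-aware
background avoids inflating enrichment of broadly expressed categories.
The significance filter is the raw `P < 0.05` (strict) used by the source
protocol; no multiple-testing correction is applied to the filter, but BH
q-values are emitted for transparency. The χ² test with Yates correction is
provided only as a cross-check (`chisq_enrich`), flagged as applicable when
all expected cells are ≥ 5; Fisher is authoritative. Terms with no universe
members are skipped with a log entry; `k = 0` with `K > 0` yields `P = 1`.

## Ontology graph

The "GO-tree" is the ancestor closure of the significant terms under the
child→parent hierarchy, with edges restricted to the closure and ancestors
flagged non-significant unless significant themselves. The hierarchy input
is an OBO-lite TSV (child, parent, namespace) rather than full OBO parsing
— fixtures and tests need no ontology download, and a full-OBO adapter is a
straightforward extension point. Multiple parents are allowed (GO is a DAG,
the "tree" name notwithstanding); cycles are detected by DFS and reported
with the offending cycle. Because the published criterion for narrowing
hundreds of significant terms to a focus set is unstated, focus-term
selection is explicit user input: name patterns, matched
case-insensitively, returning the union of the matched terms' DEG
memberships with per-gene term indices.

## Networks

**Pathway-act / gene-act.** Induced subgraphs of typed relation tables
(closed vocabulary: activation, binding/association, compound, expression,
indirect effect, inhibition, missing interaction, phosphorylation,
dephosphorylation, ubiquitination) on the significant pathways and the
called DEGs respectively. Pathway centrality is plain degree; the maximum
set is reported as the "central" pathways. Relations touching unknown ids
are skipped and counted.

**Co-expression.** All-pairs Pearson correlation of the selected genes'
normalized expression across one group's replicates; two-sided p from
`t = r√((n−2)/(1−r²))` with `n − 2` df; BH across all pairs; edges where
`q < 0.05`, signed by the sign of `r`, with `|r|` as weight. BH is used
because the protocol says only "FDR < 0.05". At `n = 3`, `|r| > 0.997` is
required for even a raw `p < 0.05` (t critical 12.706 at df = 1), so
per-group networks with three replicates are near-empty by statistical
necessity: the faithful per-group/0.05 default is kept, a loud warning is
emitted when no edge passes, and the CLI exposes
`--coexpr-samples pooled` and `--edge-alpha` as explicit relaxations.
Zero-variance genes are excluded with a log entry.

**k-core.** Own implementation of the standard decomposition by iterative
minimum-degree peeling on the undirected simple view (sign and weight are
ignored — the definition is purely topological). Hubs are *all* nodes
attaining the maximum core number (plateau sets, matching reports of 9 and
11 hub genes). The tests check it against an independent brute-force
oracle and the monotonicity of core numbers under edge addition.

## qPCR

Technical replicates are averaged per (gene, sample);
`ΔCt_s = Ct_gene,s − Ct_ref,s`; `ΔΔCt` is the mean ΔCt difference of test
minus calibrator group; `RQ = 2^−ΔΔCt` with amplification efficiency fixed
at 2 (the method's namesake; efficiency calibration is out of scope). The
per-animal ΔCt is the biological unit, so significance is a Welch t-test on
the per-animal ΔCt values (n = 3 per group), starred at P < 0.05 / < 0.01.
Two exact identities are tested: `RQ(A vs B) · RQ(B vs A) = 1`, and
invariance under adding a constant to every Ct of a sample (a global
efficiency shift cancels in ΔCt). Concordance with RNA-seq is sign
agreement of `log2 RQ` with the DE fold change.

## The synthetic world

The generator emulates the two-breed study: two groups × 3 replicates
(configurable), expected library sizes uniform in 12.8–16.4 M (the
unique-mapped totals of the motivating study), NB counts with per-gene mean
`baseline_g · sf_j · 2^(lfc_g·[group2])`, and a ground-truth record of every
plant. Defaults, chosen once:

* **Baseline** log-normal, log2 mean 5, sd 2 — spans the observed
  normalized-count dynamic range (tens to hundreds of thousands).
* **DE plants** at rate `p_de = 0.1`; `|log2FC| = 0.585 + Exp(mean 0.8)`,
  sign ±½ — effect sizes straddle the 1.5-fold call threshold so the call
  rule, not only the statistics, is exercised.
* **Dispersion** `φ = 0.005 + 1/Gamma(shape 3, rate 0.15)` (mean ≈ 0.08,
  i.e. biological CV ≈ 28%, plausible for outbred farm animals of one
  breed under a common environment; the source study provides no
  within-breed variance estimates, so this is not calibrated to the real
  data).
* **Gene lengths** log-normal around 2.5 kb (only RPKM uses them).
* **Modules**: each planted co-expression module shares a per-sample
  latent factor. Module genes are drawn among adequately expressed genes
  (baseline ≥ median), their conditional dispersion is the 0.005 technical
  floor — the latent factor *is* their biological variability; otherwise
  NB noise scaling with the factor caps the attainable linear correlation
  at `1/(1+φ)` — and each gene's log-normal loading solves the exact
  linear-scale equation `signal/(signal+noise) = ρ`. The latent draws are
  standardized within each group so the *realized* within-group
  correlation matches the target `module_rho` even with 3–6 replicates;
  groups get independent realizations (no cross-group sharing).
* **Annotation**: random term memberships (sizes log-uniform 10–100) over
  four namespaces; planted terms sample members with 10× odds for DE
  genes; the hierarchy is a random forest per namespace (first three terms
  are roots, every later term picks one earlier parent).
* **Relations**: unordered pairs at a configurable density, types uniform
  over the closed vocabulary.
* **qPCR**: `Ct = intercept − slope·log2(relative expression) + N(0, sd)`,
  slope 1, sd 0.15 cycles, reference gene constant across groups, 3
  animals × 3 technical replicates; a planted-DE reference gene is refused.
* **Determinism**: each generator derives its own stream from
  `(master seed, stage name)`, so regenerating one input never perturbs
  another; identical seeds give byte-identical outputs.

What the generator does **not** emulate: read-level artifacts (GC bias,
positional bias, mapping ambiguity), correlated library-preparation
batches, outlier samples, isoform switching, and annotation
incompleteness. A green test therefore establishes that the *algorithms*
are correct and calibrated in their stated model, not that the biological
conclusions of any particular study are right.

## Known limitations

* At n = 3 the per-group co-expression stage is structurally powerless at
  FDR < 0.05 (see above); this is reported loudly rather than silently
  relaxed.
* The DE engine's sensitivity at n = 3 is limited for effects near the
  1.5-fold threshold: on simulation, roughly half the planted genes with
  the default effect-size mix are recovered (rising to ~0.8 when all
  planted effects exceed 2-fold), at an observed FDR well under the
  nominal target. Under the null the calibrated engine still makes ~1
  false call per 10^4 genes; "zero calls" on a null dataset is therefore
  probable only for small gene panels.
* Hyperparameter estimation assumes a common (α, β·) across genes; strong
  mean-dispersion trends are handled by the dispersion prior, not by
  expression-stratified hyperparameters.
* The enrichment filter deliberately uses raw P < 0.05 (as in the
  motivating protocol); interpret term lists accordingly and prefer the
  emitted BH column for any confirmatory claim.
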