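---
title: "Hierarchical enrichment and combined gene scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical enrichment and combined gene scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicscore)
```

`omicscore` implements a cross-platform "global omics" workflow: DEG
selection by fold change, directional hypergeometric pathway enrichment,
meta-z aggregation over a system/subsystem/pathway hierarchy, the
composite gene scores MCS and ARCS, cross-platform Jaccard concordance,
and an efficiency-adjusted comparative-Ct calculator. This vignette
documents the statistical model, the tunable parameters, the numerical
choices, and the design decisions taken where the method family leaves
room — and what the synthetic validation does and does not establish.

## The enrichment model

A contrast compares a treatment group to a control group within one
genotype and platform. Group summaries are arithmetic means of replicate
samples *on the declared scale*: differences of means for log2-scale
(microarray-like) data, log2 ratios of means (plus an optional
pseudocount, default 1) for linear-scale (FPKM-like) data. The two
conventions agree exactly only when groups have one sample or identical
replicates; with replicates they differ by the arithmetic-vs-geometric
mean gap, which we treat as part of the platform difference rather than
harmonizing it away.

DEGs are genes with fold change ≥ 2 (`threshold` and the
inclusive/strict comparator are configurable). Up- and down-sets are
tested separately against each pathway with the hypergeometric upper
tail

$$p = \sum_{i=x}^{\min(M,n)} \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

where the universe $N$ is the union of genes in the loaded annotation —
not the platform's gene list. DEGs absent from the annotation are
dropped from $M$ and $x$ with a reported count; this matches the
convention that the enrichment background is the set of genes the
annotation knows about. Raw p < 0.05 defines significance; no
multiple-testing correction is applied, by design of the original
method.

### z-transformation and its clamps

Pathway p-values are transformed as $z = \Phi^{-1}(1-p)$, computed with
the numerically stable tail form. Two clamps keep $z$ finite:

* below, $p$ is clamped at $10^{-16}$ (z ≈ 8.2), needed for extreme
  overlaps whose tail underflows;
* above, $p$ is clamped at $1 - 10^{-16}$ (z ≈ −8.2), needed because a
  discrete test yields $p = 1$ exactly whenever the overlap is zero.

The second clamp means "pathway with zero overlapping DEGs" maps to a
large negative z. That is the honest Stouffer transform of the exact
tail, but it makes meta-z values of sparsely hit units noisy when DEG
sets are small; it fades as DEG sets approach realistic sizes (15–40%
of the universe), where zero overlaps are rare.

### Direction collapse

Each pathway carries two z-scores (up, down). For aggregation and gene
scoring a single combined z per pathway is needed. The default is the
**maximum** of the two. The alternatives (`sum`, `signed`) are
available but have a structural weakness in this setting: a strongly
regulated pathway is *depleted* of the opposite direction's DEGs, so
the opposite upper-tail z is systematically negative and, under
summation, cancels real signal; the signed difference additionally
flips the sign of down-regulated pathways, so up- and down-planted
pathways cancel at the system level. The max rule is biased under the
null — the max of two null z-scores has mean ≈ 0.56 — so combined z
values, and every meta-z built from them, sit high by a predictable
offset. Consequence: system-level significance calls at the
$\Phi^{-1}(0.95)$ quantile are liberal. We keep the quantile rule for
its simplicity and note that the same liberality appears in the
original method's uniformly large positive system scores.

### Meta-z

Subsystem and system scores are $\sum_i z_i / \sqrt{n}$ over their
member pathways (Stouffer), with $\sum_i z_i / n$ (a plain average)
available via `meta_denominator`. The root form is the default because
observed system-level magnitudes (|meta-z| ≈ 10 over dozens of
pathways) are consistent with $\sqrt{n}$ scaling, and because a single
pathway then contributes its own z unchanged under both conventions.

## Gene scoring

For gene $i$ belonging to $N_i$ pathways:

$$\mathrm{MCS} = \max_j\left(Z^{sys}_{x(j)} + Z^{sub}_{y(j)} + Z^{path}_j\right) + S_N + S_{FC}$$
$$\mathrm{ARCS} = \frac{\sum_j\left(Z^{sys}_{x(j)} + Z^{sub}_{y(j)} + Z^{path}_j\right) + N_i S_N + S_{FC}}{\sqrt{N_i}}$$

$Z^{sys}$ and $Z^{sub}$ are the gene's mean pathway z within each
system and subsystem it touches; $S_N$ and $S_{FC}$ are its pathway
count and |log2FC|. Every term is min-max normalized to [0, 1]. Three
decisions here were genuinely open:

* **The max runs over the gene's pathways**, each pathway j
  contributing its own system/subsystem terms, with $S_N$ and $S_{FC}$
  added once outside the max — the only reading under which five
  unit-normalized terms give the documented [0, 5] range.
* **Normalization pools are global**, one pool per term kind across all
  (gene, system) and (gene, subsystem) values, the pathway z pool, the
  pathway-count pool and the |log2FC| pool — pooled over genes that are
  both annotated and measured. Per-gene pools would break the [0, 5]
  bound. A degenerate pool (max = min) maps to 0.
* **ARCS divides by $\sqrt{N_i}$** ("average root") by default, with
  $/N_i$ as an option; the root form preserves the documented property
  that the score's range grows with the pathway count.

Genes in no annotated pathway get no MCS/ARCS (the expressions are
undefined at $N_i = 0$); they remain eligible for fold-change ranking.
Ranking is descending with deterministic lexicographic tie-breaks, and
precision@k is the fraction of the top k found in the gold-standard
positive set. Orthology mapping for cross-species gold standards is a
pure union lookup: a target gene is positive if any mapped source gene
is, and unmappable genes are dropped with a count.

## Concordance and clustering

Per condition, the two platforms are compared by Jaccard similarity at
three levels: DEG sets, significant-pathway sets, and
significant-system sets (meta-z above $\Phi^{-1}(0.95)$, exposed as
`system_z_threshold`). Two empty sets return 0 with a warning rather
than NaN, keeping report aggregation total. Condition profiles
(conditions × systems meta-z) are clustered with Euclidean distance and
average linkage (configurable), with a flat 2-group cut; the procedure
is deterministic given input order, and invariant to input order up to
label permutation.

## qPCR calculator

ΔΔCt = (Ct_target − Ct_ref)_experimental − (Ct_target − Ct_ref)_control
and fold change = base^(−ΔΔCt) with base 1.94, an
efficiency-adjusted amplification factor treated as a given constant (a
perfectly efficient reaction would use 2). Technical-replicate Cts are
averaged per (sample, gene) before ΔΔCt; biological samples stay
separate, each experimental sample is referred to the control group's
mean ΔCt, and groups are summarized as median ± standard error with at
least 3 independent samples required.

## The synthetic study design

`synthetic_design()` emulates a two-platform feeding study: four
genotypes of increasing severity × three diets (control NOR plus DIO
and FAT treatments) × 4 replicates, 2000 genes, 60 pathways (25–55
genes) in 18 subsystems and 6 systems. Both platforms share per-gene
baselines (log2 N(7, 1.5²)) and true signal; noise is platform-specific
(sd 0.5 log2 microarray, 0.6 RNA-seq before exponentiation; the linear
platform is the exponentiated signal, hence nonnegative by
construction). Three signal layers:

* **Planted pathways** (4, under one system, 2 up / 2 down, 60% of
  members recruited): per-gene effect = genotype multiplier (1.0, 1.4,
  1.8, 2.2 log2) × per-gene jitter U(0.3, 1.3). The wide lower jitter
  tail is deliberate: it keeps a sub-population of genes crossing the
  fold-change threshold at every step of the genotype grid, so the
  planted system's expected meta-z keeps rising instead of saturating
  at the top of the dose–response.
* **Diet responders** (400 genes at ±U(0.7, 1.6) log2, identical in all
  genotypes and on both platforms), roughly half concentrated in 18
  diet-responsive pathways (one coherent direction per pathway) and
  half scattered. Effects sit near the fold-change cutoff on purpose:
  each platform detects about half of them, largely independently, so
  gene-level platform agreement stays low while the pathway- and
  system-level calls those genes produce are shared — the convergence
  phenomenon the workflow is built to exploit.
* **Idiosyncratic responders** (50 per platform, ±U(1.5, 3) log2,
  platform-specific): probe artifacts and single-gene responders. They
  dominate the top of a fold-change ranking but lack pathway support,
  which is exactly why MCS outranks FC on the planted positives.

The gold standard is the planted-gene set, optionally diluted with
decoys. Everything is deterministic given the design seed.

What passing the synthetic suites does **not** show: the generator has
Gaussian log-scale noise (no count overdispersion or mean–variance
trend), no batch or library-size artifacts, no correlated gene modules
beyond the planted/diet structure, and an orthology-free gold standard.
Results on real two-platform data depend on upstream normalization
quality, which is out of scope here (matrices are consumed
preprocessed).

## Verification sizes and numerical checks

The test suite verifies the hypergeometric tail against exhaustive
subset enumeration for every valid configuration with universe ≤ 12 (to
1e-12), the z-transform as the inverse normal tail on [−6, 6] (to
1e-9), and the two closed-form anchors exactly: a constructed gene
attaining every pool maximum scores MCS = 5, and the Ct calculator
returns 1.94 at ΔΔCt = −1. The statistical suites run at these sizes,
chosen so the full suite completes in well under a minute on one core:

* null calibration: 100 null replicates at database scale (4000 genes,
  10 pathways of 400–700 genes, per-direction DEG fraction ≈ 0.3 from
  noise alone), 2000 pathway tests. A one-sided discrete test is
  conservative, so the rejection rate approaches 5% only where the
  overlap distribution is dense; at this scale the exact expected rate
  is ≈ 0.045, inside the binomial 99% band around 0.05 that the test
  asserts. At desk scale (small pathways, small M) the same test is far
  below nominal — a property of discreteness, not an implementation
  artifact.
* recovery, precision, concordance and dose–response: 20 replicates of
  the default design (seeds 1–20). Planted pathways are significant at
  the strongest contrast in ≥ 90% of pathway × platform × replicate
  combinations; mean precision@20 under MCS exceeds FC; pooled Jaccard
  medians order strictly gene < pathway < system; and the replicate-mean
  planted-system meta-z is nondecreasing along the genotype axis on both
  platforms. The mean profile is the right object for the dose–response
  claim: single replicates can invert adjacent genotypes by sampling
  noise, as multi-condition studies themselves occasionally report.

## Known limitations

* The annotation universe definition (genes in ≥ 1 pathway) makes N
  depend on the annotation release; scores are comparable only within
  one annotation.
* With the max direction-collapse rule, combined z and meta-z are not
  null-calibrated quantities; treat them as enrichment indices, not
  test statistics.
* S_FC uses one contrast's |log2FC|; scoring a gene across several
  contrasts means running the scorer per contrast.
* MCS favors well-annotated genes by construction (unannotated genes
  are unscored), mirroring the original method's stated bias toward
  well-studied genes.
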