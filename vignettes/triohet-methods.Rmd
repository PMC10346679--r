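---
title: "Models and methods behind triohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind triohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(triohet)
```

This vignette is the package's account of its science: the models it
fits, the parameters that matter, the choices made where the underlying
study left the design open, and what the synthetic validation does and
does not establish.

## The experimental design the package targets

All functions are organized around a *trio* — a female parent (P1), a
male parent (P2) and their F1 hybrid — measured by bulk RNA-seq across
environments, timepoints and biological replicates. The motivating design
is a super-hybrid rice flag-leaf study: 3 genotypes × 2 environments
(early- and middle-season) × 2 timepoints (1 and 10 days post-anthesis)
× 3 replicates = 36 libraries, with matching phenotype measurements
(flag-leaf length, width, area, thousand-grain weight).

## Phenotypic heterosis

For a trait with genotype means $P_1$, $P_2$, $F_1$:

$$\mathrm{MPH} = 100\,\frac{F_1 - (P_1+P_2)/2}{(P_1+P_2)/2},\qquad
  \mathrm{HPH} = 100\,\frac{F_1 - \max(P_1,P_2)}{\max(P_1,P_2)}.$$

"Higher parent" means the parent with the larger mean regardless of which
direction is agronomically desirable; that convention is what reproduces
negative published HPH values for traits where the hybrid falls below the
better parent. Both measures are scale-invariant, so unit choices do not
matter.

Significance: the source table marks heterosis with `*`/`**` at p < 0.05
/ 0.01 but does not state its test. `heterosis_significance()` uses a
two-sided Welch t-test of the F1 replicates against (i) per-replicate-pair
mid-parent values $(P_{1i}+P_{2i})/2$ — requiring paired parental
replicates — and (ii) the better parent's replicates. Welch rather than
pooled-variance because genotypes need not share a variance; the paired
mid-parent construction keeps the parental contrast on the replicate
scale rather than treating the mid-parent as a known constant.

The packaged trait table carries the published genotype means alongside
the published MPH/HPH columns. Recomputation reproduces every printed
percentage within 0.15 points — consistent with the table's mixture of
rounding and truncation — except two entries (early-season 10-DPA TGW
MPH, printed 2.81 where the means give 3.05; and early-season 10-DPA
leaf-area HPH, printed 0.1 where the means give 0.95). Both are flagged
in the fixture's `note` column and treated as printing errors, not
reproduction targets.

## Expression normalization and differential expression

Counts are normalized to FPKM with per-sample column totals standing in
for "total mapped reads" (alignment-level totals are not available at the
count-table boundary). The DEG rule is the study's:
$|\log_2 \mathrm{ratio}| \ge 1$ and $\mathrm{FDR} \le 0.005$, thresholds
inclusive. The reported effect size is always
$\log_2\!\big((\bar x_B + c)/(\bar x_A + c)\big)$ on FPKM with
pseudocount $c = 1$, which keeps ratios finite at zero expression.

**Choice of test.** The study names no usable test statistic, so the
package had to choose. Two are provided behind one interface:

* `exact_nb` (default): edgeR's classic exact negative-binomial test
  (TMM normalization, empirical-Bayes dispersion estimation, exact
  two-group test). Sharing dispersion information across genes is what
  makes an FDR cutoff as stringent as 0.005 usable at $n = 3$ replicates:
  a 4-fold shift then reaches BH-adjusted significance reliably.
* `welch`: a per-gene Welch t-test on $\log_2(\mathrm{FPKM}+1)$, fully
  self-contained. With 3 replicates its per-gene p-values cannot get
  small enough to clear FDR ≤ 0.005 after multiplicity adjustment at
  realistic effect sizes, so it is offered for large-replicate designs
  and as a transparent cross-check, not as the default.

Genes with zero counts in both groups are defined to have
$\log_2$ ratio 0 and p = 1.

## Mode of inheritance

Treating per-gene expression as a quantitative trait, the trio ANOVA

$$y = u + G_A + G_D + S_R + e$$

decomposes expression into the overall (mid-parent) mean $u$, a composite
additive effect $[a] = (\bar P_1 - \bar P_2)/2$, a composite dominance
effect $[d] = \bar F_1 - (\bar P_1 + \bar P_2)/2$, a replication effect
$S_R$, and residual error. $S_R$ is estimable only when replicates form
blocks across genotypes; with paired replicates it is removed from the
residual (two-way ANOVA, $2(n-1)$ residual df), otherwise the model
reduces to genotype means with a pooled within-genotype variance. Sign
convention: P1 is the female parent listed first, so $[a] > 0$ means the
female parent expresses higher.

The potency (dominance) ratio $H_p = [d]/[a]$ classifies each gene:
additive $(-0.2, 0.2]$, partial dominance $(0.2, 0.8] \cup (-0.8, -0.2]$,
dominance $(0.8, 1.2] \cup (-1.2, -0.8]$, over-dominance $H_p \le -1.2$
or $H_p > 1.2$. The intervals are implemented exactly as published, which
makes the boundary points asymmetric in sign ($-0.2$ is partial dominance
while $+0.2$ is additive); away from the four boundary points the
classification is sign-symmetric. Degenerate cases are defined so the
classes partition the extended real line: $[a]=0, [d]\neq 0$ maps to
signed infinity (over-dominance), both zero to 0 (additive).

**Expression scale.** The analysis scale is $\log_2(\mathrm{FPKM}+1)$ by
default (configurable). The source does not state its scale; the log
scale makes $[a]$ and $[d]$ fold-change-like, matching the fold-change
basis of the DEG rule.

**Grouping.** `fit_inheritance()` defaults to one fit per environment ×
timepoint cell, mirroring how per-timepoint breakdowns are reported. With
3 replicates per cell, however, $\widehat{H_p}$ carries substantial noise
(standard deviation ≈ 0.3 at NB dispersion 0.1 and $|a| = 1$), and
plug-in classification leaks a few percent of genes across the interval
boundaries — mostly out of the narrow additive class. When no environment
or timepoint effect is expected (as in the package's class-recovery
validation, where none is planted), `group_by = NULL` pools all libraries
of each genotype, which is the configuration under which planted class
proportions are recovered within ±3 percentage points. Per-cell
breakdowns at $n = 3$ should be read with that boundary-leakage caveat.

**Confidence-interval gate.** The source mentions 99.8% confidence
intervals for $[d]-[a]$ (when $[d]>0$) or $[d]+[a]$ (when $[d]<0$) in its
classification; the intended role is ambiguous as written.
`hp_ci_gate()` implements it as an optional pre-filter — genes whose
relevant contrast interval covers 0 are dropped before summarizing — and
it is off by default, since applying it changes the composition of the
summarized set in ways the published breakdowns do not document.

## Gene-set logic

SDG is the union of up- and down-regulated genes of the timepoint
contrast for one genotype in one environment. SDG_hp is
$\mathrm{SDG}_{F1} \setminus (\mathrm{SDG}_{P1} \cup \mathrm{SDG}_{P2})$:
"present in the hybrid but not in the parents" is read as excluding genes
significant in *either* parent, the stricter reading of hybrid-specific.
SSDG_hp is the intersection of the per-environment SDG_hp sets. Venn
counts enumerate the seven disjoint regions of three sets and always sum
to the union size.

## Co-expression networks

The WGCNA-style workflow is implemented in full rather than wrapped:

1. low-expression filter: keep genes with nonzero expression in ≥ 80% of
   samples;
2. variability selection: top `n_top` genes (study value 5000) by median
   absolute deviation, computed on the analysis scale
   ($\log_2(x+1)$ by default) — a raw-scale MAD would rank genes by
   expression level rather than variability;
3. unsigned adjacency $a_{ij} = |\mathrm{cor}(x_i,x_j)|^\beta$ (study
   soft power β = 20; unsigned is the classical default and the source
   does not state signed vs unsigned). Zero-variance genes get
   correlation 0 with a warning;
4. topological overlap
   $\mathrm{TOM}_{ij} = \big(\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}\big) /
   \big(\min(k_i,k_j) + 1 - a_{ij}\big)$ with
   $k_i = \sum_{u \ne i} a_{iu}$;
5. average-linkage hierarchical clustering of $1-\mathrm{TOM}$ with a
   **static cut at height 0.995** on the dissimilarity scale. A
   quantile-of-merge-heights rule was considered and rejected: once
   unclustered background genes exist, their many near-1 merges push any
   high quantile above every informative split and everything collapses
   into one module. The absolute 0.995 cut (the conventional static
   default) lets unconnected genes fall off as singletons while
   correlated blocks stay together. Clusters below `min_module_size`
   (default 30, the classical choice; unstated in the source) become
   "grey"; modules are labelled M1, M2, … by decreasing size. A
   degenerate tree whose merges all occur at one height returns a single
   module;
6. module eigengenes: first principal component of the gene-standardized
   module expression, sign-oriented to correlate positively with the
   module's mean profile, unit variance;
7. module–trait correlation: Pearson r with two-sided t p-values,
   matched by sample id; constant profiles report r = 0, p = 1 with a
   warning.

The published module count (24 modules from 5000 genes) and specific
modules are data-dependent and not reproducible without the raw data;
validation instead demonstrates recovery of planted correlation blocks
(adjusted Rand index ≥ 0.9 under 36 samples, within-block correlation
0.8, between-block 0).

## Enrichment

Over-representation only (upper tail): for a term annotating $K$ of $N$
universe genes and a query of $n$ genes overlapping it in $k$,
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeometric}(N, K, n)$, BH-adjusted
across tested terms, significant at FDR ≤ 0.05 (inclusive). Terms
annotating fewer than 5 universe genes are excluded before testing
(the study's minimum-mapping-entries setting). The universe defaults to
the annotated genes intersected with the measured genes; "genome
background" is not otherwise defined in the source. Annotations are flat
gene sets; no ontology-graph propagation is attempted.

## The synthetic-data generator

`simulate_trio_counts()` plants effects on the log2-expression scale: a
gene with baseline $m$ has genotype means $m \pm a$ (parents) and $m + d$
(hybrid), with $H_p = d/a$ drawn uniformly inside the interval of its
planted class ($|H_p| \le 2.5$ for over-dominance) and $|a|$ fixed at
`effect_scale`. Class sizes follow the configured proportions
deterministically (largest-remainder rounding); the default proportions
(22.07 / 41.81 / 10.9 / 25.22 percent) mirror the published early-season
1-DPA breakdown. Timepoint shifts of `sdg_shift` (default 2 on log2, i.e.
4-fold — comfortably above the 2-fold DEG rule) are planted in all
genotypes for "shared" genes and in the hybrid only for "hybrid" genes;
environment effects on non-shifted genes are zero. Planted co-expression
blocks add a per-sample latent factor with loading $\sqrt{\rho}$ plus
independent noise $\sqrt{1-\rho}$, giving within-block correlation ρ on
the log2 scale. Expected counts are rescaled so every library's expected
total equals `library_size` (default 20 million reads), then drawn
NB(mean, dispersion) with variance $= \mu + \phi\mu^2$ (default
$\phi = 0.1$, a typical bulk RNA-seq magnitude; 0 gives Poisson). The
depth and dispersion defaults are conventional values, not estimates
from the source, and are configurable.

What the generator does *not* emulate: GC/length biases, sample-specific
library composition effects beyond total-depth rescaling, outlier
samples, batch structure, isoform-level variation, or correlated
environment × genotype interactions. Passing recovery tests on this
generator therefore demonstrates that the implementations are correct
under their stated models, not that the biological conclusions of any
particular dataset would be recovered.

## Numerical choices and problem sizes

Tie-breaks: MAD selection keeps earlier genes on ties; module labels
order by decreasing size. Degenerate inputs are defined rather than
errored wherever a sensible limit exists (all-zero genes, zero-variance
genes, constant traits, $[a] = 0$). BH adjustment and the classifier are
pure functions of their inputs; the only randomness anywhere is the
simulator's, and every simulation function takes an explicit seed, so
identical configuration and seed reproduce outputs bit for bit.

The validation suite sizes its simulations for sharp checks at modest
cost: 5000 genes × 36 libraries for class-proportion recovery, 2000
genes for DEG recovery at dispersion 0.05, 600 genes for the
hybrid-specific set logic, 3 × 60-gene planted blocks for network
recovery, and 200 annotation draws for the enrichment ranking check.

## Known limitations

* The per-gene ANOVA is fit independently per gene; no variance
  moderation is applied to $[a]$/$[d]$ standard errors (the DEG stage is
  where information sharing happens).
* The potency-ratio classification ignores estimation uncertainty unless
  the CI gate is enabled; breakdowns at small replicate numbers carry
  boundary leakage (quantified above).
* The static tree cut is deliberately simple and deterministic; the
  dynamic hybrid tree cut used by some network analyses can split nested
  modules that a static cut merges.
* FPKM's column-total normalization is composition-sensitive; the DEG
  default mitigates this via TMM factors on the count side, but the
  reported fold changes remain FPKM-based by design.
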