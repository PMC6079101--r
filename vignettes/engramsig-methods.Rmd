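---
title: "Activity signatures and reactivation prediction: models and methods"
author: "engramsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity signatures and reactivation prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Hippocampal dentate granule (DG) neurons are sparsely active, yet the few
that fire during a salient experience mount a strong, multi-wave
transcriptional response. Immediate early protein markers give a temporal
handle on that response: FOS protein appears within an hour of activation
and decays within a few hours, while ARC protein persists for roughly five
hours in the DG. Sorting nuclei on FOS and ARC therefore separates cells
activated recently (FOS+), cells activated hours ago (ARC+FOS−), and cells
activated in both of two spaced exposures (ARC+FOS+). `engramsig`
implements the single-nucleus RNA-seq analysis built on this design: from
log2(TPM+1) expression matrices it identifies cell types, quantifies the
activity-induced differential expression in each, classifies genes into
temporal response groups, scores nuclei for the late-developing signature,
and asks the central question: does a transcriptional signature measurable
hours after a first experience predict which neurons will *reactivate* when
the experience recurs?

Because the package must be exercisable end to end without any download,
a first-class simulator generates cohorts with the statistical structure
the analysis assumes, together with complete ground truth. Every stage is
validated against that truth or against closed-form oracles.

## Pipeline stages and their models

### Quality control

Nuclei are dropped when total aligned reads fall below 100,000 or detected
genes below 4,000 (values at the cutoff are kept: only nuclei *below* the
thresholds are outliers). A second rule targets label consistency: a
nucleus stained FOS− but expressing *Arc* transcript above 2.5 log2(TPM+1)
was probably active shortly before sacrifice and has already lost FOS
protein, so it cannot serve as an inactive baseline; the rule uses a
strict inequality and never touches FOS+ nuclei. In the assembled
pipeline the Arc rule is applied only to home-cage and 1-h nuclei —
ARC+FOS− nuclei at the 4/5-h time points are *selected by* Arc and must
not be removed. Both filters are idempotent and order-independent, which
the test suite checks directly.

### Cell-type identification

Hierarchical iterative clustering: embed the current nucleus set into two
dimensions with t-SNE (initial dimensions 20, perplexity 17, theta 0 —
the exact algorithm), bisect the embedding with hierarchical clustering
(Euclidean distance, complete linkage), test the bisection by differential
expression, and recurse into each half. A branch becomes a leaf when the
split can no longer support differential expression (fewer than
`min_de_genes = 10` genes at adjusted p < 0.05; the stopping rule in the
original workflow is qualitative, so the count is a package choice) or
when a child would fall below `min_leaf` nuclei. Perplexity shrinks
automatically on small branches to satisfy the t-SNE constraint
`n > 3 * perplexity`.

Refinement then fits two successive random forests, each retaining genes
whose Mean Decrease Gini exceeds a cutoff (default 1.0, on genes with at
least 10 TPM summed across nuclei), and a final forest on the surviving
genes re-predicts every nucleus's label out of bag. Per-cluster precision
is the out-of-bag fraction of nuclei whose prediction recovers their
cluster. Importance cutoffs on the Gini scale are *not* dimensionless:
the total importance budget grows with sample count and concentrates or
dilutes with feature count, so the scaled-down configurations used in the
test suite scale the cutoff accordingly (0.25 at ~1,200 genes and ~100
nuclei); the full-size default stays 1.0.

### Reproducibility-optimized differential expression

The two-group statistic for gene $g$ is

$$ d_g = \frac{|m_{A,g} - m_{B,g}|}{\alpha_1 + \alpha_2\, s_g}, $$

with group means $m$ and pooled standard error $s_g$. The regularization
pair $(\alpha_1, \alpha_2)$ is tuned by bootstrap reproducibility: for
each of $B$ pairs of within-group bootstrap resamples the top-$K$ gene
lists are compared, the mean overlap is baselined against permuted-label
pairs, scaled by the bootstrap SD of the overlap, and the
$(\alpha_1, \alpha_2, K)$ maximizing this Z-score is selected. The scanned
grid is $\alpha_1 \in \{0, 0.1, \ldots, 5\}$ with $\alpha_2 = 1$, plus a
scale-free $\alpha_2 = 0$ (fold-change ranking) candidate;
$K \in \{25, 50, 100, 200, 300, 500\}$ capped at the gene count. $B$
defaults to 500 with seed 1234; the test suite and acceptance script use
$B = 100$ at their reduced problem sizes. A zero pooled SE is guarded:
$d = 0$ when the mean difference is also zero, infinite otherwise, so
$\alpha_1 > 0$ acts as the regularizer the statistic is designed around.

p-values come from group-label permutation. When $\binom{n}{n_A}$ is small
(at most 200 by default) every assignment is enumerated and each gene gets
an exact per-gene p-value — the suite verifies these against an
independent brute-force oracle on 3+3 and 4+4 groups. Otherwise `n_perm`
sampled permutations are pooled across genes (the statistic's
regularization makes gene nulls comparable), giving p-value resolution of
order $1/(n_\mathrm{genes} \cdot n_\mathrm{perm})$, and Benjamini–Hochberg
controls the FDR.

Two caveats shape the DE evaluation design. First, TPM is compositional:
planting a large, single-direction shift in 10% of the transcriptome
changes every other gene's TPM through library renormalization, which no
two-group test can distinguish from signal. The operating-characteristic
evaluation therefore plants a direction-balanced signature (half up, half
down), measuring the test rather than the normalization artifact. Second,
with many true effects the pooled permutation null is contaminated and
conservative; sensitivity targets are evaluated against that reality.

The subsampling comparison draws equal-size FOS+/FOS− subsets per cell
type without replacement (10 + 10, five repetitions), counts adjusted-p <
0.05 genes per draw and compares counts across cell types by one-way
ANOVA on the untransformed counts — the design that shows DEG-count
differences across cell types are not sample-size artifacts.

### Temporal gene groups and signature scores

Genes are grouped by their pattern of significance across three
comparisons against home-cage FOS−: 1 h FOS+, 4 h ARC+FOS−, 5 h ARC+FOS−.
The mapping is: {1h}→1, {5h}→2, {4h}→3, {4h,5h}→4 (late), {1h,4h,5h}→5
(sustained), {1h,5h}→6, {1h,4h}→7. The source workflow lists six patterns
for seven groups; {1h,4h} is the unique unlisted non-empty subset and is
assigned to group 7 on combinatorial-completeness grounds. The seven
patterns enumerate all non-empty subsets of the three comparisons, so the
assignment partitions the significant genes — a property test loops over
all eight patterns.

The late-signature score is each nucleus's projection on the first
principal component of the group-4 genes (centered, unscaled log2(TPM+1);
no scaling is standard when none is stated). PC signs are arbitrary, so
the component is oriented to correlate positively with summed late-gene
expression. Classification into early/late uses 1-D 2-means by default,
labelling the higher-center cluster late; the fixed-threshold policy
(boundary assigned to late) is available but its canonical value of 10 is
in dataset-specific units and does not transport across cohorts or
simulation scales, which is why two-means is the default. A center
separation below the pooled within-cluster SD flags the split as weakly
supported. ARC+FOS+ double-exposure nuclei labelled early are Newly
Activated; labelled late, Reactivated.

Activity pseudotime reduces nuclei (restricted to activity-dependent
genes) to two independent components, builds a Euclidean minimum spanning
tree in component space and takes geodesic distance from one end of the
tree's diameter path, oriented so pseudotime increases with the anchor
gene (*Arc* by default; if the anchor is constant the orientation falls
back to summed activity-gene expression and the result is flagged). Two
implementation notes: the ICA is a compact fastICA (logcosh contrast,
symmetric decorrelation) written in the package, and the estimated
sources are rescaled by their mixing-column norms — unit-variance
whitening would inflate a noise component to signal scale and scramble
MST geodesics. The diameter-path construction recovers a 1-D ordering; it
deliberately does not attempt branch-point detection.

### Reactivity prediction

Candidate genes are those differentially expressed between Reactivated
and Not Reactivated nuclei, filtered on the fraction of Reactivated
nuclei expressing them above 1 log2(TPM+1): at least 80% for upregulated
genes, at most 40% for downregulated ones. Genes differentially expressed
at 1 h versus home cage (the immediate early response) and genes
associated with batch are excluded, leaving genes whose signal is already
in place hours after the first exposure. Batch association, unspecified
in the source workflow, is a Kruskal–Wallis test across batches at FDR
0.05. An optional initial feature-elimination round (one forest plus a
Gini cutoff, the same machinery as pooling) is provided but off by
default: at simulated scale it can empty small, clean gene sets, and the
pooling step already performs the importance-based reduction.

Pairwise random forests — model i (Reactivated vs Newly Activated) and
model ii (Reactivated vs Not Reactivated) — train on 15 nuclei per class;
genes above 0.4 Mean Decrease Gini in either model are pooled; a
three-way forest on the pooled set reports per-class hold-out error.
Forests default to 10,000 trees; the test suite uses 1,000, which is past
the point where importance rankings stabilize at these sample sizes. ROC
curves sweep all probability thresholds with trapezoidal AUC (cross-checked
in the tests against both brute-force enumeration and an independent ROC
library). The trained three-way model scores single-exposure 4/5-h
nuclei: a nucleus whose highest-probability class is Reactivated is
predicted-Reactivated (pR), otherwise pNR.

Validation uses the *reactivity component*: among the ten leading
principal components of the full transcriptome, the one maximizing the
two-sample t-statistic between reactivity-defined subgroups (FOS+ nuclei
split by early/late signature, or late-signature nuclei split by FOS
status). Scores on a second, independently simulated cohort are
correlated (Pearson) with the first cohort's model probabilities — the
across-cohort design that shows the signature is not a batch artifact.

### Functional annotation

Enrichment is a local upper-tail hypergeometric test per annotation term
with BH adjustment across terms overlapping the query (standard
enrichment practice; configurable). The gene–gene distance represents
each gene as a weighted indicator vector over its terms, weighting term
$t$ by $\log_2(1 + \mathrm{parents}_t)$ so deeper, more specific terms
count more — the weighting form is a package choice since only the
existence of parent-count weights is documented; identity weighting is
available, and cosine distance is invariant to rescaling all weights.
Genes annotated only to zero-parent (root) terms carry no weighted
information and are rejected by the distance (and skipped by the
pipeline's network stage). Networks export as SIF edge lists at a
distance threshold.

## The simulator

`simulate_experiment()` draws molecule counts per gene and nucleus from a
negative binomial (dispersion 0.3; 0 gives Poisson) whose mean is a
per-gene baseline (uniform on 2–50 counts) times $2^{\mathrm{lfc}}$, where
the log-fold-change matrix encodes cell-type markers (+3 log2 in the own
type), the seven temporal groups (mean shift `effect_size`, default 2
log2 units, applied in the states where each group is on; a quarter of
group-1/4 genes are repressed instead), batch (gene-wise additive log2
shift per batch, SD 0.15), and the predictive program. Counts are then
zeroed by independent Bernoulli dropout whose rate decays with the
expected count (`rate * exp(-mu/5)`, rate 0.1) — deep-coverage
SmartSeq2-style nuclei essentially never lose a TPM ~500 gene, and a flat
rate would dominate log-scale variance with unrealistic outliers —
normalized to TPM per nucleus and reported as log2(TPM+1). Metadata
(reads, detected genes, batch, mouse) is derived from the realized counts.

Model choices worth knowing when interpreting test results:

- **Canonical IEGs.** A handful of genes carry real symbols (*Fos*,
  *Arc*, *Sorcs3*, ...) planted at the head of their temporal groups with
  near-zero baseline (0.1 counts) and strong induction (~30 counts),
  matching the biology the Arc-discordance rule depends on: without a
  low IEG baseline the TPM > 2.5 rule would be meaningless.
- **Predictive genes.** Upregulated predictive genes are off at baseline
  (0.2 counts) and on (8–45 counts, drawn per gene) in Reactivated and in
  a `reactivated_fraction`-sized primed subset of single-exposure late
  nuclei — the bimodality the selection filters rely on. Downregulated
  ones are expressed everywhere and suppressed in the same nuclei. The
  per-gene strength heterogeneity mirrors the wide importance range of
  real predictive genes; with uniform strengths, forest importance
  spreads evenly and an absolute Gini pooling cutoff selects nothing.
- **Reactivation as a selection effect.** Reactivated and primed nuclei
  carry the late/sustained program scaled by `reactivated_late_scale`
  (default 1.5). Conditioning on reactivation selects the high tail of a
  heterogeneous late program, so Reactivated cells sit above Not
  Reactivated cells on exactly the genes that are developing hours after
  the first exposure; this is also what makes late activity-induced genes
  legitimate members of the predictive set. Without this, Newly Activated
  and Not Reactivated nuclei would be identical on every feature
  surviving the selection filters and no classifier could separate them.
- **Default cohort.** The double-exposure design mirrors the reported
  train/test split (15 per class training; 37/50/21 testing, i.e. 88
  ARC+FOS+ and 65 ARC+FOS− A>A nuclei), with `reactivated_fraction = 0.4`
  (≈ 36/88) and round counts elsewhere; per-condition counts not reported
  anywhere are set to 20–40 nuclei, typical for sorted SmartSeq2 plates.

What the simulator does **not** emulate: gene length bias in TPM (all
genes share an implicit length), gene–gene correlation beyond the planted
programs, empty-droplet/doublet artifacts, mouse-level random effects
separate from batch, and FACS gating noise (protein labels are exact, with
the optional FOS-low intermediate off by default). Passing tests
demonstrate correctness of the machinery under these assumptions, not
performance on any real dataset.

## Problem sizes

The test suite and acceptance script run the same code as a full-size
analysis at reduced, fixed sizes chosen to exercise every code path:
DE operating characteristics on 2,000 genes with 20+20 nuclei over five
seeds; clustering on 150 nuclei × 2,000 genes with 30 markers per type;
the reactivity cohort at 2,000 genes with the full 88/65 double-exposure
design; the end-to-end determinism run on 1,200 genes and ~250 nuclei
with B = 60 bootstrap pairs and 1,000-tree forests. Full-size defaults
(5,000 genes, B = 500, 10,000 trees) remain the package defaults.

## Known limitations

- The pooled permutation null is conservative when a large fraction of
  genes is truly differential; per-gene exhaustive p-values are exact but
  only feasible for small groups.
- Gini-scale cutoffs (refinement 1.0, pooling 0.4) are absolute and tied
  to data scale; they are exposed as parameters and must be rescaled for
  small problems.
- The two-means signature policy assumes two latent states; genuinely
  unimodal scores are split anyway (flagged when centers are closer than
  the pooled SD).
- Pseudotime assumes a single unbranched trajectory.
- The clustering-based "extreme outlier" removal mentioned alongside the
  original QC has no reconstructable rule and is provided only as an
  optional silhouette-based filter, off by default.
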