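---
title: "senatlas: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{senatlas: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and the numerical conventions adopted where the design was open.
It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The setting

The package targets paired single-nucleus RNA + ATAC data from a two-age-group,
multi-donor design over several mononuclear cell types (MuSC, FAP, EC, SMC in
the default naming). Cell-type labels, peak calls and count matrices are
inputs: clustering, alignment and peak calling are upstream of this package.

## Quality control and normalization

Cells are retained when all rules hold with **strict** inequalities: total
UMI > 1,000 and < 40,000; mitochondrial percentage (on raw counts, the
conventional choice) < 20; and, when ATAC data is present, total fragments
> 1,000 and < 100,000. A cell exactly on a bound is excluded; the rules are
a conjunction, and the report counts exclusions per rule.

Normalization is `log1p` of counts-per-10k (`normalize_log()`, `scale`
configurable). A regression-based variance-stabilizing transform would also
be defensible; the package deliberately uses the simpler transform because
every downstream decision that matters here — the senescence call, the
rank-sum tests, Spearman correlations — depends only on within-cell or
within-group *order*, and the median-split invariance property is tested
explicitly: any per-set strictly monotone transform of the scores leaves the
senescent calls unchanged.

## Unified senescence scoring

Each cell is scored against four senescence sets (SenMayo, CellAge, GenAge,
senescence eigengene) with a rank-based single-sample enrichment statistic.
With genes ranked by expression descending (average ranks for ties) and
bottom-up rank $r_g = n - \mathrm{pos}(g) + 1$,

$$ S = \sum_{i=1}^{n} \left[ P_\mathrm{in}(i) - P_\mathrm{out}(i) \right],
\qquad
P_\mathrm{in}(i) = \frac{\sum_{g \in G,\ \mathrm{pos}(g) \le i} r_g^\alpha}
                        {\sum_{g \in G} r_g^\alpha}, $$

with $P_\mathrm{out}$ the fraction of out-of-set genes at or above position
$i$. The implementation uses the algebraically identical closed form
$S = \sum_{g\in G} r_g^{1+\alpha} / \sum_{g\in G} r_g^\alpha -
\sum_{g\notin G} r_g / (n - |G|)$, which the tests check against a literal
running-sum enumeration at $10^{-12}$ tolerance. The weight exponent
defaults to $\alpha = 0.25$; $\alpha = 0$ gives the unweighted statistic.
The final running term telescopes to zero exactly.

Canonical senescence markers (p16/CDKN2A, p15/CDKN2B, p19/CDKN2D,
p21/CDKN1A, p27/CDKN1B, PAI-1/SERPINE1) are removed from every set before
scoring so they stay available as independent validation of the calls.

**The call.** Within each cell type, age groups pooled (pooling is what
makes the young/aged fraction comparison meaningful), each set's scores are
split at the median; a cell is senescent when strictly above the median on
**all four** sets. Ties at the median fall in the lower half, so at most
half the cells of a type can be positive on a set. Four further choices
were genuinely open and are resolved as follows:

* the literature names four senescence databases although it counts five;
  the package scores four;
* "upper half" could mean any set or all sets — the conjunction is the
  default (`rule = "all"`), with `"any"` and `"k_of_4"` exposed, because the
  conjunction has a well-characterized null: with independent scores the
  null positive fraction is $(1/2)^4 = 6.25\%$, which the tests verify at
  20,000 cells;
* a median split needs two cells, so types with fewer than two cells are
  skipped with a warning (a two-cell type calls exactly one cell when one
  cell dominates all sets);
* the conjunction has a false-positive floor (non-senescent cells above all
  four medians by chance), so recovered fractions sit a couple of
  percentage points above planted ones — visible in the worked example.

## Transcriptional noise

The statistic is the Euclidean distance of each cell to its own
(cell type, age group) centroid over invariant genes, computed after three
controls: cells below the target depth are dropped and the rest downsampled
to exactly that depth (true molecule subsampling — multivariate
hypergeometric without replacement, not binomial thinning); the larger age
group of each type is randomly subsampled to the smaller one's size; and
expression is re-normalized on the invariant genes. Distances are averaged
per donor to remove donor-level technical confounding; the aged/young ratio
of donor means and two-sided rank-sum tests at both levels are reported.

The invariant-gene list is operationalized as the lowest-CV fraction
(default 10%) of genes detected in at least half the cells; a user-supplied
list overrides it. The target depth is study-specific and therefore a
required parameter (the tests use 1,000 UMI). Under negative-binomial
noise, low CV selects high-expressed constant genes — the realistic
behaviour, since housekeeping genes are both.

The donor-level test is exact rank-sum; with five donors per group the
smallest achievable two-sided p is $2/252 \approx 0.0079$, so donor-level
significance is meaningful but coarse. The null calibration in the test
suite switches off every age-linked difference except the dispersion
multiplier (equal planted senescent fractions in both groups): with
age-asymmetric senescence the aged group genuinely is more heterogeneous,
which is signal, not miscalibration.

## Differential expression and set algebra

Per-gene two-sided Wilcoxon rank-sum on normalized expression: exact null
enumeration when both groups have ≤ 10 cells and the gene has no ties,
otherwise the tie-corrected normal approximation with continuity
correction (the two branches agree within 0.01 at 10 vs 10 in the tests).
All-tied genes get p = 1. BH adjustment is applied across tested genes and
cross-checked against an independent step-up implementation.

The fold change is reported as log2 with pseudocount 0.01 and is computed on
the **de-logged** (counts-per-10k) scale for expression input — the
convention under which a 2-fold expression shift yields log2FC ≈ 1 and the
conventional `LogFC > 0.5`, `q < 0.05` thresholds behave as intended; on the
log scale a 2-fold shift could never reach 0.5. Catalogue thresholds use
log2 (the base was unstated upstream; log2 is the field convention).
Sn-DEG catalogues, SASP intersections and shared-in-k combination counts
satisfy the partition identities by construction and by test. Enrichment is
one-sided upper-tail hypergeometric, $p = P[X \ge k]$ with
$(N, K, n, k) = (|U|, |A \cap U|, |Q|, |A \cap Q|)$, BH across sets.

## Cell–cell communication

Per-type ligand and receptor abundances are Tukey trimeans
$(Q_1 + 2Q_2 + Q_3)/4$ of normalized expression with linear-interpolation
(type-5) quartiles — the quartile definition matters and is pinned by a
closed-form test (`{0,0,0,10} → 1.25`). Multi-subunit complexes collapse by
the geometric mean, so one absent subunit zeroes the complex. The
communication probability is the saturating Hill form
$P = LR/(K_h + LR)$ with $K_h = 0.5$ on the trimean scale; it is strictly
increasing in each aggregate and bounded in $[0, 1)$. Significance is by
joint permutation of cell-type labels, $p = (1 + \#\{P^{perm} \ge
P^{obs}\})/(n_{perm}+1)$ with $n_{perm} = 100$ by default; an observed
probability of zero is reported at p = 1. Aggregations (total interaction
strength, sender×receiver matrices, per-pathway information flow, relative
flows between groups) keep only significant entries (p < 0.05).

These functional forms are this package's declared model of the quantities
a communication analysis reports; they are not a reimplementation of any
specific published tool, and absolute strength values are comparable only
within a run.

## Trajectory statistics

The pseudotime axis is the first principal axis of the normalized
ordering-gene submatrix, rank-transformed to $[0,1]$ and oriented so aged
cells sit late (the axis sign is arbitrary; the anchor makes the output
well-defined; a root-cell override or an externally supplied pseudotime TSV
can be used instead). Tree embeddings and branch discovery are out of
scope: every downstream statistic here (correlation, binned curves,
lead–lag) depends only on an ordering, and branch-vs-branch comparisons
reduce to `rank_sum_de()` on branch labels.

Module-score curves use 55 sliding windows of width 0.10 with centres
spanning [0.05, 0.95] (55 disjoint bins of width 0.10 cannot tile [0,1], so
sliding windows are the consistent reading), per-window means, and a local
*linear* (degree-1, tricube) loess fit with pointwise normal 95% bands;
empty windows are NA and interpolated by the fit.

## Regulatory inference

**Motif deviations.** For motif $m$ and cell $c$,
$d = (x_{obs} - e)/e$ with $e$ = cell total × the motif peaks' global count
share, z-scored against `n_bg = 50` background peak sets built by replacing
each motif peak with one of its 50 nearest neighbours in standardized
(GC, mean accessibility) space (seeded). Motifs with fewer than 10 peaks
are skipped.

**DORC.** Candidate peaks lie within ±50 kb of the TSS — the "100 kb window
centred on the TSS" read as half-width 50 kb with **closed** boundaries, and
configurable because conventions differ between tools. Per candidate, the
Spearman correlation of peak counts with the gene's normalized expression
across cells is z-scored against `n_bg = 100` matched background peaks
(one-sided p). The per-cell DORC score is the summed counts of the gene's
significant peaks; genes with ≥ 5 significant peaks (`n_sig_min`, a
threshold that is a package decision) are flagged as DORC genes.
Correlations are computed on single cells; optional smoothing was
considered and rejected to keep the null calibration interpretable.

**Regulation score.** For TF $t$ and gene $g$:
$p_\mathrm{motif}$ = one-sided hypergeometric over-representation of the
motif among the gene's significant peaks relative to its candidate-window
peaks; $\rho_{TF}$ = Spearman(TF expression, DORC score), with $p_{corr}$
from the t approximation; and

$$ RS = \mathrm{sign}(\rho_{TF}) \sqrt{(-\log_{10} p_\mathrm{motif})
        (-\log_{10} p_{corr})}. $$

Positive RS marks an activator, negative a repressor; either evidence at
p = 1 forces RS = 0. The combination formula is this package's
concretization — only the sign semantics are inherited from the literature.
One degenerate input needs a rule: when the motif hits *every* candidate
peak of a gene, the window-conditional hypergeometric has a constant margin
and always returns p = 1, carrying no information; in that case (and only
then) enrichment is assessed against the genome-wide peak universe, the
convention used by motif-deviation frameworks.

**Lead–lag.** Cells ordered by pseudotime are grouped into consecutive bins
of `cells_per_bin` cells; per-bin means of the DORC score and the RNA
signal are loess-smoothed, each curve clip-normalized to [0,1] by its
1st–99th percentiles, and the lead is $t_{50}(\mathrm{RNA}) -
t_{50}(\mathrm{DORC})$ in bins, where $t_{50}$ is the first bin reaching
0.5. Both signals must be on a linear scale (the DORC score is raw counts,
so RNA enters as `expm1` of the log-normalized values); mixing a
log-compressed curve with a linear one shifts the half-rise point and
biases the lead. Swapping the inputs negates the lead exactly.

**Peak annotation.** Promoter: peak centre within 3 kb of the nearest TSS;
else gene body when the centre falls in a gene span; else intergenic — the
classes are exclusive and partition the peaks. `distal` marks > 3 kb from
every TSS; `enhancer` marks any half-open overlap with an H3K27ac interval
(1 bp suffices). Target assignment: promoter peaks → nearest gene;
enhancer-flagged distal peaks → nearest TSS within 100 kb; equidistant
ties resolve to the lexicographically smaller symbol (a deterministic,
documented tie-break). Peaks on chromosomes absent from the annotation are
skipped with a warning.

## The synthetic generator

`generate_multiome()` draws negative-binomial (Gamma–Poisson) counts over a
structured panel: cell-type markers (6× in their own type), a
senescence/SASP program elevated $2^{\mathrm{sn\_effect\_log2fc}}$-fold in
planted senescent cells (default log2FC = 1), mitochondrial genes holding a
fixed expected share (default 5%, symbols `MT-*` so the QC rule is
exercisable), high-expressed constant housekeeping genes (the truth
invariant list, together with the mitochondrial genes), logistic
pseudotime trends (4-parameter logistic; cell-cycle genes decrease),
activator/repressor TFs whose latent activities drive their targets' RNA
and planted peaks, and ligand/receptor genes 8× concentrated in designated
sender/receiver types. Planted senescent fractions default to 20% of aged
and 8% of young cells per type — an age-asymmetric pattern of the kind such
studies report — and aged cells carry a 1.5× dispersion multiplier.

Key conventions:

* **Pseudotime.** Young cells draw u ~ Beta(1,2), aged u ~ Beta(2,1); with
  equal group sizes the pooled distribution is exactly uniform, so
  equal-cell bins downstream correspond to equal pseudotime spans, which
  the lag convention presupposes.
* **Chromatin lead.** One lag bin = 1% of the pseudotime axis: flagged
  genes' planted peaks follow a logistic with midpoint shifted earlier by
  `pt_lag_bins / 100` (default 10 bins = 0.1 pseudotime units) relative to
  the RNA midpoint. Analyses that estimate the lead should bin the axis
  into ~100 equal-cell bins so both quantities share the unit.
* **Copula coupling.** Planted peak–gene pairs share a Gaussian latent with
  correlation `dorc_rho / 0.92`; discreteness ties attenuate the
  count-level Spearman by roughly the factor 0.92 at the default count
  means (measured once, offline, and frozen), so the realized count-level
  correlation is the configured `dorc_rho` (default 0.6). The copula acts
  through the NB quantile function, so marginals are unchanged.
* **Exact NB marginals.** Gene weights are normalized by a constant (the
  chunk-mean total weight), not per cell, so each gene's mean depends only
  on its own multipliers and every count marginal is exactly NB — which is
  what makes the generator's moments testable. Expected per-cell depth
  consequently varies a few percent with cell state.
* **Decoy LR pairs** are drawn from filler genes abundant enough to be
  detected: a decoy models an expressed-but-unstructured pair, not an
  absent transcript (absent transcripts give probability 0 and p = 1
  structurally).
* **Determinism.** All draws run under the config seed with a fixed chunk
  size, so identical configs give bit-identical output.

Features of real data deliberately **not** emulated: doublets, ambient RNA,
batch/donor effects, per-cell depth variation beyond count noise, read-level
structure, realistic genome geometry (genes sit 200 kb apart on synthetic
chromosomes with 6 peaks within 48 kb of each TSS), and motif PWM scanning
(hits are planted directly, with a 5% background rate). Passing tests on
synthetic data therefore demonstrate the statistics' correctness and
calibration under the stated model, not robustness to those artefacts.

## Problem sizes and tolerances in the test suite

The suite validates at sizes chosen to make each oracle decisive while the
whole suite stays quick: enrichment-score enumeration over all 720
permutations of 6-gene rankings at $10^{-12}$; the USS null at 20,000 cells
(3σ binomial); recovery of a planted 20% aged-MuSC senescent fraction at
2,000 cells (±3 percentage points, AUROC ≥ 0.9); noise power over 20 seeds
and null calibration over 200 simulations of 600 cells; communication
calibration over 500 decoy pairs at 100 permutations; DORC and
regulation-score recovery at 500 cells; and lead estimation at 3,000 cells
with 100 bins (±3 bins of the planted 10). Exact values (rank-sum 2/252,
hypergeometric 1/252, trimean 1.25) are asserted to machine precision.

## Known limitations

* Absolute communication strengths depend on the declared Hill/trimean
  model and are comparable within, not across, analyses.
* The conjunction USS rule's false-positive floor (~$(1/2)^4$ under
  independence) biases recovered senescent fractions upward by a few
  points; reported fractions should be read with that floor in mind.
* The exact donor-level rank-sum is coarse below five donors per group.
* DORC discovery with few peaks per gene gives the motif over-representation
  test little resolution; the regulation score's sign is then carried
  almost entirely by the correlation evidence (which is the tested
  guarantee).
* `run_pipeline()` drives the synthetic study end-to-end; on real data the
  stage functions are called directly with the user's matrices and
  annotations.
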