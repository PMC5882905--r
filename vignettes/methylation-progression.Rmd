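---
title: "Stage-resolved methylation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved methylation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`methylstage` analyses base-resolution methylation calls from a staged
case/control bisulfite-sequencing study. This vignette explains the
statistical model behind each stage, the parameters that matter, what
the synthetic generator does and does not emulate, and the design
choices made where the methodology was genuinely open.

## The data model

The atomic observation is a CpG in one sample: methylated count `M`,
unmethylated count `U`, at a 1-based cytosine position with strand.
Every cross-module identity comparison of loci uses exact
`(chrom, pos, strand)` equality; strand is carried but never merged into
CpG pairs — each stranded cytosine is an independent locus, since
destranding is an assay-level decision this pipeline does not take.
Internally all coordinates are 1-based inclusive; BED files on disk are
0-based half-open, and the conversion lives in exactly one place (the
GRanges-backed readers/writers in `io.R`).

## Differential methylation

The methylation score is `m = M/(M + U)`. A locus enters a contrast only
if every sample *of that contrast* covers it with at least
`min_coverage = 10` reads and at most that sample's 99.9th coverage
percentile — the upper cap suppresses PCR-duplicate pileups and can be
disabled. Filtering is recorded on the matrix object, so re-applying the
same filter is a no-op.

The default test (`fisher_pooled`) sums counts within each group and
applies the two-sided conditional exact test to the pooled 2×2 table;
the reported difference Δ (percentage points) is always the pooled case
score minus the pooled control score, matching the single score formula
above rather than an average of per-replicate scores. A per-locus
binomial-regression alternative (`logistic`) is provided; for grouped
binomial counts with a single two-level covariate its likelihood-ratio
contrast is equivalent to a pooled-table test, so it is a presentation
alternative, not an overdispersion correction. q-values are
Benjamini–Hochberg; a CpG is a DMC when `|Δ| ≥ 10` points **and**
`q < 0.01`, with equality at the magnitude threshold counting as
significant. A stricter display threshold (Δ ≥ 25) is a configuration
knob, not a second code path.

For the premalignant-to-malignant transition, case samples of the early
stages are pooled against case samples of the late stages; the same
contrast run on control samples defines a developmental background, and
genes whose promoters carry DMCs in the control contrast are removed
from the case gene lists.

## Dense regions (DMRs)

The merge distance `d*` is estimated from the data: a two-component
Gaussian mixture is fitted to log10 nearest-neighbour CpG distances by
EM (deterministic quantile-based initialisation, tolerance 1e-8, at most
500 iterations) and `d*` is the posterior crossing point between the
component means. The fit degrades gracefully: fewer than 100 gap
observations, a component weight below 0.05, or means closer than
0.1 log10 fall back to a fixed 100 bp. Consecutive same-direction DMCs
with gaps ≤ `d*` seed a candidate region spanning first to last DMC;
all covered CpGs inside the span contribute to the region mean
difference, so `mean_diff` averages over covered CpGs, not DMCs only —
the more conservative of the two readings. Filters: ≥ 3 covered CpGs,
≥ 1 DMC, |mean Δ| ≥ 20 points. The region p-value is an equal-weight
Stouffer combination of per-CpG one-sided z-scores oriented by the
region direction (clipped at p = 1e-300), with BH across candidates and
`q < 0.05` retained. Stouffer is used instead of a cost-function region
score because it is simple, deterministic, and checkable against a
brute-force oracle; hyper- and hypomethylated CpGs never share a region.

The cross-stage DMR union keeps any interval that was a DMR in at least
one stage, merging overlaps and recording stage provenance. Trajectories
(union interval × stage mean Δ, missing cells imputed with the stage
mean and logged) are clustered with Ward linkage on Euclidean distance
and cut at k = 3; the linkage, metric and k are not dictated by the
underlying methodology and are exposed as parameters. Groups are
relabelled by decreasing mean trajectory so group 1 is the
hypermethylated one.

## Annotation and enrichment

Promoters are TSS ± 2 kb (width 4001, 1-based inclusive); gene bodies
TSS–TES when provided; enhancers as supplied. A locus may belong to
several compartments at once, and promoter assignment lists *all* genes
whose windows contain it — gene-level analyses need every assignment, so
no precedence collapse is applied, and compartment fractions consequently
need not sum to one. Enhancer targets are the nearest TSS within 10 kb
of the enhancer edge, ties included.

Compartment enrichment uses an empirical permutation test: `B = 1000`
random locus sets of the observed size, drawn uniformly *without
replacement* from the coverage-filtered captured-CpG universe (not the
genome — the assay only ever sees captured CpGs, which makes the
captured universe the only defensible null), with the one-sided add-one
p-value `(1 + #{null ≥ obs})/(B + 1)`. Because the overlap count is
discrete, the p-value is mildly conservative by about half the count's
modal probability mass; calibration checks therefore use set sizes large
enough that the count support is wide (the tests use sets of 2000 in a
universe of 10000, where the bias is ~0.015).

Gene-set enrichment is overlap-based: the hypergeometric upper tail of
the query/set overlap within a gene universe, BH across sets. The
universe defaults to genes with at least one covered promoter CpG.
Ranked enrichment with phenotype permutation is out of scope — the
tested quantities are fixed gene lists. Methylation–expression
integration intersects promoter hyper-/hypomethylated gene lists with
differentially expressed genes (FDR < 0.05) split by direction; the
Wilcoxon comparison of expression between gene groups uses the exact
null when both groups have ≤ 10 tie-free values and the tie-corrected
normal approximation otherwise, always removing target genes from the
reference group.

## Co-methylation network

Network loci are DMCs (q < 0.01 in ≥ 1 stage) restricted to the 2 kb
window strictly upstream of a TSS, oriented by gene strand. The signed
adjacency is `a = ((1 + r)/2)^β` with Pearson r across all samples and
β = 12 (the signed-network convention); an optional scale-free criterion
picks the smallest even β ∈ {2, …, 20} with log-log degree fit R² ≥ 0.8.
Modules come from average-linkage clustering of `1 − TOM` (topological
overlap, configurable to raw `1 − a`, but TOM suppresses single-edge
noise) with a simplified dynamic tree cut: a static cut at absolute
dissimilarity 0.99, then recursive branch decomposition that re-cuts a
branch just below its top join only when that join sits clearly (≥ 0.05)
above the next merge — a deliberate simplification of the full
variable-height/PAM procedure, trading its flexibility for a small,
deterministic rule. Loci in branches below `min_module_size = 30` stay
unassigned.

The module eigengene is the first right-singular vector of the
row-standardised member × sample matrix, sign-aligned to non-negative
mean correlation with members. Preservation between a reference (case)
and test (control) dataset uses two statistics: module **density** (mean
off-diagonal within-module adjacency in the test network) standardised
against `n_perm = 200` random same-size locus sets, and **connectivity**
preservation (correlation between members' intramodular connectivity in
reference vs test) standardised against random reorderings of the
test-side connectivity vector within the module. The density null asks
"is this set denser than a random set?"; the connectivity null asks "is
the hub ordering reproduced beyond chance?". A shared random-set null
for both was considered and rejected: random sets that mix module and
background loci trivially reproduce the module-versus-background
connectivity contrast (cor ≈ 0.97 with tiny spread), which drives the
connectivity Z of genuinely preserved modules strongly negative — an
instrument that cannot rank a preserved module above a shuffled one is
measuring the wrong thing. `Z_summary` is the mean of the two Z-scores;
~10 and above indicates strong preservation, 2–10 moderate, and these
thresholds are reported, never hard-coded. Degenerate nulls (sd = 0)
yield ±Inf with a warning, never NaN. Correlations for module detection
use all samples; preservation correlates within group.

## The synthetic generator

The generator emulates the observable structure of an ERRBS study at
desk scale — defaults: 2 chromosomes × 150 islands ≈ 20,000 CpGs, 200
genes with TSS centred on islands, 50 enhancers (70% within 10 kb of a
TSS), 3 cases vs 3 controls at each of 4 stages:

* **Positions**: bimodal inter-CpG distances (within-island ~10^1.3 bp,
  between-island ~10^3.5 bp), so gap-threshold estimation has the
  structure it expects.
* **Coverage**: negative binomial (mean 30, size 5), truncated at 1.
* **Baseline methylation**: a two-component beta mixture — low mode
  (Beta(2,18)) for promoter islands, high mode (Beta(12,3)) for 80% of
  the remaining islands — giving the bimodal marginal typical of CpG
  methylomes.
* **Replicate noise**: beta-binomial with precision 50, deliberately
  making pooled-count tests mildly anti-conservative, as in real ERRBS
  replicates.
* **Spikes**: 20 hyper regions planted in promoter islands (60% of them
  in promoters of a designated planted gene set) and 30 hypo regions in
  high-baseline islands — more hypo than hyper, mirroring the direction
  bias of tumour hypomethylation. Each spike shifts the case group mean
  by `direction × 40 × multiplier(stage)` percentage points with
  monotone multipliers (0.6, 0.7, 0.9, 1.0), clipped to [0.01, 0.99];
  controls are never shifted. Expression couples to the truth by a −1
  log-fold-change shift on hyper-spiked genes.

What the generator does **not** emulate: read-level artefacts (bisulfite
conversion error, mapping bias), copy-number confounding, correlated
methylation *structure* in control samples (spikes shift means, they do
not plant co-methylation), chromosome-scale features, and realistic
effect-size distributions — spike sizes are chosen for testability.
Consequently, passing recovery tests demonstrates algorithmic
correctness under a favourable, known-truth regime, not performance on
real tissue. Network module recovery and preservation are therefore
exercised on directly constructed correlated score matrices
(`simulate_comethylation_scores()`, optionally with graded "hub"
loadings), where correlation structure is the planted quantity.

Two empirical notes from working under these defaults. First, the
observed DMC false-discovery proportion at Δ = 40 sits at ~0.09–0.14
depending on seed: the false positives are ordinary-coverage loci whose
three-replicate beta-binomial group means alone drift ~20 points, which
a pooled-count exact test cannot distinguish from signal. That is the
intended anti-conservative behaviour of the noise model, and neither the
precision nor the thresholds are adjusted to hide it. Second, because
detection saturates between the 0.9 and 1.0 multiplier stages, DMC
counts rise from first to last stage but are not strictly monotone at
every adjacent pair; the tested generator property is the trend, not
stepwise monotonicity.

## Numerical and reproducibility choices

Exact-test p-values sum hypergeometric point probabilities with the
customary 1 + 1e-7 relative tolerance; region p-values clip per-CpG p at
1e-300 before the normal quantile; ties in hub ranking break on
(chrom, pos) order; trajectory group labels sort by mean trajectory.
Every randomised operation takes a seed derived deterministically from a
global seed and the stage name (`derive_seed()`), seeded functions
restore the caller's RNG state on exit, and the pipeline serialises its
full configuration into every output directory, so a run is reproducible
from its artifacts alone and a re-run under the same seed is
byte-identical. Pipeline stages are resumable: a stage re-runs only when
its artifacts are missing or something upstream was recomputed. Outlier
flagging in the PCA QC (beyond 5 MADs on PC1/PC2) is a suggestion in the
output, never an automatic removal.

Problem sizes in the test-suite and acceptance runs are the package's
own reduced "desk scale" (single-stage contrasts at ~15,000 filtered
loci for recovery metrics; 40-island single-chromosome studies for
multi-seed calibration loops; 200-locus networks), chosen so the full
validation remains quick on one CPU while every statistic retains enough
resolution to be meaningfully tested.

## Known limitations

* No per-CpG dispersion shrinkage or beta-binomial GLM: the caller is
  deliberately the pooled exact test, with its documented
  anti-conservatism under replicate overdispersion.
* The simplified tree cut has no PAM-like reassignment stage; very
  unbalanced or nested modules may be split or left unassigned where the
  full procedure would recover them.
* Enrichment is overlap-based only; no ranked statistic.
* No destranding/CpG-pair merging, no liftover between assemblies, and
  no handling of sex chromosomes or copy-number effects.
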