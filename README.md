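# methylstage

Stage-resolved differential DNA methylation analysis for bisulfite
sequencing time courses.

## The problem

In staged disease models — the motivating case is breast tumour
progression in the MMTV-PyMT mouse, profiled by enhanced
reduced-representation bisulfite sequencing (ERRBS) at four stages
(hyperplasia, adenoma/MIN, early carcinoma, late carcinoma) against
age-matched controls — the questions are: which CpGs gain or lose
methylation at each stage, whether those changes concentrate into dense
regions and regulatory compartments, which gene sets they hit, how
methylation trajectories evolve across stages, and whether co-methylation
network structure is preserved between cases and controls. `methylstage`
implements that full analysis as a tested, reusable R pipeline, plus a
synthetic ERRBS-like generator with planted ground truth so every stage
can be validated without external data.

## The statistics at the core

* **Methylation score** of a CpG: `m = M / (M + U)` for methylated /
  unmethylated read counts, after requiring coverage ≥ 10 in every sample
  of a contrast (and below each sample's 99.9th coverage percentile).
* **DMC calling**: counts are pooled within case and control groups at a
  stage; a two-sided exact test on the pooled 2×2 table gives `p`, BH
  gives `q`, and a CpG is a DMC when `|Δ| = |m_case − m_ctrl|·100 ≥ 10`
  percentage points and `q < 0.01` (hyper- or hypomethylated by the sign
  of Δ).
* **DMR detection**: consecutive same-direction DMCs closer than a merge
  distance `d*` — the crossing point of a two-component Gaussian mixture
  fitted to log10 inter-CpG distances — are merged; regions need ≥ 3
  covered CpGs, |mean Δ| ≥ 20, and a BH-adjusted Stouffer region p < 0.05.
* **Annotation and enrichment**: promoters are TSS ± 2 kb, enhancer
  targets the nearest TSS within 10 kb; compartment enrichment uses an
  empirical permutation p `(1 + #{null ≥ obs}) / (B + 1)` over random
  locus sets from the captured-CpG universe; gene-set enrichment is the
  hypergeometric upper tail with BH FDR.
* **Trajectories**: the cross-stage DMR union × stage matrix of mean Δ is
  Ward-clustered into k = 3 progression groups.
* **Co-methylation network**: signed adjacency `a = ((1 + r)/2)^β`
  (Pearson r across samples, β = 12) over promoter-upstream DMCs,
  modules by average-linkage clustering of 1 − TOM with a simplified
  dynamic tree cut, module eigengenes (first PC), case/control eigengene
  Wilcoxon tests, and a permutation z-summary
  `(Z_density + Z_connectivity)/2` for module preservation.

## Worked example

```r
library(methylstage)

ds  <- simulate_methylation_dataset(sim_config(seed = 7))   # 4 stages, 3v3
dir <- tempfile(); write_simulation(ds, dir)
res <- run_pipeline(dir, file.path(dir, "out"))

sapply(res$dmr, nrow)
#>  w6  w8 w10 w12
#>  31  41  49  50

head(res$enrichment$w12[, c("set_name", "n_overlap", "p", "fdr")], 2)
#>               set_name n_overlap            p          fdr
#> 1 PLANTED_PRC2_TARGETS        12 3.403300e-08 1.735680e-06
#> 2            DECOY_009         7 4.055860e-03 1.034240e-01

evaluate_against_truth(res$dmc, res$dmr, res$enrichment$w12, ds$truth)[
  c("dmc_sensitivity", "dmc_fdr", "dmr_jaccard", "planted_set_rank")]
#> $dmc_sensitivity [1] 0.959   $dmc_fdr [1] 0.112
#> $dmr_jaccard     [1] 0.887   $planted_set_rank [1] 1
```

The per-stage DMR counts rise with tumour progression (50 regions were
planted); the planted gene set ranks first among 51 candidates with
FDR ≪ 0.05; at the final stage 96% of planted DMCs are recovered, and
the called regions cover the planted ones with base-pair Jaccard 0.89.
The observed DMC false-discovery proportion (~0.09–0.11) reflects the
generator's deliberately anti-conservative beta-binomial replicate noise
(see the methods vignette).

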