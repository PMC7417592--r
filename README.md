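# ascfate

Branching differentiation analysis of LPS-activated B cells into
antibody-secreting cells (ASC), for computational immunologists and
single-cell analysts who want the full bulk + single-cell chain of that
analysis as tested, composable R functions.

Activated B cells divide up to eight times and bifurcate early: an
**ASC-destined** branch induces the ASC program (*Prdm1*, *Xbp1*, *Irf4*,
*Sdc1*), MYC-target/OXPHOS modules and loses *Sell* (CD62L), while a
**non-ASC** branch keeps the B-cell program and mounts an inflammatory
signature; terminal ASC sub-split by ER stress. `ascfate` implements the
computations that resolve this structure:

- **Absolute quantification** of division-sorted bulk RNA-seq with ERCC
  spike-ins:
  `mRNA_A/cell = FPKM_A / n_cells x (Σ molecules_ERCC / Σ FPKM_ERCC)`,
  plus per-sample total mRNA content, RPM normalization, a per-group
  detection filter and BH-FDR differential-expression flags.
- **Single-cell preprocessing**: QC (genes in < 10 cells, cells with
  < 1000 UMI removed), library-size/sqrt and log normalization.
- **Markov diffusion imputation**: adaptive Gaussian kNN kernel in PC
  space, symmetrized and row-normalized; imputation is `P^t · data`.
- **Reference annotation**: quantile-normalized k-nearest-neighbor label
  transfer from bulk panels (cell types nB/actB/ASC; divisions
  0, 1, 3, 5, 8-, 8+).
- **Trajectory**: density-peak clustering (neighbor-count density,
  nearest-denser-cell distance, saddle-density merge), Kruskal-Wallis
  ordering genes, a minimum-spanning-tree principal tree with geodesic
  pseudotime, branch points (nodes of degree >= 3) and branch segments.
- **Preranked enrichment**: signed `sign(FC)·(1−p)` ranking, weighted
  Kolmogorov-Smirnov enrichment score, gene-label permutation null with
  the 1/(nPerm+1) floor, sign-stratified NES, leading-edge extraction,
  cubed-mean activity scores and pseudotime expression profiles.
- **Regulon activity**: rank-AUC target-recovery scores per cell,
  activity-vs-expression fold-change correlation between clusters, and
  motif-class (AP-1 / AICE) composition.
- **A synthetic experiment generator** with full ground truth (division,
  branch, state, generating program, spike-in reference) so every stage
  is testable end to end.

## Worked example

```r
library(ascfate)

cfg <- simConfig(nCells = 800, nGenes = 800, seed = 1)
sim <- simulateExperiment(cfg)
cfg
#> SimConfig: 800 cells x 800 genes, 50 spike-ins
#>   divisions 0-8 | branch at division 3 | ASC fraction 0.1
#>   mRNA scale/division 1.3 | NB dispersion 0.2 | seed 1
table(groundTruth(sim)$branch)
#> ASC-destined      non-ASC   pre-branch
#>          322          268          210

res <- runPipeline(cfg, params = list(nPerm = 1000, nTop = 600))
res$trajectory
#> TrajectoryModel: 800 cells, 12 tree nodes, 11 edges
#>   root node 12 | 1 branch point(s) | 3 branch(es)
```

The fitted tree recovers the bifurcation: one branch point splits the
trajectory into a pre-branch stem and the two fates, and the per-cell
branch labels agree with the generator's truth:

```r
s <- res$summary
sprintf("branch ARI %.3f | cell-type accuracy %.1f%% | division within one step %.1f%%",
        s$branchAdjustedRandIndex, 100 * s$cellTypeAccuracy,
        100 * s$divisionWithinOneStep)
#> "branch ARI 0.935 | cell-type accuracy 91.4% | division within one step 98.9%"
```

Preranked enrichment between the two post-branch populations points the
module directions the right way — OXPHOS/MYC up on the ASC-destined side,
the inflammatory module up on the non-ASC side, both at the permutation
floor of 1/1001:

```r
sprintf("OXPHOS/MYC: ES %.2f, p = %.4g | inflammatory: ES %.2f, p = %.4g",
        s$enrichment$oxphos$es, s$enrichment$oxphos$p,
        s$enrichment$inflam$es, s$enrichment$inflam$p)
#> "OXPHOS/MYC: ES 0.65, p = 0.000999 | inflammatory: ES -0.81, p = 0.000999"
```

And the spike-in equation on its worked substitution (FPKM 10, one cell,
100 input molecules against a spike FPKM sum of 50):

```r
moleculesPerCell(rbind(geneA = 10, `ERCC-1` = 50),
                 spikes = c(`ERCC-1` = 100), cellsPerSample = 1)
#>       s1
#> geneA 20
```

A positive enrichment score means the gene set leads the ranked list
(here: enriched in the ASC-destined branch); the ARI compares tree
segments against the generator's branch truth, so 1.0 is perfect
recovery and 0 is chance.

See `vignettes/ascfate-methods.Rmd` for the model, every tunable
parameter, the numerical choices, and what the synthetic data do and do
not emulate.

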