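# chimeraDecomp

Decomposition of evolutionary divergence in cellular traits into
cell-intrinsic, cell-extrinsic, and intrinsic-extrinsic interaction
components from reciprocal interspecies chimera data.

## The problem

When a gene is expressed differently in mouse and rat, is that because the
cells themselves differ (genotype, *cell-intrinsic*), or because the
extracellular environments of the two species differ (*cell-extrinsic*)?
Reciprocal chimeras separate the two: injecting rat embryonic stem cells
into a mouse blastocyst (and vice versa) places cells of one genotype in
the other species' environment. For any trait measured in a cell type,
this yields four species-environment combinations:

| | mouse-like environment | rat-like environment |
|---|---|---|
| **mouse cells** | host mouse `HM` | donor mouse `DM` |
| **rat cells** | donor rat `DR` | host rat `HR` |

Modelling each measurement as the product of an intrinsic and an extrinsic
factor gives two independent estimates of each divergence component
(log2 units, rat-higher positive):

```
I1 = log2(HR/DM)   I2 = log2(DR/HM)    intrinsic
E1 = log2(DM/HM)   E2 = log2(HR/DR)    extrinsic
I = (I1+I2)/2      E = (E1+E2)/2
N = (I1-I2)/2 = (E2-E1)/2              interaction
```

The paired estimates agree exactly unless genotype and environment
interact (or measurement noise intervenes); their half-difference `N` is
the interaction divergence, positive when species-matched combinations
are higher. Magnitudes normalized to sum to one give the proportions
`Ip`, `Ep`, `Np`, reported for traits with an absolute log2 fold-change
above 0.5 in at least one of the four comparisons.

The package implements everything around this estimator as it is used in
practice: barnyard species assignment from dual-genome alignments (70%
rule), quality-control and gene-detection filters, pseudobulking,
equal-depth resampled count normalization (which removes depth-imbalance
artefacts in pseudocounted fold-changes), a self-contained preranked
gene-set enrichment engine with a symmetric rank transform for unsigned
metrics, trait-level analyses (cell-state ratios, Tau specificity,
covariate correlations, developmental-dynamics classes, bulk
imprinted-gene workflows), immunofluorescence image quantification with a
masking-robustness sweep, and a synthetic reciprocal-chimera data
generator with known ground truth.

## Worked example

Simulate a reciprocal chimera experiment with mostly intrinsic divergence
and a 20-gene imprinted-like set (mismatch-environment effect of 1 log2
unit), run the standard pipeline, and test the imprinted set for
interaction divergence:

```r
library(chimeraDecomp)

sim <- simulate_chimera_counts(
  n_genes = 500,
  cells_per_combo = c(HM = 250, HR = 250, DM = 150, DR = 100),
  effect_spec = list(sd_I = 1, sd_E = 0.5, sd_N = 0,
                     n_imprinted = 20, imprinted_N = 1),
  seed = 1)

fit <- decompose_simulation(sim, n_reps = 100, seed = 1)
summary(fit)
#> Divergence decomposition summary
#>   traits: 498 (420 pass divergence filter)
#>   mean proportions (filter-passing): Ip=0.595 Ep=0.303 Np=0.102
#>   ...

imprinted <- sim$truth$gene_id[sim$truth$is_imprinted]
imprinted_interaction_test(fit, imprinted, mode = "absolute",
                           n_perm = 1000, seed = 6)
#>   set_name size    ES NES       p FDR leading_edge_cutoff_rank log2_fold_enrichment
#> 1 gene_set   20 0.998 3.5 0.00197   0                       21                 4.39
```

The mean proportions mirror the planted design (intrinsic > extrinsic >
interaction), and the planted imprinted-like set is strongly enriched for
large interaction components: its enrichment score is near the maximum,
the permutation FDR is below 0.05, and the tail fold-enrichment of 4.4
log2 units means the set is concentrated almost entirely at the
high-interaction end of the ranking.

`decompose_divergence()` also accepts any normalized quartet table
directly (e.g. read from TSV), which is how externally deposited chimera
datasets are fed through the same machinery.

## Package layout

- `R/decompose.R` — the quartet estimator and its S3 methods
  (`print`, `summary`, `coef`, `plot`)
- `R/ingest.R`, `R/normalize.R` — species assignment, QC, pseudobulking,
  equal-depth resampled normalization
- `R/enrichment.R` — preranked running-sum enrichment, symmetric rank
  transform, tail fold-enrichment, TF-target propagation
- `R/traits.R`, `R/imaging.R` — ratio traits, Tau, covariates, dynamics
  classes, bulk imprinted workflows; IF quantification and cutoff sweep
- `R/synthetic.R`, `R/pipeline.R` — ground-truth generators, the
  end-to-end pipeline, cross-cell-type summaries
- `vignettes/divergence-decomposition.Rmd` — the methods vignette
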