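---
title: "Decomposing cellular trait divergence with reciprocal chimeras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing cellular trait divergence with reciprocal chimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeraDecomp)
```

## The model

A reciprocal interspecies chimera experiment measures each trait (a
gene's expression in one cell type, a cell-state ratio, a protein level)
in four species-environment combinations: host mouse (`HM`), host rat
(`HR`), donor mouse (`DM`, mouse cells in a rat-like environment) and
donor rat (`DR`). The model treats each measurement as the product of an
intrinsic factor set by the cell's genotype and an extrinsic factor set by
its environment, e.g. `DR = I_rat x E_mouse`. On a log2 scale this is a
saturated two-factor (genotype x environment) model on a 2x2 table, and
the estimator has a closed form:

- `I1 = log2(HR/DM)`, `I2 = log2(DR/HM)`: two estimates of intrinsic
  divergence, each comparing genotypes within one environment.
- `E1 = log2(DM/HM)`, `E2 = log2(HR/DR)`: two estimates of extrinsic
  divergence, each comparing environments within one genotype.
- `I = (I1+I2)/2`, `E = (E1+E2)/2`, and `N = (I1-I2)/2 = (E2-E1)/2`,
  the interaction divergence. The identity `E2-E1 = I1-I2` is exact, so
  the interaction has a single value however it is derived.

Sign conventions, fixed throughout: `I > 0` means higher in rat cells,
`E > 0` higher in the rat-like environment, `N > 0` higher in
species-matched than species-mismatched combinations. A gene that
collapses in both donor combinations (the typical imprinted-gene
phenotype) therefore has positive `N`; a gene upregulated by a mismatched
environment has negative `N`. `decompose_divergence()` is the fitting
function; `coef()`, `summary()` and `plot()` operate on its result.

Three consequences of the algebra are worth keeping in mind (and are
enforced by tests):

- Relabeling the two species (exchanging `HM` with `HR` and `DM` with
  `DR`) negates `I` and `E` but *preserves* `N`, because the
  matched/mismatched split is unchanged.
- Exchanging environments only (`HM` with `DM`, `HR` with `DR`) negates
  `E` and `N` and fixes `I`; exchanging genotypes only negates `I` and
  `N` and fixes `E`.
- Multiplying all four values of one trait by a constant changes nothing:
  the estimator sees only ratios. A constant applied to one *column*
  (e.g. a normalization factor) shifts every gene's components, which is
  why normalization matters (below).

Proportions `Ip = |I|/(|I|+|E|+|N|)` (and likewise `Ep`, `Np`) express
the relative contribution of each component; signed proportions multiply
by the component's sign. Proportions are only reported for traits with
some evidence of divergence — an absolute log2 fold-change strictly
greater than 0.5 in at least one of the four comparisons `I1, I2, E1,
E2`. Traits failing this filter keep their component estimates with `NA`
proportions, so joins across cell types remain stable. When all three
magnitudes are zero the proportions are undefined and reported `NA`.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| species threshold | 0.70 | fraction of aligned reads | inclusive barnyard cutoff; below both cutoffs = doublet |
| mito maximum | 0.15 | fraction | QC: cells strictly above are removed |
| genes-detected maximum | 7500 | genes | QC doublet proxy, strictly above removed |
| detection fraction | 0.20 | fraction of cells | gene kept if detected in at least this share of one combination (inclusive) |
| pseudobulk floors | 10 / 10 | cells / counts | cell type dropped below 10 cells in any combination; gene dropped below 10 counts in all four |
| normalization | 10,000 / 1 / 100 | scale / pseudocount / repetitions | counts per 10k, pseudocount added once, 100 resampling draws |
| divergence evidence | 0.5 | log2 | strict threshold on max |log2 FC| |
| enrichment | 1000 / 6 / 10-300 | permutations / seed / set sizes | preranked defaults |

All of these are the defaults of `default_config()` so a bare
`run_pipeline()` reproduces the standard parameterization; the config is
serialized into the run manifest.

## Equal-depth resampled normalization

Sequencing depth differs several-fold between combinations (donor cells
are rare and sorted). Direct per-10,000 normalization with a pseudocount
then distorts fold-changes for low counts: with totals of 1e6 for three
combinations and 1e5 for `DR`, a gene with 99 counts in `DM`/`HM` and 0
in `HR`/`DR` normalizes to (1, 1, 0.01, 0.1) — a 100-fold `DM/HR` ratio
but only 10-fold `DM/DR`, inflating extrinsic and interaction estimates.
`normalize_resampled()` therefore downsamples every combination, without
replacement, to the minimum column total before normalizing, 100 times,
and averages.

Interpretive choices, made once and documented here:

- *Without replacement* (multivariate hypergeometric), because drawing
  from the observed count distribution so that "totals are identical"
  fixes the total only under without-replacement sampling. Implemented as
  sequential conditional hypergeometric draws (`downsample_counts()`),
  whose per-gene expectation `count x target/total` is tested against the
  closed form.
- *Target = minimum column total*, the only choice permitting
  without-replacement draws for all four columns.
- *Pseudocount after averaging*, then division: this order reproduces the
  printed (1, 1, 0.01, 0.1) example in the identity case (equal totals),
  where resampling to a column's own total is a no-op and the resampled
  output must equal the direct output exactly. Pseudocounting before
  averaging would break that identity.
- Columns may represent a filtered gene subset; the counts held by
  removed genes compete in the draw as one pseudo-gene so expectations
  stay unbiased against the full library totals.

On pseudobulk-scale tables with 2-10x imbalance the resampled and direct
normalizations agree to Spearman rho > 0.999 while removing the
low-count artefact above.

## The enrichment engine

Enrichment uses a self-contained weighted Kolmogorov-Smirnov running-sum
statistic with a gene-permutation null (1000 permutations, seed 6, set
sizes 10-300 by default; weight 1). Writing the engine in-package keeps
the running sum unit-testable — the ES is checked against a brute-force
enumeration oracle and against an independent implementation — and gives
direct access to the position of the running-sum extremum, which defines
the *leading-edge cutoff rank*. The tail log2 fold-enrichment is
`log2((k_top+1)/(k_bottom+1))` for set members in the top and bottom
`cutoff` positions (direction reversed for negative enrichments); 15
members in the top 500 and none in the bottom 500 give exactly 4.

Because the running sum was designed for signed metrics, ranking directly
by an absolute metric (such as `|N|`) produces spuriously strong
enrichments. `symmetric_rank_transform()` maps an unsigned metric to
mirrored ranks: with `n` genes the largest value becomes `ceiling(n/2)`,
descending to 1, and the smallest becomes `-ceiling(n/2)`, ascending to
-1; zero is skipped for even `n`. For an odd list the two halves share
the central magnitude (e.g. `3, 2, 1, -2, -3` for five genes) — one
consistent reading of the mirrored construction, fixed here. Ties in any
ranking metric are broken lexicographically by gene id, making every
ranking deterministic.

For imprinted-gene style questions, `imprinted_interaction_test()` runs
the absolute mode (`|N|` via the symmetric transform) to ask whether a
set has unusually *large* interactions, and a signed mode (ranking by
signed `Np`) to ask in which direction: under the sign convention above,
sets upregulated in species-mismatched environments enrich at the
negative end.

## The synthetic-data generator

`simulate_chimera_counts()` emulates the measurement process, not any
particular tissue: per-gene log2 baselines (normal, mean 4, sd 1.5),
per-gene effects `I_g`, `E_g`, `N_g` (normal; defaults sd 1, 0.5, 0 —
intrinsic-dominant, as chimera data are), negative-binomial counts
(dispersion size 10), log-normal per-cell library factors (sdlog 0.3),
unequal default cell numbers (250/250/150/100) and depths
(3000/2500/2000/1200 expected counts per cell) mirroring the practical
asymmetry between host and sorted donor libraries, and doublet barcodes
mixing one mouse and one rat cell with a mixing fraction uniform in
(0.3, 0.7) so they always fail the 70% rule. Two genomes are disjoint
namespaces over the same orthologs; singlets carry 1-5% cross-genome
misalignment. An `n_imprinted` subset receives a fixed mismatch effect
(`imprinted_N`, default 2 log2 units, i.e. severalfold misexpression as
observed for strongly affected imprinted genes; the detection tests use
the more conservative 1).

One sign subtlety: the generator's `N_g` is *mismatch-positive*
(positive = higher in donor combinations), the natural way to write a
mismatch penalty/boost, while the estimator's `N` is matched-positive.
The decomposition of the expected quartet — returned by
`truth_decomposition()` — carries the estimator's convention (`I = I_g`,
`E = E_g`, interaction `= -N_g`) and is the recovery target for all
round-trip tests.

Two latent-model caveats, noted rather than guessed at: real chimera
pairs have replicate-specific latent values (chimera-to-chimera
variability), which the generator collapses into a single latent per
gene plus the planted interaction; and expression is compositional, so
only effects that vary across genes are identifiable — a shift shared by
all genes is absorbed into the library totals. Planted-effect tests
therefore use sparse effects, and the closed-form expectation oracle for
the pipeline is the decomposition of the *column-normalized* expected
counts. What passing tests show about real data is correspondingly
limited: parameter recovery under negative-binomial noise with exchangeable
cells, not robustness to spatial structure, ambient RNA, batch effects or
cell-type misannotation, none of which the generator emulates.

Noise asymmetry is a known property, not a defect: measurement error
enters `N` and `E` through more terms than `I`, so noise inflates the
interaction and extrinsic components more than the intrinsic one. No
correction is applied; the property tests quantify it on synthetic truth
instead.

## Trait-level and covariate analyses

`ratio_decompose()` applies the same estimator to count ratios (e.g.
neurons over progenitors per combination); per-combination totals cancel,
so proportions and raw counts are equivalent. `tau()` is the standard
specificity index `sum(1 - x/max)/(n-1)`. `predictor_correlations()`
relates `Ip - Ep` to external gene-level covariates by Spearman
correlation with either a complete-case or per-covariate join (external
covariates arrive as a user table; only expression-derived covariates are
computed in-package). `classify_dynamics()` uses Pearson correlations of
expression against developmental stage — Pearson because three timepoints
make rank correlations degenerate — with class cutoffs 0.7 (similar) and
-0.25 (opposite) on the cross-species correlation product, and a
temporal-shift subclass (similar trajectories, |log2 FC| < 0.25 at both
later stages). `imprinted_bulk_workflow()` medians TPM per condition,
floors at 5 TPM (a gene must pass in at least one condition), standardizes
per gene and clusters samples with Euclidean distance and average linkage
— "default" linkage of common heatmap tools is ambiguous, so the linkage
is a documented, configurable choice; flags use |log2 median ratio| > 1
on the raw medians.

## Immunofluorescence quantification

`quantify_if()` implements blur-mask-measure: Gaussian-blur the DAPI and
TdTomato channels (never the measured target channel), threshold into
masks, call DAPI+TdT+ pixels donor and DAPI+TdT- pixels host, restrict to
pixels with non-zero raw target intensity, and average. Within-image
contrasts use unsubtracted means; means with the average background (from
a nucleus-free rectangle) subtracted are reported alongside and used for
between-image quartets (`if_decompose()`), where intensity offsets do not
cancel — both variants are emitted because either choice is defensible
for the within-image contrast. Numerical conventions: blur kernels are
truncated at 4 sigma with reflective boundaries (so border nuclei are not
attenuated and a flat image blurs to itself exactly); ROIs are half-open
pixel rectangles with origin top-left; masks use strict thresholds and
are therefore monotone in their cutoffs. `mask_robustness_sweep()`
enumerates all 3^4 = 81 combinations of three DAPI and three TdTomato
cutoffs across the two chimera images and reports the standard error of
each log2 fold-change, excluding and counting combinations that empty a
mask.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized so the full suite runs in
well under a minute: identity checks use 10,000 random quartets,
normalization comparisons 2,000-2,500 genes with 2-10x imbalance,
parameter recovery 500 genes at 200 cells per combination, and the
imprinted-detection study 20 replicate simulations of 2,050 genes.
Fold-change identities asserted as exact are exact in floating point
(the worked normalization example and the enrichment examples);
estimator-vs-oracle agreement uses 1e-12 tolerances; stochastic
recoveries use the margins stated with each test (e.g. Pearson r >= 0.9,
+/-0.1 log2). The divergence filter's strictly-greater reading means the
0.5 boundary itself fails the filter; boundary tests probe either side
rather than the unrepresentable exact boundary.

## Scope and limitations

Alignment, clustering and cell-type annotation are out of scope: cell
types, ortholog maps and gene sets are inputs. The species-assignment
rule uses all aligned reads (whether a restriction to ortholog-mapped
reads is preferable is unresolved; this default is documented). Point
estimates only — no per-gene uncertainty is attached to `I`, `E`, `N`;
with four observations and three degrees of freedom the saturated model
leaves no residual. Spatial structure of donor cells, which can blur the
intrinsic/extrinsic boundary for locally clustered cells, is invisible to
dissociated measurements and outside the model.
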