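---
title: "Group analysis of FA-weighted structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of FA-weighted structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucnet)
```

## The analysis in one paragraph

`strucnet` compares white-matter structural networks between two matched
groups of subjects and relates regional network differences to regional
gene expression. Each subject contributes two region-by-region matrices
derived upstream from diffusion MRI tractography: a streamline-count
matrix (how many tractography streamlines connect two regions) and a
mean fractional-anisotropy (FA) matrix (the average FA along those
connections, a scalar in [0, 1] indexing white-matter microstructural
organization). The package builds FA-weighted networks by thresholding
the counts and masking the FA map, computes weighted graph metrics in
Brain Connectivity Toolbox conventions, integrates every metric across a
range of count thresholds (area under the curve, AUC) so that no single
arbitrary threshold drives the result, and runs matched-pair statistics
at three levels: anatomical edge classes, whole-network metrics, and
individual regions. A final stage regresses group-average regional
metrics on regional gene-expression profiles with influence diagnostics.

Because real cohorts of rare monogenic disorders are tiny and rarely
shareable, the package ships a synthetic-cohort generator with *planted*
effects. Every statistical property the pipeline claims — type-I error
control, power at realistic effect sizes, unbiased slope recovery — is
demonstrated against this generator's known ground truth.

## Network construction

Raw tractography counts are direction-dependent; `symmetric_density()`
averages streamlines starting and ending in each region
(`(raw + t(raw)) / 2`). `build_weighted_network()` then applies a strict
streamline threshold (`counts > tau`) and multiplies the resulting binary
mask with the FA matrix. The strictness convention means `tau = 0`
removes only zero-count pairs. Besides FA weights, three alternative
edge-weight definitions are available for sensitivity analyses: raw
streamline count, count normalized by mean region size, and count
normalized by mean streamline length.

Each region pair belongs to one of four anatomical classes —
subcortical-cortical, left-hemispheric, right-hemispheric, and
interhemispheric — and class-mean edge weights average over *all* pairs
of a class, with absent connections counting as zero. This zero-included
convention is what makes a sparse class (interhemispheric connections,
say) show a low class mean even when its few present edges are strong,
and it matches how group tables of class means are usually reported.
Pairs of two subcortical regions are assigned to the subcortical class;
the alternative (a fifth class) would leave that class with very few
pairs at this parcellation resolution.

Consensus thresholding (`consensus_mask()`) retains only connections
present in every subject of a pool. Clustering and efficiency are
strongly density-dependent, so group differences in them can be an
artifact of degree differences; comparing them inside the consensus
support equalizes density across groups. The consensus pool is all
subjects by default (`consensus_scope = "joint"`); a per-group scope is
provided because the pooling choice is a genuine degree of freedom in
this design, and the two scopes answer slightly different questions
(joint: same support for everyone; per-group: each group's reliable
core).

## Graph metrics

All metrics operate on weighted undirected networks with nonnegative
weights, following the Brain Connectivity Toolbox conventions:

* **Degree** `k_i`: number of nonzero connections.
* **Strength** `s_i`: sum of incident weights.
* **Clustering coefficient**: geometric-mean-of-triangles form on
  max-normalized weights, `C_i = sum_(j,h) (u_ij u_ih u_jh)^(1/3) /
  (k_i (k_i - 1))` with `u = w / max(w)`; zero for degree < 2. The
  max-normalization makes `C_i` invariant to rescaling all weights.
* **Shortest paths**: edge length is the reciprocal weight `1/w`, so
  stronger connections are shorter; unreachable pairs have infinite
  distance.
* **Global efficiency**: mean inverse distance over ordered pairs, with
  `1/Inf = 0`; lies in [0, 1] for weights in [0, 1].
* **Local efficiency**: efficiency of each node's neighborhood subgraph,
  with cube-root length scaling and `(w_ij w_ih)^(1/3)` entry terms, the
  toolbox's weighted convention. A unit-weight clique scores exactly 1.
  Published weighted local-efficiency variants differ in detail; the
  chosen convention is isolated in `local_efficiency()` and validated
  against a literal loop implementation of the formula.
* **Eccentricity** (`node_eccentricity()`): the largest finite distance
  from a node, provided as a secondary descriptive metric.

Every metric is tested against an independent brute-force oracle
(triple-enumeration clustering, Floyd-Warshall distances) to
`1e-10`, and unit-weight networks are verified to reproduce binary-graph
values exactly.

## Threshold sweeps and AUC

The streamline threshold that separates real from spurious connections
is unknowable; instead of committing to one value, every metric is
evaluated across a grid of thresholds (`threshold_sweep()`) and reduced
to the area under the curve (`auc()`, trapezoidal — exact for
piecewise-linear curves). Group comparisons then operate on per-subject
AUC values. The default grid is integer thresholds 0-20, a logged
configuration item rather than a constant of nature: it covers the range
where the default synthetic counts (Poisson around 15) transition from
fully connected to almost empty. Comparison tables report AUC divided by
the grid span, which keeps values on the original metric scale (a
threshold-averaged metric).

Group curves are summarized by the median with a percentile-bootstrap
confidence interval (`bootstrap_median_ci()`), the conventional display
for small groups where means are fragile.

## The statistical battery

Subjects are age-matched in pairs (±2 years), so the primary tests are
paired: `paired_t()` on per-pair differences, with `wilcoxon_signed_rank()`
(exact signed-rank distribution up to n = 25, midranks for ties) as the
nonparametric companion, and `welch_t()` for unpaired comparisons such
as group ages. Every compared sample is screened with `shapiro_wilk()`;
regions failing the screen at alpha = 0.05 are reported but flagged and
excluded from significance claims rather than silently dropped — with
seven pairs the t-test is the most sensitive available comparison, and
the screen guards its normality assumption.

Multiple-comparison control is two-tier: Bonferroni within small
families (four edge classes; four global metrics; group x gene x metric
cells in the expression screen) and Benjamini-Hochberg FDR across the 85
regions of each nodal metric, one family per metric. Pooling all metrics
into one FDR family was the alternative; per-metric families match the
one-table-per-metric reporting structure and keep the four metric tables
mutually comparable. Regions with zero-variance paired differences
cannot be tested and are removed from the FDR family with a warning.

Global clustering and efficiency are compared twice: natively and after
consensus masking (computed at each grid point from the thresholded
supports). Reporting both disambiguates density-driven from
organization-driven differences, and because it is ambiguous whether a
consensus comparison should fix one mask or recompute per threshold,
the per-threshold recomputation is used — it keeps the consensus
property exact at every grid point.

## Expression association

`normalize_expression()` z-scores each donor's regional values across
regions before averaging donors, so donors with different microarray
scalings contribute equally. `fit_expression_regression()` is ordinary
least squares of a regional graph metric on regional expression with an
intercept; it exposes residuals, leverages, and Cook's distances, and
`cooks_flags()` applies the common `4/n` influence cutoff by default
(the rule is configurable because no single cutoff is canonical).
`sensitivity_refit()` re-fits without flagged regions — an association
that survives the removal of its most influential observations is far
more credible at n = 68. Regressions default to cortical regions only,
since expression maps at this parcellation resolution are typically
cortical; subcortical regions join when expression is available for
them. The regression outcome is the group mean of per-subject regional
AUC values — group-average networks are never formed, so the outcome
scale stays interpretable per subject.

`multi_gene_screen()` fits one regression per (group, gene, metric) cell
and Bonferroni-corrects over all cells, the specificity design: a real
gene-specific association should survive the correction only in the
implicated gene's cells.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a matched-pair
case/control study on an 85-region parcellation (34 cortical regions per
hemisphere plus 17 subcortical structures):

* **Edge support.** A cohort-wide backbone (random spanning tree plus
  common random edges) carries 70% of the target density and is present
  in every subject, with pair-specific random edges filling the rest to
  the default density 0.4. The backbone guarantees the consensus network
  stays connected and non-degenerate, as real consensus networks are;
  the generative topology is otherwise deliberately simple
  (Erdős–Rényi), since no topology model is being tested.
* **Edge weights.** A per-pair FA template is drawn from a truncated
  normal per edge class; both pair members observe the template with
  truncated-normal noise (`subject_noise_sd`, default 0.02 — small
  relative to the distance of class means from the [0, 1] bounds, so
  truncation bias is negligible). Class targets are the *zero-included*
  control class means: subcortical-cortical 0.18, left 0.33, right 0.30,
  interhemispheric 0.06. Internally the generator divides by the density
  so that the class mean over all pairs (absent edges counting zero)
  hits the target.
* **Planted effects.** The case member's template is multiplied by a
  global attenuation in (0, 1] and by per-node expression-coupled
  factors `a_i = clamp(1 - coupling * x_i)` applied to both endpoints of
  each incident edge. Streamline-count intensities are attenuated the
  same way, so count thresholds remove case edges earlier — which is
  what produces genuine degree differences. With no planted effect the
  two group labels are exchangeable by construction, which is what makes
  the generator a valid null for calibration.
* **Expression maps.** `generate_expression_map()` draws regional values
  with a configurable left-hemisphere cortical surplus (default +0.5,
  dispersion 0.1), emulating a left > right expression gradient.
* **Ages.** Controls uniform on 10-43 years; the case age is the control
  age ± uniform(0, 2), preserving the ±2-year matching.
* **Reproducibility.** One master seed; pair `p` uses the substream seed
  `(seed + 104729 p) mod (2^31 - 1)` so cohorts are bit-reproducible and
  pairs are independent.

`planted_truth()` records what was planted — the global ratio, the
above-median-attenuation node set, the coupling slope, and the analytic
(truncation-aware) expected class means — so recovery tests never reuse
the generator's own arithmetic as their expectation.

What the generator does *not* emulate: between-edge covariance (edges
are independent given their class mean — real FA has spatially
correlated noise and subject-level global factors), realistic
streamline-count dispersion, hemispheric asymmetries in topology, or any
imaging artifact. Passing calibration on this generator therefore shows
the statistics are correct under the stated model, not that the model
captures every property of real tractography data.

## Numerical choices and degenerate inputs

* Threshold comparison is strict (`counts > tau`).
* Matrix symmetry tolerance on file input is `1e-9`, with the offending
  cell named in the error.
* Zero-variance paired differences raise a degenerate-input error in the
  primitive tests and are flagged and excluded (with a warning) in the
  nodal table.
* A perfect regression fit (residuals at machine noise) reports zero
  Cook's distances; an exact-leverage point (`h = 1`) reports an
  infinite distance and is always flagged.
* Empty networks yield zero metrics throughout; `1/Inf = 0` handles
  disconnected pairs in efficiencies.

## Problem sizes used in the shipped checks

The calibration and power studies shipped with the package use: 500
null cohorts (7 pairs, 85 regions, thresholds 0-20 in steps of 5) for
type-I calibration of the nodal FDR pipeline and the uniformity of
global-metric p-values; 200 cohorts at global attenuation 0.55 (the
left-hemisphere class-mean ratio implied by a 0.33 to ~0.19 reduction)
for power; 500 simulations for expression-slope recovery and confidence
interval coverage; and 200 runs of the five-gene screen (one coupled
gene, four null genes, Bonferroni family 2 x 5 x 4 = 40). The coarser
calibration grid keeps the studies inside a few minutes on one CPU; all
structural checks use the full 0-20 grid.

## Limitations

The package starts from region-by-region matrices: tractography,
parcellation, registration, and voxel-level FA averaging are upstream
and out of scope. The statistical battery assumes matched pairs and
implements exactly the tests described above — no covariate adjustment,
mixed models, or permutation-based network statistics. The weighted
local-efficiency convention is one of several in circulation; it is
pinned down by its oracle test and kept behind a single function so an
alternative convention is a one-function change.
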