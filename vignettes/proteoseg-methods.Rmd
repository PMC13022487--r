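---
title: "Segmenting plasma proteomic cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting plasma proteomic cohorts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoseg)
```

## The problem

Population-scale plasma proteomics (Olink-style NPX panels of thousands of
proteins measured in tens of thousands of participants) invites an
unsupervised question: do subgroups of participants share a proteomic
profile, and do those subgroups carry disease structure? Two obstacles
dominate: *structured missingness* — whole groups of proteins tend to be
missing for the same participants, because panels are assayed together and
delivered in batches — and *dimensionality*, which makes distances between
participants increasingly uninformative. `proteoseg` implements two
complementary segmentation paths that attack these obstacles differently,
plus the downstream analyses that turn the resulting clusters into disease
biology.

## The two clustering paths

### DIRAM: avoid missing values

The observation driving DIRAM is that missingness is block-structured:
whole protein subsets share missing masks, so slicing the matrix into
complete subdatasets loses little information.

1. **Missingness grouping** (`groupByMissingness`). Similarity between two
   proteins is the Jaccard index of their missing-entry participant sets.
   The Jaccard index is exact for the "identical mask" case (J = 1),
   scale-free, and zero for disjoint masks. Proteins are grouped by single
   linkage at a threshold (default 0.5): single linkage realises
   "grouped together" transitively. Both the metric and the threshold are
   parameters because there is no canonical choice; fully observed
   proteins form one shared complete group, all-missing proteins are set
   aside. Within each group, the few participants with residual missing
   values are dropped, leaving dense complete subdatasets. Groups
   retaining fewer than `min_group_participants` (default 100, the
   minimum admissible cluster size) are flagged degenerate and skipped —
   they can never yield an admissible cluster.
2. **Embedding** (`embed2d`). Each subdataset is reduced to two
   dimensions with UMAP at the embedding library's default neighbourhood
   parameters; only the seed is fixed. Because a stochastic embedding can
   land in a local minimum, a multi-seed audit re-embeds under several
   seeds and reports the distribution of pairwise adjusted Rand indices
   of the downstream clusterings. The audit is a report with a warning
   below median ARI 0.5, not an automated rejection — inspecting
   embeddings is a judgement call, and an automated hard gate would hide
   the evidence it is based on.
3. **Density clustering** (`densityCluster`). DBSCAN on the embedding
   with `eps = 0.1`, `min_samples = 10`, keeping clusters of 100–20,000
   participants and relabelling the rest noise. DBSCAN is implemented in
   the package (grid-based region query, textbook density-connected
   expansion) and is verified against a brute-force O(n²) reference in
   the test suite. Note that a *fixed* radius interacts with cohort size:
   embedding density grows with n, so the default radius is calibrated
   for cohorts of a few thousand participants and upward; far smaller
   inputs need a larger `eps`.
4. **Merging** (`mergeClusters`). Clusters found in different
   subdatasets may be one subpopulation seen through different panels.
   For clusters C1, C2 restricted to their shared universe of size N,
   the expected overlap under independence is E = |C1||C2|/N; with
   observed overlap O the merge score is (O − E)/min(|C1|, |C2|) and
   pairs above 0.4 merge, transitively. The normalisation by the smaller
   cluster is a design choice — the score is then ≈ 1 for identical
   clusters and 0 in expectation under independence — and the
   denominator is configurable (`union`, `geomean`) because other
   conventions are defensible. When merged clusters compete for a
   participant, the assignment prefers more source votes, then the
   *smaller* merged cluster: a diffuse whole-subdataset detection should
   not strip members from a compact cluster seen elsewhere.

### DIRCOD: impute, iterate, validate on raw data

1. **Imputation** (`imputeKnn`). Each missing entry becomes the mean of
   the protein over the participant's 15 nearest neighbours (Euclidean
   distance with mean-filled missing entries for the distance step only).
   Imputed values are estimates, not measurements — which motivates the
   validation step below.
2. **Community detection** (`detectCommunities`). A k-nearest-neighbour
   graph (k = 15) on the current protein subset, partitioned by the
   Leiden algorithm under the modularity objective at resolution 1.
3. **Differential-protein selection** (`selectDifferentialProteins`).
   Every (community, protein) pair is tested on the **raw, non-imputed**
   values with a two-sample Kolmogorov–Smirnov test, Bonferroni-corrected
   over all pairs tested; a protein significant in *any* community is
   kept. The KS test is the package's choice of an omnibus
   distributional test (no particular test is canonical here), and
   Bonferroni matches the overall multiplicity policy. Validating on raw
   data keeps imputation artefacts from steering the iteration.
4. **Iteration** (`iterateDircod`). Steps 2–3 alternate; iteration 1
   uses all proteins and iteration t+1 exactly the proteins selected at
   t. The loop records everything and does not assume convergence — the
   default is 20 iterations, with more available for exploration.
5. **Pattern assignment** (`assignByPattern`). Community labels are
   arbitrary per iteration, so only co-membership is used: the
   co-assignment similarity of two participants is the fraction of
   iterations sharing a community, and clusters are connected components
   of the graph linking pairs at similarity ≥ 0.9. Exact-pattern matching
   (threshold 1.0) is available but brittle to single-iteration label
   churn, which is why 0.9 is the default. Components under the minimum
   cluster size become noise.

## Downstream analyses

**Quartile abundance rule** (`callAbundance`). A protein is
high-abundance in a cluster only when the in-cluster 25th percentile
strictly exceeds the out-of-cluster 75th percentile ("the top three
quartiles inside clear the top quartile outside"), and symmetrically for
low. This is deliberately conservative; ties at the boundary yield
`none`. Percentiles use linear interpolation between closest ranks
(R type 7); the convention is fixed and documented because verdicts near
the boundary depend on it. Missing values are excluded, never imputed,
and sides with fewer than 20 observed values are flagged.

**Cluster recreation** (`recreate`, `leaveOneOut`). A signature's
percentile values, computed *inside* the pooled cluster group, are
applied as cutoffs to the whole population (≥ threshold for high
proteins, ≤ for low). Filtering across proteins is conjunctive by
default — all constraints simultaneously — with a disjunctive flag;
participants missing a signature value count as unselected (a flag drops
them entirely). Each percentile yields a 2×2 selected-by-disease table,
the cross-product odds ratio and a Woolf log-OR 95% CI with
Haldane–Anscombe 0.5 correction when a cell is zero. Leave-one-out
curves quantify each protein's contribution; since omitting a constraint
can only enlarge the selection, the delta-OR isolates proteins that
carry the association.

**Principal-axis prevalence** (`fitAxis`, `binPrevalence`). The
signature is collapsed to the first principal axis of the cluster
group's covariance, standardized by default (proteins on different
scales; the flag disables it), with the sign fixed so the first
signature protein loads nonnegatively. The whole population is then
binned into equal-size groups (default 20 bins; ties broken by
participant id for determinism) and per-bin prevalence is regressed on
the bin's mean coordinate, excluding the two extreme bins, which are
noisy. The per-bin bookkeeping is exact: bin sizes differ by at most
one and size-weighted prevalences sum to the case count.

**Differential coregulation** (`differentialCorrelation`,
`criticalCorrelation`). Candidates (signature proteins shared by all or
all-but-one cluster) are screened for |r| ≥ 0.8 with some other
candidate; correlation matrices are computed on pairwise-complete
non-imputed values inside the group (A) and outside it (B), and the
result is Δ = A − B. Pairs with fewer than 30 complete observations on
a side are masked, not silently reported. The Bonferroni critical
correlation for a sample of size n under m tests inverts the t
transform: r* = t*/√(n−2+t*²), t* = qt(1 − α/2m, n−2); it is reported
for each side at the median per-pair sample size.

**Characterization** (`diseaseEnrichment`, `demographicContrast`).
Fisher's exact test per (cluster, ICD-10 code) with one Bonferroni
family per call, cross-product odds ratios with Woolf CIs
(Haldane–Anscombe when needed — the exact test always uses raw counts),
optional sex stratification; Mann–Whitney for age and chi-square for sex
composition, with the minority-sex fraction reported. The tests are
pragmatic defaults; nothing in the framework depends on them
specifically.

ICD-10 codes are analyzed at the 3-character level (`normalizeIcd10`):
uppercase, dot suffix dropped, truncated to three characters. Coarser
user-defined groupings are supported through an explicit mapping rather
than a built-in table, because no canonical grouping exists.

## The synthetic cohort generator

`generateCohort` draws the statistical structure the framework assumes,
so every stage is testable without access-restricted cohort data:

- baseline abundances are i.i.d. standard normal — NPX units are
  log-scale and approximately normal, and the simplest model consistent
  with the data type keeps every downstream property interpretable;
- planted clusters are multinomial with given proportions, realized as
  mean shifts (default 3 SD) on disjoint 30-protein blocks;
- block missingness masks contiguous protein subsets for a shared random
  participant fraction (emulating panels and delivery batches that share
  missing masks), batch dropout masks the tail of the panel, and a
  uniform missing-at-random rate is available;
- disease labels are Bernoulli with cluster-dependent odds
  (odds = baseline odds × per-cluster multiplier) — logistic in the
  cluster indicator only, with no age/sex confounding by default, so
  enrichment properties are isolated; optional per-cluster age shifts
  and sex probabilities exist for the demographic tests;
- coregulation uses the shared-latent-factor construction
  x = √ρ·z + √(1−ρ)·e, which has unit variance and exact pairwise
  correlation ρ.

The defaults (3,000 participants × 120 proteins, 4 equal clusters,
3 SD shifts) are the package's reference conditions; they are small
enough to run everywhere yet large enough for the paper-scale defaults
(DBSCAN radius, minimum cluster size 100) to operate. What the generator
does **not** emulate: assay chemistry, limits of detection as a
censoring mechanism, plate effects, heavy-tailed or skewed abundance
distributions, and confounded missingness (missingness independent of
the planted clusters given the block structure). Passing tests on this
generator therefore demonstrate that the machinery recovers the
structure it assumes, not that real cohorts satisfy those assumptions.

## Determinism and numerical choices

Every stochastic step takes an explicit seed; the pipeline derives
per-stage seeds from one global seed by a stable hash, and a rerun with
the same configuration is byte-identical (output provenance headers
carry the package version and parameters, deliberately no timestamps).
Quantiles are type 7 throughout. Degenerate inputs are handled
explicitly rather than silently: empty selections flag undefined odds
ratios, sparse correlation pairs are masked, all-missing proteins are
discarded and reported, embedding inputs smaller than the neighbourhood
size are errors, and regressions through fewer than three bins carry no
confidence interval.

## A worked example

```{r example, eval = FALSE}
cfg <- SyntheticConfig(missing_block_spec = list(c(40, 0.3)),
                       disease_spec = list(list(code = "I10",
                                                baseline = 0.05,
                                                multipliers = c(1, 4, 1, 1))))
cohort <- generateCohort(cfg)
diram  <- diramCluster(cohort$matrix)
dircod <- dircodCluster(cohort$matrix)
calls  <- abundanceTable(cohort$matrix, dircod)
```

The test suite (`tests/testthat`) runs the same machinery at reduced
problem sizes — planted-recovery at n = 3,000, null calibrations at a
few hundred participants over 40–200 replicates — chosen so the whole
suite completes in minutes while keeping Monte-Carlo error well inside
the asserted bounds.

## Known limitations

- The DBSCAN radius does not adapt to cohort size; tiny cohorts need a
  manual `eps`.
- Pattern assignment materialises an n × n co-assignment matrix;
  fine to tens of thousands of participants, not to millions.
- The merge rule's "40%" score has no canonical denominator; three
  conventions are offered, and results near the margin deserve a look at
  the provenance.
- Fisher/KS/Mann–Whitney are defaults, not claims of optimality.
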