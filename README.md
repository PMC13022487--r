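# proteoseg

Unsupervised segmentation of high-dimensional plasma-proteomic cohorts,
and the disease-association analyses that make the resulting participant
clusters interpretable.

Population-scale proteomics panels (thousands of NPX-scale protein
abundances per participant) hold subgroup structure that supervised,
single-disease analyses never look for. Finding it is hard for two
reasons: missingness is *structured* (whole protein panels are missing
for the same participants, by assay design and delivery batch), and
distances degrade in thousands of dimensions. `proteoseg` is for
researchers who want to segment such a cohort into participant clusters
and then ask what those clusters mean clinically. It implements two
complementary clustering paths:

- **DIRAM** — avoid missing data: group proteins by the Jaccard
  similarity of their missing-value masks, slice the matrix into
  complete subdatasets, embed each to 2-D with UMAP, detect clusters
  with DBSCAN (`eps = 0.1`, `min_samples = 10`, cluster sizes
  100–20,000), and merge clusters from different subdatasets when their
  observed overlap O exceeds the independence expectation
  E = |C1||C2|/N by more than 40% of the smaller cluster:
  (O − E)/min(|C1|,|C2|) > 0.4.
- **DIRCOD** — impute and validate: k-nearest-neighbour imputation
  (k = 15), then alternate Leiden community detection on a kNN
  participant graph with selection of proteins whose distributions
  differ per community — tested on the **raw, non-imputed** values
  (two-sample Kolmogorov–Smirnov, Bonferroni) — for 20 iterations, and
  finally cluster participants whose community-assignment patterns
  co-occur in ≥ 90% of iterations.

Downstream, per cluster or cluster group:

- a conservative **quartile abundance rule**: a protein is "high" in a
  cluster only if the in-cluster Q1 strictly exceeds the outside Q3
  (and the mirror image for "low");
- **cluster recreation**: slice the whole population at the signature's
  in-cluster percentile values and trace the disease odds-ratio curve,
  with leave-one-out curves measuring each protein's contribution;
- a **principal-axis prevalence gradient**: collapse the signature to
  the first principal axis fitted on the cluster group, bin the
  population into equal-size groups along it, and regress per-bin
  prevalence on axis position;
- **differential coregulation**: within-group minus rest-of-population
  correlation matrices (Δ = A − B) on non-imputed values, with the
  Bonferroni critical correlation r\* = t\*/√(n−2+t\*²);
- **ICD-10 enrichment and demographics**: Fisher's exact odds ratios per
  (cluster, 3-character code) and age/sex contrasts, all
  Bonferroni-corrected.

A synthetic cohort generator with planted clusters, block-structured
missingness and cluster-dependent disease odds makes every stage
testable without access-restricted cohort data.

## Worked example

```r
library(proteoseg)

cfg <- SyntheticConfig(n_participants = 3000, n_proteins = 120,
                       missing_block_spec = list(c(40, 0.3)),
                       disease_spec = list(list(code = "I10", baseline = 0.05,
                                                multipliers = c(1, 4, 1, 1))),
                       seed = 1)
cohort <- generateCohort(cfg)
cohort$matrix
#> ProteinMatrix: 3000 participants x 120 proteins (10.0% missing)

groupByMissingness(cohort$matrix)
#> MissingnessGrouping: 2 groups at Jaccard >= 0.50 (0 proteins discarded)
#>   complete: 80 proteins, 3000 retained participants
#>   G1: 40 proteins, 2100 retained participants

clusters <- dircodCluster(cohort$matrix, T = 10)
clusters
#> ClusterAssignment [DIRCOD]: 3000 participants, 6 clusters, 0 noise

diseaseEnrichment(clusters, cohort$phenotypes, "I10")
#>   cluster_id   a   b odds_ratio    ci_low   ci_high p_bonferroni
#> ...
#> 4         B4 127 651  3.8561092 2.9384290 5.0603838 3.801847e-21
```

Cluster B4 captures the planted disease-enriched subpopulation
(generating odds multiplier 4; estimated OR 3.86, CI 2.94–5.06). Its
high-abundance signature recreates a disease-enriched slice of the whole
population:

```r
calls <- abundanceTable(cohort$matrix, clusters)
sig <- commonSignature(calls, "B4", "high")       # 30 proteins
rc <- recreate(cohort$matrix, cohort$phenotypes, clusterMembers(clusters, "B4"),
               data.frame(protein_id = head(sig, 8), direction = "high"),
               "I10", c(25, 50, 75))
curveTable(rc)
#>   percentile selected_n cases_in cases_out odds_ratio    ci_low   ci_high  flagged
#> 1         25         76       17       217   3.594392 2.0594098  6.273474    FALSE
#> 2         50          6        1       233   2.369957 0.2757335 20.370021    FALSE
#> 3         75          0        0       234         NA        NA        NA     TRUE
```

Participants above the signature's 25th in-cluster percentile on all
eight proteins carry 3.6-fold disease odds; stricter thresholds select
too few participants for a stable estimate, and an empty selection is
flagged rather than reported as a number.

A YAML-configured end-to-end run (synthesis through characterization,
with provenance headers and an MD5 manifest) is available as
`runPipeline()` / `inst/scripts/proteoseg.R`; see `?runPipeline`.

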