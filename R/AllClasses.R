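#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom IRanges CharacterList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Participants-by-proteins abundance matrix with explicit missingness
#'
#' `ProteinMatrix` holds continuous (NPX-like, log-scale) protein abundances
#' for a cohort, together with the missingness structure that drives the
#' clustering framework. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"npx"` assay
#' stored in the Bioconductor orientation (proteins as rows, participants as
#' columns); `NA` entries are missing. The user-facing accessor [npx()]
#' returns the matrix in the participants-by-proteins orientation of the
#' delimited input files.
#'
#' @slot .Data inherited SummarizedExperiment internals.
#' @seealso [readProteinMatrix()], [npx()], [observedMask()]
#' @export
setClass("ProteinMatrix", contains = "SummarizedExperiment")

.validProteinMatrix <- function(object) {
  msg <- NULL
  if (!"npx" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'npx' is required")
  else if (!is.numeric(SummarizedExperiment::assay(object, "npx")))
    msg <- c(msg, "assay 'npx' must be numeric")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, sprintf("duplicate participant id: %s",
                          colnames(object)[duplicated(colnames(object))][1L]))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, sprintf("duplicate protein id: %s",
                          rownames(object)[duplicated(rownames(object))][1L]))
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "participant and protein ids are required")
  if (is.null(msg)) TRUE else msg
}
setValidity("ProteinMatrix", .validProteinMatrix)

#' Construct a ProteinMatrix
#'
#' @param values numeric matrix, participants in rows and proteins in columns
#'   (the orientation of the delimited input files); `NA` marks a missing
#'   (unobserved) measurement.
#' @param participant_ids,protein_ids optional identifier vectors; default to
#'   the dimnames of `values`.
#' @return A [ProteinMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("P", 1:3), c("ALB", "CRP")))
#' pm <- ProteinMatrix(m)
#' nParticipants(pm)
#' @export
ProteinMatrix <- function(values, participant_ids = rownames(values),
                          protein_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(participant_ids) || is.null(protein_ids))
    stop("participant and protein ids are required")
  storage.mode(values) <- "double"
  dimnames(values) <- list(as.character(participant_ids),
                           as.character(protein_ids))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = t(values)))
  new("ProteinMatrix", se)
}

#' Per-participant phenotypes: age, sex and ICD-10 diagnoses
#'
#' Stores one row per participant with age in years, binary sex, and the set
#' of 3-character ICD-10 codes recorded for that participant (a
#' [IRanges::CharacterList]). Codes are normalized with [normalizeIcd10()]
#' at construction. The participant universe may differ from a
#' [ProteinMatrix-class]'s; analyses join on the intersection.
#'
#' @slot data a [S4Vectors::DataFrame] with rownames = participant ids and
#'   columns `age`, `sex`, `icd10`.
#' @export
setClass("PhenotypeTable", representation(data = "DataFrame"))

.validPhenotypeTable <- function(object) {
  d <- object@data
  msg <- NULL
  if (!all(c("age", "sex", "icd10") %in% colnames(d)))
    msg <- c(msg, "columns 'age', 'sex', 'icd10' are required")
  if (anyDuplicated(rownames(d)))
    msg <- c(msg, "duplicate participant id")
  if ("age" %in% colnames(d) && any(d$age < 0, na.rm = TRUE))
    msg <- c(msg, "negative age")
  if ("icd10" %in% colnames(d)) {
    codes <- unlist(d$icd10, use.names = FALSE)
    bad <- codes[!grepl("^[A-Z][0-9]{2}$", codes)]
    if (length(bad))
      msg <- c(msg, sprintf("malformed ICD-10 code after normalization: %s",
                            bad[1L]))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("PhenotypeTable", .validPhenotypeTable)

#' Construct a PhenotypeTable
#'
#' @param participant_id character vector of unique identifiers.
#' @param age numeric, years.
#' @param sex character or factor with two levels (e.g. `"F"`/`"M"`).
#' @param icd10 list (one element per participant) of raw ICD-10 codes;
#'   normalized to the 3-character level on construction.
#' @return A [PhenotypeTable-class].
#' @export
PhenotypeTable <- function(participant_id, age, sex,
                           icd10 = vector("list", length(participant_id))) {
  participant_id <- as.character(participant_id)
  icd10 <- lapply(icd10, function(x)
    if (length(x)) unique(normalizeIcd10(x)) else character())
  d <- DataFrame(age = as.numeric(age), sex = as.character(sex),
                 icd10 = CharacterList(icd10), row.names = participant_id)
  new("PhenotypeTable", data = d)
}

#' Participant-to-cluster assignment with provenance
#'
#' Labels are a named character vector (names = participant ids); `NA` is the
#' noise label. Provenance records the method and the parameters and source
#' subdatasets or iterations behind each cluster.
#'
#' @slot method `"DIRAM"`, `"DIRCOD"` or another short method tag.
#' @slot labels named character vector, `NA` = noise.
#' @slot provenance list of per-run / per-cluster records.
#' @export
setClass("ClusterAssignment",
         representation(method = "character", labels = "character",
                        provenance = "list"))

.validClusterAssignment <- function(object) {
  msg <- NULL
  if (length(object@method) != 1L) msg <- c(msg, "method must be length 1")
  if (is.null(names(object@labels)) && length(object@labels))
    msg <- c(msg, "labels must be named by participant id")
  if (anyDuplicated(names(object@labels)))
    msg <- c(msg, "duplicate participant in labels")
  if (is.null(msg)) TRUE else msg
}
setValidity("ClusterAssignment", .validClusterAssignment)

#' @rdname ClusterAssignment-class
#' @param method short method tag.
#' @param labels named character vector of cluster labels, `NA` = noise.
#' @param provenance free-form provenance list.
#' @export
ClusterAssignment <- function(method, labels, provenance = list()) {
  new("ClusterAssignment", method = as.character(method),
      labels = structure(as.character(labels), names = names(labels)),
      provenance = provenance)
}

#' A group of proteins sharing a missing-value pattern
#'
#' Produced by [groupByMissingness()]: proteins whose missing-entry sets are
#' linked at the chosen Jaccard threshold, together with the participants
#' fully observed on the group (the rows of the complete subdataset).
#'
#' @slot group_id identifier.
#' @slot protein_ids proteins in the group.
#' @slot retained_participants participants with no missing value on the
#'   group's proteins.
#' @slot degenerate `TRUE` when fewer than the minimum number of participants
#'   survive; degenerate groups are skipped by the DIRAM pipeline.
#' @export
setClass("MissingnessGroup",
         representation(group_id = "character", protein_ids = "character",
                        retained_participants = "character",
                        degenerate = "logical"))

#' The partition of proteins by missingness pattern
#'
#' @slot groups list of [MissingnessGroup-class].
#' @slot discarded proteins with all values missing (never grouped).
#' @slot threshold the Jaccard similarity threshold used.
#' @export
setClass("MissingnessGrouping",
         representation(groups = "list", discarded = "character",
                        threshold = "numeric"))

#' A 2-D embedding of one complete subdataset
#'
#' @slot subdataset_id identifier of the source missingness group.
#' @slot seed the random seed used for the reported coordinates.
#' @slot coords participants x 2 coordinate matrix (rownames = participants).
#' @slot stability multi-seed audit: list with `seeds`, `pairwise_ari` and
#'   `median_ari` (empty when no audit was requested).
#' @export
setClass("EmbeddingResult",
         representation(subdataset_id = "character", seed = "integer",
                        coords = "matrix", stability = "list"))

#' Quartile-rule abundance call for one (cluster, protein) pair
#'
#' Verdict `"high"` requires the in-cluster 25th percentile to exceed the
#' out-of-cluster 75th percentile (strictly); `"low"` is the mirror image;
#' otherwise `"none"`.
#'
#' @slot cluster_id,protein_id identifiers.
#' @slot verdict one of `"high"`, `"low"`, `"none"`.
#' @slot q1_in,q3_in,q1_out,q3_out the quartile evidence.
#' @slot n_in,n_out observed (non-missing) counts on each side.
#' @slot flagged `TRUE` when either side had fewer than the minimum observed
#'   count and the verdict was forced to `"none"`.
#' @export
setClass("AbundanceCall",
         representation(cluster_id = "character", protein_id = "character",
                        verdict = "character", q1_in = "numeric",
                        q3_in = "numeric", q1_out = "numeric",
                        q3_out = "numeric", n_in = "integer",
                        n_out = "integer", flagged = "logical"))

#' Percentile-slicing recreation curve with leave-one-out contributions
#'
#' @slot disease_code 3-character ICD-10 code.
#' @slot signature data.frame with columns `protein_id`, `direction`.
#' @slot curve data.frame, one row per percentile: selected counts, 2x2
#'   cells, odds ratio and Woolf 95% CI, and a flag for undefined cells.
#' @slot loo named list (protein omitted -> curve data.frame with `delta_or`).
#' @export
setClass("RecreationCurve",
         representation(disease_code = "character", signature = "data.frame",
                        curve = "data.frame", loo = "list"))

#' First-principal-axis transform fitted on a cluster group
#'
#' @slot proteins signature proteins, in loading order.
#' @slot loadings first-axis weights (sign fixed: first protein nonnegative).
#' @slot center,scale per-protein centering/scaling from the fitting
#'   population (`scale` all 1 when standardization is off).
#' @slot fitted_on participants used for the fit.
#' @export
setClass("AxisTransform",
         representation(proteins = "character", loadings = "numeric",
                        center = "numeric", scale = "numeric",
                        fitted_on = "character"))

#' Equal-size axis bins with per-bin disease prevalence
#'
#' @slot transform the [AxisTransform-class] applied.
#' @slot bins data.frame: bin index, size, cases, prevalence, mean axis
#'   coordinate (midpoint).
#' @slot regression list with `slope`, `intercept` and the bins used (the
#'   extreme bins are excluded when requested).
#' @slot prevalence_fit disease prevalence in the fitting population.
#' @slot prevalence_population prevalence in the binned population.
#' @export
setClass("AxisBinning",
         representation(transform = "AxisTransform", bins = "data.frame",
                        regression = "list", prevalence_fit = "numeric",
                        prevalence_population = "numeric"))

#' Differential coregulation result
#'
#' Within-group (`A`) and rest-of-population (`B`) Pearson correlation
#' matrices on pairwise-complete non-imputed values, their difference
#' `delta = A - B`, per-pair observation counts, and the Bonferroni critical
#' correlation for each side.
#'
#' @slot proteins ordered proteins entering the analysis.
#' @slot A,B,delta symmetric correlation matrices (`NA` = masked pair).
#' @slot n_in,n_out per-pair complete-observation counts.
#' @slot critical_r_in,critical_r_out Bonferroni |r| thresholds.
#' @export
setClass("DiffCorrResult",
         representation(proteins = "character", A = "matrix", B = "matrix",
                        delta = "matrix", n_in = "matrix", n_out = "matrix",
                        critical_r_in = "numeric", critical_r_out = "numeric"))

#' Synthetic cohort configuration
#'
#' Defines the statistical structure of a generated cohort: planted latent
#' participant clusters realized as mean shifts on disjoint protein blocks,
#' block-structured missingness (groups of proteins sharing missing masks),
#' optional batch-style dropout of a contiguous protein subset, optional
#' uniform random missingness, binary disease labels with cluster-dependent
#' odds, and optional within-cluster coregulation through a shared latent
#' factor.
#'
#' @slot n_participants,n_proteins,n_clusters cohort dimensions.
#' @slot cluster_proportions simplex vector over clusters.
#' @slot shift_proteins_per_cluster proteins shifted per cluster (disjoint
#'   consecutive blocks from protein 1).
#' @slot shift_magnitude shift in baseline-SD units.
#' @slot missing_block_spec list of `c(size, fraction)` pairs: each block
#'   masks a contiguous protein subset (allocated from the end of the panel)
#'   for a random participant fraction, all proteins of a block sharing the
#'   same participants.
#' @slot batch_dropout `c(fraction, size)` or empty: contiguous protein
#'   subset masked for a random participant fraction (a batch-style dropout).
#' @slot missing_random_rate uniform completely-at-random missingness rate.
#' @slot disease_spec list of `list(code, baseline, multipliers)`: baseline
#'   prevalence and per-cluster odds multipliers.
#' @slot coregulation_spec empty, or `list(cluster, size, rho)`: pairwise
#'   correlation `rho` among the first `size` proteins of the cluster's shift
#'   block, within that cluster, via a shared latent factor.
#' @slot age_mean,age_sd age distribution (years).
#' @slot age_shift_per_cluster optional per-cluster additive age shift.
#' @slot sex_prob probability of sex `"F"`, scalar or per-cluster.
#' @slot seed integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @export
setClass("SyntheticConfig",
         representation(n_participants = "integer", n_proteins = "integer",
                        n_clusters = "integer",
                        cluster_proportions = "numeric",
                        shift_proteins_per_cluster = "integer",
                        shift_magnitude = "numeric",
                        missing_block_spec = "list",
                        batch_dropout = "numeric",
                        missing_random_rate = "numeric",
                        disease_spec = "list", coregulation_spec = "list",
                        age_mean = "numeric", age_sd = "numeric",
                        age_shift_per_cluster = "numeric",
                        sex_prob = "numeric", seed = "integer"))

.validSyntheticConfig <- function(object) {
  msg <- NULL
  if (abs(sum(object@cluster_proportions) - 1) > 1e-9)
    msg <- c(msg, "cluster_proportions must sum to 1")
  if (length(object@cluster_proportions) != object@n_clusters)
    msg <- c(msg, "cluster_proportions length must equal n_clusters")
  if (object@shift_magnitude < 0) msg <- c(msg, "shift_magnitude must be >= 0")
  if (object@n_clusters * object@shift_proteins_per_cluster >
      object@n_proteins)
    msg <- c(msg, "shift blocks exceed n_proteins")
  for (b in object@missing_block_spec)
    if (length(b) != 2L || b[1L] < 1 || b[2L] < 0 || b[2L] > 1)
      msg <- c(msg, "each missing block must be c(size >= 1, fraction in [0,1])")
  if (length(object@missing_block_spec)) {
    tot <- sum(vapply(object@missing_block_spec, `[`, 0, 1L))
    if (tot > object@n_proteins)
      msg <- c(msg, "missing blocks exceed n_proteins")
  }
  if (length(object@batch_dropout) &&
      (length(object@batch_dropout) != 2L ||
       object@batch_dropout[1L] < 0 || object@batch_dropout[1L] > 1 ||
       object@batch_dropout[2L] > object@n_proteins))
    msg <- c(msg, "batch_dropout must be c(fraction in [0,1], size <= n_proteins)")
  if (object@missing_random_rate < 0 || object@missing_random_rate >= 1)
    msg <- c(msg, "missing_random_rate must be in [0,1)")
  for (d in object@disease_spec) {
    if (!all(c("code", "baseline", "multipliers") %in% names(d)))
      msg <- c(msg, "disease_spec entries need code, baseline, multipliers")
    else if (d$baseline < 0 || d$baseline > 1)
      msg <- c(msg, sprintf("baseline prevalence of %s outside [0,1]", d$code))
    else if (length(d$multipliers) != object@n_clusters)
      msg <- c(msg, sprintf("multipliers of %s must have one entry per cluster",
                            d$code))
  }
  if (length(object@coregulation_spec)) {
    cs <- object@coregulation_spec
    if (!all(c("cluster", "size", "rho") %in% names(cs)))
      msg <- c(msg, "coregulation_spec needs cluster, size, rho")
    else {
      if (cs$cluster < 1 || cs$cluster > object@n_clusters)
        msg <- c(msg, "coregulation cluster index out of range")
      if (cs$rho < 0 || cs$rho >= 1)
        msg <- c(msg, "coregulation rho must be in [0,1)")
      if (cs$size < 2)
        msg <- c(msg, "coregulation needs a protein subset of size >= 2")
      if (cs$size > max(object@shift_proteins_per_cluster, object@n_proteins))
        msg <- c(msg, "coregulation subset larger than available proteins")
    }
  }
  if (length(object@sex_prob) != 1L &&
      length(object@sex_prob) != object@n_clusters)
    msg <- c(msg, "sex_prob must be scalar or per-cluster")
  if (any(object@sex_prob < 0 | object@sex_prob > 1))
    msg <- c(msg, "sex_prob must be in [0,1]")
  if (length(object@age_shift_per_cluster) &&
      length(object@age_shift_per_cluster) != object@n_clusters)
    msg <- c(msg, "age_shift_per_cluster must have one entry per cluster")
  if (is.null(msg)) TRUE else msg
}
setValidity("SyntheticConfig", .validSyntheticConfig)
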