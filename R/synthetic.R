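#' Configure a synthetic cohort
#'
#' Builds a validated [SyntheticConfig-class]. The generated cohort has
#' independent standard-normal baseline abundances (NPX-like log-scale
#' values), `n_clusters` planted participant clusters realized as mean
#' shifts of `shift_magnitude` SD on disjoint consecutive protein blocks of
#' size `shift_proteins_per_cluster`, and the missingness / disease /
#' coregulation structure described in [SyntheticConfig-class].
#'
#' The defaults are the cohort used throughout the package's own
#' evaluations: 3,000 participants, 120 proteins, 4 equally likely clusters
#' each shifting its own 30-protein block by 3 SD.
#'
#' @param n_participants,n_proteins,n_clusters cohort dimensions.
#' @param cluster_proportions simplex vector (default uniform).
#' @param shift_proteins_per_cluster,shift_magnitude planted signal.
#' @param missing_block_spec list of `c(size, fraction)` missing blocks;
#'   blocks occupy contiguous protein ranges allocated from the end of the
#'   panel, and all proteins of a block share the same masked participants.
#' @param batch_dropout `c(fraction, size)` batch-style dropout of the last
#'   `size` proteins for a random participant fraction, or `NULL`.
#' @param missing_random_rate completely-at-random missingness rate.
#' @param disease_spec list of `list(code, baseline, multipliers)`.
#' @param coregulation_spec `list(cluster, size, rho)` or `NULL`.
#' @param age_mean,age_sd,age_shift_per_cluster age model (years).
#' @param sex_prob probability of sex `"F"`, scalar or per cluster.
#' @param seed integer seed.
#' @return A [SyntheticConfig-class].
#' @export
SyntheticConfig <- function(n_participants = 3000L, n_proteins = 120L,
                            n_clusters = 4L,
                            cluster_proportions = rep(1 / n_clusters,
                                                      n_clusters),
                            shift_proteins_per_cluster = 30L,
                            shift_magnitude = 3,
                            missing_block_spec = list(),
                            batch_dropout = NULL,
                            missing_random_rate = 0,
                            disease_spec = list(),
                            coregulation_spec = NULL,
                            age_mean = 57, age_sd = 8,
                            age_shift_per_cluster = NULL,
                            sex_prob = 0.5, seed = 1L) {
  new("SyntheticConfig",
      n_participants = as.integer(n_participants),
      n_proteins = as.integer(n_proteins),
      n_clusters = as.integer(n_clusters),
      cluster_proportions = as.numeric(cluster_proportions),
      shift_proteins_per_cluster = as.integer(shift_proteins_per_cluster),
      shift_magnitude = as.numeric(shift_magnitude),
      missing_block_spec = missing_block_spec,
      batch_dropout = if (is.null(batch_dropout)) numeric()
                      else as.numeric(batch_dropout),
      missing_random_rate = as.numeric(missing_random_rate),
      disease_spec = disease_spec,
      coregulation_spec = if (is.null(coregulation_spec)) list()
                          else coregulation_spec,
      age_mean = as.numeric(age_mean), age_sd = as.numeric(age_sd),
      age_shift_per_cluster = if (is.null(age_shift_per_cluster)) numeric()
                              else as.numeric(age_shift_per_cluster),
      sex_prob = as.numeric(sex_prob), seed = as.integer(seed))
}

#' Protein indices shifted by each planted cluster
#'
#' Cluster `k` shifts the `k`-th consecutive block of
#' `shift_proteins_per_cluster` proteins (empty when the shift size is 0).
#'
#' @param config a [SyntheticConfig-class].
#' @return list of integer index vectors, one per cluster.
#' @export
shiftProteinIndices <- function(config) {
  s <- config@shift_proteins_per_cluster
  lapply(seq_len(config@n_clusters), function(k)
    if (s > 0L) ((k - 1L) * s + 1L):(k * s) else integer())
}

.coregIndices <- function(config) {
  cs <- config@coregulation_spec
  if (!length(cs)) return(integer())
  blocks <- shiftProteinIndices(config)
  blk <- blocks[[cs$cluster]]
  if (length(blk) >= cs$size) blk[seq_len(cs$size)] else seq_len(cs$size)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from a [SyntheticConfig-class]: the result is a pure
#' function of the configuration (same config, bit-identical cohort).
#' Baseline abundances are i.i.d. standard normal; each cluster adds its
#' mean shift on its protein block; the coregulation spec (when present)
#' replaces the baseline of its protein subset inside its cluster by the
#' shared-latent-factor construction
#' `x = sqrt(rho) * z + sqrt(1 - rho) * e`, which has unit variance and
#' exact pairwise correlation `rho`. Missing blocks, batch dropout and
#' random missingness then mask entries; disease labels are drawn with
#' cluster-dependent odds (`odds = baseline_odds * multiplier[cluster]`).
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements `matrix` ([ProteinMatrix-class]),
#'   `phenotypes` ([PhenotypeTable-class]), `truth` (named integer vector of
#'   planted cluster indices) and `info` (list: per-cluster shifted protein
#'   ids, coregulated protein ids, per-block masked protein ids).
#' @examples
#' cohort <- generateCohort(SyntheticConfig(n_participants = 200,
#'                                          n_proteins = 40,
#'                                          shift_proteins_per_cluster = 10))
#' table(cohort$truth)
#' @export
generateCohort <- function(config) {
  methods::validObject(config)
  n <- config@n_participants
  p <- config@n_proteins
  K <- config@n_clusters
  set.seed(config@seed)
  pid <- sprintf("P%0*d", nchar(as.character(n)), seq_len(n))
  prot <- sprintf("PROT%0*d", nchar(as.character(p)), seq_len(p))

  truth <- sample.int(K, n, replace = TRUE,
                      prob = config@cluster_proportions)
  names(truth) <- pid
  X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(pid, prot))

  coreg <- .coregIndices(config)
  if (length(coreg)) {
    cs <- config@coregulation_spec
    rows <- which(truth == cs$cluster)
    if (length(rows)) {
      z <- stats::rnorm(length(rows))
      X[rows, coreg] <- sqrt(cs$rho) * z +
        sqrt(1 - cs$rho) * matrix(stats::rnorm(length(rows) * length(coreg)),
                                  length(rows), length(coreg))
    }
  }

  blocks <- shiftProteinIndices(config)
  if (config@shift_magnitude > 0)
    for (k in seq_len(K)) {
      rows <- which(truth == k)
      if (length(rows) && length(blocks[[k]]))
        X[rows, blocks[[k]]] <- X[rows, blocks[[k]]] + config@shift_magnitude
    }

  # structured missingness: contiguous blocks from the end of the panel
  block_cols <- list()
  hi <- p
  for (b in config@missing_block_spec) {
    size <- as.integer(b[1L])
    cols <- (hi - size + 1L):hi
    hi <- hi - size
    rows <- sample.int(n, round(b[2L] * n))
    X[rows, cols] <- NA_real_
    block_cols[[length(block_cols) + 1L]] <- prot[cols]
  }
  if (length(config@batch_dropout)) {
    size <- as.integer(config@batch_dropout[2L])
    cols <- (p - size + 1L):p
    rows <- sample.int(n, round(config@batch_dropout[1L] * n))
    X[rows, cols] <- NA_real_
  }
  if (config@missing_random_rate > 0) {
    drop <- which(stats::runif(n * p) < config@missing_random_rate)
    X[drop] <- NA_real_
  }

  icd <- replicate(n, character(), simplify = FALSE)
  for (d in config@disease_spec) {
    odds <- d$baseline / (1 - d$baseline) * d$multipliers[truth]
    sick <- stats::runif(n) < odds / (1 + odds)
    code <- normalizeIcd10(d$code)
    for (i in which(sick)) icd[[i]] <- c(icd[[i]], code)
  }

  age <- stats::rnorm(n, config@age_mean, config@age_sd)
  if (length(config@age_shift_per_cluster))
    age <- age + config@age_shift_per_cluster[truth]
  age <- pmax(age, 0)
  sp <- if (length(config@sex_prob) == 1L) rep(config@sex_prob, K)
        else config@sex_prob
  sex <- ifelse(stats::runif(n) < sp[truth], "F", "M")

  list(matrix = ProteinMatrix(X),
       phenotypes = PhenotypeTable(pid, age, sex, icd),
       truth = truth,
       info = list(shift_proteins = lapply(blocks, function(ix) prot[ix]),
                   coregulated_proteins = prot[coreg],
                   missing_block_proteins = block_cols))
}

#' Achieved within-cluster correlation of the planted coregulated subset
#'
#' Test support for the differential-coregulation analyses: measures the
#' mean pairwise sample correlation of the configuration's coregulated
#' protein subset among the participants of the named cluster.
#'
#' @param matrix a [ProteinMatrix-class] from [generateCohort()].
#' @param config the generating [SyntheticConfig-class] (must carry a
#'   coregulation spec).
#' @param labels the true cluster labels returned by the generator.
#' @return mean pairwise Pearson correlation (scalar).
#' @export
plantedCorrelationCheck <- function(matrix, config, labels) {
  cs <- config@coregulation_spec
  if (!length(cs)) stop("config carries no coregulation spec")
  idx <- .coregIndices(config)
  if (length(idx) < 2L) stop("coregulated subset must have >= 2 proteins")
  rows <- names(labels)[labels == cs$cluster]
  if (!length(rows)) stop(sprintf("cluster %d absent from labels", cs$cluster))
  sub <- npx(matrix)[rows, proteinIds(matrix)[idx], drop = FALSE]
  cm <- stats::cor(sub, use = "pairwise.complete.obs")
  mean(cm[upper.tri(cm)])
}
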