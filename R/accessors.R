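#' @describeIn ProteinMatrix-class abundance values, participants x proteins,
#'   `NA` = missing.
#' @export
setMethod("npx", "ProteinMatrix", function(x)
  t(SummarizedExperiment::assay(x, "npx")))

#' @describeIn ProteinMatrix-class logical participants x proteins matrix,
#'   `TRUE` = observed.
#' @export
setMethod("observedMask", "ProteinMatrix", function(x)
  !is.na(npx(x)))

#' @describeIn ProteinMatrix-class participant identifiers, file order.
#' @export
setMethod("participantIds", "ProteinMatrix", function(x) colnames(x))

#' @describeIn ProteinMatrix-class protein identifiers, file order.
#' @export
setMethod("proteinIds", "ProteinMatrix", function(x) rownames(x))

#' @describeIn ProteinMatrix-class number of participants.
#' @export
setMethod("nParticipants", "ProteinMatrix", function(x) ncol(x))

#' @describeIn ProteinMatrix-class number of proteins.
#' @export
setMethod("nProteins", "ProteinMatrix", function(x) nrow(x))

setMethod("show", "ProteinMatrix", function(object) {
  v <- SummarizedExperiment::assay(object, "npx")
  miss <- mean(is.na(v))
  cat(sprintf("ProteinMatrix: %d participants x %d proteins (%.1f%% missing)\n",
              ncol(v), nrow(v), 100 * miss))
})

# --- PhenotypeTable -------------------------------------------------------

#' @describeIn PhenotypeTable-class participant identifiers.
#' @export
setMethod("participantIds", "PhenotypeTable", function(x) rownames(x@data))

#' @describeIn PhenotypeTable-class ages in years, named by participant.
#' @export
setMethod("ages", "PhenotypeTable", function(x)
  structure(x@data$age, names = rownames(x@data)))

#' @describeIn PhenotypeTable-class sex labels, named by participant.
#' @export
setMethod("sexes", "PhenotypeTable", function(x)
  structure(x@data$sex, names = rownames(x@data)))

#' @describeIn PhenotypeTable-class per-participant sets of normalized
#'   3-character codes.
#' @export
setMethod("icd10Codes", "PhenotypeTable", function(x)
  structure(x@data$icd10, names = rownames(x@data)))

#' @describeIn PhenotypeTable-class named logical: does each participant
#'   carry `code`?
#' @export
setMethod("hasCode", "PhenotypeTable", function(x, code) {
  code <- normalizeIcd10(code)
  lst <- x@data$icd10
  all_codes <- unlist(lst, use.names = FALSE)
  owner <- rep(seq_along(lst), lengths(lst))
  hit <- tabulate(owner[all_codes == code], nbins = length(lst)) > 0L
  structure(hit, names = rownames(x@data))
})

setMethod("show", "PhenotypeTable", function(object) {
  d <- object@data
  cat(sprintf("PhenotypeTable: %d participants, %d distinct ICD-10 codes\n",
              nrow(d), length(unique(unlist(d$icd10)))))
})

#' Subset a PhenotypeTable by participant
#'
#' @param x a [PhenotypeTable-class].
#' @param i participant ids or indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PhenotypeTable", function(x, i, j, ..., drop = FALSE) {
  new("PhenotypeTable", data = x@data[i, , drop = FALSE])
})

# --- ClusterAssignment ----------------------------------------------------

#' @describeIn ClusterAssignment-class named label vector (`NA` = noise).
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @describeIn ClusterAssignment-class the method tag.
#' @export
setMethod("clusterMethod", "ClusterAssignment", function(x) x@method)

#' @describeIn ClusterAssignment-class cluster sizes (noise excluded).
#' @export
setMethod("clusterSizes", "ClusterAssignment", function(x)
  table(x@labels, useNA = "no"))

#' @describeIn ClusterAssignment-class participants in one cluster.
#' @export
setMethod("clusterMembers", "ClusterAssignment", function(x, label)
  names(x@labels)[!is.na(x@labels) & x@labels == label])

#' @describeIn ClusterAssignment-class participant identifiers.
#' @export
setMethod("participantIds", "ClusterAssignment", function(x) names(x@labels))

setMethod("show", "ClusterAssignment", function(object) {
  n <- length(object@labels)
  k <- length(unique(object@labels[!is.na(object@labels)]))
  cat(sprintf("ClusterAssignment [%s]: %d participants, %d clusters, %d noise\n",
              object@method, n, k, sum(is.na(object@labels))))
})

# --- MissingnessGrouping --------------------------------------------------

#' @describeIn MissingnessGrouping-class number of groups.
#' @param x a [MissingnessGrouping-class].
#' @export
setMethod("length", "MissingnessGrouping", function(x) length(x@groups))

#' @describeIn MissingnessGrouping-class extract one [MissingnessGroup-class].
#' @param i group index or id.
#' @param j,... ignored.
#' @export
setMethod("[[", "MissingnessGrouping", function(x, i, j, ...) {
  if (is.character(i))
    i <- match(i, vapply(x@groups, function(g) g@group_id, ""))
  x@groups[[i]]
})

#' @describeIn MissingnessGrouping-class named list: group id -> proteins.
#' @export
setMethod("groupProteins", "MissingnessGrouping", function(x) {
  out <- lapply(x@groups, function(g) g@protein_ids)
  names(out) <- vapply(x@groups, function(g) g@group_id, "")
  out
})

#' @describeIn MissingnessGrouping-class named list: group id -> retained
#'   participants.
#' @export
setMethod("retainedParticipants", "MissingnessGrouping", function(x) {
  out <- lapply(x@groups, function(g) g@retained_participants)
  names(out) <- vapply(x@groups, function(g) g@group_id, "")
  out
})

#' @describeIn MissingnessGrouping-class all-missing proteins set aside.
#' @export
setMethod("discardedProteins", "MissingnessGrouping", function(x) x@discarded)

setMethod("show", "MissingnessGrouping", function(object) {
  cat(sprintf("MissingnessGrouping: %d groups at Jaccard >= %.2f (%d proteins discarded)\n",
              length(object@groups), object@threshold,
              length(object@discarded)))
  for (g in object@groups)
    cat(sprintf("  %s: %d proteins, %d retained participants%s\n",
                g@group_id, length(g@protein_ids),
                length(g@retained_participants),
                if (g@degenerate) " [degenerate]" else ""))
})

# --- EmbeddingResult ------------------------------------------------------

#' @describeIn EmbeddingResult-class the participants x 2 coordinates.
#' @export
setMethod("embeddingCoords", "EmbeddingResult", function(x) x@coords)

#' @describeIn EmbeddingResult-class the multi-seed agreement audit.
#' @export
setMethod("stabilityReport", "EmbeddingResult", function(x) x@stability)

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf("EmbeddingResult [%s]: %d participants, seed %d\n",
              object@subdataset_id, nrow(object@coords), object@seed))
  if (length(object@stability))
    cat(sprintf("  stability audit: median pairwise ARI %.3f over %d seeds\n",
                object@stability$median_ari,
                length(object@stability$seeds)))
})

# --- result containers ----------------------------------------------------

#' @describeIn AbundanceCall-class the verdict string.
#' @export
setMethod("verdict", "AbundanceCall", function(x) x@verdict)

setMethod("show", "AbundanceCall", function(object) {
  cat(sprintf("AbundanceCall %s / %s: %s (q1_in=%.3g q3_out=%.3g q3_in=%.3g q1_out=%.3g, n=%d/%d)%s\n",
              object@cluster_id, object@protein_id, object@verdict,
              object@q1_in, object@q3_out, object@q3_in, object@q1_out,
              object@n_in, object@n_out,
              if (object@flagged) " [flagged]" else ""))
})

#' @describeIn RecreationCurve-class per-percentile table for the full
#'   signature.
#' @export
setMethod("curveTable", "RecreationCurve", function(x) x@curve)

#' @describeIn RecreationCurve-class named list of leave-one-out tables.
#' @export
setMethod("looTables", "RecreationCurve", function(x) x@loo)

setMethod("show", "RecreationCurve", function(object) {
  cat(sprintf("RecreationCurve [%s]: %d signature proteins, %d percentiles%s\n",
              object@disease_code, nrow(object@signature),
              nrow(object@curve),
              if (length(object@loo))
                sprintf(", leave-one-out over %d proteins", length(object@loo))
              else ""))
})

#' @describeIn AxisTransform-class the first-axis loadings.
#' @export
setMethod("axisLoadings", "AxisTransform", function(x)
  structure(x@loadings, names = x@proteins))

setMethod("show", "AxisTransform", function(object) {
  cat(sprintf("AxisTransform: %d proteins, fitted on %d participants\n",
              length(object@proteins), length(object@fitted_on)))
})

setMethod("show", "AxisBinning", function(object) {
  cat(sprintf("AxisBinning: %d bins, prevalence %.4f (fit) / %.4f (population), slope %.3g\n",
              nrow(object@bins), object@prevalence_fit,
              object@prevalence_population, object@regression$slope))
})

#' @describeIn DiffCorrResult-class the A - B difference matrix.
#' @export
setMethod("deltaMatrix", "DiffCorrResult", function(x) x@delta)

setMethod("show", "DiffCorrResult", function(object) {
  d <- object@delta[upper.tri(object@delta)]
  cat(sprintf("DiffCorrResult: %d proteins, delta range [%.3f, %.3f], critical |r| %.3f (in) / %.3f (out)\n",
              length(object@proteins), min(d, na.rm = TRUE),
              max(d, na.rm = TRUE), object@critical_r_in,
              object@critical_r_out))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d participants x %d proteins, %d clusters (shift %.1f SD on %d proteins each), seed %d\n",
              object@n_participants, object@n_proteins, object@n_clusters,
              object@shift_magnitude, object@shift_proteins_per_cluster,
              object@seed))
})
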