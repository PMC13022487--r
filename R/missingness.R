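#' Group proteins by similarity of their missing-value patterns
#'
#' In large proteomic panels, groups of proteins often share missing values
#' for the same participants (assay panels measured together, delivery
#' batches). Grouping such proteins and dropping the few incomplete rows
#' yields dense, complete subdatasets with minimal information loss — the
#' preprocessing step of the DIRAM path.
#'
#' Similarity between two proteins is the Jaccard index of their
#' missing-entry participant sets (1 for identical masks, 0 for disjoint
#' ones). Proteins are grouped by single linkage: any chain of pairs with
#' similarity at or above `similarity_threshold` ends up in one group.
#' Proteins with no missing values form one shared `complete` group;
#' all-missing proteins are set aside on a discard list. Within each group,
#' participants with any missing value on the group's proteins are dropped;
#' groups retaining fewer than `min_group_participants` participants are
#' flagged degenerate (too small to ever yield an admissible cluster).
#'
#' @param matrix a [ProteinMatrix-class].
#' @param similarity_threshold Jaccard threshold in \[0, 1\], default 0.5.
#' @param min_group_participants minimum retained participants before a
#'   group is flagged degenerate; default 100, the minimum cluster size.
#' @return A [MissingnessGrouping-class].
#' @examples
#' m <- matrix(rnorm(40), 10, 4,
#'             dimnames = list(paste0("P", 1:10), paste0("Q", 1:4)))
#' m[1:2, 3:4] <- NA       # Q3, Q4 share a missing mask
#' g <- groupByMissingness(ProteinMatrix(m), min_group_participants = 2)
#' groupProteins(g)
#' @export
groupByMissingness <- function(matrix, similarity_threshold = 0.5,
                               min_group_participants = 100L) {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1)
  M <- !observedMask(matrix)            # TRUE = missing
  if (!length(M)) stop("empty matrix")
  pid <- participantIds(matrix)
  prot <- proteinIds(matrix)
  nmiss <- colSums(M)
  discarded <- prot[nmiss == nrow(M)]
  complete <- prot[nmiss == 0L]
  partial <- prot[nmiss > 0L & nmiss < nrow(M)]

  comp <- if (length(partial)) {
    Mi <- M[, partial, drop = FALSE]
    storage.mode(Mi) <- "double"
    inter <- crossprod(Mi)
    sz <- diag(inter)
    uni <- outer(sz, sz, "+") - inter
    J <- inter / uni
    adj <- J >= similarity_threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    igraph::components(g)$membership
  } else integer()

  groups <- list()
  mkGroup <- function(id, prots) {
    sub <- M[, prots, drop = FALSE]
    keep <- pid[rowSums(sub) == 0L]
    new("MissingnessGroup", group_id = id, protein_ids = prots,
        retained_participants = keep,
        degenerate = length(keep) < min_group_participants)
  }
  if (length(complete))
    groups <- c(groups, list(mkGroup("complete", complete)))
  if (length(partial)) {
    ids <- sort(unique(comp))
    for (k in ids)
      groups <- c(groups, list(mkGroup(sprintf("G%d", k),
                                       partial[comp == k])))
  }
  new("MissingnessGrouping", groups = groups, discarded = discarded,
      threshold = similarity_threshold)
}

#' Extract the complete subdataset of a missingness group
#'
#' @param matrix the [ProteinMatrix-class] the group was derived from.
#' @param group a [MissingnessGroup-class].
#' @return A dense [ProteinMatrix-class] (retained participants x group
#'   proteins) with no missing entries; row/column order preserved.
#' @export
extractSubdataset <- function(matrix, group) {
  keep_p <- intersect(participantIds(matrix), group@retained_participants)
  keep_q <- intersect(proteinIds(matrix), group@protein_ids)
  if (!length(keep_p) || !length(keep_q))
    stop(sprintf("group '%s' yields an empty subdataset", group@group_id))
  sub <- npx(matrix)[keep_p, keep_q, drop = FALSE]
  if (anyNA(sub))
    stop(sprintf("group '%s' is inconsistent with this matrix: missing values remain",
                 group@group_id))
  ProteinMatrix(sub)
}
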