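#' Embed a complete subdataset in two dimensions
#'
#' UMAP projection of a complete (missing-free) subdataset to 2-D, the
#' dimensionality-reduction step of the DIRAM path. Neighborhood size and
#' minimum distance stay at the embedding library's defaults; only the
#' random seed is fixed. Because a nonconvex embedding can get trapped in a
#' local minimum, an optional multi-seed audit re-embeds the data under
#' `n_seeds_audit` seeds, density-clusters each embedding, and reports the
#' distribution of pairwise adjusted Rand indices between the resulting
#' clusterings; a median below 0.5 raises a warning (the audit is a report,
#' not an automated rejection).
#'
#' @param sub a complete [ProteinMatrix-class] (no missing entries).
#' @param seed integer seed for the reported embedding.
#' @param n_seeds_audit number of audit seeds (`1, 2, ..., n_seeds_audit`);
#'   0 disables the audit.
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @param eps,min_samples density-clustering parameters used inside the
#'   stability audit.
#' @param subdataset_id identifier stored with the result.
#' @return An [EmbeddingResult-class].
#' @export
embed2d <- function(sub, seed = 1L, n_seeds_audit = 0L, n_neighbors = 15L,
                    eps = 0.1, min_samples = 10L,
                    subdataset_id = "subdataset") {
  X <- npx(sub)
  if (anyNA(X)) stop("subdataset must be complete (no missing values)")
  if (nrow(X) < n_neighbors)
    stop(sprintf("%d participants is fewer than the neighborhood size %d",
                 nrow(X), n_neighbors))
  run_one <- function(s) {
    set.seed(s)
    co <- uwot::umap(X, n_neighbors = n_neighbors, n_threads = 1,
                     n_sgd_threads = 1)
    rownames(co) <- rownames(X)
    co
  }
  coords <- run_one(seed)
  stability <- list()
  if (n_seeds_audit >= 2L) {
    seeds <- seq_len(n_seeds_audit)
    labs <- lapply(seeds, function(s)
      .dbscan(run_one(s), eps = eps, min_samples = min_samples))
    pr <- utils::combn(length(seeds), 2L)
    ari <- vapply(seq_len(ncol(pr)), function(j)
      mclust::adjustedRandIndex(labs[[pr[1L, j]]], labs[[pr[2L, j]]]), 0)
    stability <- list(seeds = seeds, pairwise_ari = ari,
                      median_ari = stats::median(ari))
    if (stability$median_ari < 0.5)
      warning(sprintf("embedding unstable: median pairwise ARI %.2f across %d seeds",
                      stability$median_ari, n_seeds_audit))
  }
  new("EmbeddingResult", subdataset_id = subdataset_id,
      seed = as.integer(seed), coords = coords, stability = stability)
}

# DBSCAN on 2-D coordinates with a grid-based region query.
# Core point: >= min_samples points (self included) within radius eps.
# Clusters are density-connected sets; border points join the first cluster
# that reaches them; everything else is noise (0).
.dbscan <- function(coords, eps, min_samples) {
  if (eps <= 0) stop("eps must be positive")
  n <- nrow(coords)
  x <- coords[, 1L]
  y <- coords[, 2L]
  kx <- as.integer(floor(x / eps))
  ky <- as.integer(floor(y / eps))
  kx <- kx - min(kx) + 2L                  # 1-cell guard band
  ky <- ky - min(ky) + 2L
  nx <- max(kx) + 1L
  ny <- max(ky) + 1L
  key <- kx + (ky - 1L) * nx
  cells <- vector("list", nx * ny)
  filled <- split(seq_len(n), key)
  cells[as.integer(names(filled))] <- filled
  eps2 <- eps * eps
  off <- as.vector(outer(-1L:1L, (-1L:1L) * nx, "+"))
  region <- function(i) {
    cand <- unlist(cells[key[i] + off], use.names = FALSE)
    cand[(x[cand] - x[i])^2 + (y[cand] - y[i])^2 <= eps2]
  }
  labels <- integer(n)
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    Ni <- region(i)
    if (length(Ni) < min_samples) next     # provisionally noise
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- Ni
    ptr <- 1L
    while (ptr <= length(seeds)) {
      j <- seeds[ptr]
      ptr <- ptr + 1L
      if (!visited[j]) {
        visited[j] <- TRUE
        Nj <- region(j)
        if (length(Nj) >= min_samples) seeds <- c(seeds, Nj)
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Density-based cluster detection on a 2-D embedding
#'
#' DBSCAN on the embedding coordinates: core points have at least
#' `min_samples` points (themselves included) within radius `eps`; clusters
#' are density-connected sets; unreachable points are noise. Clusters whose
#' size falls outside `[min_cluster_size, max_cluster_size]` are relabeled
#' noise — very small detections are unstable and very large ones merge
#' distinct subpopulations. Defaults: `eps = 0.1`, `min_samples = 10`,
#' size bounds `[100, 20000]`.
#'
#' @param embedding an [EmbeddingResult-class].
#' @param eps neighborhood radius (must be positive).
#' @param min_samples core-point threshold.
#' @param min_cluster_size,max_cluster_size admissible size bounds.
#' @return A [ClusterAssignment-class] with labels
#'   `"<subdataset_id>.C<k>"`, noise = `NA`.
#' @export
densityCluster <- function(embedding, eps = 0.1, min_samples = 10L,
                           min_cluster_size = 100L,
                           max_cluster_size = 20000L) {
  co <- embeddingCoords(embedding)
  raw <- .dbscan(co, eps = eps, min_samples = min_samples)
  sizes <- tabulate(raw)
  keep <- which(sizes >= min_cluster_size & sizes <= max_cluster_size)
  lab <- rep(NA_character_, length(raw))
  for (j in seq_along(keep))
    lab[raw == keep[j]] <- sprintf("%s.C%d", embedding@subdataset_id, j)
  names(lab) <- rownames(co)
  ClusterAssignment("DIRAM", lab, provenance = list(
    subdataset = embedding@subdataset_id, seed = embedding@seed,
    params = list(eps = eps, min_samples = min_samples,
                  min_cluster_size = min_cluster_size,
                  max_cluster_size = max_cluster_size),
    raw_cluster_sizes = sizes))
}

#' Merge clusters found in different subdatasets
#'
#' Clusters detected in different complete subdatasets may be the same
#' subpopulation seen through different protein panels. For clusters C1, C2
#' from different subdatasets, restricted to their shared participant
#' universe of size N, the expected overlap under independence is
#' `E = |C1| * |C2| / N`; with observed overlap `O = |C1 n C2|`, the merge
#' score is `(O - E) / d` where the denominator `d` is `min(|C1|, |C2|)`
#' (default; `|C1 u C2|` and `sqrt(|C1| * |C2|)` available). Pairs scoring
#' above `overlap_margin` (default 0.4) are merged; merging is transitive
#' (connected components of the merge graph) and the merged cluster is the
#' union of its members. For identical clusters the min-normalized score is
#' `1 - E / |C|` (close to 1); under independence its expectation is 0.
#'
#' A participant claimed by several merged clusters is assigned to the one
#' that contains it in the most source clusters; remaining ties prefer the
#' smaller (more specific) merged cluster, then label order. A diffuse
#' detection spanning a whole subdataset thus never strips members from a
#' compact cluster seen elsewhere.
#'
#' @param assignments list of [ClusterAssignment-class] from different
#'   subdatasets (each labels vector names its participant universe).
#' @param overlap_margin merge threshold on the score, default 0.4.
#' @param denominator `"min"`, `"union"` or `"geomean"`.
#' @return A merged [ClusterAssignment-class] over the union universe.
#' @export
mergeClusters <- function(assignments, overlap_margin = 0.4,
                          denominator = c("min", "union", "geomean")) {
  denominator <- match.arg(denominator)
  stopifnot(length(assignments) >= 1L)
  if (length(assignments) == 1L) return(assignments[[1L]])

  universes <- lapply(assignments, function(a) names(clusterLabels(a)))
  clusters <- list()
  for (ai in seq_along(assignments)) {
    labs <- clusterLabels(assignments[[ai]])
    for (lb in sort(unique(labs[!is.na(labs)])))
      clusters[[length(clusters) + 1L]] <-
        list(aid = ai, label = lb, members = names(labs)[!is.na(labs) &
                                                           labs == lb])
  }
  nc <- length(clusters)
  if (nc == 0L) {
    uni <- sort(unique(unlist(universes)))
    return(ClusterAssignment("DIRAM",
                             structure(rep(NA_character_, length(uni)),
                                       names = uni)))
  }
  edges <- integer()
  for (i in seq_len(nc - 1L)) for (j in (i + 1L):nc) {
    ci <- clusters[[i]]; cj <- clusters[[j]]
    if (ci$aid == cj$aid) next
    U <- intersect(universes[[ci$aid]], universes[[cj$aid]])
    if (!length(U)) {
      warning(sprintf("no shared universe between %s and %s; pair skipped",
                      ci$label, cj$label))
      next
    }
    m1 <- intersect(ci$members, U)
    m2 <- intersect(cj$members, U)
    if (!length(m1) || !length(m2)) next
    O <- length(intersect(m1, m2))
    E <- length(m1) * length(m2) / length(U)
    d <- switch(denominator,
                min = min(length(m1), length(m2)),
                union = length(union(m1, m2)),
                geomean = sqrt(length(m1) * length(m2)))
    if ((O - E) / d > overlap_margin) edges <- c(edges, i, j)
  }
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership

  keys <- vapply(clusters, function(cl) paste0(cl$aid, ":", cl$label), "")
  comp_order <- order(vapply(split(keys, comp), min, ""))
  labels_out <- character()
  votes <- list()
  for (r in seq_along(comp_order)) {
    members_cl <- which(comp == comp_order[r])
    name <- sprintf("M%d", r)
    for (ci in members_cl)
      for (pp in clusters[[ci]]$members)
        votes[[pp]] <- c(votes[[pp]], name)
  }
  uni <- sort(unique(unlist(universes)))
  lab <- rep(NA_character_, length(uni))
  names(lab) <- uni
  if (length(votes)) {
    grp_size <- table(unlist(votes))
    for (pp in names(votes)) {
      v <- votes[[pp]]
      tb <- sort(table(v), decreasing = TRUE)
      top <- names(tb)[tb == tb[1L]]
      if (length(top) > 1L)
        top <- top[order(grp_size[top], top)][1L]
      lab[pp] <- top
    }
  }
  prov <- list(params = list(overlap_margin = overlap_margin,
                             denominator = denominator),
               sources = split(keys, sprintf("M%d", match(comp,
                                                          comp_order))))
  ClusterAssignment("DIRAM", lab, provenance = prov)
}

#' DIRAM clustering: complete subdatasets, 2-D embedding, density clusters
#'
#' End-to-end DIRAM path: [groupByMissingness()] partitions the proteins by
#' missing-value pattern; every non-degenerate group's complete subdataset
#' is embedded with [embed2d()] and clustered with [densityCluster()]; the
#' per-subdataset assignments are reconciled with [mergeClusters()].
#'
#' @param matrix a [ProteinMatrix-class].
#' @param similarity_threshold,min_group_participants see
#'   [groupByMissingness()].
#' @param n_neighbors UMAP neighborhood size.
#' @param eps,min_samples,min_cluster_size,max_cluster_size see
#'   [densityCluster()].
#' @param merge_margin,merge_denominator see [mergeClusters()].
#' @param seed embedding seed.
#' @param audit_seeds multi-seed stability audit count per subdataset.
#' @return A [ClusterAssignment-class] with method `"DIRAM"`.
#' @export
diramCluster <- function(matrix, similarity_threshold = 0.5,
                         min_group_participants = 100L, n_neighbors = 15L,
                         eps = 0.1, min_samples = 10L,
                         min_cluster_size = 100L, max_cluster_size = 20000L,
                         merge_margin = 0.4, merge_denominator = "min",
                         seed = 1L, audit_seeds = 0L) {
  grouping <- groupByMissingness(matrix, similarity_threshold,
                                 min_group_participants)
  assignments <- list()
  audits <- list()
  for (g in grouping@groups) {
    if (g@degenerate) next
    sub <- extractSubdataset(matrix, g)
    emb <- embed2d(sub, seed = seed, n_seeds_audit = audit_seeds,
                   n_neighbors = n_neighbors, eps = eps,
                   min_samples = min_samples, subdataset_id = g@group_id)
    if (length(emb@stability)) audits[[g@group_id]] <- emb@stability
    assignments[[length(assignments) + 1L]] <-
      densityCluster(emb, eps = eps, min_samples = min_samples,
                     min_cluster_size = min_cluster_size,
                     max_cluster_size = max_cluster_size)
  }
  if (!length(assignments))
    stop("no non-degenerate subdataset produced clusters")
  out <- mergeClusters(assignments, overlap_margin = merge_margin,
                       denominator = merge_denominator)
  out@provenance$params <- c(out@provenance$params,
                             list(similarity_threshold = similarity_threshold,
                                  eps = eps, min_samples = min_samples,
                                  min_cluster_size = min_cluster_size,
                                  max_cluster_size = max_cluster_size,
                                  seed = seed))
  out@provenance$stability_audits <- audits
  methods::validObject(out)
  out
}
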