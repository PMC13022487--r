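#' Nearest-neighbour imputation of missing abundances
#'
#' Each missing entry is replaced by the mean of that protein over the
#' `n_neighbors` nearest participants. Distances are Euclidean over the
#' protein panel with missing entries mean-filled for the distance
#' computation only; among a participant's `n_neighbors` nearest
#' neighbours, the mean is taken over those with the protein observed (the
#' overall protein mean is used in the rare case that none of them observed
#' it). Observed entries are never changed.
#'
#' @param matrix a [ProteinMatrix-class].
#' @param n_neighbors neighbourhood size, default 15.
#' @return A complete [ProteinMatrix-class].
#' @export
imputeKnn <- function(matrix, n_neighbors = 15L) {
  X <- npx(matrix)
  obs_per_protein <- colSums(!is.na(X))
  short <- which(obs_per_protein < n_neighbors)
  if (length(short))
    stop(sprintf("protein '%s' observed in only %d participants (< n_neighbors = %d)",
                 colnames(X)[short[1L]], obs_per_protein[short[1L]],
                 n_neighbors))
  if (!anyNA(X)) return(matrix)
  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  for (j in which(colSums(is.na(X)) > 0L))
    Xf[is.na(X[, j]), j] <- mu[j]
  need <- which(rowSums(is.na(X)) > 0L)
  nn <- RANN::nn2(Xf, query = Xf[need, , drop = FALSE],
                  k = min(n_neighbors + 1L, nrow(Xf)))$nn.idx
  out <- X
  for (r in seq_along(need)) {
    i <- need[r]
    nb <- setdiff(nn[r, ], i)[seq_len(min(n_neighbors,
                                          ncol(nn) - 1L))]
    for (j in which(is.na(X[i, ]))) {
      v <- X[nb, j]
      v <- v[!is.na(v)]
      out[i, j] <- if (length(v)) mean(v) else mu[j]
    }
  }
  ProteinMatrix(out)
}

#' Leiden community detection on a k-nearest-neighbour participant graph
#'
#' Builds an (undirected, unweighted) k-nearest-neighbour graph of the
#' participants on the selected-protein submatrix and partitions it with
#' the Leiden algorithm under the modularity objective at the default
#' resolution 1. Deterministic under a fixed seed.
#'
#' @param matrix a [ProteinMatrix-class], complete on `selected`.
#' @param selected protein subset to use (default: all).
#' @param resolution Leiden resolution parameter, default 1.
#' @param seed integer seed.
#' @param k neighbourhood size of the graph, default 15 (reduced to
#'   `n - 1` for tiny inputs, with a warning).
#' @return named integer vector: participant -> community label.
#' @export
detectCommunities <- function(matrix, selected = proteinIds(matrix),
                              resolution = 1, seed = 1L, k = 15L) {
  if (!length(selected)) stop("selected protein subset is empty")
  X <- npx(matrix)[, selected, drop = FALSE]
  if (anyNA(X)) stop("matrix must be complete on the selected proteins")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 participants")
  if (n <= k) {
    warning(sprintf("only %d participants; reducing k to %d", n, n - 1L))
    k <- n - 1L
  }
  nn <- RANN::nn2(X, k = k + 1L)$nn.idx[, -1L, drop = FALSE]
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  set.seed(seed)
  cm <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution)
  structure(as.integer(igraph::membership(cm)), names = rownames(X))
}

#' Select proteins with community-specific distributions on raw data
#'
#' For every (community, protein) pair, a two-sample Kolmogorov-Smirnov
#' test compares the observed (non-missing, non-imputed) values inside the
#' community with those outside it. P-values are Bonferroni-corrected over
#' all pairs actually tested, and a protein is selected when it is
#' significant for at least one community at corrected level `alpha`.
#' Validating on the raw matrix keeps imputation artifacts out of the
#' selection.
#'
#' @param raw the non-imputed [ProteinMatrix-class].
#' @param communities named vector, participant -> community label.
#' @param alpha family-wise significance level, default 0.05.
#' @param min_observed pairs with fewer observed values than this on either
#'   side are skipped (and recorded in the `skipped` attribute).
#' @return character vector of selected proteins, with attributes
#'   `n_tests` and `skipped`.
#' @export
selectDifferentialProteins <- function(raw, communities, alpha = 0.05,
                                       min_observed = 20L) {
  X <- npx(raw)[names(communities), , drop = FALSE]
  comm <- sort(unique(communities))
  pmat <- matrix(NA_real_, length(comm), ncol(X),
                 dimnames = list(as.character(comm), colnames(X)))
  skipped <- 0L
  for (ci in seq_along(comm)) {
    inside <- communities == comm[ci]
    for (j in seq_len(ncol(X))) {
      xin <- X[inside, j]
      xin <- xin[!is.na(xin)]
      xout <- X[!inside, j]
      xout <- xout[!is.na(xout)]
      if (length(xin) < min_observed || length(xout) < min_observed) {
        skipped <- skipped + 1L
        next
      }
      pmat[ci, j] <- suppressWarnings(
        stats::ks.test(xin, xout)$p.value)
    }
  }
  m <- sum(!is.na(pmat))
  sel <- if (m)
    colnames(X)[apply(pmat, 2L, function(p)
      any(!is.na(p) & p <= alpha / m))]
  else character()
  structure(sel, n_tests = m, skipped = skipped)
}

#' One iteration record of the DIRCOD loop
#'
#' @slot iteration 1-based index.
#' @slot selected_proteins proteins used by this iteration's community
#'   detection (iteration 1 uses all proteins).
#' @slot community_of named integer vector, participant -> community.
#' @export
setClass("CommunityHistory",
         representation(iteration = "integer",
                        selected_proteins = "character",
                        community_of = "integer"))

setMethod("show", "CommunityHistory", function(object) {
  cat(sprintf("CommunityHistory iteration %d: %d proteins, %d communities\n",
              object@iteration, length(object@selected_proteins),
              length(unique(object@community_of))))
})

#' Iterate Leiden detection and differential-protein selection
#'
#' Alternates [detectCommunities()] on the imputed matrix (restricted to
#' the current protein subset) with [selectDifferentialProteins()] on the
#' raw matrix. Iteration 1 uses all proteins; iteration `t + 1` uses
#' exactly the proteins selected at iteration `t`. The loop records every
#' iteration and does not assume convergence; should a selection come back
#' empty the loop stops early with a warning and returns the history so
#' far.
#'
#' @param matrix the imputed (complete) [ProteinMatrix-class].
#' @param raw the original non-imputed [ProteinMatrix-class].
#' @param T number of iterations, default 20.
#' @param seed integer seed; per-iteration seeds are derived as
#'   `seed + t - 1`.
#' @param alpha,min_observed see [selectDifferentialProteins()].
#' @param resolution,k see [detectCommunities()].
#' @return list of [CommunityHistory-class], length at most `T`.
#' @export
iterateDircod <- function(matrix, raw, T = 20L, seed = 1L, alpha = 0.05,
                          min_observed = 20L, resolution = 1, k = 15L) {
  stopifnot(T >= 1L)
  selected <- proteinIds(matrix)
  history <- vector("list", T)
  for (t in seq_len(T)) {
    comm <- detectCommunities(matrix, selected, resolution = resolution,
                              seed = seed + t - 1L, k = k)
    history[[t]] <- new("CommunityHistory", iteration = t,
                        selected_proteins = selected, community_of = comm)
    nxt <- selectDifferentialProteins(raw, comm, alpha = alpha,
                                      min_observed = min_observed)
    if (!length(nxt)) {
      warning(sprintf("selection emptied the protein subset at iteration %d; stopping early",
                      t))
      return(history[seq_len(t)])
    }
    selected <- as.character(nxt)
  }
  history
}

#' Cluster participants by their pattern of community assignments
#'
#' Community labels are arbitrary per iteration, so only co-membership is
#' used: the co-assignment similarity of two participants is the fraction
#' of iterations in which they fall in the same community. Participants are
#' clustered as the connected components of the graph linking pairs with
#' similarity at or above `pattern_threshold` (default 0.9; 1.0 recovers
#' exact pattern matching). Components smaller than `min_cluster_size` are
#' labeled noise.
#'
#' @param history list of [CommunityHistory-class] from [iterateDircod()].
#' @param min_cluster_size components below this size become noise.
#' @param pattern_threshold co-assignment fraction linking a pair.
#' @return A [ClusterAssignment-class] with method `"DIRCOD"`.
#' @export
assignByPattern <- function(history, min_cluster_size = 100L,
                            pattern_threshold = 0.9) {
  stopifnot(length(history) >= 1L)
  pid <- names(history[[1L]]@community_of)
  n <- length(pid)
  S <- matrix(0L, n, n)
  for (h in history) {
    lab <- h@community_of[pid]
    S <- S + outer(lab, lab, "==")
  }
  A <- S / length(history) >= pattern_threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_cluster_size)
  lab <- rep(NA_character_, n)
  for (j in seq_along(keep)) lab[comp == keep[j]] <- sprintf("B%d", j)
  names(lab) <- pid
  ClusterAssignment("DIRCOD", lab, provenance = list(
    params = list(iterations = length(history),
                  pattern_threshold = pattern_threshold,
                  min_cluster_size = min_cluster_size),
    component_sizes = sizes))
}

#' DIRCOD clustering: impute, iterate communities, assign by pattern
#'
#' End-to-end DIRCOD path: [imputeKnn()] completes the matrix,
#' [iterateDircod()] alternates Leiden community detection with
#' raw-data-validated differential-protein selection for `T` iterations,
#' and [assignByPattern()] groups participants with similar community
#' assignment patterns.
#'
#' @param matrix the raw [ProteinMatrix-class] (missing values allowed).
#' @param T iterations, default 20.
#' @param n_neighbors imputation neighbourhood, default 15.
#' @param alpha selection significance level.
#' @param pattern_threshold,min_cluster_size see [assignByPattern()].
#' @param resolution,k see [detectCommunities()].
#' @param seed integer seed.
#' @return A [ClusterAssignment-class] with method `"DIRCOD"`; the
#'   iteration history is attached as provenance element `history`.
#' @export
dircodCluster <- function(matrix, T = 20L, n_neighbors = 15L, alpha = 0.05,
                          pattern_threshold = 0.9, min_cluster_size = 100L,
                          resolution = 1, k = 15L, seed = 1L) {
  imputed <- imputeKnn(matrix, n_neighbors = n_neighbors)
  history <- iterateDircod(imputed, matrix, T = T, seed = seed,
                           alpha = alpha, resolution = resolution, k = k)
  out <- assignByPattern(history, min_cluster_size = min_cluster_size,
                         pattern_threshold = pattern_threshold)
  out@provenance$history <- history
  out@provenance$params <- c(out@provenance$params,
                             list(n_neighbors = n_neighbors, alpha = alpha,
                                  seed = seed))
  out
}
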