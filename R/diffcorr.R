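#' Keep candidates strongly correlated with another candidate
#'
#' Screens a candidate protein set (typically a [commonSignature()] with
#' tolerance at most 1) before the differential-coregulation analysis: a
#' candidate is kept when the magnitude of its Pearson correlation with at
#' least one other candidate reaches `r_keep` (default 0.8), computed on
#' pairwise-complete observations within the stated population.
#'
#' @param matrix a [ProteinMatrix-class].
#' @param candidates candidate protein ids (>= 2).
#' @param population participant ids over which to compute the screen
#'   (default: all).
#' @param r_keep magnitude threshold, default 0.8.
#' @return character vector of retained proteins.
#' @export
prefilterProteins <- function(matrix, candidates,
                              population = participantIds(matrix),
                              r_keep = 0.8) {
  if (length(candidates) < 2L) stop("need at least 2 candidate proteins")
  X <- npx(matrix)[intersect(population, participantIds(matrix)),
                   candidates, drop = FALSE]
  cm <- abs(suppressWarnings(stats::cor(X, use = "pairwise.complete.obs")))
  diag(cm) <- NA
  keep <- apply(cm, 2L, function(r) any(r >= r_keep, na.rm = TRUE))
  candidates[keep]
}

#' Within-group vs rest-of-population differential correlation
#'
#' Computes two Pearson correlation matrices on pairwise-complete,
#' non-imputed observations — `A` inside the participant group, `B` over
#' all other participants — and their difference `delta = A - B`. A delta
#' entry near +0.7 marks a protein pair far more tightly coregulated
#' inside the group than outside; negative entries mark a loss of
#' coregulation. Pairs with fewer than `min_pairs` complete observations
#' on either side are masked (`NA`), as are pairs involving a protein that
#' is constant on a side. The Bonferroni critical correlation
#' ([criticalCorrelation()]) is reported for each side at the median
#' per-pair sample size over all tested pairs.
#'
#' @param matrix a [ProteinMatrix-class].
#' @param group participant ids of the cluster group (strict subset).
#' @param proteins proteins entering the analysis (>= 2).
#' @param min_pairs minimum complete observations per pair per side,
#'   default 30.
#' @param alpha family-wise level for the critical correlations.
#' @return A [DiffCorrResult-class].
#' @export
differentialCorrelation <- function(matrix, group, proteins,
                                    min_pairs = 30L, alpha = 0.05) {
  stopifnot(length(proteins) >= 2L)
  pid <- participantIds(matrix)
  group <- intersect(group, pid)
  if (!length(group) || length(group) == length(pid))
    stop("group must be a nonempty strict subset of participants")
  X <- npx(matrix)
  side <- function(rows) {
    M <- X[rows, proteins, drop = FALSE]
    obs <- !is.na(M)
    npair <- crossprod(obs * 1)
    cm <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
    sds <- apply(M, 2L, stats::sd, na.rm = TRUE)
    cm[npair < min_pairs] <- NA
    const <- which(is.na(sds) | sds == 0)
    if (length(const)) {
      cm[const, ] <- NA
      cm[, const] <- NA
      warning(sprintf("constant protein on one side: %s",
                      paste(proteins[const], collapse = ", ")))
    }
    diag(cm) <- 1
    list(cm = cm, n = npair)
  }
  A <- side(group)
  B <- side(setdiff(pid, group))
  delta <- A$cm - B$cm
  diag(delta) <- 0
  m <- length(proteins) * (length(proteins) - 1L) / 2L
  up <- upper.tri(A$n)
  crit <- function(np) {
    med <- stats::median(np[up])
    if (is.na(med) || med < 4) NA_real_
    else criticalCorrelation(med, alpha = alpha, m_tests = m)
  }
  new("DiffCorrResult", proteins = as.character(proteins), A = A$cm,
      B = B$cm, delta = delta, n_in = A$n, n_out = B$n,
      critical_r_in = crit(A$n), critical_r_out = crit(B$n))
}

#' Bonferroni critical correlation for a given sample size
#'
#' The smallest |r| whose two-sided p-value under the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom is
#' at most `alpha / m_tests`. Inverting the t quantile gives
#' `r* = t* / sqrt(n - 2 + t*^2)` with `t* = qt(1 - alpha / (2 m), n - 2)`.
#' The threshold strictly increases in `m_tests` and strictly decreases in
#' `n`.
#'
#' @param n sample size (>= 4).
#' @param alpha family-wise level.
#' @param m_tests number of pairwise tests in the Bonferroni family.
#' @return the critical |r| in (0, 1).
#' @examples
#' criticalCorrelation(100, 0.05, 1)   # ~= 0.197
#' @export
criticalCorrelation <- function(n, alpha = 0.05, m_tests = 1L) {
  stopifnot(n >= 4, m_tests >= 1)
  p <- alpha / m_tests
  if (p <= 0 || p >= 1)
    stop("alpha / m_tests must lie strictly between 0 and 1")
  tstar <- stats::qt(1 - p / 2, df = n - 2)
  tstar / sqrt(n - 2 + tstar^2)
}
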