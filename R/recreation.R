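#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio `(a d) / (b c)` of a 2x2 exposure-by-disease
#' table with a Woolf (log-OR normal approximation) confidence interval.
#' When any cell is zero the Haldane-Anscombe correction adds 0.5 to all
#' four cells for both the estimate and the interval, and the result is
#' flagged `corrected`.
#'
#' @param a,b,c,d cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases (vectorized).
#' @param conf_level confidence level, default 0.95.
#' @return data.frame with columns `odds_ratio`, `ci_low`, `ci_high`,
#'   `corrected`.
#' @examples
#' oddsRatioWoolf(10, 490, 10, 4490)   # OR = 9.163
#' @export
oddsRatioWoolf <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(all(c(a, b, c, d) >= 0))
  corrected <- a == 0 | b == 0 | c == 0 | d == 0
  a2 <- a + 0.5 * corrected
  b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected
  d2 <- d + 0.5 * corrected
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(odds_ratio = or, ci_low = exp(log(or) - z * se),
             ci_high = exp(log(or) + z * se), corrected = corrected)
}

#' Per-protein thresholds of a signature at a percentile of the pooled cluster
#'
#' The percentile is evaluated on each signature protein's observed values
#' inside the pooled cluster of interest (type-7 linear interpolation); the
#' resulting value is the cutoff later applied to the whole population:
#' selection keeps values at or above the threshold for `high` proteins and
#' at or below it for `low` proteins.
#'
#' @param matrix a [ProteinMatrix-class].
#' @param pooled_cluster participant ids of the regrouped clusters of
#'   interest (nonempty).
#' @param signature data.frame with columns `protein_id` and `direction`
#'   (`"high"`/`"low"`).
#' @param percentile value in \[0, 100\].
#' @return named numeric vector, protein -> threshold.
#' @export
signatureThresholds <- function(matrix, pooled_cluster, signature,
                                percentile) {
  stopifnot(length(pooled_cluster) >= 1L, percentile >= 0,
            percentile <= 100)
  X <- npx(matrix)[intersect(pooled_cluster, participantIds(matrix)),
                   signature$protein_id, drop = FALSE]
  thr <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    v <- v[!is.na(v)]
    if (!length(v))
      stop(sprintf("protein '%s' unobserved in the pooled cluster",
                   signature$protein_id[j]))
    stats::quantile(v, percentile / 100, names = FALSE, type = 7)
  }, 0)
  names(thr) <- signature$protein_id
  thr
}

# Selection at one percentile: participants satisfying all (or, in
# disjunctive mode, any) signature thresholds; participants missing a
# signature value never satisfy that protein's constraint.
.selectAtPercentile <- function(X, thresholds, signature,
                                conjunctive = TRUE) {
  ok <- matrix(FALSE, nrow(X), nrow(signature))
  for (j in seq_len(nrow(signature))) {
    v <- X[, signature$protein_id[j]]
    ok[, j] <- !is.na(v) &
      (if (signature$direction[j] == "high") v >= thresholds[j]
       else v <= thresholds[j])
  }
  if (conjunctive) rownames(X)[rowSums(ok) == nrow(signature)]
  else rownames(X)[rowSums(ok) > 0L]
}

#' Recreate a disease-enriched subpopulation by percentile slicing
#'
#' For each percentile of the grid, thresholds are defined on the pooled
#' cluster of interest ([signatureThresholds()]) and applied to the whole
#' population: a participant is selected when it satisfies every signature
#' constraint simultaneously (conjunctive filtering; a disjunctive mode is
#' available). Participants missing a signature protein's value are counted
#' as unselected (a flag drops them from the table entirely). At each
#' percentile the function reports the 2x2 selected-by-disease table and
#' the odds ratio with Woolf 95% CI ([oddsRatioWoolf()]); a percentile
#' selecting nobody yields a flagged, undefined odds ratio.
#'
#' @param matrix a [ProteinMatrix-class].
#' @param phenotypes a [PhenotypeTable-class].
#' @param pooled_cluster participants of the regrouped clusters of
#'   interest.
#' @param signature data.frame with `protein_id`, `direction`.
#' @param disease_code 3-character ICD-10 code.
#' @param percentile_grid default `seq(5, 95, by = 5)`.
#' @param conjunctive AND (default) vs OR filtering across proteins.
#' @param drop_missing drop participants with missing signature values from
#'   the 2x2 table instead of counting them unselected.
#' @return A [RecreationCurve-class] (without leave-one-out curves; see
#'   [leaveOneOut()]).
#' @export
recreate <- function(matrix, phenotypes, pooled_cluster, signature,
                     disease_code, percentile_grid = seq(5, 95, by = 5),
                     conjunctive = TRUE, drop_missing = FALSE) {
  disease_code <- normalizeIcd10(disease_code)
  common <- intersect(participantIds(matrix), participantIds(phenotypes))
  X <- npx(matrix)[common, , drop = FALSE]
  sick <- hasCode(phenotypes, disease_code)[common]
  keep <- rep(TRUE, length(common))
  if (drop_missing)
    keep <- !apply(is.na(X[, signature$protein_id, drop = FALSE]), 1L, any)
  rows <- lapply(percentile_grid, function(pct) {
    thr <- signatureThresholds(matrix, pooled_cluster, signature, pct)
    sel <- common %in% .selectAtPercentile(X, thr, signature, conjunctive)
    a <- sum(sel & sick & keep)
    b <- sum(sel & !sick & keep)
    cc <- sum(!sel & sick & keep)
    dd <- sum(!sel & !sick & keep)
    if (a + b == 0L)
      data.frame(percentile = pct, selected_n = 0L, cases_in = 0L,
                 cases_out = cc, odds_ratio = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, flagged = TRUE)
    else {
      or <- oddsRatioWoolf(a, b, cc, dd)
      data.frame(percentile = pct, selected_n = a + b, cases_in = a,
                 cases_out = cc, odds_ratio = or$odds_ratio,
                 ci_low = or$ci_low, ci_high = or$ci_high,
                 flagged = or$corrected)
    }
  })
  new("RecreationCurve", disease_code = disease_code,
      signature = as.data.frame(signature), curve = do.call(rbind, rows),
      loo = list())
}

#' Leave-one-out contribution of each signature protein
#'
#' Reruns [recreate()] with each signature protein omitted in turn and
#' reports, per omitted protein and percentile, the odds ratio of the
#' reduced signature and its difference (`delta_or`) from the full
#' signature's. Omitting a protein can only enlarge the selected set
#' (fewer constraints), so a large |delta| marks a protein that carries
#' the disease association.
#'
#' @inheritParams recreate
#' @return A [RecreationCurve-class] whose `loo` slot maps each omitted
#'   protein to its per-percentile curve with `delta_or`.
#' @export
leaveOneOut <- function(matrix, phenotypes, pooled_cluster, signature,
                        disease_code, percentile_grid = seq(5, 95, by = 5),
                        conjunctive = TRUE, drop_missing = FALSE) {
  stopifnot(nrow(signature) >= 2L)
  full <- recreate(matrix, phenotypes, pooled_cluster, signature,
                   disease_code, percentile_grid, conjunctive,
                   drop_missing)
  loo <- list()
  for (j in seq_len(nrow(signature))) {
    part <- recreate(matrix, phenotypes, pooled_cluster,
                     signature[-j, , drop = FALSE], disease_code,
                     percentile_grid, conjunctive, drop_missing)
    tab <- curveTable(part)
    tab$delta_or <- tab$odds_ratio - curveTable(full)$odds_ratio
    loo[[signature$protein_id[j]]] <- tab
  }
  new("RecreationCurve", disease_code = full@disease_code,
      signature = as.data.frame(signature), curve = curveTable(full),
      loo = loo)
}
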