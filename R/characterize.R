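#' ICD-10 disease enrichment per cluster
#'
#' For every (cluster, code) pair, a 2x2 table of cluster membership by
#' diagnosis over the joined participant universe (noise participants
#' count on the "outside" of every cluster and never form their own
#' cluster). P-values come from Fisher's exact test on the raw counts;
#' p-values are Bonferroni-corrected over all pairs tested in the call
#' (one family per analysis). The odds ratio is the cross-product
#' `(a d) / (b c)` with Woolf CI, Haldane-Anscombe corrected when a cell
#' is zero ([oddsRatioWoolf()]); the exact test always uses the raw
#' counts. With `stratify_sex = TRUE` every (cluster, code) pair is tested
#' within each sex as well, all tests in one Bonferroni family.
#'
#' @param clusters a [ClusterAssignment-class].
#' @param phenotypes a [PhenotypeTable-class].
#' @param codes ICD-10 codes to test (normalized to 3 characters).
#' @param stratify_sex also test within each sex level.
#' @return A [S4Vectors::DataFrame], one row per test: cluster, code,
#'   stratum, the four cells, odds ratio with CI, raw and
#'   Bonferroni-corrected p-values, and a flag for zero-cell tables or
#'   codes absent from the phenotypes.
#' @export
diseaseEnrichment <- function(clusters, phenotypes, codes,
                              stratify_sex = FALSE) {
  codes <- normalizeIcd10(codes)
  labs <- clusterLabels(clusters)
  common <- intersect(names(labs), participantIds(phenotypes))
  labs <- labs[common]
  ph <- phenotypes[common]
  strata <- list(all = rep(TRUE, length(common)))
  if (stratify_sex)
    for (s in sort(unique(sexes(ph))))
      strata[[s]] <- sexes(ph) == s
  cl_ids <- sort(unique(labs[!is.na(labs)]))
  rows <- list()
  for (st in names(strata)) {
    in_st <- strata[[st]]
    for (code in codes) {
      sick <- hasCode(ph, code) & in_st
      absent <- !any(sick)
      for (cl in cl_ids) {
        inside <- !is.na(labs) & labs == cl & in_st
        a <- sum(inside & sick)
        b <- sum(inside & !sick & in_st)
        cc <- sum(!inside & sick & in_st)
        dd <- sum(!inside & !sick & in_st)
        p <- stats::fisher.test(matrix(c(a, b, cc, dd), 2L))$p.value
        or <- oddsRatioWoolf(a, b, cc, dd)
        rows[[length(rows) + 1L]] <-
          DataFrame(cluster_id = cl, disease_code = code, stratum = st,
                    a = a, b = b, c = cc, d = dd,
                    odds_ratio = or$odds_ratio, ci_low = or$ci_low,
                    ci_high = or$ci_high, p_raw = p,
                    flagged = or$corrected | absent)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Age and sex contrasts of each cluster against the rest
#'
#' Per cluster: a two-sample Mann-Whitney (Wilcoxon rank-sum) test of age
#' against all other participants, a chi-square test of sex composition,
#' and the fraction of the minority sex (clusters where one sex falls
#' below 40% are the ones worth flagging). Each test family (age, sex) is
#' Bonferroni-corrected over the clusters tested. Clusters smaller than 10
#' are skipped with a warning.
#'
#' @param clusters a [ClusterAssignment-class].
#' @param phenotypes a [PhenotypeTable-class].
#' @return A [S4Vectors::DataFrame], one row per cluster: size, median age
#'   in/out, age p-values, sex composition, minority-sex fraction and sex
#'   p-values.
#' @export
demographicContrast <- function(clusters, phenotypes) {
  labs <- clusterLabels(clusters)
  common <- intersect(names(labs), participantIds(phenotypes))
  labs <- labs[common]
  ph <- phenotypes[common]
  age <- ages(ph)
  sex <- sexes(ph)
  cl_ids <- sort(unique(labs[!is.na(labs)]))
  rows <- list()
  for (cl in cl_ids) {
    inside <- !is.na(labs) & labs == cl
    if (sum(inside) < 10L) {
      warning(sprintf("cluster %s has fewer than 10 participants; skipped",
                      cl))
      next
    }
    p_age <- stats::wilcox.test(age[inside], age[!inside])$p.value
    tab <- table(factor(sex[inside], levels = sort(unique(sex))),
                 dnn = NULL)
    tab_out <- table(factor(sex[!inside], levels = sort(unique(sex))),
                     dnn = NULL)
    p_sex <- suppressWarnings(
      stats::chisq.test(rbind(as.vector(tab), as.vector(tab_out)))$p.value)
    rows[[length(rows) + 1L]] <-
      DataFrame(cluster_id = cl, size = sum(inside),
                median_age_in = stats::median(age[inside]),
                median_age_out = stats::median(age[!inside]),
                p_age_raw = p_age,
                minority_sex_fraction = min(tab) / sum(tab),
                p_sex_raw = p_sex)
  }
  if (!length(rows)) stop("no cluster large enough to characterize")
  out <- do.call(rbind, rows)
  out$p_age_bonferroni <- pmin(1, out$p_age_raw * nrow(out))
  out$p_sex_bonferroni <- pmin(1, out$p_sex_raw * nrow(out))
  out
}
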