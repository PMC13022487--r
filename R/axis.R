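#' Fit the first principal axis of a signature on a cluster group
#'
#' Collapses the signature proteins to a single coordinate: the first
#' principal axis of the fitting population's (centered, by default
#' standardized) covariance. Participants of the pooled cluster with any
#' missing signature value are excluded from the fit (a message reports
#' how many). The axis sign is fixed so the first signature protein's
#' loading is nonnegative, making results reproducible.
#'
#' @param matrix a [ProteinMatrix-class].
#' @param pooled_cluster participants of the clusters of interest.
#' @param proteins signature protein ids (length >= 1).
#' @param standardize scale each protein to unit variance on the fitting
#'   population before the eigendecomposition (default `TRUE`; proteins may
#'   sit on different scales).
#' @return An [AxisTransform-class].
#' @export
fitAxis <- function(matrix, pooled_cluster, proteins, standardize = TRUE) {
  stopifnot(length(proteins) >= 1L)
  rows <- intersect(pooled_cluster, participantIds(matrix))
  X <- npx(matrix)[rows, proteins, drop = FALSE]
  ok <- !apply(is.na(X), 1L, any)
  if (sum(!ok))
    message(sprintf("fitAxis: excluded %d of %d participants with missing signature values",
                    sum(!ok), length(ok)))
  X <- X[ok, , drop = FALSE]
  if (nrow(X) < length(proteins) + 1L)
    warning(sprintf("only %d fitting participants for %d proteins",
                    nrow(X), length(proteins)))
  ctr <- colMeans(X)
  scl <- if (standardize) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  if (any(scl == 0))
    stop(sprintf("zero-variance protein in fitting population: %s",
                 proteins[which(scl == 0)[1L]]))
  Xs <- scale(X, center = ctr, scale = scl)
  v <- if (ncol(Xs) == 1L) 1
       else eigen(stats::cov(Xs), symmetric = TRUE)$vectors[, 1L]
  if (v[1L] < 0) v <- -v
  new("AxisTransform", proteins = as.character(proteins),
      loadings = as.numeric(v), center = as.numeric(ctr),
      scale = as.numeric(scl), fitted_on = rownames(X))
}

#' Axis coordinates of participants under a fitted transform
#'
#' Applies the centering, scaling and loadings learned by [fitAxis()] to
#' any set of participants; rows with missing signature values are
#' dropped. Applying the transform to the fitting population reproduces
#' the fitting-time coordinates exactly.
#'
#' @param transform an [AxisTransform-class].
#' @param matrix a [ProteinMatrix-class].
#' @param participants participant ids (default: all in `matrix`).
#' @return named numeric vector of axis coordinates.
#' @export
axisScores <- function(transform, matrix,
                       participants = participantIds(matrix)) {
  rows <- intersect(participants, participantIds(matrix))
  X <- npx(matrix)[rows, transform@proteins, drop = FALSE]
  ok <- !apply(is.na(X), 1L, any)
  X <- X[ok, , drop = FALSE]
  sc <- as.vector(scale(X, center = transform@center,
                        scale = transform@scale) %*% transform@loadings)
  names(sc) <- rownames(X)
  sc
}

#' Bin a population along the axis and relate position to prevalence
#'
#' Applies the transform fitted on the cluster group to a population, cuts
#' the participants into `n_bins` equal-size groups by axis rank (ties
#' broken by participant id for determinism; bin sizes differ by at most
#' one), and computes each bin's disease prevalence. An ordinary
#' least-squares line of prevalence on the bin's mean axis coordinate is
#' fitted, excluding the lowest and highest bins when
#' `exclude_extremes = TRUE` (the extreme bins are noisy). The prevalence
#' in the fitting clusters and in the binned population are reported as
#' reference levels.
#'
#' @param transform an [AxisTransform-class] from [fitAxis()].
#' @param matrix a [ProteinMatrix-class].
#' @param population participant ids to bin (default: all).
#' @param phenotypes a [PhenotypeTable-class].
#' @param disease_code 3-character ICD-10 code.
#' @param n_bins number of equal-size bins, default 20 (>= 3 when extremes
#'   are excluded).
#' @param exclude_extremes drop the first and last bins from the
#'   regression, default `TRUE`.
#' @return An [AxisBinning-class]. The weighted mean of per-bin prevalences
#'   (weights = bin sizes) equals the binned population's prevalence
#'   exactly.
#' @export
binPrevalence <- function(transform, matrix,
                          population = participantIds(matrix), phenotypes,
                          disease_code, n_bins = 20L,
                          exclude_extremes = TRUE) {
  disease_code <- normalizeIcd10(disease_code)
  if (exclude_extremes && n_bins < 3L)
    stop("need at least 3 bins when excluding the extremes")
  pop <- intersect(population, participantIds(phenotypes))
  sc <- axisScores(transform, matrix, pop)
  if (n_bins > length(sc)) stop("more bins than participants")
  ord <- order(sc, names(sc))
  bin <- rep(seq_len(n_bins),
             times = diff(round(seq(0, length(sc),
                                    length.out = n_bins + 1L))))
  sick <- hasCode(phenotypes, disease_code)[names(sc)[ord]]
  bins <- data.frame(bin = seq_len(n_bins),
                     size = as.vector(table(bin)),
                     cases = as.vector(tapply(sick, bin, sum)),
                     midpoint = as.vector(tapply(sc[ord], bin, mean)))
  bins$prevalence <- bins$cases / bins$size
  use <- if (exclude_extremes) 2L:(n_bins - 1L) else seq_len(n_bins)
  reg <- if (length(use) >= 3L) {
    fit <- stats::lm(prevalence ~ midpoint, data = bins[use, ])
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]), bins_used = use,
         ci_slope = unname(suppressWarnings(stats::confint(fit))[2L, ]))
  } else {
    # a line through <3 points carries no uncertainty worth reporting
    fit <- stats::lm(prevalence ~ midpoint, data = bins[use, , drop = FALSE])
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]), bins_used = use,
         ci_slope = c(NA_real_, NA_real_))
  }
  fit_sick <- hasCode(phenotypes, disease_code)[
    intersect(transform@fitted_on, participantIds(phenotypes))]
  new("AxisBinning", transform = transform, bins = bins,
      regression = reg,
      prevalence_fit = mean(fit_sick),
      prevalence_population = mean(sick))
}
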