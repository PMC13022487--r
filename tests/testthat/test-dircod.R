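test_that("kNN imputation preserves observed values and beats column means", {
  d <- blobMatrix(n_per = 50, K = 2, p = 10, shift = 3, seed = 1)
  expect_identical(npx(imputeKnn(d$pm)), npx(d$pm))   # complete: identity

  # constant neighborhood: the imputed value is that constant
  X <- matrix(rnorm(40 * 3), 40, 3,
              dimnames = list(sprintf("P%02d", 1:40), c("a", "b", "c")))
  X[, "c"] <- 2.0
  X[1, "c"] <- NA
  imp <- imputeKnn(ProteinMatrix(X), n_neighbors = 15)
  expect_equal(npx(imp)[1, "c"], 2.0)
  expect_identical(npx(imp)[-1, ], X[-1, ])

  # rank-1 + noise: kNN recovers structure better than column means
  set.seed(10)
  n <- 500; p <- 50
  z <- rnorm(n)
  w <- rnorm(p)
  truthM <- outer(z, w)
  X <- truthM + matrix(rnorm(n * p, sd = 0.5), n, p)
  dimnames(X) <- list(sprintf("P%03d", 1:n), sprintf("Q%02d", 1:p))
  holes <- sample(length(X), round(0.1 * length(X)))
  Xm <- X
  Xm[holes] <- NA
  imp <- npx(imputeKnn(ProteinMatrix(Xm)))
  rmse_knn <- sqrt(mean((imp[holes] - X[holes])^2))
  mu <- colMeans(Xm, na.rm = TRUE)
  colfill <- matrix(mu, n, p, byrow = TRUE)
  rmse_col <- sqrt(mean((colfill[holes] - X[holes])^2))
  expect_lt(rmse_knn, rmse_col)

  Xbad <- Xm
  Xbad[1:495, 1] <- NA                       # protein observed < n_neighbors
  expect_error(imputeKnn(ProteinMatrix(Xbad)), "Q01")
})

test_that("Leiden communities recover separated blobs deterministically", {
  d <- blobMatrix(n_per = 300, K = 2, p = 20, shift = 6, seed = 2)
  cm <- detectCommunities(d$pm, seed = 1)
  expect_identical(sort(names(cm)), sort(participantIds(d$pm)))
  expect_identical(length(unique(cm)), 2L)
  expect_gte(ariOf(cm, d$lab[names(cm)]), 0.95)
  expect_identical(detectCommunities(d$pm, seed = 1), cm)

  expect_error(detectCommunities(d$pm, selected = character()), "empty")
  tiny <- ProteinMatrix(matrix(rnorm(5 * 4), 5, 4,
                               dimnames = list(paste0("P", 1:5),
                                               paste0("Q", 1:4))))
  expect_warning(detectCommunities(tiny, seed = 1), "reducing k")
})

test_that("differential selection finds shifts, respects the null and the mask", {
  set.seed(5)
  n <- 1500; p <- 30
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("P%04d", 1:n), sprintf("Q%02d", 1:p)))
  comm <- structure(rep(c(1L, 2L, 3L), each = 500), names = rownames(X))
  X[comm == 1, 1] <- X[comm == 1, 1] + 3     # planted shift in community 1
  pm <- ProteinMatrix(X)
  sel <- selectDifferentialProteins(pm, comm)
  expect_true("Q01" %in% sel)
  expect_lte(length(sel), 3)                 # essentially only the shift

  # permuted labels: a true null, family-wise error at most ~alpha
  set.seed(6)
  false_hits <- vapply(1:40, function(r) {
    perm <- structure(sample(comm), names = names(comm))
    length(selectDifferentialProteins(pm, perm)) > 0
  }, TRUE)
  expect_lte(mean(false_hits), 0.1)

  # selection reads only raw observed values: masking the shifted cells
  # down to fewer than min_observed makes the pair skipped, not imputed
  Xm <- X
  Xm[which(comm == 1)[1:490], 1] <- NA
  sel_m <- selectDifferentialProteins(ProteinMatrix(Xm), comm)
  expect_false("Q01" %in% sel_m)
  expect_gt(attr(sel_m, "skipped"), 0)
})

test_that("the iteration contract holds: subsets chain and seeds reproduce", {
  d <- blobMatrix(n_per = 250, K = 3, p = 30, shift = 3, seed = 3)
  imp <- imputeKnn(d$pm)
  h1 <- iterateDircod(imp, d$pm, T = 1, seed = 1)
  expect_length(h1, 1)
  expect_identical(h1[[1]]@selected_proteins, proteinIds(d$pm))

  h <- iterateDircod(imp, d$pm, T = 4, seed = 1)
  h2 <- iterateDircod(imp, d$pm, T = 4, seed = 1)
  for (t in 1:4) {
    expect_identical(h[[t]]@community_of, h2[[t]]@community_of)
    expect_true(all(h[[t]]@selected_proteins %in% proteinIds(d$pm)))
  }
  # iteration t+1 uses exactly the proteins selected from iteration t
  for (t in 2:4) {
    sel_prev <- selectDifferentialProteins(d$pm, h[[t - 1]]@community_of)
    expect_identical(h[[t]]@selected_proteins, as.character(sel_prev))
  }
})

test_that("pattern assignment groups by co-assignment fraction", {
  mkHist <- function(mat) {
    lapply(seq_len(ncol(mat)), function(t)
      new("CommunityHistory", iteration = t,
          selected_proteins = "Q1",
          community_of = structure(mat[, t],
                                   names = rownames(mat))))
  }
  # 3 stable planted groups over 20 iterations, with label churn per iteration
  set.seed(4)
  n <- 90
  grp <- rep(1:3, each = 30)
  M <- vapply(1:20, function(t) {
    perm <- sample(1:3)
    perm[grp]
  }, integer(n))
  rownames(M) <- sprintf("P%03d", 1:n)
  ca <- assignByPattern(mkHist(M), min_cluster_size = 10)
  expect_length(unique(na.omit(clusterLabels(ca))), 3)
  expect_gte(ariVsTruth(ca, structure(grp, names = rownames(M))), 0.99)

  # two participants never co-assigned end up in different clusters
  M2 <- matrix(c(1L, 2L), nrow = 2, ncol = 5,
               dimnames = list(c("Pa", "Pb"), NULL))
  ca2 <- assignByPattern(mkHist(M2), min_cluster_size = 1)
  labs <- clusterLabels(ca2)
  expect_false(labs["Pa"] == labs["Pb"])
})

test_that("DIRCOD recovers planted clusters under random missingness", {
  cfg <- SyntheticConfig(n_participants = 1500, n_proteins = 60,
                         n_clusters = 3,
                         cluster_proportions = rep(1 / 3, 3),
                         shift_proteins_per_cluster = 15,
                         shift_magnitude = 3, missing_random_rate = 0.1,
                         seed = 2)
  co <- generateCohort(cfg)
  dc <- dircodCluster(co$matrix, T = 8)
  expect_gte(ariVsTruth(dc, co$truth), 0.8)
  hist <- dc@provenance$history
  expect_identical(hist[[1]]@selected_proteins, proteinIds(co$matrix))
})
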