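mkEmbedding <- function(coords, id = "t") {
  new("EmbeddingResult", subdataset_id = id, seed = 1L,
      coords = `rownames<-`(coords, sprintf("P%04d", seq_len(nrow(coords)))),
      stability = list())
}

test_that("density clustering separates point masses and drops sparse scatter", {
  set.seed(1)
  co <- rbind(matrix(rnorm(400, sd = 0.02), 200, 2),
              matrix(rnorm(400, sd = 0.02), 200, 2) + 10)
  ca <- densityCluster(mkEmbedding(co), eps = 0.1, min_samples = 10,
                       min_cluster_size = 100)
  expect_length(unique(na.omit(clusterLabels(ca))), 2)
  expect_identical(sum(is.na(clusterLabels(ca))), 0L)

  sparse <- matrix(runif(100, 0, 100), 50, 2)
  ca2 <- densityCluster(mkEmbedding(sparse), eps = 0.1, min_samples = 10)
  expect_true(all(is.na(clusterLabels(ca2))))

  # size filter: an 80-point mass is relabeled noise at min size 100
  small <- matrix(rnorm(160, sd = 0.02), 80, 2)
  ca3 <- densityCluster(mkEmbedding(small), eps = 0.1, min_samples = 10,
                        min_cluster_size = 100)
  expect_true(all(is.na(clusterLabels(ca3))))
  ca4 <- densityCluster(mkEmbedding(small), eps = 0.1, min_samples = 10,
                        min_cluster_size = 50)
  expect_length(unique(na.omit(clusterLabels(ca4))), 1)

  expect_error(densityCluster(mkEmbedding(small), eps = 0), "positive")
})

test_that("grid-based DBSCAN agrees with the O(n^2) reference", {
  set.seed(42)
  for (r in 1:10) {
    co <- matrix(rnorm(300), 150, 2) * sample(c(0.3, 1, 2), 1)
    eps <- runif(1, 0.1, 0.8)
    mp <- sample(3:12, 1)
    mine <- proteoseg:::.dbscan(co, eps, mp)
    ref <- dbscanReference(co, eps, mp)
    expect_identical(mine > 0, ref > 0)       # same core/noise split
    expect_gt(ariOf(mine, ref), 0.999)        # same partition
  }
})

test_that("embedding is deterministic and validates its input", {
  d <- blobMatrix(n_per = 100, K = 2, p = 10, shift = 6, seed = 2)
  e1 <- embed2d(d$pm, seed = 5)
  e2 <- embed2d(d$pm, seed = 5)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))

  tiny <- ProteinMatrix(matrix(rnorm(50), 10, 5,
                               dimnames = list(paste0("P", 1:10),
                                               paste0("Q", 1:5))))
  expect_error(embed2d(tiny, n_neighbors = 15), "fewer than")
  m <- npx(d$pm)
  m[1, 1] <- NA
  expect_error(embed2d(ProteinMatrix(m)), "complete")
})

test_that("two well-separated blobs are recovered across audit seeds", {
  d <- blobMatrix(n_per = 200, K = 2, p = 20, shift = 6, seed = 3)
  hits <- 0
  for (s in 1:10) {
    emb <- embed2d(d$pm, seed = s)
    ca <- densityCluster(emb, eps = 0.5, min_samples = 10,
                         min_cluster_size = 100)
    labs <- clusterLabels(ca)
    if (length(unique(na.omit(labs))) == 2 &&
        ariVsTruth(ca, d$lab) > 0.95) hits <- hits + 1
  }
  expect_gte(hits, 9)

  emb <- embed2d(d$pm, seed = 1, n_seeds_audit = 4, eps = 0.5)
  st <- stabilityReport(emb)
  expect_length(st$pairwise_ari, choose(4, 2))
  expect_gt(st$median_ari, 0.9)
})

test_that("the merge rule follows its overlap score", {
  mkA <- function(members, universe, label = "C1", id = 1) {
    labs <- rep(NA_character_, length(universe))
    names(labs) <- universe
    labs[members] <- label
    ClusterAssignment("DIRAM", labs)
  }
  uni <- sprintf("P%05d", 1:10000)
  c1 <- uni[1:100]
  # identical clusters: score (100 - 1)/100 = 0.99 -> merged
  m <- mergeClusters(list(mkA(c1, uni), mkA(c1, uni, "D1")), 0.4)
  expect_length(unique(na.omit(clusterLabels(m))), 1)

  # |C1|=|C2|=100, O=80, N=1000: (80 - 10)/100 = 0.70 -> merged
  uni2 <- sprintf("P%05d", 1:1000)
  a1 <- uni2[1:100]
  a2 <- uni2[21:120]
  m2 <- mergeClusters(list(mkA(a1, uni2), mkA(a2, uni2, "D1")), 0.4)
  expect_length(unique(na.omit(clusterLabels(m2))), 1)
  expect_setequal(clusterMembers(m2, "M1"), union(a1, a2))
  # at a margin above the score they stay apart
  m3 <- mergeClusters(list(mkA(a1, uni2), mkA(a2, uni2, "D1")), 0.75)
  expect_length(unique(na.omit(clusterLabels(m3))), 2)

  # independent random clusters: score ~ 0 -> rarely anywhere near 0.4
  set.seed(7)
  not_merged <- 0
  for (r in 1:40) {
    b1 <- sample(uni2, 100)
    b2 <- sample(uni2, 100)
    mr <- mergeClusters(list(mkA(b1, uni2), mkA(b2, uni2, "D1")), 0.1)
    if (length(unique(na.omit(clusterLabels(mr)))) == 2)
      not_merged <- not_merged + 1
  }
  expect_gte(not_merged, 38)                  # score < 0.1 in ~95% of draws
})

test_that("merging is invariant to assignment list order", {
  uni <- sprintf("P%04d", 1:1000)
  mk <- function(members, label) {
    labs <- rep(NA_character_, length(uni))
    names(labs) <- uni
    labs[members] <- label
    ClusterAssignment("DIRAM", labs)
  }
  a <- mk(uni[1:100], "x.C1")
  b <- mk(uni[21:120], "y.C1")
  f <- mk(uni[500:650], "z.C1")
  m_ab <- mergeClusters(list(a, b, f), 0.4)
  m_ba <- mergeClusters(list(f, b, a), 0.4)
  part <- function(m) {
    labs <- clusterLabels(m)
    unname(split(names(labs), labs))
  }
  expect_setequal(lapply(part(m_ab), sort), lapply(part(m_ba), sort))
})

test_that("DIRAM recovers planted clusters end to end with a missing block", {
  cfg <- SyntheticConfig(n_participants = 3000, n_proteins = 120,
                         n_clusters = 4, shift_proteins_per_cluster = 30,
                         shift_magnitude = 3,
                         missing_block_spec = list(c(40, 0.3)), seed = 1)
  co <- generateCohort(cfg)
  dr <- diramCluster(co$matrix)
  sizes <- clusterSizes(dr)
  expect_true(all(sizes >= 100 & sizes <= 20000))
  expect_gte(ariVsTruth(dr, co$truth), 0.8)
})
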