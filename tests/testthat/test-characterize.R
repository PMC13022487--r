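mkPheno <- function(n, sick, age = rep(55, n), sex = rep(c("F", "M"),
                                                         length.out = n),
                    code = "K90") {
  PhenotypeTable(sprintf("P%04d", seq_len(n)), age, sex,
                 lapply(sick, function(s) if (s) code else character()))
}
mkAsg <- function(labels) {
  ClusterAssignment("DIRCOD",
                    structure(labels,
                              names = sprintf("P%04d", seq_along(labels))))
}

test_that("enrichment reproduces the cross-product table by hand", {
  # a=20 b=80 in cluster, c=100 d=1800 outside -> OR 4.5
  n <- 2000
  sick <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 100), rep(FALSE, 1800))
  labels <- c(rep("A1", 100), rep(NA, 1900))
  enr <- diseaseEnrichment(mkAsg(labels), mkPheno(n, sick), "K90")
  expect_identical(c(enr$a, enr$b, enr$c, enr$d), c(20L, 80L, 100L, 1800L))
  expect_equal(enr$odds_ratio, 4.5)
  expect_equal(enr$p_raw,
               fisher.test(matrix(c(20, 80, 100, 1800), 2))$p.value)
  expect_equal(enr$p_bonferroni, min(1, enr$p_raw * nrow(enr)))

  # a cluster holding every case: zero cell, Haldane-Anscombe, flagged
  labels2 <- c(rep("A1", 120), rep("A2", 500), rep(NA, 1380))
  sick2 <- c(rep(TRUE, 120), rep(FALSE, 1880))
  enr2 <- diseaseEnrichment(mkAsg(labels2), mkPheno(n, sick2), "K90")
  r1 <- enr2[enr2$cluster_id == "A1", ]
  expect_true(is.finite(r1$odds_ratio) && r1$flagged)

  # absent code: zero cases everywhere, flagged rows
  enr3 <- diseaseEnrichment(mkAsg(labels), mkPheno(n, sick), "Z99")
  expect_identical(enr3$a + enr3$c, 0L)
  expect_true(all(enr3$flagged))
})

test_that("complementary clusters have reciprocal odds ratios", {
  set.seed(2)
  n <- 1000
  sick <- runif(n) < 0.15
  labels <- rep(c("A1", "A2"), each = n / 2)
  enr <- diseaseEnrichment(mkAsg(labels), mkPheno(n, sick), "K90")
  expect_equal(enr$odds_ratio[enr$cluster_id == "A1"],
               1 / enr$odds_ratio[enr$cluster_id == "A2"])
})

test_that("sex stratification tests within each sex in one family", {
  set.seed(3)
  n <- 1200
  sick <- runif(n) < 0.1
  labels <- rep(c("A1", NA), length.out = n)
  enr <- diseaseEnrichment(mkAsg(labels), mkPheno(n, sick), "K90",
                           stratify_sex = TRUE)
  expect_setequal(unique(enr$stratum), c("all", "F", "M"))
  expect_identical(nrow(enr), 3L)
  expect_equal(enr$p_bonferroni, pmin(1, enr$p_raw * 3))
})

test_that("enrichment keeps the family-wise error under the null", {
  set.seed(4)
  n <- 600
  hits <- vapply(1:150, function(r) {
    sick <- runif(n) < 0.1
    labels <- sample(rep(c("A1", "A2", "A3"), each = n / 3))
    enr <- diseaseEnrichment(mkAsg(labels), mkPheno(n, sick), "K90")
    any(enr$p_bonferroni <= 0.05)
  }, TRUE)
  expect_lte(mean(hits), 0.075)              # <= alpha plus binomial slack
})

test_that("demographic contrasts flag planted age and sex structure", {
  set.seed(5)
  n <- 3000
  age <- rnorm(n, 57, 8)
  age[1:500] <- age[1:500] + 10              # shifted cluster
  sex <- rep(c("F", "M"), length.out = n)
  sex[501:800] <- "F"                        # single-sex cluster
  labels <- c(rep("A1", 500), rep("A2", 300), rep(NA, n - 800))
  ph <- PhenotypeTable(sprintf("P%04d", 1:n), age, sex,
                       replicate(n, character(), simplify = FALSE))
  asg <- ClusterAssignment("DIRAM",
                           structure(labels, names = sprintf("P%04d", 1:n)))
  dem <- demographicContrast(asg, ph)
  a1 <- dem[dem$cluster_id == "A1", ]
  expect_lt(a1$p_age_bonferroni, 0.05)
  a2 <- dem[dem$cluster_id == "A2", ]
  expect_identical(a2$minority_sex_fraction, 0)
  expect_lt(a2$p_sex_bonferroni, 0.05)

  # null cluster: same age distribution, rarely flagged
  set.seed(6)
  null_flags <- vapply(1:60, function(r) {
    lab0 <- structure(rep(NA_character_, 1500),
                      names = sprintf("P%04d", 1:1500))
    lab0[sample(1500, 300)] <- "A1"
    ph0 <- PhenotypeTable(names(lab0), rnorm(1500, 57, 8),
                          rep(c("F", "M"), length.out = 1500),
                          replicate(1500, character(), simplify = FALSE))
    dem0 <- demographicContrast(ClusterAssignment("DIRAM", lab0), ph0)
    dem0$p_age_bonferroni < 0.05
  }, TRUE)
  expect_lte(mean(null_flags), 0.05 + 0.05)

  tiny <- structure(c(rep("A1", 5), rep(NA, 45)),
                    names = sprintf("P%04d", 1:50))
  ph_t <- PhenotypeTable(names(tiny), rep(50, 50),
                         rep(c("F", "M"), 25),
                         replicate(50, character(), simplify = FALSE))
  expect_warning(expect_error(
    demographicContrast(ClusterAssignment("DIRAM", tiny), ph_t),
    "no cluster"), "fewer than 10")
})
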