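# cohort with one disease whose odds rise with a planted factor on Q1/Q2
mkRecCohort <- function(n = 2000, seed = 1, assoc = c("Q1"), beta = 1.5,
                        baseline = 0.05) {
  set.seed(seed)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("P%04d", 1:n), paste0("Q", 1:4)))
  eta <- log(baseline / (1 - baseline)) +
    beta * rowSums(X[, assoc, drop = FALSE])
  sick <- runif(n) < plogis(eta)
  icd <- lapply(sick, function(s) if (s) "I10" else character())
  list(pm = ProteinMatrix(X),
       ph = PhenotypeTable(rownames(X), rep(55, n), rep(c("F", "M"),
                                                        length.out = n),
                           icd),
       sick = structure(sick, names = rownames(X)))
}

test_that("signature thresholds follow the percentile convention", {
  X <- matrix(1:100, 100, 1, dimnames = list(sprintf("P%03d", 1:100), "Q1"))
  pm <- ProteinMatrix(X)
  sig <- data.frame(protein_id = "Q1", direction = "high")
  cl <- sprintf("P%03d", 1:100)
  expect_equal(unname(signatureThresholds(pm, cl, sig, 75)), 75.25)
  expect_equal(unname(signatureThresholds(pm, cl, sig, 0)), 1)    # minimum
  expect_equal(unname(signatureThresholds(pm, cl, sig, 100)), 100)
  # thresholds come from the cluster of interest only
  expect_equal(unname(signatureThresholds(pm, sprintf("P%03d", 1:50),
                                          sig, 100)), 50)
})

test_that("the odds ratio is the cross-product with Woolf interval", {
  or <- oddsRatioWoolf(10, 490, 10, 4490)
  expect_equal(or$odds_ratio, (10 * 4490) / (490 * 10))
  expect_equal(or$odds_ratio, 9.163, tolerance = 1e-4)
  expect_false(or$corrected)
  expect_true(or$ci_low < or$odds_ratio && or$odds_ratio < or$ci_high)
  # zero cell: Haldane-Anscombe on all four cells, flagged
  orz <- oddsRatioWoolf(0, 100, 10, 890)
  expect_true(orz$corrected)
  expect_equal(orz$odds_ratio, (0.5 * 890.5) / (100.5 * 10.5))
})

test_that("recreate matches the count-the-cells oracle on every percentile", {
  d <- mkRecCohort(seed = 2)
  sig <- data.frame(protein_id = c("Q1", "Q2"),
                    direction = c("high", "high"))
  pooled <- sprintf("P%04d", 1:400)
  rc <- recreate(d$pm, d$ph, pooled, sig, "I10", seq(10, 90, 10))
  tab <- curveTable(rc)
  X <- npx(d$pm)
  for (i in seq_len(nrow(tab))) {
    thr <- signatureThresholds(d$pm, pooled, sig, tab$percentile[i])
    sel <- X[, "Q1"] >= thr["Q1"] & X[, "Q2"] >= thr["Q2"]
    cells <- orCellsOracle(sel, d$sick)
    expect_identical(tab$selected_n[i], as.integer(cells["a"] + cells["b"]))
    expect_identical(tab$cases_in[i], as.integer(cells["a"]))
    if (!tab$flagged[i]) expect_equal(tab$odds_ratio[i],
                                      unname(cells["or"]))
  }
  # selected_n is non-increasing along the percentile grid (high direction)
  expect_true(all(diff(tab$selected_n) <= 0))
})

test_that("missing signature values make a participant unselected, or drop it", {
  d <- mkRecCohort(n = 500, seed = 3)
  X <- npx(d$pm)
  X[1:50, "Q1"] <- NA
  pm <- ProteinMatrix(X)
  sig <- data.frame(protein_id = "Q1", direction = "high")
  pooled <- sprintf("P%04d", 100:400)
  rc <- recreate(pm, d$ph, pooled, sig, "I10", 50)
  tab <- curveTable(rc)
  # the 50 missing participants are counted on the unselected side
  expect_identical(tab$selected_n + sum(!is.na(X[, "Q1"]) &
                                          X[, "Q1"] < signatureThresholds(
                                            pm, pooled, sig, 50)),
                   500L - 50L)
  rc2 <- recreate(pm, d$ph, pooled, sig, "I10", 50, drop_missing = TRUE)
  expect_identical(curveTable(rc2)$selected_n +
                     curveTable(rc2)$cases_out +
                     (450L - curveTable(rc2)$selected_n -
                        curveTable(rc2)$cases_out), 450L)
})

test_that("leave-one-out selections are supersets and deltas flag the carrier", {
  d <- mkRecCohort(n = 3000, seed = 4, assoc = "Q1", beta = 2)
  sig <- data.frame(protein_id = c("Q1", "Q2", "Q3"),
                    direction = "high")
  pooled <- names(sort(npx(d$pm)[, "Q1"], decreasing = TRUE))[1:500]
  lo <- leaveOneOut(d$pm, d$ph, pooled, sig, "I10", c(25, 50, 75))
  X <- npx(d$pm)
  full_sel <- lapply(c(25, 50, 75), function(p) {
    thr <- signatureThresholds(d$pm, pooled, sig, p)
    rownames(X)[X[, "Q1"] >= thr["Q1"] & X[, "Q2"] >= thr["Q2"] &
                  X[, "Q3"] >= thr["Q3"]]
  })
  for (j in 1:3) {
    thr <- signatureThresholds(d$pm, pooled, sig[-j, , drop = FALSE], 50)
    keep <- rep(TRUE, nrow(X))
    for (q in sig$protein_id[-j]) keep <- keep & X[, q] >= thr[q]
    expect_true(all(full_sel[[2]] %in% rownames(X)[keep]))
  }
  # the planted carrier Q1 has the largest |delta OR| at percentile 50
  deltas <- vapply(looTables(lo), function(t)
    abs(t$delta_or[t$percentile == 50]), 0)
  expect_identical(names(which.max(deltas)), "Q1")
  # omitting a protein whose threshold binds nobody leaves the curve alone
  Xc <- cbind(X, Q5 = rep(c(0, 1), length.out = nrow(X)))
  pmc <- ProteinMatrix(Xc)
  sig2 <- data.frame(protein_id = c("Q1", "Q5"), direction = "high")
  lo2 <- leaveOneOut(pmc, d$ph, rownames(X), sig2, "I10", 0)
  expect_equal(looTables(lo2)[["Q5"]]$delta_or, 0)
})

test_that("a disease unrelated to the signature stays near OR 1", {
  d <- mkRecCohort(n = 4000, seed = 6, beta = 0, baseline = 0.1)
  sig <- data.frame(protein_id = c("Q1", "Q2"), direction = "high")
  pooled <- sprintf("P%04d", 1:800)
  rc <- recreate(d$pm, d$ph, pooled, sig, "I10", seq(5, 70, 5))
  tab <- curveTable(rc)
  covered <- !tab$flagged & tab$ci_low <= 1 & tab$ci_high >= 1
  expect_gte(mean(covered), 0.85)
})
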