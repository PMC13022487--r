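test_that("same configuration gives a bit-identical cohort", {
  cfg <- SyntheticConfig(n_participants = 300, n_proteins = 40,
                         shift_proteins_per_cluster = 8,
                         missing_block_spec = list(c(6, 0.2)),
                         disease_spec = list(list(code = "I10",
                                                  baseline = 0.1,
                                                  multipliers = c(1, 2, 1, 1))),
                         seed = 9)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(npx(a$matrix), npx(b$matrix))
  expect_identical(a$truth, b$truth)
  expect_identical(as.list(icd10Codes(a$phenotypes)),
                   as.list(icd10Codes(b$phenotypes)))
})

test_that("null configuration yields iid normals with a full mask", {
  cfg <- SyntheticConfig(n_participants = 2000, n_proteins = 30,
                         n_clusters = 1, cluster_proportions = 1,
                         shift_proteins_per_cluster = 0, shift_magnitude = 0,
                         seed = 4)
  co <- generateCohort(cfg)
  expect_true(all(observedMask(co$matrix)))
  v <- as.vector(npx(co$matrix))
  expect_lt(abs(mean(v)), 0.02)
  expect_lt(abs(sd(v) - 1), 0.02)
})

test_that("missing blocks share masks and proportions track the simplex", {
  cfg <- SyntheticConfig(n_participants = 2500, n_proteins = 50,
                         shift_proteins_per_cluster = 10,
                         cluster_proportions = c(0.4, 0.3, 0.2, 0.1),
                         missing_block_spec = list(c(5, 0.3)), seed = 2)
  co <- generateCohort(cfg)
  blk <- co$info$missing_block_proteins[[1]]
  expect_length(blk, 5)
  masks <- observedMask(co$matrix)[, blk]
  for (j in 2:5) expect_identical(masks[, j], masks[, 1])
  expect_equal(mean(!masks[, 1]), 0.3, tolerance = 0.01)

  prop <- as.vector(table(co$truth)) / cfg@n_participants
  expect_true(all(abs(prop - cfg@cluster_proportions) <=
                    3 / sqrt(cfg@n_participants)))
})

test_that("disease draws reproduce the generating odds ratio", {
  cfg <- SyntheticConfig(n_participants = 20000, n_proteins = 10,
                         n_clusters = 2, cluster_proportions = c(0.5, 0.5),
                         shift_proteins_per_cluster = 0, shift_magnitude = 0,
                         disease_spec = list(list(code = "K90",
                                                  baseline = 0.05,
                                                  multipliers = c(4, 1))),
                         seed = 5)
  co <- generateCohort(cfg)
  sick <- hasCode(co$phenotypes, "K90")
  in1 <- co$truth == 1
  or <- orCellsOracle(in1, sick[names(co$truth)])["or"]
  expect_gt(or, 3.4)
  expect_lt(or, 4.6)
})

test_that("planted coregulation reaches its target within sampling error", {
  base <- list(n_participants = 2000, n_proteins = 40, n_clusters = 4,
               shift_proteins_per_cluster = 10, shift_magnitude = 0,
               seed = 6)
  cfg <- do.call(SyntheticConfig,
                 c(base, list(coregulation_spec = list(cluster = 1, size = 6,
                                                       rho = 0.6))))
  co <- generateCohort(cfg)
  rho <- plantedCorrelationCheck(co$matrix, cfg, co$truth)
  expect_gt(rho, 0.5)
  expect_lt(rho, 0.7)

  cfg0 <- do.call(SyntheticConfig,
                  c(base, list(coregulation_spec = list(cluster = 1, size = 6,
                                                        rho = 0))))
  co0 <- generateCohort(cfg0)
  rho0 <- plantedCorrelationCheck(co0$matrix, cfg0, co0$truth)
  expect_lt(abs(rho0), 0.1)

  expect_error(SyntheticConfig(coregulation_spec = list(cluster = 1,
                                                        size = 1, rho = 0.5)),
               "size >= 2")
  expect_error(plantedCorrelationCheck(co$matrix, SyntheticConfig(),
                                       co$truth),
               "no coregulation")
})

test_that("infeasible configurations are rejected", {
  expect_error(SyntheticConfig(n_proteins = 20,
                               shift_proteins_per_cluster = 10,
                               n_clusters = 4),
               "exceed")
  expect_error(SyntheticConfig(cluster_proportions = c(0.5, 0.4, 0.05, 0.04)),
               "sum to 1")
  expect_error(SyntheticConfig(disease_spec = list(list(code = "I10",
                                                        baseline = 1.5,
                                                        multipliers = rep(1, 4)))),
               "prevalence")
})
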