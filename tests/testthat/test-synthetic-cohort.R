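smallSpec <- function(n = 40, seed = 1, ...) {
  cohortSpec(nSamples = n, seed = seed, nGenes = 20, nImmuneGenes = 5,
             nMetabolites = 24, nLipids = 14, mutationRate = 4,
             genePanelSize = 50, ...)
}

test_that("identical spec and seed reproduce the cohort exactly", {
  a <- generateCohort(smallSpec(seed = 7))
  b <- generateCohort(smallSpec(seed = 7))
  expect_identical(cohortTable(a), cohortTable(b))
  expect_identical(mutations(a), mutations(b))
  expect_identical(segments(a), segments(b))
  expect_identical(expressionMatrix(a), expressionMatrix(b))
  expect_identical(metaboliteMatrix(a), metaboliteMatrix(b))
  expect_identical(lipidMatrix(a), lipidMatrix(b))
  expect_identical(cohortTruth(a), cohortTruth(b))
  c_ <- generateCohort(smallSpec(seed = 8))
  expect_false(identical(mutations(a), mutations(c_)))
})

test_that("a degenerate one-sample cohort lands in every layer", {
  spec <- smallSpec(n = 1, groupProportions = c(negative = 0, probably_benign = 0,
                                                low_moderate = 0,
                                                high_suspicion = 1))
  co <- generateCohort(spec)
  ct <- cohortTable(co)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$calc_group, "high_suspicion")
  id <- ct$sample
  expect_true(all(mutations(co)$sample == id | nrow(mutations(co)) == 0))
  expect_equal(unique(segments(co)$sample), id)
  expect_equal(colnames(expressionMatrix(co)), id)
  expect_equal(colnames(metaboliteMatrix(co)), id)
  expect_equal(colnames(lipidMatrix(co)), id)
})

test_that("invalid specs are rejected", {
  expect_error(cohortSpec(groupProportions = c(negative = 0.5,
                                               probably_benign = 0.5,
                                               low_moderate = 0.5,
                                               high_suspicion = 0.5)),
               "sum to 1")
  expect_error(cohortSpec(pik3caFreq = 1.5), "\\[0, 1\\]")
  expect_error(cohortSpec(nSamples = 0), ">= 1")
  expect_error(cohortSpec(hazardRatio = -1), "> 0")
  expect_error(generateSurvival(data.frame(sample = "a", calc_group = "negative"),
                                1, censorRate = 2), "\\[0, 1\\]")
})

test_that("planted mutation frequencies are recovered within binomial error", {
  spec <- smallSpec(n = 1500, seed = 21,
                    pik3caFreq = c(negative = 0.15, probably_benign = 0.15,
                                   low_moderate = 0.15, high_suspicion = 0.30))
  co <- generateCohort(spec)
  truth <- cohortTruth(co)
  grp <- truth$group
  hit <- truth$pik3ca
  for (g in c("high_suspicion", "negative")) {
    planted <- ifelse(g == "high_suspicion", 0.30, 0.15)
    n_g <- sum(grp == g)
    se <- sqrt(planted * (1 - planted) / n_g)
    expect_lt(abs(mean(hit[grp == g]) - planted), 3 * se)
    # and the truth matches the actual mutation layer
    mut_pik <- unique(mutations(co)$sample[mutations(co)$gene == "PIK3CA"])
    expect_setequal(mut_pik, names(hit)[hit])
  }
})

test_that("survival generation respects censoring and event ordering", {
  ct <- data.frame(sample = paste0("s", 1:300),
                   calc_group = rep(calcGroups(), 75))
  full <- generateSurvival(ct, 1, censorRate = 1, seed = 3)
  expect_equal(sum(full$os_event), 0)
  none <- generateSurvival(ct, 1, censorRate = 0, seed = 3)
  expect_equal(sum(none$os_event), 300)
  mid <- generateSurvival(ct, 1, censorRate = 0.4, seed = 3)
  expect_equal(mean(1 - mid$os_event), 0.4, tolerance = 0.1)
  # RFS time never exceeds OS time; all times non-negative
  expect_true(all(mid$rfs_time <= mid$os_time + 1e-12))
  expect_true(all(mid$os_time >= 0))
})

test_that("planted hazard differences surface in the cohort table", {
  ct <- data.frame(sample = paste0("s", 1:800),
                   calc_group = rep(c("high_suspicion", "negative"), 400))
  out <- generateSurvival(ct, c(negative = 1, probably_benign = 1,
                                low_moderate = 1, high_suspicion = 2),
                          censorRate = 0.2, seed = 9)
  fit <- coxHazard(out, "os", c("high_suspicion", "negative"),
                   covariates = character(0))
  expect_true(fit$ci_low <= 2 && fit$ci_high >= 2)
})

test_that("per-layer missingness drops samples without creating orphans", {
  spec <- smallSpec(n = 60, seed = 4,
                    missingness = c(mutations = 0.3, expression = 0.2))
  co <- generateCohort(spec)
  expect_lt(length(unique(mutations(co)$sample)), 60)
  expect_equal(ncol(expressionMatrix(co)), 48)
  expect_true(methods::validObject(co))
})

test_that("cohort layers round-trip through their writers", {
  co <- generateCohort(smallSpec(n = 12, seed = 13))
  dir <- withr::local_tempdir()
  paths <- writeCohortLayers(co, dir)
  expect_true(all(file.exists(paths)))
  back_ct <- readCohort(paths["cohort"])
  expect_equal(back_ct$sample, cohortTable(co)$sample)
  back_seg <- readSegments(paths["segments"])
  expect_equal(back_seg[, c("sample", "chrom", "start", "end")],
               segments(co)[, c("sample", "chrom", "start", "end")],
               ignore_attr = TRUE)
  back_expr <- readMatrixTsv(paths["expression"])
  expect_equal(back_expr, expressionMatrix(co), tolerance = 1e-8)
  back_maf <- readMaf(paths["maf"])
  expect_equal(nrow(back_maf), nrow(mutations(co)))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(unlist(truth$group), cohortTruth(co)$group)
})
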