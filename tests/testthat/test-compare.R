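test_that("unadjusted logistic odds ratio equals the 2x2 cross-product", {
  g <- rep(c("high_suspicion", "negative"), each = 100)
  feat <- c(rep(1, 30), rep(0, 70), rep(1, 15), rep(0, 85))
  res <- compareCategorical(feat, g, c("high_suspicion", "negative"))
  expect_equal(res$estimate, (30 * 85) / (70 * 15), tolerance = 1e-6)
  expect_equal(res$method, "logistic")
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("identical distributions give OR 1 and zero cells fall back to Fisher", {
  g <- rep(c("a", "b"), each = 60)
  feat <- rep(c(1, 0, 1, 0), c(18, 42, 18, 42))
  res <- compareCategorical(feat, g, c("a", "b"))
  expect_equal(res$estimate, 1, tolerance = 1e-6)
  expect_gt(res$p, 0.9)
  feat0 <- c(rep(1, 10), rep(0, 50), rep(0, 60))  # zero cell in group b
  res0 <- compareCategorical(feat0, g, c("a", "b"))
  expect_equal(res0$method, "fisher")
})

test_that("'rest' pools all other groups as reference", {
  g <- rep(c("high_suspicion", "negative", "probably_benign"), each = 50)
  feat <- rbinom(150, 1, ifelse(g == "high_suspicion", 0.5, 0.1))
  res <- compareCategorical(feat, g, c("high_suspicion", "rest"))
  expect_equal(res$n, 150L)
  expect_gt(res$estimate, 1)
})

test_that("continuous contrasts estimate adjusted mean differences", {
  set.seed(60)
  g <- rep(c("pos", "ref"), each = 250)
  y <- rnorm(500) + (g == "pos") * 1
  res <- compareContinuous(y, g, c("pos", "ref"))
  expect_equal(res$estimate, 1, tolerance = 0.25)
  expect_lt(res$p, 1e-10)
  expect_lt(res$p_rank, 1e-10)
  # identical groups: estimate ~ 0
  y0 <- rnorm(500)
  res0 <- compareContinuous(y0, g, c("pos", "ref"))
  expect_lt(abs(res0$estimate), 0.25)
  # a covariate fully explaining the shift removes the group effect
  x <- rnorm(500)
  y2 <- 2 * x + rnorm(500, sd = 0.1)
  # plant group imbalance in the covariate itself
  x[g == "pos"] <- x[g == "pos"] + 1
  y2 <- 2 * x + rnorm(500, sd = 0.1)
  raw <- compareContinuous(y2, g, c("pos", "ref"))
  adj <- compareContinuous(y2, g, c("pos", "ref"),
                           covariates = data.frame(x = x))
  expect_gt(abs(raw$estimate), 1.5)
  expect_lt(abs(adj$estimate), 0.1)
  # constant feature
  expect_warning(resc <- compareContinuous(rep(1, 500), g, c("pos", "ref")),
                 "constant")
  expect_equal(resc$p, 1)
})

test_that("frequency tables match brute-force counting and plant detection", {
  set.seed(61)
  n <- 2000
  g <- sample(c("high_suspicion", "negative"), n, replace = TRUE)
  ev <- rbind(
    planted = rbinom(n, 1, ifelse(g == "high_suspicion", 0.30, 0.15)),
    null1 = rbinom(n, 1, 0.2),
    null2 = rbinom(n, 1, 0.05),
    never = rep(0, n))
  colnames(ev) <- paste0("s", 1:n)
  ft <- featureFrequencyTable(ev, g,
                              contrasts = list(c("high_suspicion", "negative")))
  # frequencies equal direct counting
  for (gene in rownames(ev)) {
    for (grp in c("high_suspicion", "negative")) {
      expect_equal(ft$frequencies[gene, grp], mean(ev[gene, g == grp]))
    }
  }
  expect_equal(unname(ft$frequencies["never", ]), c(0, 0))
  tab <- ft$contrasts
  expect_lt(tab$fdr[tab$gene == "planted"], 0.05)
  expect_gt(min(tab$fdr[tab$gene %in% c("null1", "null2")]), 0.05)
})

test_that("BH adjustment matches the brute-force oracle", {
  expect_equal(adjustFdr(0.03), 0.03)
  set.seed(62)
  for (r in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjustFdr(p), oracleBh(p))
  }
  p_sorted <- sort(runif(20))
  expect_true(all(diff(adjustFdr(p_sorted)) >= 0))
  expect_error(adjustFdr(c(0.5, 1.2)), "0, 1")
})

test_that("Cox models recover hazards and reject undersized inputs", {
  set.seed(63)
  ct <- data.frame(sample = paste0("s", 1:400),
                   calc_group = rep(c("high_suspicion", "negative"), each = 200))
  ct <- generateSurvival(ct, c(negative = 1, probably_benign = 1,
                               low_moderate = 1, high_suspicion = 2),
                         censorRate = 0.3, seed = 7)
  res <- coxHazard(ct, "os", c("high_suspicion", "negative"),
                   covariates = character(0))
  expect_gt(res$hr, 1.3)
  expect_true(res$ci_low <= 2.8)
  expect_true(res$converged)
  # all-censored input errors
  ct0 <- ct
  ct0$os_event <- 0
  expect_error(coxHazard(ct0, "os", c("high_suspicion", "negative")),
               "no events")
  ct1 <- ct
  ct1$os_event[-(1:5)] <- 0
  expect_error(coxHazard(ct1, "os", c("high_suspicion", "negative")),
               "minimum")
})
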