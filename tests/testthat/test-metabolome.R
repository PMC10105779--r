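test_that("prefiltering requires both FDR and fold-change conditions", {
  set.seed(30)
  n <- 30
  feats <- paste0("m", 1:4)
  base <- matrix(rnorm(4 * n, 10, 0.3), 4, n,
                 dimnames = list(feats, paste0("t", 1:n)))
  normal <- matrix(rnorm(4 * n, 10, 0.3), 4, n,
                   dimnames = list(feats, paste0("n", 1:n)))
  tumor <- base
  tumor["m1", ] <- tumor["m1", ] + 2    # strong shift, big lfc -> kept
  tumor["m2", ] <- tumor["m2", ] + 0.5  # significant but |lfc| < 1 -> dropped
  # m3/m4 null -> dropped by FDR
  out <- prefilterFeatures(tumor, normal)
  expect_equal(rownames(out), "m1")
  st <- attr(out, "stats")
  expect_true(st$fdr[st$feature == "m2"] < 0.01)  # dropped by lfc, not FDR

  # SD truncation contract: 500 survivors -> exactly 200 kept
  big <- matrix(rnorm(500 * 10), 500, 10,
                dimnames = list(paste0("x", 1:500), paste0("s", 1:10)))
  expect_warning(kept <- prefilterFeatures(big, NULL, topSd = 200),
                 "skipping")
  expect_equal(nrow(kept), 200L)
})

mkDaData <- function(nPath = 3, perPath = 5, nPer = 30, shift = 0, seed = 1) {
  set.seed(seed)
  nfeat <- nPath * perPath
  feats <- sprintf("m%03d", 1:nfeat)
  groups <- rep(c("pos", "ref"), each = nPer)
  mat <- matrix(rnorm(nfeat * nPer * 2, 10, 1), nfeat, nPer * 2,
                dimnames = list(feats, paste0("s", 1:(nPer * 2))))
  ann <- data.frame(feature = feats,
                    pathway = rep(paste0("P", 1:nPath), each = perPath))
  list(mat = mat, groups = groups, ann = ann)
}

test_that("DA score hits its -1/1 endpoints and the printed formula", {
  d <- mkDaData()
  # pathway P1 all strongly increased -> DA = 1
  d$mat[d$ann$pathway == "P1", d$groups == "pos"] <-
    d$mat[d$ann$pathway == "P1", d$groups == "pos"] + 5
  # pathway P2 all strongly decreased -> DA = -1
  d$mat[d$ann$pathway == "P2", d$groups == "pos"] <-
    d$mat[d$ann$pathway == "P2", d$groups == "pos"] - 5
  res <- daScore(d$mat, d$groups, d$ann, positive = "pos")
  expect_equal(res$da_score[res$pathway == "P1"], 1)
  expect_equal(res$da_score[res$pathway == "P2"], -1)
  expect_lte(abs(res$da_score[res$pathway == "P3"]), 0.4)

  # 3 up, 1 down, 1 null out of 5 -> (3 - 1)/5 = 0.4
  d2 <- mkDaData(nPath = 1, seed = 2)
  rows <- d2$ann$feature
  d2$mat[rows[1:3], d2$groups == "pos"] <- d2$mat[rows[1:3], d2$groups == "pos"] + 5
  d2$mat[rows[4], d2$groups == "pos"] <- d2$mat[rows[4], d2$groups == "pos"] - 5
  res2 <- daScore(d2$mat, d2$groups, d2$ann, positive = "pos")
  expect_equal(res2$da_score, 0.4)
  expect_equal(res2$n_increased, 3L)
  expect_equal(res2$n_decreased, 1L)
})

test_that("DA scores match the brute-force recount and stay within [-1, 1]", {
  set.seed(31)
  for (r in 1:10) {
    d <- mkDaData(nPath = 4, perPath = sample(3:6, 1), nPer = 12,
                  seed = 100 + r)
    shift_rows <- sample(nrow(d$mat), nrow(d$mat) / 2)
    d$mat[shift_rows, d$groups == "pos"] <-
      d$mat[shift_rows, d$groups == "pos"] +
      sample(c(-3, 0, 3), length(shift_rows), replace = TRUE)
    res <- daScore(d$mat, d$groups, d$ann, positive = "pos")
    oracle <- oracleDa(d$mat, d$groups, d$ann, positive = "pos")
    expect_true(all(abs(res$da_score) <= 1))
    expect_equal(stats::setNames(res$da_score, res$pathway),
                 unlist(oracle)[res$pathway])
  }
})

test_that("small pathways are excluded and tiny groups rejected", {
  d <- mkDaData(nPath = 1, perPath = 2)
  expect_equal(nrow(daScore(d$mat, d$groups, d$ann, positive = "pos")), 0L)
  d2 <- mkDaData()
  expect_error(daScore(d2$mat, c("pos", rep("ref", ncol(d2$mat) - 1)),
                       d2$ann, positive = "pos"), "two samples")
})

test_that("lipid subclass fold changes recover constructed shifts", {
  set.seed(32)
  n <- 40
  feats <- paste0("L", 1:12)
  ann <- data.frame(feature = feats,
                    category = rep(c("GL", "SP", "FA"), each = 4),
                    main_class = rep(c("triradylglycerols", "ceramides",
                                       "fatty acids"), each = 4))
  groups <- rep(c("pos", "ref"), each = n / 2)
  lin <- matrix(runif(12 * n, 50, 100), 12, n,
                dimnames = list(feats, paste0("s", 1:n)))
  # double every triradylglycerol in the positive group
  lin[1:4, groups == "pos"] <- lin[1:4, groups == "pos"] * 2
  res <- lipidSubclassFc(lin, groups, ann, positive = "pos")
  tg <- res[res$main_class == "triradylglycerols", ]
  expect_equal(tg$median_log2fc, 1, tolerance = 0.15)
  other <- res[res$main_class != "triradylglycerols", ]
  expect_true(all(abs(other$median_log2fc) < 0.2))
  # identical groups: all medians ~ 0
  null_mat <- matrix(runif(12 * n, 50, 100), 12, n,
                     dimnames = list(feats, paste0("s", 1:n)))
  res0 <- lipidSubclassFc(null_mat, groups, ann, positive = "pos")
  expect_true(all(abs(res0$median_log2fc) < 0.25))
  # coverage: exactly the subclasses present in annotation & matrix
  expect_setequal(res$main_class, unique(ann$main_class))
  # unmeasured subclass warns
  ann2 <- rbind(ann, data.frame(feature = "Lmissing", category = "ST",
                                main_class = "sterols"))
  expect_warning(lipidSubclassFc(lin, groups, ann2, positive = "pos"),
                 "sterols")
  # log-scale convention: difference of means
  logm <- log2(lin)
  res_log <- lipidSubclassFc(logm, groups, ann, positive = "pos",
                             method = "difference_of_log_means")
  expect_equal(res_log$median_log2fc[res_log$main_class == "triradylglycerols"],
               1, tolerance = 0.15)
})
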