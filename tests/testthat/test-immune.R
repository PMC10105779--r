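set.seed(100)
exprFix <- matrix(rnorm(200), 20, 10,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))

test_that("signature scores are exactly standardized and collapse correctly", {
  s <- signatureScore(exprFix, paste0("g", 1:5))
  expect_equal(mean(s), 0, tolerance = 1e-9)
  expect_equal(sd(s), 1, tolerance = 1e-9)
  # single-gene signature equals the z-scored centered gene
  s1 <- signatureScore(exprFix, "g7")
  g <- exprFix["g7", ] - mean(exprFix["g7", ])
  expect_equal(unname(s1), unname((g - mean(g)) / sd(g)))
  # adding a constant to one gene leaves scores unchanged (mean-centering)
  shifted <- exprFix
  shifted["g2", ] <- shifted["g2", ] + 100
  expect_equal(signatureScore(shifted, paste0("g", 1:5)),
               signatureScore(exprFix, paste0("g", 1:5)))
})

test_that("missing signature genes warn, empty overlap errors", {
  expect_warning(signatureScore(exprFix, c("g1", "g2", "nope")), "absent")
  expect_error(signatureScore(exprFix, c("x", "y")), "no signature genes")
  lst <- signatureScore(exprFix, list(a = paste0("g", 1:3),
                                      b = paste0("g", 4:6)))
  expect_equal(dim(lst), c(2L, 10L))
})

test_that("ssGSEA matches the explicit running-sum oracle on small matrices", {
  set.seed(101)
  for (r in 1:30) {
    nf <- sample(3:6, 1)
    ns <- sample(2:4, 1)
    mat <- matrix(rnorm(nf * ns), nf, ns,
                  dimnames = list(paste0("f", 1:nf), paste0("c", 1:ns)))
    m <- sample(1:(nf - 1), 1)
    members <- sample(rownames(mat), m)
    scores <- ssgseaScores(mat, list(set = members), normalize = FALSE)
    for (j in 1:ns) {
      expect_equal(scores["set", j],
                   oracleSsgsea(mat[, j], members, rownames(mat)),
                   tolerance = 1e-10, info = paste("rep", r, "sample", j))
    }
  }
})

test_that("ssGSEA hand-computed 3-feature example and rank invariance hold", {
  mat <- matrix(c(3, 2, 1), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  # set {a}: a has rank 3 (top). walking a,b,c:
  # step1: in-set 3^.25/3^.25 = 1, out 0 -> 1
  # step2: out 1/2 -> 1 - 0.5 = 0.5 ; step3: -> 1 - 1 = 0
  expect_equal(ssgseaScores(mat, list(top = "a"), normalize = FALSE)[1, 1],
               1 + 0.5 + 0)
  # monotone transform of one sample leaves its scores unchanged
  set.seed(5)
  m2 <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
  sets <- list(A = c("f1", "f5"), B = c("f2", "f3", "f8"))
  sc <- ssgseaScores(m2, sets, normalize = FALSE)
  m3 <- m2
  m3[, 2] <- exp(m2[, 2])
  expect_equal(ssgseaScores(m3, sets, normalize = FALSE)[, 2], sc[, 2])
  # two samples with identical rank order get identical scores
  m4 <- m2
  m4[, 3] <- rank(m2[, 1]) * 10
  m4[, 1] <- rank(m2[, 1])
  sc4 <- ssgseaScores(m4, sets, normalize = FALSE)
  expect_equal(sc4[, 1], sc4[, 3])
})

test_that("ssGSEA rejects sets without members in the matrix", {
  expect_error(ssgseaScores(exprFix, list(bad = c("nope1", "nope2"))),
               "no members")
})

test_that("TME inference recovers a planted high-infiltration sample", {
  set.seed(102)
  genes <- paste0("g", 1:60)
  cd8_genes <- paste0("g", 1:8)
  mat <- matrix(rnorm(60 * 20), 60, 20,
                dimnames = list(genes, paste0("s", 1:20)))
  mat[cd8_genes, "s1"] <- mat[cd8_genes, "s1"] + 3
  refsets <- list(CD8_T = cd8_genes, NK = paste0("g", 9:16),
                  Fibroblast = paste0("g", 17:24))
  sc <- inferTme(mat, refsets)
  expect_equal(dim(sc), c(3L, 20L))
  expect_gt(sc["CD8_T", "s1"], median(sc["CD8_T", ]))
  # permuting samples permutes columns only
  perm <- sample(colnames(mat))
  expect_equal(inferTme(mat[, perm], refsets), sc[, perm])
})
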