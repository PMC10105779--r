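test_that("SBS96 bins SNVs with pyrimidine-strand collapse", {
  m <- data.frame(sample = "s1", ref = "C", alt = "A", context = "ACA")
  cat1 <- buildSbs96(m)
  expect_equal(sum(cat1), 1)
  expect_equal(cat1["A[C>A]A", "s1"], 1L)
  # purine reference G>T in TGT is the reverse complement of A[C>A]A
  m2 <- data.frame(sample = "s1", ref = "G", alt = "T", context = "TGT")
  expect_equal(buildSbs96(m2)["A[C>A]A", "s1"], 1L)
  # catalog total equals the number of SNVs; indels ignored
  m3 <- data.frame(sample = "s1", ref = c("C", "T", "A"),
                   alt = c("A", "G", "-"),
                   context = c("ACA", "TTA", NA))
  expect_equal(sum(buildSbs96(m3)), 2)
})

test_that("SBS96 labels agree with a string-munging oracle on random SNVs", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  for (r in 1:200) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
    cat_r <- buildSbs96(data.frame(sample = "s", ref = ref, alt = alt,
                                   context = ctx))
    expect_equal(names(which(cat_r[, 1] == 1L)),
                 oracleSbs96Label(ref, alt, ctx))
  }
})

test_that("a catalog and its full reverse complement are identical", {
  set.seed(8)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- sample(bases, 50, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  l <- sample(bases, 50, replace = TRUE); r <- sample(bases, 50, replace = TRUE)
  fwd <- data.frame(sample = "s", ref = ref, alt = alt,
                    context = paste0(l, ref, r))
  rev <- data.frame(sample = "s", ref = unname(comp[ref]),
                    alt = unname(comp[alt]),
                    context = paste0(comp[r], comp[ref], comp[l]))
  expect_equal(buildSbs96(fwd), buildSbs96(rev))
})

test_that("malformed contexts are rejected", {
  expect_error(buildSbs96(data.frame(sample = "s", ref = "C", alt = "A",
                                     context = "ACAT")), "3-mer")
  expect_error(buildSbs96(data.frame(sample = "s", ref = "C", alt = "A",
                                     context = "ATA")), "center")
})

test_that("refitting recovers exact members and constructed mixtures", {
  set.seed(9)
  ref <- matrix(stats::runif(5 * 96), 5, 96)
  ref <- ref / rowSums(ref)
  rownames(ref) <- paste0("SIG", 1:5)
  # catalog proportional to one signature: full weight, residual ~ 0
  y <- 100 * ref[3, ]
  fit <- refitSignatures(y, ref)
  w <- unlist(fit[paste0("SIG", 1:5)])
  expect_equal(unname(w["SIG3"] / sum(w)), 1, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-6)
  # well-separated 0.6/0.4 mixture
  y2 <- 500 * (0.6 * ref[1, ] + 0.4 * ref[2, ])
  fit2 <- refitSignatures(y2, ref)
  w2 <- unlist(fit2[paste0("SIG", 1:5)])
  expect_equal(unname(w2["SIG1"] / sum(w2)), 0.6, tolerance = 0.05)
  expect_equal(unname(w2["SIG2"] / sum(w2)), 0.4, tolerance = 0.05)
})

test_that("refit matches the subset-enumeration NNLS oracle", {
  set.seed(10)
  for (r in 1:25) {
    ref <- matrix(stats::runif(4 * 96), 4, 96)
    ref <- ref / rowSums(ref)
    rownames(ref) <- paste0("R", 1:4)
    y <- as.numeric(stats::rpois(96, 3))
    fit <- refitSignatures(y, ref, sparsify = FALSE)
    oracle <- oracleNnls(t(ref), y)
    expect_lte(fit$residual, oracle$residual + 1e-6)
    expect_equal(unname(unlist(fit[paste0("R", 1:4)])), oracle$w,
                 tolerance = 1e-4)
  }
})

test_that("exposures are non-negative and error never grows with more signatures", {
  set.seed(11)
  ref <- matrix(stats::runif(6 * 96), 6, 96)
  ref <- ref / rowSums(ref)
  rownames(ref) <- paste0("S", 1:6)
  y <- as.numeric(stats::rpois(96, 5))
  resid <- vapply(2:6, function(k) {
    fit <- refitSignatures(y, ref[1:k, , drop = FALSE], sparsify = FALSE)
    expect_true(all(unlist(fit[paste0("S", 1:k)]) >= 0))
    fit$residual
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-8))
})

test_that("dimension mismatches and invalid references are rejected", {
  ref <- matrix(1 / 96, 2, 96)
  expect_error(refitSignatures(rep(1, 50), ref), "classes")
  bad <- matrix(stats::runif(2 * 96), 2, 96)
  expect_error(refitSignatures(rep(1, 96), bad), "sum to 1")
})
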