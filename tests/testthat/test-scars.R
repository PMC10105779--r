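build10 <- syntheticGenomeBuild()
buildNoCen <- syntheticGenomeBuild(centromeres = FALSE)

test_that("NtAI counts telomeric subchromosomal imbalance longer than 11 Mb", {
  # fully balanced genome
  seg <- makeSegs("1", 1, 100e6, 2, 2)
  expect_equal(computeNtai(seg, build10), 0L)
  # one 12-Mb imbalanced segment at the p telomere
  seg <- makeSegs("1", c(1, 12e6 + 1), c(12e6, 100e6), c(2, 1), c(1, 1))
  expect_equal(computeNtai(seg, build10), 1L)
  # 11-Mb exactly: "longer than" is strict
  seg <- makeSegs("1", c(1, 11e6 + 1), c(11e6, 100e6), c(2, 1), c(1, 1))
  expect_equal(computeNtai(seg, build10), 0L)
  # whole-chromosome imbalance is not subchromosomal
  seg <- makeSegs("1", 1, 100e6, 2, 1)
  expect_equal(computeNtai(seg, build10), 0L)
  # q-telomere event also counts; both telomeres -> 2
  seg <- makeSegs("1", c(1, 20e6 + 1, 80e6 + 1), c(20e6, 80e6, 100e6),
                  c(2, 1, 3), c(1, 1, 1))
  expect_equal(computeNtai(seg, build10), 2L)
  # interior imbalance never counts
  seg <- makeSegs("1", c(1, 30e6 + 1, 60e6 + 1), c(30e6, 60e6, 100e6),
                  c(1, 2, 1), c(1, 0, 1))
  expect_equal(computeNtai(seg, build10), 0L)
})

test_that("LOH score counts sub-chromosomal runs > 15 Mb outside chromosome 17", {
  b <- GenomeBuild(c("1", "17"), c(100e6, 81e6))
  # 20-Mb LOH run on chromosome 1
  seg <- makeSegs("1", c(1, 30e6 + 1, 50e6 + 1), c(30e6, 50e6, 100e6),
                  c(1, 1, 1), c(1, 0, 1))
  expect_equal(computeLohScore(seg, b), 1L)
  # identical run on chromosome 17 is excluded
  seg17 <- makeSegs("17", c(1, 30e6 + 1, 50e6 + 1), c(30e6, 50e6, 81e6),
                    c(1, 1, 1), c(1, 0, 1))
  expect_equal(computeLohScore(seg17, b), 0L)
  # LOH spanning the entire chromosome is excluded
  whole <- makeSegs("1", 1, 100e6, 2, 0)
  expect_equal(computeLohScore(whole, b), 0L)
  # 15-Mb exactly: strict
  seg15 <- makeSegs("1", c(1, 15e6 + 1), c(15e6, 100e6), c(1, 1), c(0, 1))
  expect_equal(computeLohScore(seg15, b), 0L)
  # homozygous deletion (0,0) is not LOH
  hom <- makeSegs("1", c(1, 30e6 + 1), c(30e6, 100e6), c(0, 1), c(0, 1))
  expect_equal(computeLohScore(hom, b), 0L)
})

test_that("LST counts breakpoints with both flanks > 10 Mb after 3-Mb smoothing", {
  # single-segment chromosome
  expect_equal(computeLst(makeSegs("1", 1, 100e6, 2, 1), buildNoCen), 0L)
  # 40 Mb (2,1) | 50 Mb (2,0) | 10 Mb (2,2): only the first breakpoint has
  # both flanks > 10 Mb
  seg <- makeSegs("1", c(1, 40e6 + 1, 90e6 + 1), c(40e6, 90e6, 100e6),
                  c(2, 2, 2), c(1, 0, 2))
  expect_equal(computeLst(seg, buildNoCen), 1L)
  # inserting a 2-Mb segment inside a uniform region changes nothing
  base <- makeSegs("1", c(1, 50e6 + 1), c(50e6, 100e6), c(2, 1), c(1, 1))
  split <- makeSegs("1", c(1, 20e6 + 1, 22e6 + 1, 50e6 + 1),
                    c(20e6, 22e6, 50e6, 100e6),
                    c(2, 3, 2, 1), c(1, 3, 1, 1))
  expect_equal(computeLst(split, buildNoCen), computeLst(base, buildNoCen))
})

test_that("arm-aware LST does not count breakpoints spanning the centromere", {
  # state change exactly at the centromere midpoint: whole-chromosome mode
  # sees one qualifying breakpoint, arm-aware mode none
  seg <- makeSegs("1", c(1, 50e6 + 1), c(50e6, 100e6), c(2, 1), c(1, 1))
  expect_equal(computeLst(seg, buildNoCen), 1L)
  expect_equal(computeLst(seg, build10, armAware = TRUE), 0L)
})

test_that("HRD is the sum of its components and scores are subdivision-invariant", {
  set.seed(41)
  for (r in 1:25) {
    seg <- randomProfile(buildNoCen)
    h <- computeHrd(seg, buildNoCen, lstArgs = list(armAware = FALSE))
    expect_equal(h$hrd, h$ntai + h$loh + h$lst)
    # split every segment longer than 2 Mb in half: identical states
    halves <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i) {
      s <- seg[i, ]
      if (s$end - s$start + 1 < 2e6) return(s)
      mid <- floor((s$start + s$end) / 2)
      rbind(transform(s, end = mid), transform(s, start = mid + 1))
    }))
    h2 <- computeHrd(halves, buildNoCen, lstArgs = list(armAware = FALSE))
    expect_equal(h2[c("ntai", "loh", "lst", "hrd")],
                 h[c("ntai", "loh", "lst", "hrd")])
  }
})

test_that("scar scores match the bin-vector brute-force oracle on random profiles", {
  set.seed(42)
  build5 <- GenomeBuild(as.character(1:5), rep(60e6, 5),
                        cenStart = rep(28e6, 5), cenEnd = rep(32e6, 5))
  for (r in 1:40) {
    arm_aware <- r %% 2 == 0
    seg <- randomProfile(build5)
    h <- computeHrd(seg, build5, lstArgs = list(armAware = arm_aware))
    o <- oracleScars(seg, build5, armAware = arm_aware)
    expect_equal(h$ntai, o$ntai, info = paste("ntai rep", r))
    expect_equal(h$loh, o$loh, info = paste("loh rep", r))
    expect_equal(h$lst, o$lst, info = paste("lst rep", r))
  }
})

test_that("unknown chromosomes and negative components are rejected", {
  expect_error(computeNtai(makeSegs("99", 1, 10e6, 1, 1), build10),
               "unknown chromosome")
})
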