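test_that("shuffling preserves chromosome and width multisets for every seed", {
  gl <- toyGenome()
  set.seed(5)
  peaks <- randomIntervals(gl, 200, maxWidth = 700)
  for (seed in 1:10) {
    sh <- shuffleIntervals(peaks, gl, seed = seed)
    expect_identical(as.character(seqnames(sh)), as.character(seqnames(peaks)))
    expect_identical(width(sh), width(peaks))
    expect_true(all(start(sh) >= 1))
    expect_true(all(end(sh) <= chromLengths(gl)[as.character(seqnames(sh))]))
  }
})

test_that("a full-chromosome interval has no placement freedom", {
  gl <- genomeLayout(c(c1 = 500))
  iv <- GRanges("c1", IRanges(1, 500), seqinfo = asSeqinfo(gl))
  sh <- shuffleIntervals(iv, gl, seed = 1)
  expect_equal(start(sh), 1L)
  expect_equal(end(sh), 500L)
  wide <- GRanges("c1", IRanges(1, 500), seqinfo = Seqinfo("c1", 600))
  expect_error(shuffleIntervals(wide, genomeLayout(c(c1 = 400))),
    "beyond the chromosome")
})

test_that("shuffled start positions are uniform over the admissible range", {
  gl <- genomeLayout(c(c1 = 10000))
  peaks <- GRanges("c1", IRanges(rep(1, 10000), width = 100),
    seqinfo = asSeqinfo(gl))
  sh <- shuffleIntervals(peaks, gl, seed = 99)
  s0 <- start(sh) - 1          # admissible range [0, 9900]
  h <- table(cut(s0, breaks = seq(0, 9901, length.out = 11),
    include.lowest = TRUE, right = FALSE))
  expect_gt(chisq.test(as.vector(h))$p.value, 0.01)
})

test_that("a genome-saturating feature gives ratio 0 and p 1", {
  gl <- toyGenome()
  set.seed(2)
  peaks <- randomIntervals(gl, 100)
  everything <- GRanges(names(chromLengths(gl)),
    IRanges(1, chromLengths(gl)), seqinfo = asSeqinfo(gl))
  res <- permutationEnrichment(peaks, list(all = everything), gl,
    nPerm = 50, seed = 1)
  expect_equal(res$observed, 100L)
  expect_equal(res$expected, 100)
  expect_equal(res$log2_ratio, 0)
  expect_equal(res$p_perm, 1)
})

test_that("permutation p respects the resolution floor and add-one rule", {
  gl <- toyGenome()
  set.seed(4)
  peaks <- randomIntervals(gl, 50)
  feat <- randomIntervals(gl, 20)
  res <- permutationEnrichment(peaks, list(f = feat), gl, nPerm = 10, seed = 2)
  expect_gte(res$p_perm, 1 / 11)
  expect_lte(res$p_perm, 1)
  expect_error(permutationEnrichment(GRanges(seqinfo = asSeqinfo(gl)),
    list(f = feat), gl, nPerm = 10), "empty peak set")
  empty <- GRanges(seqinfo = asSeqinfo(gl))
  res0 <- permutationEnrichment(peaks, list(none = empty), gl, nPerm = 10,
    seed = 3)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$expected, 0)
  expect_true(is.na(res0$log2_ratio))
})

test_that("permutation p approaches the exact placement-enumeration value", {
  ## 2 peaks (widths 3 and 5) and one feature [8,12) on a 20 bp chromosome:
  ## enumerate the full placement grid to get the exact two-sided p
  gl <- genomeLayout(c(c1 = 20))
  si <- asSeqinfo(gl)
  peaks <- GRanges("c1", IRanges(c(1, 10), width = c(3, 5)), seqinfo = si)
  feat <- GRanges("c1", IRanges(9, 12), seqinfo = si)   # 0-based [8,12)
  overlaps1 <- function(s0, w) as.integer(s0 < 12 && 8 < s0 + w)
  counts <- as.vector(outer(0:(20 - 3), 0:(20 - 5), function(a, b)
    mapply(function(x, y) overlaps1(x, 3) + overlaps1(y, 5), a, b)))
  obs <- countPeakOverlaps(peaks, feat)
  pExact <- min(1, 2 * min(mean(counts >= obs), mean(counts <= obs)))
  res <- permutationEnrichment(peaks, list(f = feat), gl, nPerm = 20000,
    seed = 8)
  expect_equal(res$observed, obs)
  expect_lt(abs(res$p_perm - pExact), 0.02)
  expect_equal(res$expected, mean(counts), tolerance = 0.05)
})

test_that("the dedup counting rule is applied inside the permutation test", {
  gl <- genomeLayout(c(c1 = 5000))
  si <- asSeqinfo(gl)
  trna <- GRanges("c1", IRanges(c(101, 201, 301), width = 50), seqinfo = si,
    name = c("t1", "t1", "t2"))
  peaks <- GRanges("c1", IRanges(c(110, 210, 310), width = 20), seqinfo = si)
  res <- permutationEnrichment(peaks, list(tRNA = trna), gl, nPerm = 200,
    seed = 5, dedupLabels = "tRNA")
  expect_equal(res$observed, 2L)       # t1 counted once
  expect_lte(res$expected, 2)          # per-permutation counts capped at #keys
})

test_that("BH adjustment matches the hand-computed step-up and is order-stable", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  set.seed(1)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_true(all(bhAdjust(p) <= 1))
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("chromosome density test reproduces the exact binomial enumeration", {
  gl <- genomeLayout(c(a1 = 3e6, X = 1e6))   # X = 25% of the genome
  si <- asSeqinfo(gl)
  mk <- function(nA, nX) c(
    GRanges("a1", IRanges(seq_len(nA) * 10 + 1, width = 5), seqinfo = si),
    GRanges("X", IRanges(seq_len(nX) * 10 + 1, width = 5), seqinfo = si))
  nullRes <- chromosomeDensityTest(mk(75, 25), gl)
  expect_gt(nullRes$p_binom, 0.9)
  expect_equal(nullRes$p0, 0.25)
  expect_equal(unname(nullRes$per_chrom_density["X"]), 25 / 1)

  skew <- chromosomeDensityTest(mk(1, 9), gl)
  expect_equal(skew$p_binom, bfBinomP(9, 10, 0.25), tolerance = 1e-12)

  gl2 <- genomeLayout(c(a1 = 4e6, X = 1e6))   # p0 = 0.2
  allX <- chromosomeDensityTest(
    GRanges("X", IRanges(seq_len(20) * 10 + 1, width = 5),
      seqinfo = asSeqinfo(gl2)), gl2)
  expect_equal(allX$p_binom, bfBinomP(20, 20, 0.2), tolerance = 1e-12)
  expect_lt(allX$p_binom, 1e-10)

  noX <- genomeLayout(c(a1 = 1e6, a2 = 1e6))
  expect_error(chromosomeDensityTest(mk(1, 1), noX), "no X-flagged")
})

test_that("exact binomial p matches the enumeration oracle on random instances", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    expect_equal(binom.test(x, n, p0)$p.value, bfBinomP(x, n, p0),
      tolerance = 1e-9)
  }
})

test_that("rank-sum test: exchangeability, exact enumeration, approximation", {
  a <- c(3, 1, 4, 1, 5)
  expect_equal(rankSumTest(a, a)$p, 1)
  expect_equal(rankSumTest(c(2, 2), c(2, 2, 2))$p, 1)
  r <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(r$statistic, 0)

  set.seed(31)
  for (rep in 1:60) {
    a <- round(runif(sample(2:6, 1)) * 1000)  # effectively tie-free
    b <- round(runif(sample(2:6, 1)) * 1000)
    if (anyDuplicated(c(a, b))) next
    expect_equal(rankSumTest(a, b)$p, bfRankSumP(a, b), tolerance = 1e-9)
  }
  ## continuity-corrected normal approximation tracks the exact value at 6+6
  for (rep in 1:25) {
    a <- runif(6); b <- runif(6) + 0.3
    if (anyDuplicated(c(a, b))) next
    pApprox <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(pApprox - bfRankSumP(a, b)), 0.02)
  }
})
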