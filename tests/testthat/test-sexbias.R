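test_that("the DE summary reproduces the published worked example", {
  s <- debiasSummary(c(nonDE = 13441, FE = 558, ME = 1282))
  expect_equal(s$pct_sex_biased, 100 * (558 + 1282) / 15281)
  expect_equal(round(s$pct_sex_biased, 1), 12.0)
  expect_equal(s$me_fe_ratio, 1282 / 558)
  expect_gt(s$me_fe_ratio, 2)
})

test_that("the DE summary handles degenerate counts and random tables", {
  z <- debiasSummary(c(nonDE = 10, FE = 0, ME = 0))
  expect_equal(z$pct_sex_biased, 0)
  expect_true(is.na(z$me_fe_ratio))
  set.seed(8)
  for (rep in 1:25) {
    n <- c(nonDE = sample(0:500, 1), FE = sample(1:50, 1), ME = sample(0:100, 1))
    s <- debiasSummary(n)
    expect_equal(s$pct_sex_biased, 100 * (n[["FE"]] + n[["ME"]]) / sum(n))
    expect_equal(s$me_fe_ratio, n[["ME"]] / n[["FE"]])
  }
})

test_that("the DE summary accepts labelled peaks directly", {
  gl <- toyGenome()
  pk <- randomIntervals(gl, 60)
  pk$deGroup <- rep(c("nonDE", "FE", "ME"), c(40, 8, 12))
  s <- debiasSummary(pk)
  expect_equal(s$n_FE, 8)
  expect_equal(s$pct_sex_biased, 100 * 20 / 60)
})

test_that("per-group chromosome profiles recover planted X fractions", {
  gl <- toyGenome(c(`2L` = 235137, `2R` = 252869, `3L` = 281102,
    `3R` = 320793, X = 235422))
  ## all-ME-on-X corner
  si <- asSeqinfo(gl)
  onlyX <- GRanges("X", IRanges(seq_len(50) * 100, width = 50), seqinfo = si,
    deGroup = "ME")
  pr <- deChromosomeProfile(onlyX, gl)
  expect_equal(pr$ME$fraction_on_x, 1.0)

  ## generator-planted 45% ME-on-X at n_ME ~ 1000
  ds <- generateDataset(syntheticConfig(seed = 21, nGenes = 100L,
    nPeaks = 12000L, motifHitsPerMotif = 100L))
  pr2 <- deChromosomeProfile(ds@deLabels, gl)
  expect_equal(pr2$ME$fraction_on_x, 0.45, tolerance = 0.05)
  expect_lt(pr2$ME$p_binom, 1e-6)      # 45% on a 17.8%-length arm

  ## a length-proportional group is rarely called significant
  set.seed(31)
  sig <- 0L
  for (rep in 1:100) {
    fe <- generateNullPeaks(gl, 300)
    fe$deGroup <- "FE"
    sig <- sig + (deChromosomeProfile(fe, gl)$FE$p_binom <= 0.05)
  }
  expect_lte(sig, 10L)
})

test_that("empty DE groups are omitted with a warning", {
  gl <- toyGenome()
  pk <- randomIntervals(gl, 10)
  pk$deGroup <- "nonDE"
  expect_silent(pr <- deChromosomeProfile(pk, gl))
  expect_named(pr, "nonDE")
})

test_that("motif scanning matches hand enumeration on tiny cases", {
  gl <- genomeLayout(c(c1 = 4))
  expect_length(scanMotif(c(c1 = "AAAA"), "ACGT", gl), 0)
  hits <- scanMotif(c(c1 = "AAAA"), "AA", gl)
  expect_equal(start(hits), 1:3)                 # overlapping matches kept
  expect_true(all(as.character(strand(hits)) == "+"))  # rc "TT" never matches
  ## palindromic consensus counted once per position
  pal <- scanMotif(c(c1 = "ACGT"), "ACGT", gl)
  expect_length(pal, 1)
  ## motif longer than the chromosome
  expect_length(scanMotif(c(c1 = "ACGT"), "ACGTACGT", gl), 0)
})

test_that("motif scanning equals the sliding-window oracle on random instances", {
  set.seed(19)
  motifs <- c("CWCC", "GGCGAAGGAG", "CTCCTC", "RYN", "AAWTT")
  for (rep in 1:100) {
    L <- sample(100:300, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
      collapse = "")
    m <- sample(motifs, 1)
    gl <- genomeLayout(c(c1 = L))
    got <- scanMotif(c(c1 = s), m, gl)
    want <- bfScanMotif(s, m)
    expect_equal(start(got) - 1, want$start0)
    expect_equal(as.character(strand(got)), want$strand)
  }
})

test_that("motif scanning on the synthetic genome recovers planted instances", {
  ds <- generateDataset(syntheticConfig(seed = 23, nGenes = 60L,
    nPeaks = 500L, motifHitsPerMotif = 400L))
  for (m in names(ds@motifHits)) {
    got <- scanMotif(ds@sequence, ds@config@motifModels[[m]], ds@genome)
    planted <- ds@motifHits[[m]]
    recovered <- sum(IRanges::overlapsAny(planted, got))
    expect_gte(recovered / length(planted), 0.99)
    expect_gte(length(got), recovered)   # background collisions only add
  }
})

test_that("motif density ratios are exact on constructed counts", {
  gl <- genomeLayout(c(a1 = 1e6, X = 1e6))
  si <- asSeqinfo(gl)
  mk <- function(nA, nX) GRanges(rep(c("a1", "X"), c(nA, nX)),
    IRanges(c(seq_len(nA), seq_len(nX)) * 10, width = 5), seqinfo = si)
  eq <- motifDensityRatio(mk(100, 100), gl)
  expect_equal(eq$log2_x_over_a_per_mb, 0)
  r <- motifDensityRatio(mk(100, 150), gl)
  expect_equal(r$log2_x_over_a_per_mb, log2(1.5))
  expect_equal(r$p_binom, bfBinomP(150, 250, 0.5), tolerance = 1e-12)
  ## swapping which arm carries the X flag negates the log ratio
  glSwap <- genomeLayout(c(a1 = 1e6, X = 1e6), xChrom = "a1")
  rSwap <- motifDensityRatio(mk(100, 150), glSwap)
  expect_equal(rSwap$log2_x_over_a_per_mb, -r$log2_x_over_a_per_mb)
  expect_warning(z <- motifDensityRatio(mk(100, 0), gl), "zero motif hits")
  expect_true(is.na(z$log2_x_over_a_per_mb))
})

test_that("planted 1.4-fold X motif excess is estimated within tolerance", {
  ds <- generateDataset(syntheticConfig(seed = 25, nGenes = 60L,
    nPeaks = 500L, motifHitsPerMotif = 1200L))
  allHits <- unlist(GRangesList(lapply(names(ds@motifHits), function(m)
    granges(scanMotif(ds@sequence, ds@config@motifModels[[m]], ds@genome)))))
  expect_gte(length(allHits), 2000)
  r <- motifDensityRatio(allHits, ds@genome)
  expect_equal(r$log2_x_over_a_per_mb, log2(1.4), tolerance = 0.15 / log2(1.4))
})

test_that("gene labelling applies precedence and partitions all genes", {
  gl <- genomeLayout(c(c1 = 100000))
  si <- asSeqinfo(gl)
  genes <- GRanges("c1", IRanges(c(1001, 21001, 41001, 61001), width = 5000),
    strand = "+", seqinfo = si,
    name = c("gFE", "gME", "gNon", "gNone"))
  peaks <- GRanges("c1",
    IRanges(c(1501, 2501, 21501, 22001, 41501), width = 200), seqinfo = si,
    deGroup = c("FE", "nonDE", "ME", "nonDE", "nonDE"))
  lab <- labelGenes(genes, peaks)
  expect_equal(lab$deGroup, c("FE", "ME", "nonDE", "no_R_loop"))
  ## every gene gets exactly one label
  expect_length(lab$deGroup, length(genes))
  ## precedence is configurable
  lab2 <- labelGenes(genes, peaks, precedence = c("nonDE", "ME", "FE"))
  expect_equal(lab2$deGroup[1], "nonDE")
})

test_that("group comparisons detect planted shifts and respect ordering", {
  set.seed(33)
  nm <- sprintf("g%03d", 1:600)
  labels <- setNames(rep(c("no_R_loop", "nonDE"), each = 300), nm)
  values <- setNames(c(rnorm(300, 0), rnorm(300, 1)), nm)   # 1 SD shift
  cmp <- groupCompare(values, labels, pairs = list(c("no_R_loop", "nonDE")))
  expect_lt(cmp$p, 0.001)
  expect_lt(cmp$median1, cmp$median2)
  ## identical multisets give p = 1
  same <- setNames(c(1:50, 1:50), sprintf("s%03d", 1:100))
  sameLab <- setNames(rep(c("a", "b"), each = 50), names(same))
  expect_equal(groupCompare(same, sameLab, pairs = list(c("a", "b")))$p, 1)
  ## invariance to gene ordering
  sh <- sample(600)
  cmp2 <- groupCompare(values[sh], labels, pairs = list(c("no_R_loop", "nonDE")))
  expect_equal(cmp, cmp2)
  expect_warning(groupCompare(values, labels,
    pairs = list(c("no_R_loop", "FE"))), "empty group")
})

test_that("the presence filter keeps >= minPresent of exactly four arrays", {
  calls <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 0, 0, 0),
    g3 = c(1, 1, 1, 1), g4 = c(0, 0, 0, 0))
  expect_equal(presenceFilter(calls), c("g1", "g3"))
  expect_equal(presenceFilter(calls, minPresent = 0), rownames(calls))
  expect_equal(presenceFilter(calls, minPresent = 4), "g3")
  expect_error(presenceFilter(calls[, 1:3]), "exactly 4")
  bad <- calls; bad[1, 1] <- 2
  expect_error(presenceFilter(bad), "binary")
})
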