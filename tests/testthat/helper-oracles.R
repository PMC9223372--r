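## Brute-force / enumeration oracles, deliberately independent of the
## package's vectorised implementations, plus small fixture builders.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toyGenome <- function(lengths = c(chrA = 10000, chrB = 8000, X = 6000),
    xChrom = intersect("X", names(lengths))) {
  genomeLayout(lengths, xChrom = xChrom)
}

randomIntervals <- function(genome, n, maxWidth = 500) {
  lens <- chromLengths(genome)
  chrom <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  s0 <- floor(runif(n) * (lens[chrom] - w))
  GRanges(chrom, IRanges(start = s0 + 1, width = w),
    seqinfo = asSeqinfo(genome))
}

## all-pairs overlap count, O(n*m) double loop on 0-based half-open coords
bfCountOverlaps <- function(q, s) {
  qc <- as.character(seqnames(q)); sc <- as.character(seqnames(s))
  qs <- start(q) - 1; qe <- end(q); ss <- start(s) - 1; se <- end(s)
  cnt <- 0L
  for (i in seq_along(q)) for (j in seq_along(s)) {
    if (qc[i] != sc[j]) next
    if (qs[i] < se[j] && ss[j] < qe[i]) cnt <- cnt + 1L
  }
  cnt
}

## set of overlapped subject keys
bfCountOverlapsDedup <- function(q, s, key = "name") {
  qc <- as.character(seqnames(q)); sc <- as.character(seqnames(s))
  qs <- start(q) - 1; qe <- end(q); ss <- start(s) - 1; se <- end(s)
  k <- mcols(s)[[key]]
  keys <- character(0)
  for (i in seq_along(q)) for (j in seq_along(s)) {
    if (qc[i] != sc[j]) next
    if (qs[i] < se[j] && ss[j] < qe[i]) keys <- c(keys, k[j])
  }
  length(unique(keys))
}

## all-pairs min half-open gap
bfNearest <- function(q, s) {
  qc <- as.character(seqnames(q)); sc <- as.character(seqnames(s))
  qs <- start(q) - 1; qe <- end(q); ss <- start(s) - 1; se <- end(s)
  vapply(seq_along(q), function(i) {
    best <- NA_real_
    for (j in seq_along(s)) {
      if (qc[i] != sc[j]) next
      gap <- max(0, max(qs[i], ss[j]) - min(qe[i], se[j]))
      if (is.na(best) || gap < best) best <- gap
    }
    best
  }, 0)
}

iupacTable <- list(A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

revcompChar <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
    W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

## sliding-window IUPAC scan of one sequence; returns 0-based starts per
## strand with same-position palindromic matches collapsed to "+"
bfScanMotif <- function(seqstr, motif, bothStrands = TRUE) {
  chars <- strsplit(seqstr, "")[[1]]
  matchAt <- function(pat, pos) {
    p <- strsplit(pat, "")[[1]]
    all(vapply(seq_along(p), function(k)
      chars[pos + k - 1] %in% iupacTable[[p[k]]], TRUE))
  }
  L <- length(chars); m <- nchar(motif)
  if (m > L) return(data.frame(start0 = integer(0), strand = character(0)))
  fwd <- which(vapply(1:(L - m + 1), function(p) matchAt(motif, p), TRUE))
  res <- data.frame(start0 = fwd - 1, strand = rep("+", length(fwd)))
  if (bothStrands) {
    rc <- revcompChar(motif)
    rev <- which(vapply(1:(L - m + 1), function(p) matchAt(rc, p), TRUE))
    rev0 <- setdiff(rev - 1, res$start0)
    res <- rbind(res, data.frame(start0 = rev0,
      strand = rep("-", length(rev0))))
  }
  res[order(res$start0), , drop = FALSE]
}

## piecewise integration of a binned track over [a, b) by explicit
## breakpoint enumeration (independent of the cumsum-based implementation)
bfSpanMean <- function(vals, binSize, a, b, L = length(vals) * binSize) {
  pts <- seq(floor(a / binSize) * binSize, ceiling(b / binSize) * binSize,
    by = binSize)
  pts <- sort(unique(c(a, b, pts[pts > a & pts < b])))
  acc <- 0
  for (k in seq_len(length(pts) - 1)) {
    mid <- (pts[k] + pts[k + 1]) / 2
    v <- if (mid < 0 || mid >= L) 0 else vals[floor(mid / binSize) + 1]
    acc <- acc + v * (pts[k + 1] - pts[k])
  }
  acc / (b - a)
}

## scale-regions row for one region, via bfSpanMean
bfMetageneRow <- function(vals, binSize, g0, g1, strandChr, L,
    upstream = 1000, downstream = 1000, body = 3000, bin = 50) {
  nu <- upstream / bin; nb <- body / bin; nd <- downstream / bin
  le <- g0 + bin * ((-nu):0)
  be <- g0 + (g1 - g0) * (0:nb) / nb
  re <- g1 + bin * (0:nd)
  edges <- c(le, be[-1], re[-1])
  row <- vapply(seq_len(length(edges) - 1), function(k)
    bfSpanMean(vals, binSize, edges[k], edges[k + 1], L), 0)
  if (strandChr == "-") rev(row) else row
}

## exact minimum-likelihood two-sided binomial p by full enumeration
bfBinomP <- function(x, n, p) {
  d <- dbinom(0:n, n, p)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

## exact two-sided rank-sum p by enumerating all group assignments
bfRankSumP <- function(a, b) {
  n <- length(a); m <- length(b)
  pool <- c(a, b); r <- rank(pool)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  combs <- combn(n + m, n)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mean(abs(us - mu) >= abs(u - mu) - 1e-9)
}
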