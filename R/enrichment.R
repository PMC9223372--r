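#' Chromosome- and width-preserving interval shuffle
#'
#' The permutation null of the enrichment test.  Each interval is replaced
#' by one of identical width on its own chromosome, with 0-based start drawn
#' uniformly on \code{[0, chromLength - width]} (bedtools shuffle
#' \code{-chrom} semantics).  Intervals are placed independently, so
#' shuffled intervals may overlap one another.  Names, scores and strand
#' travel with their source interval.
#'
#' @param peaks GRanges to shuffle.
#' @param genome a \linkS4class{GenomeLayout}.
#' @param seed optional integer; when given, placement is reproducible.
#' @return GRanges, parallel to \code{peaks}.
#' @export
shuffleIntervals <- function(peaks, genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .checkOnGenome(peaks, genome, "peaks")
  lens <- chromLengths(genome)[as.character(seqnames(peaks))]
  w <- width(peaks)
  if (any(w > lens))
    stop("an interval is wider than its chromosome; cannot shuffle")
  room <- lens - w + 1          # number of admissible 0-based starts
  start0 <- floor(stats::runif(length(peaks)) * room)
  start0 <- pmin(start0, room - 1)
  out <- peaks
  ranges(out) <- IRanges(start = start0 + 1, width = w)
  out
}

## internal: vectorised shuffle starts for nPerm permutations of one peak
## set; returns a (nPeaks x nPerm) matrix of 0-based starts.
.shuffleStarts <- function(room, nPerm) {
  n <- length(room)
  m <- matrix(floor(stats::runif(n * nPerm) * room), nrow = n)
  pmin(m, room - 1)
}

#' Permutation test of peak/feature enrichment
#'
#' For every feature class: the observed overlap count
#' (\code{\link{countPeakOverlaps}}, or \code{\link{countPeakOverlapsDedup}}
#' for classes listed in \code{dedupLabels}), the mean overlap count over
#' \code{nPerm} chromosome/width-preserving shuffles of the peaks, their
#' log2 ratio, a two-sided permutation p-value and a Benjamini-Hochberg
#' q-value computed across all classes in the call.
#'
#' One shuffle stream is shared by every feature class: each of the
#' \code{nPerm} shuffled peak sets is intersected with all classes, so
#' per-class results are positively correlated exactly as when a shuffled
#' BED file is intersected with every annotation in turn.
#'
#' The p-value doubles the smaller of the two one-sided proportions
#' (permutations with counts \code{>=} observed, resp. \code{<=} observed),
#' applies an add-one correction so p is never 0, and caps at 1:
#' \code{p = min(1, (1 + 2*min(nGreater, nLess)) / (nPerm + 1))}.
#'
#' @param peaks non-empty GRanges.
#' @param features named list of GRanges, one per feature class.
#' @param genome a \linkS4class{GenomeLayout}.
#' @param nPerm number of shuffles (>= 1); 10000 for publication-grade runs.
#' @param seed optional integer for a reproducible shuffle stream.
#' @param dedupLabels feature class names counted with the collapse-by-name
#'   rule (e.g. \code{"tRNA"}).
#' @param dedupKey subject metadata column used by the dedup rule.
#' @return \link[S4Vectors]{DataFrame} with one row per feature class:
#'   \code{feature, observed, expected, log2_ratio, p_perm, q_bh, n_perm}.
#'   An empty feature class yields observed = expected = 0 and
#'   \code{log2_ratio = NA}.
#' @export
permutationEnrichment <- function(peaks, features, genome, nPerm = 10000L,
    seed = NULL, dedupLabels = character(), dedupKey = "name") {
  if (length(peaks) == 0L) stop("empty peak set")
  if (is.null(names(features)) || any(!nzchar(names(features))))
    stop("features must be a named list")
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  .checkOnGenome(peaks, genome, "peaks")
  for (f in features) .checkOnGenome(f, genome, "features")

  labels <- names(features)
  dedup <- labels %in% dedupLabels
  observed <- vapply(seq_along(features), function(i) {
    if (dedup[i]) countPeakOverlapsDedup(peaks, features[[i]], key = dedupKey)
    else countPeakOverlaps(peaks, features[[i]])
  }, 0L)

  n <- length(peaks)
  chrom <- as.character(seqnames(peaks))
  w <- width(peaks)
  lens <- chromLengths(genome)[chrom]
  if (any(w > lens)) stop("an interval is wider than its chromosome")
  room <- lens - w + 1

  dedupKeys <- lapply(seq_along(features), function(i)
    if (dedup[i]) {
      k <- mcols(features[[i]])[[dedupKey]]
      if (is.null(k) || anyNA(k))
        stop("dedup feature class '", labels[i], "' lacks a complete '",
          dedupKey, "' column")
      match(k, unique(k))
    } else NULL)

  counts <- matrix(0L, nrow = nPerm, ncol = length(features))
  chunk <- max(1L, min(nPerm, floor(2e6 / n)))
  done <- 0L
  while (done < nPerm) {
    k <- min(chunk, nPerm - done)
    starts <- .shuffleStarts(room, k)           # n x k, 0-based
    big <- GRanges(rep(chrom, k),
      IRanges(start = as.vector(starts) + 1, width = rep(w, k)),
      seqinfo = asSeqinfo(genome))
    perm <- rep(seq_len(k), each = n)
    for (i in seq_along(features)) {
      hits <- findOverlaps(big, features[[i]], ignore.strand = TRUE)
      if (dedup[i]) {
        pk <- unique(cbind(perm[queryHits(hits)],
          dedupKeys[[i]][subjectHits(hits)]))
        counts[done + seq_len(k), i] <- counts[done + seq_len(k), i] +
          tabulate(pk[, 1], nbins = k)
      } else {
        counts[done + seq_len(k), i] <- counts[done + seq_len(k), i] +
          tabulate(perm[queryHits(hits)], nbins = k)
      }
    }
    done <- done + k
  }

  expected <- colMeans(counts)
  pPerm <- vapply(seq_along(features), function(i) {
    hi <- sum(counts[, i] >= observed[i])
    lo <- sum(counts[, i] <= observed[i])
    min(1, (1 + 2 * min(hi, lo)) / (nPerm + 1))
  }, 0)
  ratio <- ifelse(observed > 0 & expected > 0,
    log2(observed / expected), NA_real_)
  DataFrame(feature = labels, observed = observed, expected = expected,
    log2_ratio = ratio, p_perm = pPerm, q_bh = bhAdjust(pPerm),
    n_perm = as.integer(nPerm))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control with monotonicity
#' enforcement (\code{stats::p.adjust}, method \code{"BH"}); output order
#' matches input order.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted q-values in (0, 1], same order.
#' @export
bhAdjust <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value list")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Binomial test of X-versus-autosome peak density
#'
#' Peak counts are normalised by chromosome length in megabases; under the
#' null of equal density everywhere, the number of peaks on the X is
#' Binomial(total, p0) with p0 the X's share of genome length.  The
#' two-sided p-value is the exact minimum-likelihood binomial test
#' (\code{stats::binom.test} convention: all outcomes at most as probable
#' as the observed one are summed).
#'
#' @param peaks GRanges with at least one interval.
#' @param genome a \linkS4class{GenomeLayout} with an X-flagged arm.
#' @return list of class \code{"DensityTestResult"} with elements
#'   \code{per_chrom_density} (peaks/Mb), \code{x_count}, \code{total},
#'   \code{p0}, \code{p_binom}.
#' @export
chromosomeDensityTest <- function(peaks, genome) {
  if (length(xChrom(genome)) == 0L)
    stop("layout has no X-flagged chromosome")
  if (length(peaks) == 0L) stop("no peaks")
  .checkOnGenome(peaks, genome, "peaks")
  lens <- chromLengths(genome)
  cnt <- table(factor(as.character(seqnames(peaks)), levels = names(lens)))
  dens <- as.numeric(cnt) / (lens / 1e6)
  names(dens) <- names(lens)
  xc <- as.integer(cnt[[xChrom(genome)]])
  tot <- length(peaks)
  p0 <- xLengthShare(genome)
  structure(list(per_chrom_density = dens, x_count = xc, total = tot,
    p0 = p0,
    p_binom = stats::binom.test(xc, tot, p = p0)$p.value),
    class = "DensityTestResult")
}

#' @export
print.DensityTestResult <- function(x, ...) {
  cat("X-vs-autosome peak density test\n")
  cat("  peaks/Mb:", paste(names(x$per_chrom_density),
    sprintf("%.2f", x$per_chrom_density), sep = "=", collapse = ", "), "\n")
  cat(sprintf("  X peaks: %d / %d (null share p0 = %.4f)\n",
    x$x_count, x$total, x$p0))
  cat(sprintf("  two-sided binomial p = %.3g\n", x$p_binom))
  invisible(x)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Wilcoxon rank-sum comparison with midrank ties: exact
#' enumeration when the pooled sample size is at most 12 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.  Two identical multisets (or all values equal) give p = 1
#' by convention.
#'
#' @param a,b non-empty numeric vectors.
#' @return list with \code{statistic} (the Mann-Whitney U of group a) and
#'   \code{p} (two-sided).
#' @export
rankSumTest <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(statistic = U, p = 1))
  exact <- (length(a) + length(b) <= 12L) && !anyDuplicated(pooled)
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- res$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = U, p = min(1, p))
}
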