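#' Scale-regions metagene matrix
#'
#' deeptools-computeMatrix-style scale-regions binning: for each stranded
#' region, \code{upstream/bin} fixed-width flank bins, \code{body/bin} bins
#' over the region body rescaled to a common length, and
#' \code{downstream/bin} flank bins, each bin value the length-weighted
#' average of the overlapping track bins (computed exactly on the
#' piecewise-constant track, fractional body-bin boundaries included).
#' Rows of minus-strand regions are reversed so column 1 is always the
#' 5'-most bin.  Flank base pairs falling outside the chromosome contribute
#' zero signal at full weight.  With the default geometry (1000/3000/1000 at
#' 50 bp) the matrix has 20 + 60 + 20 = 100 columns.
#'
#' @param regions stranded GRanges (strand + or -); an optional metadata
#'   column named by \code{groupBy} supplies row group labels.
#' @param track a \linkS4class{SignalTrack} on the same genome.
#' @param upstream,downstream flank lengths in bp, multiples of \code{bin}.
#' @param body common rescaled body length in bp, a multiple of \code{bin}.
#' @param bin bin width in bp.
#' @param skipZeros drop rows whose every bin is zero (deeptools
#'   \code{--skipZeros}).
#' @param groupBy name of the region metadata column holding group labels.
#' @return a \linkS4class{MetageneMatrix}.
#' @export
metageneMatrix <- function(regions, track, upstream = 1000L,
    downstream = 1000L, body = 3000L, bin = 50L, skipZeros = TRUE,
    groupBy = "group") {
  if (upstream %% bin || downstream %% bin || body %% bin)
    stop("upstream, downstream and body must be multiples of bin")
  st <- as.character(strand(regions))
  if (any(!st %in% c("+", "-")))
    stop("regions must be stranded (+ or -)")
  .checkOnGenome(regions, trackGenome(track), "regions")
  nu <- upstream %/% bin; nb <- body %/% bin; nd <- downstream %/% bin
  vals <- trackValues(track)
  tb <- binSize(track)

  rows <- matrix(NA_real_, nrow = length(regions), ncol = nu + nb + nd)
  for (i in seq_along(regions)) {
    chr <- as.character(seqnames(regions))[i]
    v <- vals[[chr]]
    g0 <- start(regions)[i] - 1; g1 <- end(regions)[i]
    # left flank, body, right flank edges in genomic coordinates
    le <- g0 + bin * (seq_len(nu + 1) - nu - 1)
    be <- g0 + (g1 - g0) * (0:nb) / nb
    re <- g1 + bin * (0:nd)
    edges <- c(le, be[-1], re[-1])
    widths <- diff(edges)
    cell <- .trackIntegral(v, tb, edges[-length(edges)], edges[-1],
      chromLen = chromLengths(trackGenome(track))[[chr]]) / widths
    if (st[i] == "-") cell <- rev(cell)
    rows[i, ] <- cell
  }
  grp <- mcols(regions)[[groupBy]]
  if (is.null(grp)) grp <- rep("all", length(regions))
  rn <- regions$name
  if (is.null(rn)) rn <- as.character(seq_along(regions))
  keep <- rep(TRUE, length(regions))
  if (skipZeros) keep <- rowSums(rows != 0) > 0
  new("MetageneMatrix", values = `rownames<-`(rows[keep, , drop = FALSE], rn[keep]),
    group = as.character(grp)[keep],
    upstreamBins = as.integer(nu), bodyBins = as.integer(nb),
    downstreamBins = as.integer(nd), binSize = as.integer(bin),
    nDropped = as.integer(sum(!keep)))
}

#' Per-group metagene mean and SEM profiles
#'
#' For each group label of the matrix rows: the per-bin mean and standard
#' error of the mean (sample SD / sqrt(n)).  A single-region group gets
#' SEM 0 with a warning.
#'
#' @param mat a \linkS4class{MetageneMatrix}.
#' @return named list, one element per group, each a list with
#'   \code{mean}, \code{sem} (numeric per bin) and \code{n_regions}.
#' @export
metageneProfile <- function(mat) {
  if (nrow(mat@values) == 0L) stop("empty metagene matrix")
  out <- lapply(split(seq_len(nrow(mat@values)), mat@group), function(idx) {
    m <- mat@values[idx, , drop = FALSE]
    n <- nrow(m)
    if (n == 1L) {
      warning("group with a single region: SEM set to 0")
      sem <- rep(0, ncol(m))
    } else {
      sem <- apply(m, 2, stats::sd) / sqrt(n)
    }
    list(mean = colMeans(m), sem = sem, n_regions = n)
  })
  out
}

#' Binomially thin an integer-count track
#'
#' Emulates read-level downsampling (samtools \code{-s}) on binned counts:
#' each bin count c is replaced by a Binomial(c, fraction) draw.
#'
#' @param track integer-valued \linkS4class{SignalTrack}.
#' @param fraction retention probability in [0, 1].
#' @param seed optional integer for reproducibility; \code{NULL} draws from
#'   the current RNG stream.
#' @param chroms chromosomes to thin; \code{NULL} thins all (used to
#'   depth-match a subset of arms, e.g. thin autosomes only).
#' @return a \linkS4class{SignalTrack}.
#' @export
thinTrack <- function(track, fraction, seed = NULL, chroms = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("fraction must be a single value in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  vals <- trackValues(track)
  if (any(vapply(vals, function(v) any(v != floor(v)), TRUE)))
    stop("thinTrack requires an integer-valued track")
  target <- if (is.null(chroms)) names(vals) else chroms
  for (chr in target) {
    v <- vals[[chr]]
    vals[[chr]] <- as.numeric(stats::rbinom(length(v), as.integer(v), fraction))
  }
  signalTrack(vals, binSize = binSize(track), genome = trackGenome(track))
}

#' Window-Poisson peak caller
#'
#' A deliberately simple stand-in caller used to study how peak counts
#' respond to sequencing depth; it is not a MACS2 reimplementation (no
#' local-lambda, duplicate or fragment model).  For every sliding window of
#' \code{windowBins} bins (step one bin), the IP window count is tested
#' against a Poisson rate \code{lambda = controlWindowCount * ipTotal /
#' controlTotal}, floored at the genome-wide background rate (mean IP count
#' per window); windows with upper-tail p below \code{pThreshold} are
#' merged into peaks when adjacent or overlapping.
#'
#' @param ip,control integer-count \linkS4class{SignalTrack}s on identical
#'   binnings.
#' @param pThreshold Poisson upper-tail p-value cutoff.
#' @param windowBins window width in bins.
#' @return GRanges of called peaks.
#' @export
callPeaksPoisson <- function(ip, control, pThreshold = 1e-3, windowBins = 4L) {
  windowBins <- as.integer(windowBins)
  if (binSize(ip) != binSize(control))
    stop("ip and control must share a binning")
  ipv <- trackValues(ip); cv <- trackValues(control)
  if (!identical(names(ipv), names(cv)))
    stop("ip and control must cover the same chromosomes")
  ipTot <- sum(vapply(ipv, sum, 0))
  cTot <- sum(vapply(cv, sum, 0))
  if (cTot <= 0) stop("control track has zero total signal")
  r <- ipTot / cTot
  nWinTot <- sum(vapply(ipv, function(v) max(0L, length(v) - windowBins + 1L), 0L))
  lambdaBg <- ipTot / sum(lengths(ipv)) * windowBins
  gl <- trackGenome(ip)
  peaks <- GRanges(seqinfo = asSeqinfo(gl))
  if (pThreshold <= 0) return(peaks)
  b <- binSize(ip)
  lens <- chromLengths(gl)
  out <- list()
  for (chr in names(ipv)) {
    v <- ipv[[chr]]; cc <- cv[[chr]]
    nw <- length(v) - windowBins + 1L
    if (nw < 1L) next
    winSum <- function(x) {
      cs <- c(0, cumsum(x))
      cs[(windowBins + 1):(length(x) + 1)] - cs[1:nw]
    }
    wi <- winSum(v); wc <- winSum(cc)
    lambda <- pmax(wc * r, lambdaBg)
    p <- stats::ppois(wi - 1, lambda, lower.tail = FALSE)
    sig <- which(p < pThreshold)
    if (length(sig) == 0L) next
    s0 <- (sig - 1) * b
    e0 <- pmin((sig - 1 + windowBins) * b, lens[[chr]])
    out[[chr]] <- reduce(.grOnGenome(rep(chr, length(sig)), s0, e0, gl),
      min.gapwidth = 1L)
  }
  if (length(out) == 0L) return(peaks)
  sort(do.call(c, unname(out)))
}

#' Sequencing-depth titration of peak counts
#'
#' For every retention fraction and replicate seed, both tracks are
#' binomially thinned and peaks are called; reported is the mean called
#' peak count per chromosome across replicates.  This reproduces the
#' depth-dependence of ChIP/DRIP peak counts (no saturation), the reason
#' the analysis pipeline depth-matches chromosomes before comparing peak
#' densities.
#'
#' @param ip,control integer-count \linkS4class{SignalTrack}s.
#' @param fractions retention fractions in [0, 1].
#' @param seeds one integer seed per replicate.
#' @param pThreshold,windowBins passed to \code{\link{callPeaksPoisson}}.
#' @return data.frame with columns \code{fraction, chrom, mean_count}.
#' @export
depthTitration <- function(ip, control, fractions, seeds,
    pThreshold = 1e-3, windowBins = 4L) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  chroms <- chromNames(trackGenome(ip))
  rows <- list()
  for (f in fractions) {
    acc <- matrix(0, nrow = length(seeds), ncol = length(chroms),
      dimnames = list(NULL, chroms))
    for (j in seq_along(seeds)) {
      set.seed(seeds[j])
      ipThin <- thinTrack(ip, f)
      ctThin <- thinTrack(control, f)
      pk <- callPeaksPoisson(ipThin, ctThin, pThreshold = pThreshold,
        windowBins = windowBins)
      tab <- table(factor(as.character(seqnames(pk)), levels = chroms))
      acc[j, ] <- as.numeric(tab)
    }
    rows[[length(rows) + 1L]] <- data.frame(fraction = f, chrom = chroms,
      mean_count = colMeans(acc), row.names = NULL)
  }
  do.call(rbind, rows)
}
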