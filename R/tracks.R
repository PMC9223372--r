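#' Construct a SignalTrack
#'
#' @param values named list of per-chromosome numeric vectors (one value per
#'   bin), or a single number to fill every bin of every chromosome.
#' @param binSize bin width in bp.
#' @param genome the \linkS4class{GenomeLayout}.
#' @return a \linkS4class{SignalTrack}.
#' @examples
#' gl <- genomeLayout(c(chr1 = 1000))
#' tr <- signalTrack(list(chr1 = rep(2, 10)), binSize = 100, genome = gl)
#' trackTotal(tr)
#' @export
signalTrack <- function(values, binSize, genome) {
  binSize <- as.integer(binSize)
  if (is.numeric(values) && length(values) == 1L) {
    fill <- values
    values <- lapply(chromLengths(genome), function(L)
      rep(fill, ceiling(L / binSize)))
  }
  new("SignalTrack", binSize = binSize, values = values, genome = genome)
}

#' @describeIn signalTrack bin width in bp.
#' @param x a SignalTrack.
#' @export
binSize <- function(x) x@binSize

#' @describeIn signalTrack the per-chromosome value list.
#' @export
trackValues <- function(x) x@values

#' @describeIn signalTrack sum of value x bin-width over the genome
#'   (partial last bins weighted by their true width).
#' @export
trackTotal <- function(x) {
  len <- chromLengths(x@genome)
  tot <- 0
  for (chr in names(x@values)) {
    w <- rep(x@binSize, length(x@values[[chr]]))
    w[length(w)] <- len[[chr]] - (length(w) - 1L) * x@binSize
    tot <- tot + sum(x@values[[chr]] * w)
  }
  tot
}

#' @describeIn signalTrack the GenomeLayout the track is defined on.
#' @export
trackGenome <- function(x) x@genome

## internal: integral of the piecewise-constant track over [a, b), a,b real
## 0-based genomic positions on one chromosome.  Exact (no discretisation).
.trackIntegral <- function(vals, binSize, a, b, chromLen = length(vals) * binSize) {
  nb <- length(vals)
  csum <- c(0, cumsum(vals)) * binSize
  F <- function(x) {                     # integral over [0, x)
    x <- pmin(pmax(x, 0), chromLen)
    k <- pmin(floor(x / binSize), nb - 1)
    csum[k + 1] + vals[k + 1] * (x - k * binSize)
  }
  F(b) - F(a)
}

## internal: length-weighted mean of track values over [a, b) (0-based,
## half-open); spans clipped to the track extent contribute zero signal
## over the clipped part but full weight is taken over the in-track part.
.spanMean <- function(vals, binSize, a, b) {
  stopifnot(b > a)
  .trackIntegral(vals, binSize, a, b) / (b - a)
}
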