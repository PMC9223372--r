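#' Count overlapping query/subject pairs
#'
#' The observed statistic of the permutation enrichment test: the number of
#' (query, subject) pairs on the same chromosome sharing at least 1 bp
#' (bedtools-intersect pair semantics, so one peak overlapping two feature
#' copies counts twice).  Strand is ignored.
#'
#' @param query,subject GRanges on the same genome.
#' @return a single non-negative integer.
#' @seealso \code{\link{countPeakOverlapsDedup}} for the collapse-by-name
#'   variant used for multi-copy features such as tRNAs.
#' @export
countPeakOverlaps <- function(query, subject) {
  .checkSameGenome(query, subject)
  length(findOverlaps(query, subject, ignore.strand = TRUE))
}

#' Count overlapped subject keys, each at most once
#'
#' Variant of \code{\link{countPeakOverlaps}} in which every distinct
#' subject name contributes at most one count, no matter how many copies of
#' it are overlapped or by how many query intervals.  This is the counting
#' rule used for tRNA genes, where multi-copy identical gene sequences are
#' collapsed to a single countable unit.
#'
#' @param query,subject GRanges on the same genome; \code{subject} must
#'   carry a complete key column.
#' @param key name of the subject metadata column holding the identity key.
#' @return number of distinct subject keys overlapped by at least one query.
#' @export
countPeakOverlapsDedup <- function(query, subject, key = "name") {
  .checkSameGenome(query, subject)
  k <- mcols(subject)[[key]]
  if (is.null(k) || anyNA(k))
    stop("subject intervals must all carry a '", key, "' key")
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  length(unique(k[subjectHits(hits)]))
}

#' Distance to the nearest subject interval on the same chromosome
#'
#' Half-open gap distance: 0 for overlapping or book-ended intervals, else
#' the number of base pairs strictly between the two.  Queries on a
#' chromosome with no subject interval get \code{NA}.  Strand is ignored.
#' Used for distance-to-CES analyses.
#'
#' @param query,subject GRanges on the same genome.
#' @return numeric vector, one distance per query interval.
#' @export
nearestDistance <- function(query, subject) {
  .checkSameGenome(query, subject)
  out <- rep(NA_real_, length(query))
  if (length(query) == 0L || length(subject) == 0L) return(out)
  hits <- distanceToNearest(query, subject, ignore.strand = TRUE)
  out[queryHits(hits)] <- mcols(hits)$distance
  out
}

#' Length-weighted mean track signal over regions
#'
#' For each region, the mean of the overlapping track bin values weighted
#' by the number of base pairs of the region each bin covers (partial bins
#' get fractional weight).  This is the per-gene summary compared across DE
#' groups for MOF / H4K16ac signal.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param regions GRanges on the track's genome.
#' @return numeric vector, one mean per region.
#' @export
meanSignalOverRegions <- function(track, regions) {
  vals <- trackValues(track)
  chrom <- as.character(seqnames(regions))
  missing <- setdiff(unique(chrom), names(vals))
  if (length(missing))
    stop("regions on chromosomes absent from the track: ",
      paste(missing, collapse = ", "))
  .checkOnGenome(regions, trackGenome(track), "regions")
  b <- binSize(track)
  vapply(seq_along(regions), function(i)
    .spanMean(vals[[chrom[i]]], b, start(regions)[i] - 1, end(regions)[i]),
    0)
}
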