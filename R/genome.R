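#' Construct a GenomeLayout
#'
#' @param lengths named numeric vector of chromosome lengths in bp, in the
#'   order chromosomes should be reported.
#' @param xChrom name of the X-flagged arm.  Defaults to the chromosome
#'   literally named \code{"X"} when present, else no X flag.
#' @return a \linkS4class{GenomeLayout}.
#' @examples
#' gl <- genomeLayout(c(`2L` = 1e5, `2R` = 1.2e5, X = 8e4))
#' chromLengths(gl); xChrom(gl)
#' @export
genomeLayout <- function(lengths, xChrom = intersect("X", names(lengths))) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  si <- Seqinfo(seqnames = names(lengths), seqlengths = as.integer(lengths))
  new("GenomeLayout", seqinfo = si, xChrom = as.character(xChrom))
}

#' Read a two-column chrom.sizes file
#'
#' Whitespace-delimited lines of \code{name length}; blank lines ignored.
#' Duplicate names, non-integer or non-positive lengths raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @param xChrom X-arm name; \code{NULL} auto-detects a chromosome named
#'   \code{"X"}.
#' @return a \linkS4class{GenomeLayout} with entries in file order.
#' @export
readChromSizes <- function(path, xChrom = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no chromosomes in '", path, "'")
  nm <- character(length(keep)); len <- numeric(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(f) < 2L)
      stop(sprintf("%s line %d: expected two columns", path, ln))
    v <- suppressWarnings(as.numeric(f[2]))
    if (is.na(v) || v != floor(v))
      stop(sprintf("%s line %d: length '%s' is not an integer", path, ln, f[2]))
    if (v <= 0)
      stop(sprintf("%s line %d: length must be positive", path, ln))
    if (f[1] %in% nm[seq_len(i - 1L)])
      stop(sprintf("%s line %d: duplicate chromosome name '%s'", path, ln, f[1]))
    nm[i] <- f[1]; len[i] <- v
  }
  names(len) <- nm
  if (is.null(xChrom)) xChrom <- intersect("X", nm)
  genomeLayout(len, xChrom = xChrom)
}

#' @describeIn genomeLayout chromosome names, in layout order.
#' @param x a GenomeLayout.
#' @export
chromNames <- function(x) seqnames(x@seqinfo)

#' @describeIn genomeLayout named chromosome lengths (bp).
#' @export
chromLengths <- function(x) {
  len <- as.numeric(seqlengths(x@seqinfo))
  names(len) <- seqnames(x@seqinfo)
  len
}

#' @describeIn genomeLayout name of the X-flagged arm (character(0) if none).
#' @export
xChrom <- function(x) x@xChrom

#' @describeIn genomeLayout logical vector: which chromosomes are X.
#' @export
isX <- function(x) chromNames(x) %in% x@xChrom

#' @describeIn genomeLayout total genome size in bp.
#' @export
genomeSize <- function(x) sum(chromLengths(x))

#' @describeIn genomeLayout fraction of the genome on the X arm.
#' @export
xLengthShare <- function(x) {
  if (length(x@xChrom) == 0L) stop("layout has no X-flagged chromosome")
  unname(chromLengths(x)[x@xChrom] / genomeSize(x))
}

#' @describeIn genomeLayout the layout as a Seqinfo object.
#' @export
asSeqinfo <- function(x) x@seqinfo

## internal: check a GRanges fits a layout; error otherwise
.checkOnGenome <- function(gr, genome, what = "intervals") {
  bad <- !(as.character(seqnames(gr)) %in% chromNames(genome))
  if (any(bad))
    stop(sprintf("%s on chromosomes absent from the layout: %s", what,
      paste(unique(as.character(seqnames(gr))[bad]), collapse = ", ")))
  lim <- chromLengths(genome)[as.character(seqnames(gr))]
  over <- end(gr) > lim
  if (any(over))
    stop(sprintf("%d %s extend beyond the chromosome end", sum(over), what))
  invisible(TRUE)
}

## internal: do two GRanges live on compatible genomes?
.checkSameGenome <- function(a, b) {
  common <- intersect(seqlevels(a), seqlevels(b))
  la <- seqlengths(a)[common]; lb <- seqlengths(b)[common]
  known <- !is.na(la) & !is.na(lb)
  if (any(la[known] != lb[known]))
    stop("interval sets are defined on different genomes ",
      "(mismatched chromosome lengths)")
  invisible(TRUE)
}

## internal: GRanges constructor on a layout from 0-based half-open coords
.grOnGenome <- function(chrom, start0, end0, genome, strand = "*", ...) {
  if (length(strand) == 1L) strand <- rep(strand, length(chrom))
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0),
    strand = strand, seqinfo = asSeqinfo(genome))
  mc <- list(...)
  if (length(mc)) mcols(gr) <- DataFrame(mc)
  gr
}
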