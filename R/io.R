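#' Read a BED3/BED6 file into a GRanges
#'
#' Accepts the BED3 minimum; columns 4-6 (name, score, strand) are used when
#' present.  \code{track}, \code{browser} and \code{#} comment lines are
#' skipped.  Coordinates on disk are 0-based half-open and are converted to
#' the 1-based closed convention of \link[GenomicRanges]{GRanges}.  Records
#' with \code{start >= end}, ends beyond the chromosome, or chromosomes
#' absent from \code{genome} raise an error naming the line number: a BED
#' file that does not fit the declared genome is treated as a bug, not as
#' data to be trimmed.
#'
#' @param path file path.
#' @param genome a \linkS4class{GenomeLayout} to validate against.
#' @return GRanges with \code{name} and \code{score} metadata columns when
#'   the file provides them; strand \code{"."} becomes \code{"*"}.
#' @seealso \code{\link{writeBed}}
#' @export
readBed <- function(path, genome) {
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  keep <- which(!skip)
  if (length(keep) == 0L)
    return(.grOnGenome(character(0), numeric(0), numeric(0), genome))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop(sprintf("%s line %d: fewer than 3 tab-separated columns",
      path, keep[which(ncol < 3L)[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0
  if (any(bad))
    stop(sprintf("%s line %d: invalid coordinates (need 0 <= start < end)",
      path, keep[which(bad)[1]]))
  lens <- chromLengths(genome)
  unknown <- !(chrom %in% names(lens))
  if (any(unknown))
    stop(sprintf("%s line %d: unknown chromosome '%s'",
      path, keep[which(unknown)[1]], chrom[which(unknown)[1]]))
  over <- end0 > lens[chrom]
  if (any(over))
    stop(sprintf("%s line %d: end %d beyond chromosome end (%d)",
      path, keep[which(over)[1]], end0[which(over)[1]],
      lens[[chrom[which(over)[1]]]]))
  strand <- rep("*", length(keep))
  has6 <- ncol >= 6L
  strand[has6] <- vapply(fields[has6], `[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- .grOnGenome(chrom, start0, end0, genome, strand = strand)
  if (any(ncol >= 4L)) {
    nm <- rep(NA_character_, length(keep))
    nm[ncol >= 4L] <- vapply(fields[ncol >= 4L], `[`, "", 4L)
    gr$name <- nm
  }
  if (any(ncol >= 5L)) {
    sc <- rep(NA_real_, length(keep))
    sc[ncol >= 5L] <- suppressWarnings(
      as.numeric(vapply(fields[ncol >= 5L], `[`, "", 5L)))
    gr$score <- sc
  }
  gr
}

#' Write a GRanges as BED
#'
#' Emits BED6 when \code{x} carries \code{name}/\code{score}/strand
#' information, BED3 otherwise.  Coordinates are converted back to 0-based
#' half-open.
#'
#' @param x GRanges.
#' @param path output path.
#' @export
writeBed <- function(x, path) {
  df <- data.frame(chrom = as.character(seqnames(x)),
    start = start(x) - 1L, end = end(x))
  st <- as.character(strand(x))
  bed6 <- !is.null(x$name) || !is.null(x$score) || any(st != "*")
  if (bed6) {
    df$name <- if (is.null(x$name)) "." else ifelse(is.na(x$name), ".", x$name)
    df$score <- if (is.null(x$score)) 0 else ifelse(is.na(x$score), 0, x$score)
    df$strand <- ifelse(st == "*", ".", st)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a SignalTrack
#'
#' Four-column \code{chrom start end value} records (0-based half-open) are
#' rebinned onto a fixed-width grid by length-weighted averaging: each
#' target bin's value is the integral of the piecewise-constant bedGraph
#' signal over the bin divided by the covered width, with unreported base
#' pairs contributing zero.
#'
#' @param path file path.
#' @param genome a \linkS4class{GenomeLayout}.
#' @param binSize target bin width in bp.
#' @return a \linkS4class{SignalTrack}.
#' @export
readBedGraph <- function(path, genome, binSize = 50L) {
  lines <- readLines(path, warn = FALSE)
  skip <- grepl("^(track|browser|#)", lines) | !nzchar(trimws(lines))
  keep <- which(!skip)
  fields <- strsplit(lines[keep], "[ \t]+")
  if (any(lengths(fields) < 4L))
    stop(sprintf("%s line %d: expected 4 columns", path,
      keep[which(lengths(fields) < 4L)[1]]))
  chrom <- vapply(fields, `[`, "", 1L)
  s0 <- as.numeric(vapply(fields, `[`, "", 2L))
  e0 <- as.numeric(vapply(fields, `[`, "", 3L))
  val <- as.numeric(vapply(fields, `[`, "", 4L))
  if (any(is.na(s0) | is.na(e0) | is.na(val) | s0 < 0 | s0 >= e0))
    stop(path, ": invalid bedGraph record")
  lens <- chromLengths(genome)
  if (any(!(chrom %in% names(lens))))
    stop(path, ": unknown chromosome ",
      setdiff(unique(chrom), names(lens))[1])
  binSize <- as.integer(binSize)
  values <- lapply(chromLengths(genome), function(L)
    numeric(ceiling(L / binSize)))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    nb <- length(values[[chr]])
    acc <- numeric(nb)                  # integral of signal per bin
    for (j in i) {
      b1 <- floor(s0[j] / binSize); b2 <- ceiling(e0[j] / binSize) - 1
      b2 <- min(b2, nb - 1)
      bs <- b1:b2
      cov <- pmin(e0[j], (bs + 1) * binSize) - pmax(s0[j], bs * binSize)
      acc[bs + 1] <- acc[bs + 1] + val[j] * cov
    }
    w <- rep(binSize, nb)
    w[nb] <- lens[[chr]] - (nb - 1) * binSize
    values[[chr]] <- acc / w
  }
  signalTrack(values, binSize = binSize, genome = genome)
}

#' Write a SignalTrack as bedGraph
#'
#' One record per bin (zero-valued bins included); the last bin of each
#' chromosome is clipped at the chromosome end.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
  lens <- chromLengths(trackGenome(track))
  rows <- lapply(names(trackValues(track)), function(chr) {
    v <- trackValues(track)[[chr]]
    s <- (seq_along(v) - 1L) * binSize(track)
    e <- pmin(s + binSize(track), lens[[chr]])
    data.frame(chrom = chr, start = s, end = e, value = v)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column motif table (label, IUPAC consensus)
#'
#' @param path whitespace-delimited text, comment lines starting \code{#}
#'   ignored.
#' @return named character vector of consensus strings.
#' @export
readMotifTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (any(lengths(fields) < 2L))
    stop(path, ": each motif line needs a label and a consensus")
  motifs <- toupper(vapply(fields, `[`, "", 2L))
  names(motifs) <- vapply(fields, `[`, "", 1L)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", motifs)
  if (any(bad))
    stop(path, ": invalid IUPAC letters in motif ", names(motifs)[bad][1])
  motifs
}
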