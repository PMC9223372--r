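#' Summarise sex-biased peak classes
#'
#' From nonDE/FE/ME peak labels: class sizes, the percentage of peaks that
#' are sex-biased (FE + ME over all), and the male:female excess ME/FE.
#'
#' @param x either a GRanges with a \code{deGroup} metadata column, or a
#'   named count vector with entries \code{nonDE}, \code{FE}, \code{ME}.
#' @return list with \code{n_nonDE}, \code{n_FE}, \code{n_ME},
#'   \code{pct_sex_biased} (0-100) and \code{me_fe_ratio} (\code{NA} when
#'   FE = 0).
#' @examples
#' debiasSummary(c(nonDE = 13441, FE = 558, ME = 1282))
#' @export
debiasSummary <- function(x) {
  if (is(x, "GRanges")) {
    g <- x$deGroup
    if (is.null(g)) stop("peaks lack a 'deGroup' column")
    x <- c(nonDE = sum(g == "nonDE"), FE = sum(g == "FE"), ME = sum(g == "ME"))
  }
  if (!all(c("nonDE", "FE", "ME") %in% names(x)))
    stop("counts must name nonDE, FE and ME")
  n <- sum(x[c("nonDE", "FE", "ME")])
  if (n == 0L) stop("no peaks")
  list(
    n_nonDE = unname(x[["nonDE"]]), n_FE = unname(x[["FE"]]),
    n_ME = unname(x[["ME"]]),
    pct_sex_biased = 100 * (x[["FE"]] + x[["ME"]]) / n,
    me_fe_ratio = if (x[["FE"]] > 0) x[["ME"]] / x[["FE"]] else NA_real_)
}

#' Per-chromosome density and X fraction by DE group
#'
#' For each DE group with at least one peak: peaks/Mb per chromosome, the
#' fraction of the group's peaks on the X, and the two-sided binomial
#' p-value against the length-share null
#' (\code{\link{chromosomeDensityTest}}).  Empty groups are omitted with a
#' warning.
#'
#' @param peaks GRanges with a \code{deGroup} column.
#' @param genome a \linkS4class{GenomeLayout} with an X arm.
#' @return named list of \code{DensityTestResult} (one per group) with an
#'   added \code{fraction_on_x} element.
#' @export
deChromosomeProfile <- function(peaks, genome) {
  g <- peaks$deGroup
  if (is.null(g)) stop("peaks lack a 'deGroup' column")
  groups <- unique(g)
  out <- list()
  for (lab in groups) {
    sub <- peaks[g == lab]
    if (length(sub) == 0L) {
      warning("DE group '", lab, "' has no peaks; omitted")
      next
    }
    res <- chromosomeDensityTest(sub, genome)
    res$fraction_on_x <- res$x_count / res$total
    out[[lab]] <- res
  }
  if (length(out) == 0L) warning("no non-empty DE group")
  out
}

## IUPAC degeneracy map (also used by the test oracles' ground truth docs)
.iupac <- c(A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan sequences for an IUPAC consensus motif
#'
#' Exact consensus matching under IUPAC degeneracy
#' (\link[Biostrings]{matchPattern} with \code{fixed = "subject"}, so
#' ambiguity codes in the motif are expanded but \code{N}s in the sequence
#' never match).  All overlapping occurrences are reported.  With
#' \code{bothStrands}, the reverse complement is also scanned and hits are
#' reported in forward coordinates with strand \code{"-"}; a palindromic
#' match at the same position is counted once.
#'
#' @param seqs named \link[Biostrings]{DNAStringSet} (or named character),
#'   one entry per chromosome.
#' @param motif IUPAC consensus string.
#' @param genome a \linkS4class{GenomeLayout} matching \code{seqs}.
#' @param bothStrands scan the reverse complement too.
#' @param label optional motif label stored in the \code{name} column.
#' @return GRanges of motif occurrences.
#' @export
scanMotif <- function(seqs, motif, genome, bothStrands = TRUE,
    label = motif) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGTRYSWKMBDHVN]", motif))
    stop("motif must be a non-empty IUPAC consensus")
  pat <- Biostrings::DNAString(motif)
  rcp <- Biostrings::reverseComplement(pat)
  out <- list()
  for (chr in names(seqs)) {
    s <- seqs[[chr]]
    if (length(pat) > length(s)) next
    fwd <- Biostrings::matchPattern(pat, s, fixed = "subject")
    st0 <- BiocGenerics::start(fwd) - 1
    strands <- rep("+", length(st0))
    if (bothStrands) {
      rev <- Biostrings::matchPattern(rcp, s, fixed = "subject")
      rst0 <- setdiff(BiocGenerics::start(rev) - 1, st0)  # same-position
      st0 <- c(st0, rst0)                                 # matches once
      strands <- c(strands, rep("-", length(rst0)))
    }
    if (length(st0) == 0L) next
    o <- order(st0)
    out[[chr]] <- .grOnGenome(rep(chr, length(st0))[o], st0[o],
      st0[o] + length(pat), genome, strand = strands[o],
      name = rep(label, length(st0)))
  }
  if (length(out) == 0L)
    return(.grOnGenome(character(0), numeric(0), numeric(0), genome))
  do.call(c, unname(out))
}

#' X:autosome motif density ratio
#'
#' log2 of motifs-per-Mb on the X over motifs-per-Mb on the autosomes, with
#' a two-sided exact binomial p-value for the X hit count among all hits at
#' the X length-share null.
#'
#' @param hits GRanges of motif occurrences.
#' @param genome a \linkS4class{GenomeLayout} with an X arm.
#' @return list with \code{log2_x_over_a_per_mb}, \code{x_hits},
#'   \code{a_hits}, \code{p_binom}.  Zero hits on either side give an
#'   \code{NA} ratio with a warning.
#' @export
motifDensityRatio <- function(hits, genome) {
  if (length(hits) == 0L) stop("no motif hits")
  if (length(xChrom(genome)) == 0L) stop("layout has no X arm")
  lens <- chromLengths(genome)
  onX <- as.character(seqnames(hits)) %in% xChrom(genome)
  xh <- sum(onX); ah <- sum(!onX)
  xMb <- lens[[xChrom(genome)]] / 1e6
  aMb <- sum(lens[!isX(genome)]) / 1e6
  ratio <- if (xh == 0 || ah == 0) {
    warning("zero motif hits on one side; ratio undefined")
    NA_real_
  } else log2((xh / xMb) / (ah / aMb))
  list(log2_x_over_a_per_mb = ratio, x_hits = xh, a_hits = ah,
    p_binom = stats::binom.test(xh, xh + ah, p = xLengthShare(genome))$p.value)
}

#' Assign DE-group labels to genes by peak overlap
#'
#' A gene is labelled with the highest-precedence class among the peaks it
#' overlaps (default FE > ME > nonDE, so the rare sex-biased classes are
#' not swallowed by the abundant nonDE peaks), or \code{no_R_loop} when it
#' overlaps no peak.  Every gene receives exactly one label.
#'
#' @param genes GRanges with unique \code{name}s.
#' @param peaks GRanges with a \code{deGroup} column.
#' @param precedence label order, highest first.
#' @return \code{genes} with an added \code{deGroup} column.
#' @export
labelGenes <- function(genes, peaks, precedence = c("FE", "ME", "nonDE")) {
  if (is.null(genes$name) || anyDuplicated(genes$name))
    stop("genes must carry unique names")
  if (is.null(peaks$deGroup)) stop("peaks lack a 'deGroup' column")
  .checkSameGenome(genes, peaks)
  lab <- rep("no_R_loop", length(genes))
  hits <- findOverlaps(genes, peaks, ignore.strand = TRUE)
  pg <- peaks$deGroup[subjectHits(hits)]
  rank <- match(pg, precedence)
  if (anyNA(rank)) stop("peaks carry labels outside the precedence order")
  best <- tapply(rank, queryHits(hits), min)
  lab[as.integer(names(best))] <- precedence[best]
  genes$deGroup <- lab
  genes
}

#' Rank-sum comparisons of a per-gene quantity across DE groups
#'
#' For each requested pair of gene labels, a two-sided
#' \code{\link{rankSumTest}} on the per-gene values (expression,
#' log2 distance-to-CES, mean MOF/H4K16ac signal, ...) plus group medians
#' and sizes.  Pairs touching an empty group are skipped with a warning.
#'
#' @param values named numeric vector, one value per gene.
#' @param labels named character vector of gene labels (or a GRanges with
#'   \code{name} and \code{deGroup} columns).
#' @param pairs list of length-2 character vectors of labels to compare;
#'   default all unordered pairs of observed labels.
#' @return data.frame with one row per comparison.
#' @export
groupCompare <- function(values, labels, pairs = NULL) {
  if (is(labels, "GRanges")) {
    labels <- stats::setNames(labels$deGroup, labels$name)
  }
  common <- intersect(names(values), names(labels))
  if (length(common) == 0L) stop("values and labels share no gene names")
  values <- values[common]; labels <- labels[common]
  if (is.null(pairs)) {
    u <- unique(labels)
    pairs <- utils::combn(u, 2, simplify = FALSE)
  }
  rows <- list()
  for (pr in pairs) {
    a <- values[labels == pr[1]]; b <- values[labels == pr[2]]
    if (length(a) == 0L || length(b) == 0L) {
      warning("empty group in pair ", pr[1], " vs ", pr[2], "; skipped")
      next
    }
    ts <- rankSumTest(a, b)
    rows[[length(rows) + 1L]] <- data.frame(group1 = pr[1], group2 = pr[2],
      n1 = length(a), n2 = length(b),
      median1 = stats::median(a), median2 = stats::median(b),
      statistic = ts$statistic, p = ts$p)
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

#' Microarray presence-call filter
#'
#' Keeps genes called present on at least \code{minPresent} of exactly four
#' arrays (the FlyAtlas-style detectable-expression filter).
#'
#' @param calls gene-by-4 binary matrix or data.frame with rownames.
#' @param minPresent minimum number of present calls.
#' @return character vector of retained gene names.
#' @export
presenceFilter <- function(calls, minPresent = 2L) {
  m <- as.matrix(calls)
  if (ncol(m) != 4L) stop("presence-call table must have exactly 4 columns")
  if (!all(m %in% c(0, 1))) stop("presence calls must be binary")
  rn <- rownames(m)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  rn[rowSums(m) >= minPresent]
}
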