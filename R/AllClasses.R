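#' @import methods
#' @importClassesFrom GenomeInfoDb Seqinfo
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom GenomeInfoDb Seqinfo seqnames seqlengths seqinfo seqlevels
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges ranges ranges<-
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps distanceToNearest reduce
#' @importFrom BiocGenerics sort
NULL

#' GenomeLayout: the coordinate universe for all intervals
#'
#' A \code{GenomeLayout} names an ordered set of chromosome arms with their
#' lengths and flags one arm as the X chromosome.  Every interval set, signal
#' track and statistical test in the package is interpreted against a
#' \code{GenomeLayout}; intervals on unknown chromosomes or extending past a
#' chromosome end are hard errors, never silently dropped.
#'
#' @slot seqinfo a \link[GenomeInfoDb]{Seqinfo} holding names and lengths.
#' @slot xChrom character; the name of the X-flagged chromosome, or
#'   \code{character(0)} for a layout with no sex chromosome.
#'
#' @seealso \code{\link{genomeLayout}}, \code{\link{readChromSizes}}
#' @export
setClass("GenomeLayout",
  representation(seqinfo = "Seqinfo", xChrom = "character"))

setValidity("GenomeLayout", function(object) {
  si <- object@seqinfo
  if (length(si) == 0L) return("layout has no chromosomes")
  if (anyDuplicated(seqnames(si))) return("duplicate chromosome names")
  len <- seqlengths(si)
  if (any(is.na(len)) || any(len <= 0)) return("all chromosome lengths must be positive")
  if (length(object@xChrom) > 1L) return("at most one X chromosome is supported")
  if (length(object@xChrom) == 1L && !(object@xChrom %in% seqnames(si)))
    return(sprintf("X chromosome '%s' is not in the layout", object@xChrom))
  TRUE
})

#' SignalTrack: fixed-bin per-chromosome coverage
#'
#' Per-chromosome numeric signal in consecutive fixed-width bins; bin
#' \code{i} (1-based) covers base pairs \code{[(i-1)*binSize, i*binSize)} in
#' 0-based half-open genomic coordinates.  The last bin of each chromosome
#' may be partial.  Used for DRIP/MOF/H4K16ac coverage, metagene profiling,
#' downsampling and the window-Poisson peak caller.
#'
#' @slot binSize single positive integer, bin width in bp.
#' @slot values named list, one non-negative finite numeric vector per
#'   chromosome, of length \code{ceiling(chromLength/binSize)}.
#' @slot genome the \linkS4class{GenomeLayout} the track lives on.
#'
#' @seealso \code{\link{signalTrack}}, \code{\link{readBedGraph}}
#' @export
setClass("SignalTrack",
  representation(binSize = "integer", values = "list", genome = "GenomeLayout"))

setValidity("SignalTrack", function(object) {
  if (length(object@binSize) != 1L || object@binSize < 1L)
    return("binSize must be a single positive integer")
  gl <- object@genome
  want <- chromNames(gl)
  if (!identical(sort(names(object@values)), sort(want)))
    return("track values must cover exactly the layout's chromosomes")
  for (chr in want) {
    v <- object@values[[chr]]
    nb <- ceiling(chromLengths(gl)[[chr]] / object@binSize)
    if (length(v) != nb)
      return(sprintf("chromosome %s: expected %d bins, got %d", chr, nb, length(v)))
    if (any(!is.finite(v)) || any(v < 0))
      return(sprintf("chromosome %s: values must be finite and non-negative", chr))
  }
  TRUE
})

#' SyntheticConfig: parameters of the synthetic DRIP-seq data generator
#'
#' Holds every knob of \code{\link{generateDataset}}.  Defaults emulate the
#' structure of an adult Drosophila DRIP-seq study on a genome scaled 1:100
#' (five major arms, one X): roughly 2-fold X-enriched peak density, a
#' five-colour chromatin-state partition with transcription-linked placement
#' bias, ~12\% sex-biased peaks with a >2:1 male:female excess concentrated
#' on the X, TSS-proximal autosomal signal versus gene-body-broad X signal,
#' and expression stochastically higher at peak-bearing genes.
#'
#' @seealso \code{\link{syntheticConfig}} for the constructor and the
#'   meaning and default of every slot.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer",
    chromLengths = "numeric",
    xChrom = "character",
    nGenes = "integer",
    nPeaks = "integer",
    peakWidthRange = "numeric",
    xDensityMultiplier = "numeric",
    stateProportions = "numeric",
    stateEnrichment = "numeric",
    stateSegmentMean = "numeric",
    fracFE = "numeric",
    fracME = "numeric",
    meOnXFraction = "numeric",
    feOnXFraction = "numeric",
    signalNoiseSd = "numeric",
    depthReadsPerMb = "numeric",
    trackBinSize = "integer",
    exprSeparationSd = "numeric",
    motifModels = "character",
    motifHitsPerMotif = "integer",
    motifXMultiplier = "numeric"))

setValidity("SyntheticConfig", function(object) {
  if (object@fracFE + object@fracME >= 1) return("fracFE + fracME must be < 1")
  if (any(object@peakWidthRange < 1)) return("peak widths must be >= 1 bp")
  if (object@peakWidthRange[1] > object@peakWidthRange[2])
    return("peakWidthRange must be (min, max)")
  if (object@xDensityMultiplier < 0) return("xDensityMultiplier must be >= 0")
  if (any(object@stateEnrichment < 0)) return("state multipliers must be >= 0")
  if (!identical(sort(names(object@stateProportions)), sort(names(object@stateEnrichment))))
    return("stateProportions and stateEnrichment must name the same states")
  if (abs(sum(object@stateProportions) - 1) > 1e-8)
    return("stateProportions must sum to 1")
  if (object@signalNoiseSd < 0) return("signalNoiseSd must be >= 0")
  if (object@meOnXFraction < 0 || object@meOnXFraction > 1)
    return("meOnXFraction must be in [0,1]")
  TRUE
})

#' SyntheticDataset: one realisation of the synthetic study
#'
#' Container for everything \code{\link{generateDataset}} produces: the
#' genome layout, a chromatin-state partition, gene models with
#' 5'UTR/CDS/intron/3'UTR substructure, per-sample peak sets and signal
#' tracks (samples F379, F732, M379, M732), a consensus peak set with
#' nonDE/FE/ME labels, planted motif occurrences, per-chromosome sequence,
#' and gene-by-sample expression and presence-call tables.
#'
#' @slot genome \linkS4class{GenomeLayout}.
#' @slot states GRanges tiling the genome, metadata column \code{state}.
#' @slot genes GRanges of gene spans, stranded, metadata \code{name}.
#' @slot geneFeatures GRanges of gene substructure, metadata \code{type}
#'   (one of 5UTR/CDS/intron/3UTR) and \code{gene}.
#' @slot peaks named list of GRanges, one peak set per sample.
#' @slot deLabels GRanges consensus peaks, metadata \code{deGroup}.
#' @slot tracks named list of \linkS4class{SignalTrack}, one per sample.
#' @slot motifHits named list of GRanges of planted motif occurrences.
#' @slot sequence \link[Biostrings]{DNAStringSet}, one entry per chromosome.
#' @slot expression numeric matrix, genes x samples (rlog-like scale).
#' @slot presenceCalls binary matrix, genes x 4 arrays.
#' @slot config the \linkS4class{SyntheticConfig} that produced it.
#' @export
setClass("SyntheticDataset",
  representation(
    genome = "GenomeLayout",
    states = "GRanges",
    genes = "GRanges",
    geneFeatures = "GRanges",
    peaks = "list",
    deLabels = "GRanges",
    tracks = "list",
    motifHits = "list",
    sequence = "DNAStringSet",
    expression = "matrix",
    presenceCalls = "matrix",
    config = "SyntheticConfig"))

#' MetageneMatrix: per-region scale-regions signal matrix
#'
#' Rows are retained regions (genes), columns are metagene bins laid out as
#' upstream flank bins, scaled body bins, downstream flank bins, always
#' 5'-to-3' in the region's orientation.
#'
#' @slot values numeric matrix (regions x bins), rownames = region names.
#' @slot group character, one group label per row.
#' @slot upstreamBins,bodyBins,downstreamBins integer bin counts.
#' @slot binSize integer, flank bin width in bp.
#' @slot nDropped integer, regions dropped (all-zero rows under skipZeros,
#'   or degenerate after clipping).
#' @export
setClass("MetageneMatrix",
  representation(values = "matrix", group = "character",
    upstreamBins = "integer", bodyBins = "integer",
    downstreamBins = "integer", binSize = "integer", nDropped = "integer"))

setMethod("show", "GenomeLayout", function(object) {
  len <- chromLengths(object)
  cat(sprintf("GenomeLayout with %d chromosomes (%.2f Mb total)\n",
    length(len), sum(len) / 1e6))
  flag <- ifelse(names(len) %in% object@xChrom, " [X]", "")
  cat(sprintf("  %s: %s bp%s\n", names(len), format(len, big.mark = ","), flag), sep = "")
})

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack: %d bp bins on %d chromosomes, total signal %.4g\n",
    object@binSize, length(object@values), trackTotal(object)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset\n")
  cat(sprintf("  genome: %d arms, %.2f Mb; X = %s\n",
    length(chromNames(object@genome)), genomeSize(object@genome) / 1e6,
    xChrom(object@genome)))
  cat(sprintf("  states: %d segments (%s)\n", length(object@states),
    paste(levels(factor(object@states$state)), collapse = "/")))
  cat(sprintf("  genes: %d; samples: %s\n", length(object@genes),
    paste(names(object@peaks), collapse = ", ")))
  cat(sprintf("  peaks per sample: %s\n",
    paste(vapply(object@peaks, length, 0L), collapse = ", ")))
  de <- table(object@deLabels$deGroup)
  cat(sprintf("  consensus peaks: %d (%s)\n", length(object@deLabels),
    paste(names(de), de, sep = "=", collapse = ", ")))
})

setMethod("show", "MetageneMatrix", function(object) {
  cat(sprintf(
    "MetageneMatrix: %d regions x %d bins (%d up + %d body + %d down), %d dropped\n",
    nrow(object@values), ncol(object@values), object@upstreamBins,
    object@bodyBins, object@downstreamBins, object@nDropped))
})
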