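#' Build a synthetic-data generator configuration
#'
#' Defaults emulate the structure of an adult Drosophila DRIP-seq study on
#' the five major chromosome arms scaled 1:100 (so 10,000-iteration
#' permutation runs finish in seconds):
#' \itemize{
#'   \item X peak density 2.0-fold the autosomal density (R-loop density is
#'     roughly 2-fold higher on the X than on autosomes);
#'   \item a five-colour chromatin-state partition (RED/YELLOW active, BLUE
#'     Polycomb, GREEN HP1, BLACK repressive) with peak placement biased
#'     towards transcriptionally active and Polycomb states and away from
#'     heterochromatin;
#'   \item DE class fractions from the published DiffBind class sizes
#'     13441 nonDE / 558 FE / 1282 ME (about 12\% sex-biased, ME:FE > 2),
#'     with 45\% of ME peaks on the X and FE peaks placed
#'     length-proportionally;
#'   \item TSS-proximal DRIP signal at autosomal genes versus
#'     gene-body-broad signal at X-linked genes;
#'   \item expression stochastically higher at peak-bearing genes
#'     (1 SD separation);
#'   \item planted motif occurrences (a CTC repeat and GGCGAAGGAG) with a
#'     1.4-fold X density excess, embedded in the generated sequence so
#'     motif scanning has a known ground truth.
#' }
#'
#' @param seed integer; the generator is fully deterministic given the seed.
#' @param chromLengths named chromosome lengths in bp.
#' @param xChrom name of the X arm.
#' @param nGenes,nPeaks gene and per-sample peak counts.
#' @param peakWidthRange (min, max) peak width in bp.
#' @param xDensityMultiplier expected X:autosome peak density ratio.
#' @param stateProportions genome share targeted per chromatin state
#'   (sums to 1).
#' @param stateEnrichment relative peak placement density per state.
#' @param stateSegmentMean mean chromatin-state segment length in bp.
#' @param fracFE,fracME fractions of peaks labelled FE / ME.
#' @param meOnXFraction fraction of ME peaks placed on the X.
#' @param feOnXFraction fraction of FE peaks on the X; \code{NA} means the
#'   X length share (no enrichment).
#' @param signalNoiseSd gaussian noise SD added to signal tracks.
#' @param depthReadsPerMb background track depth (reads per Mb).
#' @param trackBinSize signal track bin width in bp.
#' @param exprSeparationSd expression shift (in SD units) of peak-bearing
#'   genes.
#' @param motifModels named IUPAC consensus strings to plant.
#' @param motifHitsPerMotif planted occurrences per motif.
#' @param motifXMultiplier X:autosome density multiplier for motif hits.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(
    seed = 1L,
    chromLengths = c(`2L` = 235137, `2R` = 252869, `3L` = 281102,
      `3R` = 320793, X = 235422),
    xChrom = "X",
    nGenes = 400L,
    nPeaks = 8000L,
    peakWidthRange = c(100, 500),
    xDensityMultiplier = 2.0,
    stateProportions = c(RED = 0.10, YELLOW = 0.25, BLUE = 0.15,
      GREEN = 0.15, BLACK = 0.35),
    stateEnrichment = c(RED = 3, YELLOW = 1.5, BLUE = 2,
      GREEN = 0.5, BLACK = 0.3),
    stateSegmentMean = 5000,
    fracFE = 558 / 15281,
    fracME = 1282 / 15281,
    meOnXFraction = 0.45,
    feOnXFraction = NA_real_,
    signalNoiseSd = 0.5,
    depthReadsPerMb = 2e5,
    trackBinSize = 50L,
    exprSeparationSd = 1.0,
    motifModels = c(CTC_repeat = "CTCCTCCTC", GGCGAAGGAG = "GGCGAAGGAG"),
    motifHitsPerMotif = 1000L,
    motifXMultiplier = 1.4) {
  new("SyntheticConfig", seed = as.integer(seed),
    chromLengths = chromLengths, xChrom = xChrom,
    nGenes = as.integer(nGenes), nPeaks = as.integer(nPeaks),
    peakWidthRange = peakWidthRange,
    xDensityMultiplier = xDensityMultiplier,
    stateProportions = stateProportions, stateEnrichment = stateEnrichment,
    stateSegmentMean = stateSegmentMean,
    fracFE = fracFE, fracME = fracME,
    meOnXFraction = meOnXFraction, feOnXFraction = feOnXFraction,
    signalNoiseSd = signalNoiseSd, depthReadsPerMb = depthReadsPerMb,
    trackBinSize = as.integer(trackBinSize),
    exprSeparationSd = exprSeparationSd,
    motifModels = motifModels,
    motifHitsPerMotif = as.integer(motifHitsPerMotif),
    motifXMultiplier = motifXMultiplier)
}

## internal: sample k elements from an index pool (safe for length-1 pools)
.sampleFrom <- function(pool, k) pool[sample.int(length(pool), k)]

## internal: tile one chromosome with state segments
.tileStates <- function(L, props, segMean) {
  segs <- numeric(0)
  while (sum(segs) < L) {
    k <- ceiling((L - sum(segs)) / segMean) + 10
    segs <- c(segs, pmax(200, round(stats::rexp(k, 1 / segMean))))
  }
  cum <- cumsum(segs)
  nseg <- which(cum >= L)[1]
  segs <- segs[seq_len(nseg)]
  segs[nseg] <- segs[nseg] - (cum[nseg] - L)
  ## quota assignment in random order keeps realized per-state shares
  ## within about one segment of the configured proportions
  lab <- character(nseg)
  deficit <- props * L
  for (i in sample.int(nseg)) {
    lab[i] <- names(props)[which.max(deficit)]
    deficit[lab[i]] <- deficit[lab[i]] - segs[i]
  }
  list(start0 = c(0, cumsum(segs))[seq_len(nseg)], width = segs, state = lab)
}

## internal: place n peaks; chromosome prob ~ length * xMult, position
## within chromosome ~ stateEnrichment of the local state
.placePeaks <- function(n, genome, states, stateMult, xMult, widthRange) {
  lens <- chromLengths(genome)
  if (min(widthRange) > min(lens))
    stop("peaks wider than the smallest chromosome cannot be placed")
  wts <- lens * ifelse(isX(genome), xMult, 1)
  nPer <- as.vector(stats::rmultinom(1, n, wts / sum(wts)))
  names(nPer) <- names(lens)
  chromArr <- character(0); startArr <- numeric(0); wArr <- numeric(0)
  segChrom <- as.character(seqnames(states))
  for (chr in names(lens)) {
    k <- nPer[[chr]]
    if (k == 0L) next
    idx <- which(segChrom == chr)
    segW <- width(states)[idx]
    segS0 <- start(states)[idx] - 1
    p <- segW * stateMult[states$state[idx]]
    seg <- sample(length(idx), k, replace = TRUE, prob = p)
    s0 <- segS0[seg] + floor(stats::runif(k) * segW[seg])
    w <- round(stats::runif(k, widthRange[1], widthRange[2]))
    s0 <- pmin(s0, lens[[chr]] - w)
    s0 <- pmax(s0, 0)
    chromArr <- c(chromArr, rep(chr, k))
    startArr <- c(startArr, s0); wArr <- c(wArr, w)
  }
  .grOnGenome(chromArr, startArr, startArr + wArr, genome)
}

## internal: gene models with 5'UTR / CDS / intron / 3'UTR substructure
.makeGenes <- function(genome, nGenes) {
  lens <- chromLengths(genome)
  nPer <- round(nGenes * lens / sum(lens))
  d <- nGenes - sum(nPer)
  nPer[1] <- nPer[1] + d
  geneRows <- list(); featRows <- list(); gid <- 0L
  for (chr in names(lens)) {
    k <- nPer[[chr]]
    if (k == 0L) next
    slot <- lens[[chr]] / k
    for (j in seq_len(k)) {
      gid <- gid + 1L
      hi <- min(8000, slot - 400)
      glen <- if (hi <= 2000) round(0.6 * slot)
        else round(stats::runif(1, 2000, hi))
      s0 <- round((j - 1) * slot +
        stats::runif(1, 1, max(2, slot - glen - 1)))
      strand <- sample(c("+", "-"), 1)
      name <- sprintf("g%04d", gid)
      u5 <- round(stats::runif(1, 100, 400))
      u3 <- round(stats::runif(1, 100, 400))
      nEx <- sample(2:4, 1)
      nPart <- 2L * nEx - 1L             # CDS, intron, CDS, ...
      inner <- glen - u5 - u3
      prop <- stats::runif(nPart, 0.5, 1.5)
      part <- floor(inner * prop / sum(prop))
      part[1] <- part[1] + (inner - sum(part))
      segLen <- c(u5, part, u3)
      segType <- c("5UTR", rep(c("CDS", "intron"), nEx)[seq_len(nPart)], "3UTR")
      if (strand == "-") { segLen <- rev(segLen); segType <- rev(segType) }
      segS0 <- s0 + c(0, cumsum(segLen))[seq_along(segLen)]
      geneRows[[gid]] <- data.frame(chr = chr, s0 = s0, e0 = s0 + glen,
        strand = strand, name = name)
      featRows[[gid]] <- data.frame(chr = chr, s0 = segS0,
        e0 = segS0 + segLen, strand = strand, type = segType, gene = name)
    }
  }
  g <- do.call(rbind, geneRows); f <- do.call(rbind, featRows)
  list(
    genes = .grOnGenome(g$chr, g$s0, g$e0, genome, strand = g$strand,
      name = g$name),
    features = .grOnGenome(f$chr, f$s0, f$e0, genome, strand = f$strand,
      type = f$type, gene = f$gene))
}

## internal: sample concrete bases for an IUPAC consensus
.resolveIupac <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]], function(ch) {
    opts <- strsplit(.iupac[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1)
  }, ""), collapse = "")
}

#' Generate a synthetic DRIP-seq dataset
#'
#' Deterministic given \code{config@seed}.  Produces, in a fixed draw
#' order: the genome layout; a chromatin-state partition tiling every base
#' pair exactly once; gene models; a consensus peak set with nonDE/FE/ME
#' labels (ME concentrated on the X); four per-sample peak sets (F379,
#' F732, M379, M732) derived from the consensus with coordinate jitter and
#' dropout; per-sample signal tracks (TSS-proximal bumps on autosomes,
#' gene-body plateaus on the X); planted motif occurrences; per-chromosome
#' sequence with the motif instances embedded; and gene expression /
#' presence-call tables.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
generateDataset <- function(config) {
  validObject(config)
  set.seed(config@seed)
  genome <- genomeLayout(config@chromLengths, xChrom = config@xChrom)
  lens <- chromLengths(genome)

  ## 1. chromatin states
  stRows <- lapply(names(lens), function(chr) {
    t <- .tileStates(lens[[chr]], config@stateProportions,
      config@stateSegmentMean)
    data.frame(chr = chr, s0 = t$start0, e0 = t$start0 + t$width,
      state = t$state)
  })
  st <- do.call(rbind, stRows)
  states <- .grOnGenome(st$chr, st$s0, st$e0, genome, state = st$state)

  ## 2. genes
  gm <- .makeGenes(genome, config@nGenes)

  ## 3. consensus peaks + DE labels
  consensus <- .placePeaks(config@nPeaks, genome, states,
    config@stateEnrichment, config@xDensityMultiplier, config@peakWidthRange)
  n <- length(consensus)
  onX <- as.character(seqnames(consensus)) %in% xChrom(genome)
  nME <- round(n * config@fracME); nFE <- round(n * config@fracFE)
  lab <- rep("nonDE", n)
  pickBiased <- function(nGroup, onXFraction, free) {
    wantX <- round(nGroup * onXFraction)
    xPool <- intersect(which(onX), free)
    aPool <- setdiff(free, xPool)
    gotX <- min(wantX, length(xPool))
    c(.sampleFrom(xPool, gotX),
      .sampleFrom(aPool, min(nGroup - gotX, length(aPool))))
  }
  free <- seq_len(n)
  iME <- pickBiased(nME, config@meOnXFraction, free)
  free <- setdiff(free, iME)
  feX <- config@feOnXFraction
  if (is.na(feX)) feX <- xLengthShare(genome)
  iFE <- pickBiased(nFE, feX, free)
  lab[iME] <- "ME"; lab[iFE] <- "FE"
  deLabels <- consensus
  deLabels$name <- sprintf("pk%05d", seq_len(n))
  deLabels$deGroup <- lab

  ## 4. per-sample peak sets: nonDE + own-sex biased class (plus a minority
  ## of the opposite class), jittered and thinned for replicate realism
  samples <- c("F379", "F732", "M379", "M732")
  peaks <- lapply(samples, function(sm) {
    female <- substr(sm, 1, 1) == "F"
    own <- if (female) "FE" else "ME"
    other <- if (female) "ME" else "FE"
    keep <- lab == "nonDE" | lab == own |
      (lab == other & stats::runif(n) < 0.3)
    keep <- keep & stats::runif(n) > 0.05
    p <- deLabels[keep]
    jit <- round(stats::rnorm(length(p), 0, 20))
    s0 <- pmax(0, pmin(start(p) - 1 + jit,
      lens[as.character(seqnames(p))] - width(p)))
    ranges(p) <- IRanges(start = s0 + 1, width = width(p))
    p
  })
  names(peaks) <- samples

  ## 5. per-sample signal tracks
  b <- config@trackBinSize
  bg <- config@depthReadsPerMb * b / 1e6
  geneChrom <- as.character(seqnames(gm$genes))
  geneOnX <- geneChrom %in% xChrom(genome)
  plusStrand <- as.character(strand(gm$genes)) == "+"
  tss0 <- ifelse(plusStrand, start(gm$genes) - 1, end(gm$genes))
  lambda <- lapply(names(lens), function(chr) rep(bg, ceiling(lens[[chr]] / b)))
  names(lambda) <- names(lens)
  for (i in seq_along(gm$genes)) {
    chr <- geneChrom[i]
    nb <- length(lambda[[chr]])
    if (geneOnX[i]) {
      i1 <- floor((start(gm$genes)[i] - 1) / b) + 1
      i2 <- min(nb, ceiling(end(gm$genes)[i] / b))
      lambda[[chr]][i1:i2] <- lambda[[chr]][i1:i2] + 2.4 * bg
    } else {
      centre <- tss0[i] + ifelse(plusStrand[i], 300, -300)
      i1 <- max(1, floor((centre - 1000) / b) + 1)
      i2 <- min(nb, ceiling((centre + 1000) / b))
      mid <- ((i1:i2) - 0.5) * b
      lambda[[chr]][i1:i2] <- lambda[[chr]][i1:i2] +
        3 * bg * exp(-(mid - centre)^2 / (2 * 250^2))
    }
  }
  tracks <- lapply(samples, function(sm) {
    vals <- lapply(lambda, function(lv)
      pmax(0, stats::rpois(length(lv), lv) +
        stats::rnorm(length(lv), 0, config@signalNoiseSd)))
    signalTrack(vals, binSize = b, genome = genome)
  })
  names(tracks) <- samples

  ## 6. planted motif hits (non-overlapping across motifs) and sequence
  seqChars <- lapply(lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  occupied <- lapply(lens, function(L) IRanges())
  motifHits <- list()
  for (mi in seq_along(config@motifModels)) {
    motif <- config@motifModels[[mi]]
    mlen <- nchar(motif)
    wts <- lens * ifelse(isX(genome), config@motifXMultiplier, 1)
    nPer <- as.vector(stats::rmultinom(1, config@motifHitsPerMotif,
      wts / sum(wts)))
    names(nPer) <- names(lens)
    chromArr <- character(0); s0Arr <- numeric(0); strandArr <- character(0)
    for (chr in names(lens)) {
      need <- nPer[[chr]]
      placed <- 0L
      while (placed < need) {
        cand <- floor(stats::runif(2 * (need - placed)) * (lens[[chr]] - mlen))
        ir <- IRanges(start = cand + 1, width = mlen)
        ok <- which(IRanges::countOverlaps(ir, occupied[[chr]]) == 0)
        ok <- ok[!duplicated(cand[ok])]
        ## also avoid collisions within this candidate batch
        if (length(ok) > 1L) {
          o <- ok[order(cand[ok])]
          keepSel <- c(TRUE, diff(cand[o]) >= mlen)
          ok <- o[keepSel]
        }
        take <- utils::head(ok, need - placed)
        if (length(take) == 0L) next
        occupied[[chr]] <- c(occupied[[chr]], ir[take])
        strandSel <- sample(c("+", "-"), length(take), replace = TRUE)
        for (t in seq_along(take)) {
          inst <- .resolveIupac(motif)
          if (strandSel[t] == "-")
            inst <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(inst)))
          pos <- cand[take[t]]
          seqChars[[chr]][(pos + 1):(pos + mlen)] <- strsplit(inst, "")[[1]]
        }
        chromArr <- c(chromArr, rep(chr, length(take)))
        s0Arr <- c(s0Arr, cand[take])
        strandArr <- c(strandArr, strandSel)
        placed <- placed + length(take)
      }
    }
    motifHits[[names(config@motifModels)[mi]]] <- sort(.grOnGenome(
      chromArr, s0Arr, s0Arr + mlen, genome, strand = strandArr,
      name = rep(names(config@motifModels)[mi], length(s0Arr))))
  }
  sequence <- Biostrings::DNAStringSet(vapply(seqChars, paste, "",
    collapse = ""))

  ## 7. expression and presence calls
  hasPeak <- IRanges::overlapsAny(gm$genes, consensus, ignore.strand = TRUE)
  base <- stats::rnorm(length(gm$genes), 5, 1) +
    config@exprSeparationSd * hasPeak
  expression <- sapply(samples, function(sm)
    base + stats::rnorm(length(base), 0, 0.3))
  rownames(expression) <- gm$genes$name
  presenceCalls <- matrix(stats::rbinom(length(base) * 4L, 1L,
    stats::plogis(base - 4)), ncol = 4L,
    dimnames = list(gm$genes$name, paste0("array", 1:4)))

  new("SyntheticDataset", genome = genome, states = states,
    genes = gm$genes, geneFeatures = gm$features, peaks = peaks,
    deLabels = deLabels, tracks = tracks, motifHits = motifHits,
    sequence = sequence, expression = expression,
    presenceCalls = presenceCalls, config = config)
}

#' Generate unbiased null peaks
#'
#' Calibration input for the permutation and binomial tests: each peak's
#' chromosome is drawn with probability proportional to chromosome length
#' and its start uniformly on the admissible range, with no feature or
#' state bias.
#'
#' @param genome a \linkS4class{GenomeLayout}.
#' @param n number of peaks (>= 0).
#' @param widthRange (min, max) peak width in bp.
#' @param seed optional integer.
#' @return GRanges of \code{n} peaks.
#' @export
generateNullPeaks <- function(genome, n, widthRange = c(100, 500),
    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengths(genome)
  if (n == 0L)
    return(.grOnGenome(character(0), numeric(0), numeric(0), genome))
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  w <- round(stats::runif(n, widthRange[1], widthRange[2]))
  s0 <- floor(stats::runif(n) * (lens[chrom] - w + 1))
  s0 <- pmax(0, pmin(s0, lens[chrom] - w))
  .grOnGenome(chrom, s0, s0 + w, genome)
}

#' Generate the sequencing-depth artifact scenario
#'
#' A male-like IP/control track pair in which the X chromosome carries a
#' 2-fold planted peak density but only half the sequencing depth of the
#' autosomes.  Planted peaks multiply the local IP Poisson rate by a
#' modest \code{foldChange} so that their detectability depends on depth:
#' called naively, the X shows fewer peaks per Mb than the autosomes; after
#' the autosomes are depth-matched with \code{\link{thinTrack}}, the true
#' 2-fold X excess emerges.
#'
#' @param genome a \linkS4class{GenomeLayout} with an X arm.
#' @param seed optional integer.
#' @param peaksPerMb planted autosomal peak density.
#' @param xDensityMultiplier planted X:autosome density ratio.
#' @param backgroundPerBin autosomal background depth per bin (counts).
#' @param foldChange IP rate multiplier over planted peaks.
#' @param xDepthFactor X depth relative to autosomes.
#' @param binSize track bin width in bp.
#' @param peakBins planted peak width in bins.
#' @return list with \code{ip}, \code{control}
#'   (\linkS4class{SignalTrack}s), \code{truePeaks} (GRanges) and the
#'   scenario parameters.
#' @export
generateDepthScenario <- function(genome, seed = NULL, peaksPerMb = 250,
    xDensityMultiplier = 2, backgroundPerBin = 840, foldChange = 1.15,
    xDepthFactor = 0.5, binSize = 50L, peakBins = 4L) {
  if (!is.null(seed)) set.seed(seed)
  lens <- chromLengths(genome)
  onX <- isX(genome)
  lamIp <- list(); lamCt <- list()
  chromArr <- character(0); s0Arr <- numeric(0)
  for (ci in seq_along(lens)) {
    chr <- names(lens)[ci]
    nb <- ceiling(lens[[chr]] / binSize)
    depth <- backgroundPerBin * if (onX[ci]) xDepthFactor else 1
    lc <- rep(depth, nb)
    li <- rep(depth, nb)
    dens <- peaksPerMb * if (onX[ci]) xDensityMultiplier else 1
    nPk <- round(dens * lens[[chr]] / 1e6)
    grid <- seq(1L, nb - peakBins, by = 3L * peakBins)
    pos <- sort(sample(grid, min(nPk, length(grid))))
    for (p in pos) li[p:(p + peakBins - 1L)] <- depth * foldChange
    chromArr <- c(chromArr, rep(chr, length(pos)))
    s0Arr <- c(s0Arr, (pos - 1) * binSize)
    lamIp[[chr]] <- li; lamCt[[chr]] <- lc
  }
  ip <- signalTrack(lapply(lamIp, function(l) as.numeric(stats::rpois(length(l), l))),
    binSize = binSize, genome = genome)
  control <- signalTrack(lapply(lamCt, function(l) as.numeric(stats::rpois(length(l), l))),
    binSize = binSize, genome = genome)
  list(ip = ip, control = control,
    truePeaks = .grOnGenome(chromArr, s0Arr, s0Arr + peakBins * binSize,
      genome),
    peaksPerMb = peaksPerMb, xDensityMultiplier = xDensityMultiplier,
    foldChange = foldChange, xDepthFactor = xDepthFactor)
}

#' Write a SyntheticDataset to standard formats
#'
#' BED for states, genes, gene features, per-sample peaks, DE-labelled
#' consensus peaks and motif hits; bedGraph per sample track; FASTA for the
#' sequence; TSV for expression and presence calls; chrom.sizes for the
#' layout; and a JSON manifest recording the configuration and seed.
#'
#' @param ds a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  lens <- chromLengths(ds@genome)
  utils::write.table(data.frame(names(lens), format(lens, scientific = FALSE,
    trim = TRUE)), p("genome.chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  st <- ds@states; st$name <- st$state
  writeBed(st, p("states.bed"))
  writeBed(ds@genes, p("genes.bed"))
  gf <- ds@geneFeatures; gf$name <- paste(gf$gene, gf$type, sep = ":")
  writeBed(gf, p("gene_features.bed"))
  dl <- ds@deLabels; dl$name <- paste(dl$name, dl$deGroup, sep = ":")
  writeBed(dl, p("consensus_peaks.bed"))
  for (sm in names(ds@peaks))
    writeBed(ds@peaks[[sm]], p(sprintf("peaks_%s.bed", sm)))
  for (sm in names(ds@tracks))
    writeBedGraph(ds@tracks[[sm]], p(sprintf("track_%s.bedGraph", sm)))
  for (m in names(ds@motifHits))
    writeBed(ds@motifHits[[m]], p(sprintf("motif_%s.bed", m)))
  Biostrings::writeXStringSet(ds@sequence, p("genome.fa"))
  utils::write.table(ds@expression, p("expression.tsv"), sep = "\t",
    quote = FALSE, col.names = NA)
  utils::write.table(ds@presenceCalls, p("presence_calls.tsv"), sep = "\t",
    quote = FALSE, col.names = NA)
  cfg <- ds@config
  manifest <- list(seed = cfg@seed, nGenes = cfg@nGenes, nPeaks = cfg@nPeaks,
    chromLengths = as.list(cfg@chromLengths), xChrom = cfg@xChrom,
    xDensityMultiplier = cfg@xDensityMultiplier,
    fracFE = cfg@fracFE, fracME = cfg@fracME,
    meOnXFraction = cfg@meOnXFraction,
    stateProportions = as.list(cfg@stateProportions),
    stateEnrichment = as.list(cfg@stateEnrichment),
    motifModels = as.list(cfg@motifModels))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
    p("manifest.json"))
  invisible(dir)
}
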