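#' Run the full analysis pipeline on a synthetic dataset
#'
#' Executes every analysis stage in a fixed order on one
#' \linkS4class{SyntheticDataset} — chromosome density tests,
#' feature/chromatin-state permutation enrichment, metagene profiling,
#' DE-group summaries and chromosome profiles, motif scanning with X:A
#' density ratios, and expression group comparisons — writing one TSV per
#' stage plus a JSON manifest recording the seed and configuration.
#' Identical dataset + seed give byte-identical outputs.
#'
#' @param ds a \linkS4class{SyntheticDataset}.
#' @param outDir output directory.
#' @param nPerm permutation count for the enrichment stage.
#' @param seed integer seed governing every stochastic stage.
#' @param sample which peak/track sample drives the single-sample stages.
#' @param verbose log stage timings to stderr.
#' @return (invisibly) a named list of the per-stage results.
#' @export
runPipeline <- function(ds, outDir, nPerm = 1000L, seed = 1L,
    sample = "M379", verbose = TRUE) {
  stopifnot(is(ds, "SyntheticDataset"))
  if (!sample %in% names(ds@peaks))
    stop("unknown sample '", sample, "'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, t0) if (verbose)
    message(sprintf("[rloopscape] %s done in %.1fs", stage,
      as.numeric(Sys.time()) - t0))
  out <- list()
  tsv <- function(df, name) utils::write.table(df,
    file.path(outDir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  ## 1. X-vs-autosome density
  t0 <- as.numeric(Sys.time())
  dens <- chromosomeDensityTest(ds@peaks[[sample]], ds@genome)
  tsv(data.frame(chrom = names(dens$per_chrom_density),
    peaks_per_mb = dens$per_chrom_density,
    x_count = dens$x_count, total = dens$total, p0 = dens$p0,
    p_binom = dens$p_binom), "density.tsv")
  out$density <- dens
  say("density", t0)

  ## 2. permutation enrichment against chromatin states
  t0 <- as.numeric(Sys.time())
  states <- split(ds@states, ds@states$state)
  enr <- permutationEnrichment(ds@peaks[[sample]], as.list(states),
    ds@genome, nPerm = nPerm, seed = seed)
  tsv(as.data.frame(enr), "enrichment_states.tsv")
  out$enrichment <- enr
  say("enrichment", t0)

  ## 3. metagene profile, autosomes vs X
  t0 <- as.numeric(Sys.time())
  genes <- ds@genes
  genes$group <- ifelse(as.character(seqnames(genes)) %in% xChrom(ds@genome),
    "X", "autosome")
  mm <- metageneMatrix(genes, ds@tracks[[sample]])
  prof <- metageneProfile(mm)
  profDf <- do.call(rbind, lapply(names(prof), function(g)
    data.frame(group = g, bin = seq_along(prof[[g]]$mean),
      mean = prof[[g]]$mean, sem = prof[[g]]$sem,
      n_regions = prof[[g]]$n_regions)))
  tsv(profDf, "metagene.tsv")
  out$metagene <- prof
  say("metagene", t0)

  ## 4. DE summaries and per-chromosome profile
  t0 <- as.numeric(Sys.time())
  dsum <- debiasSummary(ds@deLabels)
  tsv(as.data.frame(dsum), "de_summary.tsv")
  prof3 <- deChromosomeProfile(ds@deLabels, ds@genome)
  tsv(do.call(rbind, lapply(names(prof3), function(g)
    data.frame(group = g, chrom = names(prof3[[g]]$per_chrom_density),
      peaks_per_mb = prof3[[g]]$per_chrom_density,
      fraction_on_x = prof3[[g]]$fraction_on_x,
      p_binom = prof3[[g]]$p_binom))), "de_chromosome_profile.tsv")
  out$de_summary <- dsum
  out$de_profile <- prof3
  say("sexbias", t0)

  ## 5. motif scan + X:A densities
  t0 <- as.numeric(Sys.time())
  motifRows <- lapply(names(ds@config@motifModels), function(m) {
    hits <- scanMotif(ds@sequence, ds@config@motifModels[[m]], ds@genome,
      label = m)
    r <- motifDensityRatio(hits, ds@genome)
    data.frame(motif = m, n_hits = length(hits),
      log2_x_over_a_per_mb = r$log2_x_over_a_per_mb, p_binom = r$p_binom)
  })
  motifDf <- do.call(rbind, motifRows)
  tsv(motifDf, "motifs.tsv")
  out$motifs <- motifDf
  say("motifs", t0)

  ## 6. expression comparison across gene-level DE groups
  t0 <- as.numeric(Sys.time())
  genesLab <- labelGenes(ds@genes, ds@deLabels)
  expr <- rowMeans(ds@expression)
  cmp <- groupCompare(expr, genesLab)
  tsv(cmp, "expression_compare.tsv")
  out$compare <- cmp
  say("compare", t0)

  manifest <- list(seed = seed, n_perm = nPerm, sample = sample,
    generator_seed = ds@config@seed,
    n_peaks = ds@config@nPeaks, n_genes = ds@config@nGenes,
    package_version = as.character(utils::packageVersion("rloopscape")),
    stages = c("density", "enrichment", "metagene", "sexbias", "motifs",
      "compare"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
    file.path(outDir, "manifest.json"))
  invisible(out)
}

#' Small end-to-end demonstration run
#'
#' Generates a reduced synthetic dataset and runs the whole pipeline on it;
#' finishes in well under a minute.
#'
#' @param outDir output directory.
#' @param seed integer seed.
#' @return (invisibly) the stage results of \code{\link{runPipeline}}.
#' @export
runDemo <- function(outDir = tempfile("rloopscape_demo"), seed = 1L) {
  cfg <- syntheticConfig(seed = seed, nGenes = 120L, nPeaks = 2000L,
    motifHitsPerMotif = 300L)
  ds <- generateDataset(cfg)
  runPipeline(ds, outDir, nPerm = 200L, seed = seed)
}
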