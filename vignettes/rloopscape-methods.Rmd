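---
title: "Statistical methods for DRIP-seq R-loop landscape analysis"
author: "rloopscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for DRIP-seq R-loop landscape analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopscape)
```

# Scope

`rloopscape` implements the statistical core of a DRIP-seq R-loop landscape
analysis in a genome with one X chromosome arm and four autosomal arms:
permutation-based enrichment of peaks in genomic features and chromatin
states, exact binomial tests of X-versus-autosome peak density,
sequencing-depth downsampling with a simple window-Poisson peak caller,
scale-regions metagene profiling, IUPAC consensus motif scanning with
per-megabase X:autosome density ratios, sex-biased peak class summaries,
and rank-sum comparisons of per-gene quantities across peak classes.  A
seeded synthetic-data generator supplies inputs with known planted
structure so every stage is testable end to end without downloads.

Peak calling from reads, differential binding (the nonDE/FE/ME labels are
inputs), motif discovery, IDR filtering and GO enrichment are out of
scope; where a simplified stand-in exists (the window-Poisson caller, the
consensus motif scanner) it is labelled as such below.

# The permutation enrichment test

The central statistic is the observed number of overlap *pairs* between a
peak set and a feature class (`countPeakOverlaps`) divided by the mean
pair count over `nPerm` chromosome- and width-preserving shuffles of the
peaks (`shuffleIntervals`): each peak is replaced by an interval of the
same width on the same chromosome with 0-based start drawn uniformly on
`[0, chromLength - width]`.  Shuffled intervals are placed independently
and may overlap one another; no gap or GC masking is applied.  Results are
reported as `log2(observed/expected)` per class.

Three design points deserve explanation:

* **Pair counting.**  "Number of overlaps" is ambiguous between
  query-subject pairs and queries-with-at-least-one-hit.  The default is
  pair counting (bedtools-intersect semantics).  For multi-copy features
  whose copies are biologically one unit — tRNA genes with identical
  sequence — `countPeakOverlapsDedup` counts each distinct subject name at
  most once; `permutationEnrichment(dedupLabels = "tRNA")` applies the
  same rule inside the null.  Both interpretations are exposed because
  which one produced any given published figure is generally unknowable.
* **One shuffle stream for all classes.**  Each shuffled peak set is
  intersected with *every* feature class, as when a shuffled BED file is
  intersected with each annotation in turn.  Per-class results are
  therefore positively correlated; Benjamini-Hochberg correction
  (`bhAdjust`, standard step-up via `stats::p.adjust`) is valid under that
  positive dependence.
* **Two-sided empirical p.**  With `nGreater` permutations at or above
  and `nLess` at or below the observed count,
  `p = min(1, (1 + 2 min(nGreater, nLess)) / (nPerm + 1))`.  Doubling the
  smaller one-sided proportion with an add-one correction is the standard
  conservative convention for empirical p-values; it never returns 0, and
  at `nPerm` permutations the resolution floor is `1/(nPerm + 1)`.
  Summing or capping the two one-sided proportions would also be
  defensible; doubling was chosen as the most conservative of the three.

Calibration is part of the test suite: on length-proportionally placed
null peaks the proportion of `p < 0.05` across 200 independent datasets
stays within binomial tolerance of 0.05 for every chromatin state.

# Chromosome density and the binomial test

`chromosomeDensityTest` normalises peak counts per chromosome by length in
Mb and tests the X count among all peaks against the X's genome-length
share `p0` with the exact two-sided binomial test in the
minimum-likelihood convention of `stats::binom.test` (all outcomes no more
probable than the observed one are summed).  The same machinery drives
per-DE-group chromosome profiles (`deChromosomeProfile`) and the motif
density ratio (`motifDensityRatio`), which reports
`log2((xHits/xMb)/(autosomeHits/autosomeMb))`.

# Metagene profiles

`metageneMatrix` implements scale-regions binning with the geometry
1000 bp upstream, 3000 bp body, 1000 bp downstream at 50 bp bins
(20 + 60 + 20 = 100 bins) as defaults.  Body bins have fractional
boundaries (`gene length / 60` bp each); every bin value is the exact
integral of the piecewise-constant signal track over the bin divided by
the bin width, so no discretisation error is introduced and the
implementation is testable against a breakpoint-enumeration oracle at
`1e-9` tolerance.  Minus-strand rows are reversed so column 1 is always
the 5'-most bin; flank base pairs beyond a chromosome end contribute zero
at full weight; all-zero rows are dropped by default (`skipZeros`),
mirroring common practice.  The gene body spans annotated TSS to TES
*including* UTRs — profile shapes near the TSS are qualitatively
insensitive to this choice, and it avoids an arbitrary CDS-only
convention.  When genes have multiple isoforms the caller chooses one
region per gene; the package does not resolve isoforms.
`metageneProfile` reduces the matrix to per-group per-bin means with
standard errors (`sd/sqrt(n)`; a single-region group gets SEM 0 with a
warning).

# Downsampling and the depth artifact

Read-level downsampling is modelled on binned counts: `thinTrack`
replaces each count `c` by a `Binomial(c, fraction)` draw, optionally on
a subset of chromosomes (to depth-match arms, as when all female reads
and male autosomal reads are halved).  `callPeaksPoisson` is a
deliberately minimal caller — sliding windows of 4 bins, Poisson
upper-tail p against `lambda = controlWindow x ipTotal/controlTotal`
floored at the genome-wide mean IP rate per window, significant windows
merged — and is *not* a MACS2 reimplementation (no local lambda,
duplicate handling or fragment model).  It exists so that the
depth-dependence of peak counts is exercisable end to end
(`depthTitration`).

`generateDepthScenario` constructs the male-like situation in which the
X carries twice the autosomal peak density but half the sequencing depth.
Two mechanisms then suppress X peaks in a naive call: halved counts halve
the Poisson signal-to-noise of every planted site, and the genome-wide
background floor — dominated by the deeper autosomes — over-states the
X null rate.  After `thinTrack(fraction = 0.5)` on the autosomes both
effects vanish and the true 2-fold X excess emerges.  The scenario's
default parameters (840 counts/bin autosomal background, 1.15-fold
planted enrichment over 4-bin peaks, 250 peaks/Mb autosomal density) were
chosen so that planted peaks are reliably detectable at full depth and
reliably undetectable at half depth, making both directions of the
artifact assertable; they are scenario design constants, not fitted
quantities.

# Rank-sum comparisons

`rankSumTest` is a two-sided Mann-Whitney test with midrank ties: exact
enumeration when the pooled sample size is at most 12 and tie-free,
otherwise the normal approximation with tie and continuity correction
(`stats::wilcox.test` supplies both paths; tests verify them against a
full enumeration oracle).  Identical multisets return p = 1 by
convention.  `groupCompare` applies the test to per-gene quantities
(expression, mean MOF/H4K16ac signal from `meanSignalOverRegions`,
distance to chromosomal entry sites) across gene-level DE groups.
Distances from `nearestDistance` are half-open gaps in bp (0 for
overlapping or book-ended intervals); for plotting or comparison on a log
scale, transform as `log2(d + 1)` so that distance 0 is admissible.

Gene-level labels come from `labelGenes` with precedence FE > ME > nonDE:
a gene overlapping peaks of several classes takes the rarest-first label,
because the abundant nonDE class would otherwise swallow the sex-biased
classes entirely.  The precedence order is exposed as an argument.

# The synthetic-data generator

`generateDataset` is deterministic given `seed` and emulates, on the
five major arms scaled 1:100 (~235-321 kb each; real-scale lengths can be
passed via `chromLengths`):

* ~2-fold X-enriched peak density (`xDensityMultiplier = 2`), matching
  the roughly 2-fold X excess reported for Drosophila R-loops;
* a five-colour chromatin-state partition (RED/YELLOW active, BLUE
  Polycomb, GREEN HP1, BLACK repressive) tiling every base pair exactly
  once.  Segment lengths are exponential with mean 5 kb (~500 kb domains
  at real scale); labels are assigned by randomized quota so realized
  per-state genome shares track `stateProportions` to within about one
  segment.  Quota assignment matters: with freely sampled labels the
  realized share of a 10% state varies by several points, which would
  confound planted-enrichment recovery.  Peak placement probability
  within a chromosome is proportional to the local state's
  `stateEnrichment` multiplier.  Because a planted multiplier `m` in a
  state of share `s` raises that state's density relative to the *genome
  average*, the recoverable observed/expected ratio is `m/(1 - s + m s)`
  (2.5 for `m = 3`, `s = 0.1`), slightly attenuated further by peaks
  straddling segment boundaries (width/segment ~ 6%); the segment scale
  is chosen large relative to peak widths so this attenuation stays
  small;
* DE class fractions from the published DiffBind class sizes
  (`fracFE = 558/15281`, `fracME = 1282/15281`, ~12% sex-biased,
  ME:FE > 2) with 45% of ME peaks on the X and FE peaks placed
  length-proportionally;
* four per-sample peak sets (F379, F732, M379, M732) derived from the
  labelled consensus by sex-appropriate class inclusion, 20 bp coordinate
  jitter and 5% dropout — replicate realism only, no differential-binding
  model is simulated since those labels are pipeline inputs;
* per-sample signal tracks: Poisson background (`depthReadsPerMb`,
  default 10 counts per 50 bp bin) plus a Gaussian bump just downstream
  of the TSS at autosomal genes versus a uniform plateau across the gene
  body at X-linked genes, plus Gaussian noise (`signalNoiseSd`);
* planted motif occurrences (a CTC repeat and GGCGAAGGAG, two motifs
  with GC skew reported at female-enriched R-loops) with a 1.4-fold X
  density excess — matching the observation that R-loop motifs show
  less than 1.5-fold X enrichment — embedded verbatim (reverse
  complemented on minus-strand hits) at non-overlapping positions in an
  otherwise uniform random sequence, so scanning has exact ground truth;
* expression stochastically higher at peak-bearing genes
  (`exprSeparationSd`, default 1 SD) and binary presence calls linked to
  expression level.

What the generator does *not* emulate — read-level noise, fragment-size
and GC bias, replicate-level IDR structure, realistic gene density or
sequence composition, linkage between chromatin state and gene position —
bounds what passing tests show: they validate the statistical machinery
under its stated model, not robustness to the full messiness of real
DRIP-seq libraries.

# Problem sizes and numerical conventions

All coordinates are 0-based half-open at the I/O boundary (BED
convention) and 1-based closed inside (GRanges convention); conversion
happens only in the readers/writers.  Unknown chromosomes or
out-of-bounds records in input files are hard errors naming the line
number, never silently dropped.  Strand is ignored everywhere except
metagene orientation.  Ties in nearest-distance return the distance once;
which subject wins is unobservable.  Empty feature classes yield
observed = expected = 0 with an `NA` log-ratio rather than an error.

Default test and example problem sizes — 1:100-scaled genome, 1500-8000
peaks, 200-1000 permutations, 200 null replicates for calibration — keep
a full suite run in minutes on one CPU; `nPerm = 10000` reproduces the
publication-grade null at real scale in seconds per feature class because
all permutations are laid out as a single interval set per chunk.

# Known limitations

The consensus motif scanner is exact IUPAC matching, not a PWM model:
adequate for density-ratio statistics over planted or strongly conserved
motifs, it will undercount degenerate occurrences of information-poor
PWMs.  The window-Poisson caller's absolute peak counts are not
comparable to MACS2's; only their response to depth is meant to be.  The
generator's DE labels are assigned, not inferred, so pipelines that test
differential-binding callers need different inputs.
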