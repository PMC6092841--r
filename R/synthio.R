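## Truth-labeled synthetic capture-enrichment experiments.
##
## A molecule pool is a GRanges of distinct template molecules with metadata
## columns `template_id` and `origin` (endogenous_Y / endogenous_other /
## exogenous); exogenous templates live on the pseudo-reference "unmapped".
## Sequenced reads are a GRanges with `read_id`, `template_id`, `origin` and
## `mapping_quality`; reads copy their template's coordinates, so PCR
## duplicates share (reference, start, end, strand) by construction.

#' Generate a miniature set of on-target regions
#'
#' Places `nRegions` disjoint half-open intervals with total width
#' `totalTargetBp` uniformly at random on a reference of length
#' `referenceLength` — a reduced-scale stand-in for a probe-design region set
#' (the real design covers ~8.9 Mb of chrY in ~18,000 regions).
#'
#' @param referenceLength reference sequence length (bp).
#' @param nRegions number of regions (>= 1).
#' @param totalTargetBp summed region width (bp); must satisfy
#'   `nRegions <= totalTargetBp <= referenceLength`.
#' @param seed integer RNG seed.
#' @param reference reference sequence name (default `"chrY"`).
#' @return a sorted `GRanges` of disjoint target regions with `seqlengths`
#'   set; `sum(width())` equals `totalTargetBp`.
#' @export
#' @examples
#' makeTargetRegions(10000, 5, 2000, seed = 1)
makeTargetRegions <- function(referenceLength, nRegions, totalTargetBp, seed,
                              reference = "chrY") {
  if (nRegions < 1) stop("nRegions must be >= 1")
  if (totalTargetBp > referenceLength)
    stop("infeasible packing: totalTargetBp exceeds referenceLength")
  if (nRegions > totalTargetBp)
    stop("infeasible packing: cannot split ", totalTargetBp, " bp into ",
         nRegions, " nonempty regions")
  withSeed(seed, {
    widths <- if (nRegions == 1) totalTargetBp else
      diff(c(0, sort(sample.int(totalTargetBp - 1, nRegions - 1)),
             totalTargetBp))
    free <- referenceLength - totalTargetBp
    nGaps <- nRegions + 1
    gaps <- rep(0, nGaps)
    if (nRegions > 1 && free >= nRegions - 1) {
      # keep regions separated by >= 1 bp whenever space allows
      gaps[2:nRegions] <- 1
      free <- free - (nRegions - 1)
    }
    if (free > 0)
      gaps <- gaps + as.vector(stats::rmultinom(1, free, rep(1, nGaps)))
    start0 <- cumsum(gaps[seq_len(nRegions)]) +
      cumsum(c(0, widths[-nRegions]))
    gr <- GenomicRanges::GRanges(
      seqnames = reference,
      ranges = IRanges::IRanges(start = start0 + 1, width = widths),
      seqinfo = GenomeInfoDb::Seqinfo(reference, referenceLength))
    GenomicRanges::sort(gr)
  })
}

#' Simulate a finite pool of library template molecules
#'
#' Draws `poolSize` distinct templates: origin labels from the profile's
#' endogenous/Y proportions, fragment lengths from a lower-truncated normal,
#' strands uniform, and start coordinates uniform along the assigned
#' reference. Endogenous non-Y templates are spread over the non-Y references
#' proportionally to length; exogenous (environmental) templates are placed
#' on the pseudo-reference `"unmapped"`.
#'
#' @param profile a [LibraryProfile-class].
#' @param regions optional target regions; accepted for interface symmetry
#'   with [simulateCapture()] but unused — target definitions play no role
#'   before capture.
#' @param seed integer RNG seed; identical inputs and seed give identical
#'   pools.
#' @return a `GRanges` molecule pool (metadata columns `template_id`,
#'   `origin`).
#' @export
simulateMoleculePool <- function(profile, regions = NULL, seed) {
  methods::validObject(profile)
  refLens <- profile@referenceLengths
  otherRefs <- setdiff(names(refLens), profile@yName)
  if (profile@endogenousFraction * (1 - profile@yFraction) > 0 &&
      !length(otherRefs))
    stop("profile places endogenous templates off the Y but lists no other reference")
  P <- as.integer(profile@poolSize)
  allLens <- c(refLens, stats::setNames(max(1e6, 10 * sum(refLens)), UNMAPPED))
  withSeed(seed, {
    e <- profile@endogenousFraction
    origin <- sample(c("endogenous_Y", "endogenous_other", "exogenous"), P,
                     replace = TRUE,
                     prob = c(e * profile@yFraction,
                              e * (1 - profile@yFraction), 1 - e))
    ref <- character(P)
    ref[origin == "endogenous_Y"] <- profile@yName
    ref[origin == "exogenous"] <- UNMAPPED
    iOther <- which(origin == "endogenous_other")
    if (length(iOther))
      ref[iOther] <- sample(otherRefs, length(iOther), replace = TRUE,
                            prob = refLens[otherRefs])
    len <- round(rnormTruncLower(P, profile@fragmentLengthMean,
                                 profile@fragmentLengthSd, profile@minLength))
    len <- pmax(profile@minLength, pmin(len, allLens[ref]))
    start0 <- floor(stats::runif(P) * (allLens[ref] - len + 1))
    gr <- GenomicRanges::GRanges(
      seqnames = factor(ref, levels = names(allLens)),
      ranges = IRanges::IRanges(start = start0 + 1, width = len),
      strand = sample(c("+", "-"), P, replace = TRUE),
      template_id = sprintf("t%07d", seq_len(P)),
      origin = origin,
      seqinfo = GenomeInfoDb::Seqinfo(names(allLens), unname(allLens)))
    gr
  })
}

#' Amplify and sequence a molecule pool
#'
#' Draws `nReads` reads by sampling templates uniformly with replacement
#' (no amplification-efficiency bias). Duplicate structure arises from the
#' finite pool: the expected number of distinct templates observed is
#' `P * (1 - (1 - 1/P)^n)`.
#'
#' @param pool a `GRanges` molecule pool from [simulateMoleculePool()] or
#'   [simulateCapture()].
#' @param nReads number of reads to draw (>= 0).
#' @param seed integer RNG seed.
#' @return a `GRanges` read set (metadata columns `read_id`, `template_id`,
#'   `origin`, `mapping_quality`).
#' @export
amplifyAndSequence <- function(pool, nReads, seed) {
  if (nReads > 0 && length(pool) == 0)
    stop("cannot sequence from an empty pool")
  withSeed(seed, {
    idx <- if (nReads > 0) sample.int(length(pool), nReads, replace = TRUE)
           else integer()
    reads <- pool[idx]
    mapq <- ifelse(as.character(GenomicRanges::seqnames(reads)) == UNMAPPED,
                   0L, 37L)
    S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
      read_id = sprintf("r%08d", seq_len(nReads)),
      template_id = reads$template_id,
      origin = reads$origin,
      mapping_quality = mapq)
    reads
  })
}

#' Logistic length-bias multiplier of a capture round
#'
#' Monotone non-decreasing in template length, bounded in (0, 1], centred at
#' the probe length; returns 1 for every length when the profile's
#' `lengthBiasScale` is `NA`.
#'
#' @param length template lengths (bp).
#' @param capture a [CaptureProfile-class].
#' @return numeric multipliers in (0, 1].
#' @export
lengthBiasMultiplier <- function(length, capture) {
  if (is.na(capture@lengthBiasScale)) return(rep(1, base::length(length)))
  stats::plogis((length - capture@lengthBiasMidpoint) /
                  capture@lengthBiasScale)
}

#' Simulate one round of hybridization capture
#'
#' Each template is retained independently with probability
#' `classProbability * lengthBias(length)`; see [CaptureProfile-class].
#' A second round on the output models capture-after-capture (e.g.
#' whole-genome capture followed by Y capture) and can only lose complexity.
#'
#' @param pool a `GRanges` molecule pool.
#' @param regions target regions (`GRanges`); overlap by >= 1 bp puts a
#'   template in the on-target class.
#' @param capture a [CaptureProfile-class].
#' @param seed integer RNG seed.
#' @param yName Y-chromosome reference name for the off-target-Y class.
#' @return the retained sub-pool (`GRanges`).
#' @export
simulateCapture <- function(pool, regions, capture, seed, yName = "chrY") {
  methods::validObject(capture)
  if (!length(pool)) return(pool)
  onTarget <- IRanges::overlapsAny(pool, regions, ignore.strand = TRUE)
  isY <- as.character(GenomicRanges::seqnames(pool)) == yName
  p <- ifelse(onTarget, capture@pOnTarget,
              ifelse(isY, capture@pOffTargetY, capture@pBackground))
  p <- p * lengthBiasMultiplier(GenomicRanges::width(pool), capture)
  withSeed(seed, pool[stats::runif(length(pool)) < p])
}

#' Simulate a random Y haplogroup tree
#'
#' Grows a rooted tree by uniform random attachment and decorates every
#' non-root branch with `snpsPerBranch` defining SNPs at unique positions.
#'
#' @param nNodes total node count including the root.
#' @param seed integer RNG seed.
#' @param snpsPerBranch defining SNPs per non-root branch.
#' @param positionMax positions are drawn 0-based from `[0, positionMax)`.
#' @return a [HaplogroupTree-class].
#' @export
simulateHaplogroupTree <- function(nNodes, seed, snpsPerBranch = 1,
                                   positionMax = 1e6) {
  stopifnot(nNodes >= 2)
  withSeed(seed, {
    name <- c("ROOT", sprintf("H%03d", seq_len(nNodes - 1)))
    parent <- c(NA_character_,
                vapply(seq_len(nNodes - 1),
                       function(i) name[sample.int(i, 1)], character(1)))
    nSnps <- (nNodes - 1) * snpsPerBranch
    pos0 <- sort(sample.int(positionMax, nSnps)) - 1L
    anc <- sample(c("A", "C", "G", "T"), nSnps, replace = TRUE)
    der <- vapply(anc, function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1), character(1))
    snps <- data.frame(
      snp_id = sprintf("s%05d", seq_len(nSnps)),
      position = pos0,
      ancestral = anc, derived = unname(der),
      haplogroup = rep(name[-1], each = snpsPerBranch),
      stringsAsFactors = FALSE)
    newHaplogroupTree(data.frame(name = name, parent = parent,
                                 stringsAsFactors = FALSE), snps)
  })
}

#' Simulate a pileup of sequenced bases over a tree's SNP sites
#'
#' Sites on the root-to-`trueHaplogroup` path carry the derived allele, all
#' other sites the ancestral one. Per-site read depth is Poisson
#' (`meanDepth`); each base is flipped to a random other base with probability
#' `errorRate`; base qualities are drawn to straddle the Phred-13 quality
#' floor used by the haploid caller.
#'
#' @param tree a [HaplogroupTree-class].
#' @param trueHaplogroup node name whose lineage the individual carries.
#' @param meanDepth mean per-site depth of coverage (the shallow regime of
#'   captured ancient libraries is ~0.04--0.3x).
#' @param errorRate per-base error probability.
#' @param seed integer RNG seed.
#' @return a pileup `data.frame` with columns `position`, `base`, `quality`
#'   (one row per sequenced base).
#' @export
simulateGenotypes <- function(tree, trueHaplogroup, meanDepth,
                              errorRate = 0.001, seed) {
  if (!trueHaplogroup %in% tree@nodes$name)
    stop("unknown haplogroup: ", trueHaplogroup)
  path <- tree@rootPaths[[trueHaplogroup]]
  snps <- tree@snps
  truth <- ifelse(snps$haplogroup %in% path, snps$derived, snps$ancestral)
  withSeed(seed, {
    depth <- stats::rpois(nrow(snps), meanDepth)
    pos <- rep(snps$position, depth)
    base <- rep(truth, depth)
    n <- length(base)
    if (n) {
      err <- stats::runif(n) < errorRate
      if (any(err))
        base[err] <- vapply(base[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      quality <- sample(c(5L, 10L, 12L, 13L, 20L, 30L, 37L), n,
                        replace = TRUE,
                        prob = c(.04, .04, .04, .08, .2, .3, .3))
    } else quality <- integer()
    data.frame(position = pos, base = base, quality = quality,
               stringsAsFactors = FALSE)
  })
}
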