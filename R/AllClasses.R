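## Central S4 containers. Reads, molecule pools and target regions are plain
## GRanges with documented metadata columns (see synthio.R); the classes here
## carry model parameters and derived statistics.

#' LibraryProfile: parameters of a simulated aDNA sequencing library
#'
#' Describes the pre-capture molecule pool of one library: how many distinct
#' template molecules exist, which fraction is endogenous (host) vs
#' environmental, which fraction of the endogenous templates derives from the
#' Y chromosome, and the fragment-length distribution (lower-truncated normal).
#'
#' Defaults emulate a well-preserved archaeological library: endogenous
#' fraction 1.54\% with mean fragment length 91 bp; poorly preserved material
#' is modelled by dropping `endogenousFraction` to 0.0001--0.0004 and
#' `fragmentLengthMean` to ~65 bp.
#'
#' @slot poolSize number of distinct template molecules (>= 1).
#' @slot endogenousFraction proportion in [0,1] of templates of host origin.
#' @slot yFraction proportion in [0,1] of endogenous templates on the Y.
#' @slot fragmentLengthMean,fragmentLengthSd fragment length moments (bp).
#' @slot minLength minimum retained fragment length (bp); mean must exceed it.
#' @slot referenceLengths named numeric: reference sequence name -> length (bp);
#'   must contain `yName`.
#' @slot yName name of the Y-chromosome reference sequence.
#' @export
setClass("LibraryProfile", representation(
  poolSize = "numeric",
  endogenousFraction = "numeric",
  yFraction = "numeric",
  fragmentLengthMean = "numeric",
  fragmentLengthSd = "numeric",
  minLength = "numeric",
  referenceLengths = "numeric",
  yName = "character"
))

setValidity("LibraryProfile", function(object) {
  msg <- character()
  prop <- c(endogenousFraction = object@endogenousFraction,
            yFraction = object@yFraction)
  bad <- prop < 0 | prop > 1
  if (any(bad)) msg <- c(msg, paste(names(prop)[bad], "must lie in [0,1]"))
  if (object@poolSize < 1) msg <- c(msg, "poolSize must be >= 1")
  if (!(object@fragmentLengthMean > object@minLength && object@minLength > 0))
    msg <- c(msg, "need fragmentLengthMean > minLength > 0")
  if (object@fragmentLengthSd < 0) msg <- c(msg, "fragmentLengthSd must be >= 0")
  if (is.null(names(object@referenceLengths)) ||
      !all(nzchar(names(object@referenceLengths))))
    msg <- c(msg, "referenceLengths must be a named vector")
  if (!object@yName %in% names(object@referenceLengths))
    msg <- c(msg, "referenceLengths must contain an entry for yName")
  if (any(object@referenceLengths < object@minLength))
    msg <- c(msg, "every reference must be at least minLength long")
  if (length(msg)) msg else TRUE
})

#' @describeIn LibraryProfile-class constructor.
#' @param poolSize,endogenousFraction,yFraction,fragmentLengthMean,fragmentLengthSd,minLength,referenceLengths,yName see slots.
#' @export
LibraryProfile <- function(poolSize = 1e4,
                           endogenousFraction = 0.0154,
                           yFraction = 0.01,
                           fragmentLengthMean = 91,
                           fragmentLengthSd = 15,
                           minLength = 30,
                           referenceLengths = c(chrY = 5e4, chrX = 1.5e5,
                                                auto = 3e6),
                           yName = "chrY") {
  new("LibraryProfile", poolSize = poolSize,
      endogenousFraction = endogenousFraction, yFraction = yFraction,
      fragmentLengthMean = fragmentLengthMean,
      fragmentLengthSd = fragmentLengthSd, minLength = minLength,
      referenceLengths = referenceLengths, yName = yName)
}

setMethod("show", "LibraryProfile", function(object) {
  cat("LibraryProfile:", object@poolSize, "templates;",
      sprintf("%.3g%% endogenous (%.3g%% of those on %s);",
              100 * object@endogenousFraction, 100 * object@yFraction,
              object@yName),
      sprintf("length ~ truncN(%g, %g) >= %g bp\n", object@fragmentLengthMean,
              object@fragmentLengthSd, object@minLength))
})

#' CaptureProfile: retention model of one hybridization-capture round
#'
#' Each template is retained independently with probability
#' `classProbability * lengthBias(length)`, where the class probability is
#' `pOnTarget` for templates overlapping a target region, `pOffTargetY` for
#' Y-chromosome templates outside the targets, and `pBackground` otherwise
#' (including exogenous molecules). The length bias is a logistic multiplier
#' centred at the probe length (105 bp by default), reflecting the poorer
#' recovery of fragments much shorter than the probes; set
#' `lengthBiasScale = NA` to disable it.
#'
#' @slot pOnTarget,pOffTargetY,pBackground retention probabilities, with
#'   `0 <= pBackground <= pOffTargetY <= pOnTarget <= 1`.
#' @slot lengthBiasMidpoint logistic midpoint (bp), default 105.
#' @slot lengthBiasScale logistic scale (bp); `NA` disables the bias.
#' @export
setClass("CaptureProfile", representation(
  pOnTarget = "numeric",
  pOffTargetY = "numeric",
  pBackground = "numeric",
  lengthBiasMidpoint = "numeric",
  lengthBiasScale = "numeric"
))

setValidity("CaptureProfile", function(object) {
  p <- c(object@pBackground, object@pOffTargetY, object@pOnTarget)
  if (any(p < 0) || any(p > 1) || is.unsorted(p))
    return("need 0 <= pBackground <= pOffTargetY <= pOnTarget <= 1")
  if (!is.na(object@lengthBiasScale) && object@lengthBiasScale <= 0)
    return("lengthBiasScale must be positive or NA")
  TRUE
})

#' @describeIn CaptureProfile-class constructor.
#' @param pOnTarget,pOffTargetY,pBackground,lengthBiasMidpoint,lengthBiasScale see slots.
#' @export
CaptureProfile <- function(pOnTarget = 0.8, pOffTargetY = 0.05,
                           pBackground = 0.002,
                           lengthBiasMidpoint = 105, lengthBiasScale = 15) {
  new("CaptureProfile", pOnTarget = pOnTarget, pOffTargetY = pOffTargetY,
      pBackground = pBackground, lengthBiasMidpoint = lengthBiasMidpoint,
      lengthBiasScale = as.numeric(lengthBiasScale))
}

setMethod("show", "CaptureProfile", function(object) {
  cat(sprintf(
    "CaptureProfile: p(on-target)=%g p(off-target Y)=%g p(background)=%g",
    object@pOnTarget, object@pOffTargetY, object@pBackground))
  if (is.na(object@lengthBiasScale)) cat("; no length bias\n")
  else cat(sprintf("; logistic length bias @ %g bp (scale %g)\n",
                   object@lengthBiasMidpoint, object@lengthBiasScale))
})

#' DuplicateHistogram: counts of templates seen j times
#'
#' The sufficient statistic for library-complexity extrapolation: `counts[j]`
#' is the number of distinct template molecules observed exactly `j` times in
#' the mapped reads.
#'
#' @slot counts named numeric vector; names are multiplicities `j >= 1`.
#' @export
setClass("DuplicateHistogram", representation(counts = "numeric"))

setValidity("DuplicateHistogram", function(object) {
  j <- suppressWarnings(as.numeric(names(object@counts)))
  if (length(object@counts) == 0) return("histogram must be nonempty")
  if (any(is.na(j)) || any(j < 1) || any(j != round(j)))
    return("names must be integer multiplicities >= 1")
  if (anyDuplicated(j)) return("duplicate multiplicity entries")
  if (any(object@counts < 0)) return("counts must be >= 0")
  TRUE
})

#' @describeIn DuplicateHistogram-class constructor from parallel vectors of
#'   multiplicities and class counts.
#' @param multiplicity integer vector of multiplicities `j`.
#' @param count number of distinct templates seen exactly `j` times.
#' @export
DuplicateHistogram <- function(multiplicity, count) {
  o <- order(multiplicity)
  counts <- as.numeric(count[o])
  names(counts) <- as.character(multiplicity[o])
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty duplicate histogram")
  new("DuplicateHistogram", counts = counts)
}

setMethod("show", "DuplicateHistogram", function(object) {
  cat("DuplicateHistogram:", distinctReads(object), "distinct templates in",
      totalReads(object), "reads;", "max multiplicity",
      max(as.numeric(names(object@counts))), "\n")
})

## -- Yield models -----------------------------------------------------------

#' Yield models for library-complexity extrapolation
#'
#' `ZTNBModel` is a zero-truncated negative-binomial empirical-Bayes model of
#' per-template read counts fitted by [fitYieldModel()]; `LinearYieldModel` is
#' the duplicate-free fallback of [linearFallback()]. Both answer
#' [expectedYield()]: the expected number of distinct templates observed after
#' a given sequencing effort.
#'
#' @slot observedReads reads used to fit the model. For `ZTNBModel` this is
#'   the on-target mapped read count underlying the histogram; for
#'   `LinearYieldModel` it is the total sequenced read count (its slope
#'   already contains the on-target fraction).
#' @slot observedDistinct distinct templates observed at that effort.
#' @name YieldModel-classes
NULL

#' @rdname YieldModel-classes
#' @export
setClass("YieldModel", representation("VIRTUAL",
  observedReads = "numeric", observedDistinct = "numeric"))

#' @rdname YieldModel-classes
#' @slot size,mu negative-binomial dispersion and mean at observed effort.
#' @slot librarySize estimated total number of distinct templates.
#' @export
setClass("ZTNBModel", contains = "YieldModel", representation(
  size = "numeric", mu = "numeric", librarySize = "numeric"))

#' @rdname YieldModel-classes
#' @slot slope unique on-target reads per total sequenced read.
#' @export
setClass("LinearYieldModel", contains = "YieldModel",
         representation(slope = "numeric"))

setMethod("show", "ZTNBModel", function(object) {
  cat(sprintf(
    "ZTNBModel: library size %.1f (observed %.0f distinct / %.0f reads); k=%.3g mu=%.3g\n",
    object@librarySize, object@observedDistinct, object@observedReads,
    object@size, object@mu))
})

setMethod("show", "LinearYieldModel", function(object) {
  cat(sprintf("LinearYieldModel: slope %.3g unique on-target reads per sequenced read\n",
              object@slope))
})

#' YieldCurve: expected unique on-target reads vs total sequencing effort
#'
#' @slot effort grid of total sequenced reads.
#' @slot yield point estimate of expected distinct on-target reads.
#' @slot median,variance per-grid-point bootstrap median and variance
#'   (NA when no bootstrap was run).
#' @slot onTargetFraction fraction used to convert total to on-target effort.
#' @slot modelTag `"ztnb"` or `"linear"`.
#' @export
setClass("YieldCurve", representation(
  effort = "numeric", yield = "numeric", median = "numeric",
  variance = "numeric", onTargetFraction = "numeric", modelTag = "character"))

setValidity("YieldCurve", function(object) {
  n <- length(object@effort)
  if (length(object@yield) != n || length(object@median) != n ||
      length(object@variance) != n)
    return("effort, yield, median and variance must have equal length")
  if (is.unsorted(object@effort)) return("effort grid must be sorted")
  TRUE
})

setMethod("show", "YieldCurve", function(object) {
  cat(sprintf(
    "YieldCurve (%s): %d grid points over [%g, %g] total reads; on-target fraction %.3g\n",
    object@modelTag, length(object@effort), min(object@effort),
    max(object@effort), object@onTargetFraction))
  if (!all(is.na(object@median))) cat("  bootstrap median/variance attached\n")
})

#' EnrichmentCurve: predicted fold-enrichment vs sequencing effort
#'
#' Pointwise ratio of two [YieldCurve-class] medians on a shared effort grid.
#'
#' @slot effort shared grid of total sequenced reads.
#' @slot fold predicted fold-enrichment (NA where the denominator is zero).
#' @slot numeratorLabel,denominatorLabel condition labels.
#' @export
setClass("EnrichmentCurve", representation(
  effort = "numeric", fold = "numeric",
  numeratorLabel = "character", denominatorLabel = "character"))

setMethod("show", "EnrichmentCurve", function(object) {
  cat(sprintf("EnrichmentCurve: %s vs %s over %d efforts; max fold %.1f\n",
              object@numeratorLabel, object@denominatorLabel,
              length(object@effort), suppressWarnings(max(object@fold,
                                                          na.rm = TRUE))))
})

## -- Y-chromosome classes ---------------------------------------------------

#' HaplogroupTree: rooted Y phylogeny with branch-defining SNPs
#'
#' @slot nodes data.frame with columns `name`, `parent` (NA for the root) and
#'   `depth` (root = 0).
#' @slot snps data.frame with columns `snp_id`, `position` (0-based chrY),
#'   `ancestral`, `derived`, `haplogroup` (the node whose branch the SNP
#'   defines). Positions are unique across the tree.
#' @slot rootPaths named list: node -> character vector of node names from the
#'   root down to that node (inclusive).
#' @export
setClass("HaplogroupTree", representation(
  nodes = "data.frame", snps = "data.frame", rootPaths = "list"))

setValidity("HaplogroupTree", function(object) {
  msg <- character()
  nd <- object@nodes
  if (sum(is.na(nd$parent)) != 1) msg <- c(msg, "tree must have exactly one root")
  if (anyDuplicated(nd$name)) msg <- c(msg, "duplicate node names")
  sp <- object@snps
  if (nrow(sp)) {
    if (anyDuplicated(sp$position)) msg <- c(msg, "duplicate SNP positions")
    if (any(sp$ancestral == sp$derived))
      msg <- c(msg, "ancestral and derived alleles must differ")
    if (!all(c(sp$ancestral, sp$derived) %in% c("A", "C", "G", "T")))
      msg <- c(msg, "alleles must be A/C/G/T")
    if (!all(sp$haplogroup %in% nd$name))
      msg <- c(msg, "SNP assigned to unknown node")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HaplogroupTree", function(object) {
  cat("HaplogroupTree:", nrow(object@nodes), "nodes,", nrow(object@snps),
      "SNPs, max depth", max(object@nodes$depth), "\n")
})

#' HaplogroupCall: result of the most-derived-SNP tree search
#'
#' @slot haplogroup assigned node name, or `NA` when unresolved.
#' @slot mostDerivedSnp id of the deepest supporting derived SNP (`NA` when
#'   unresolved).
#' @slot nDerivedPath,nAncestralPath derived/ancestral call counts at SNPs on
#'   the supporting root path.
#' @slot conflicts snp_ids of derived calls off the chosen path.
#' @slot candidates equally supported nodes when a depth tie forced an
#'   unresolved call.
#' @slot nIgnored calls at positions absent from the tree.
#' @export
setClass("HaplogroupCall", representation(
  haplogroup = "character", mostDerivedSnp = "character",
  nDerivedPath = "integer", nAncestralPath = "integer",
  conflicts = "character", candidates = "character", nIgnored = "integer"))

setMethod("show", "HaplogroupCall", function(object) {
  if (is.na(object@haplogroup)) {
    cat("HaplogroupCall: unresolved (-)")
    if (length(object@candidates))
      cat("; tied candidates:", paste(object@candidates, collapse = ", "))
    cat("\n")
  } else {
    cat(sprintf(
      "HaplogroupCall: %s (most derived SNP %s; %d derived / %d ancestral on path; %d conflicts)\n",
      object@haplogroup, object@mostDerivedSnp, object@nDerivedPath,
      object@nAncestralPath, length(object@conflicts)))
  }
})

#' SexResult: genetic sex assignment from sex-chromosome read counts
#'
#' @slot nChrX,nChrY reads mapping to each sex chromosome.
#' @slot ry `nChrY / (nChrX + nChrY)`.
#' @slot ciLower,ciUpper normal-approximation 95\% interval, clipped to [0,1].
#' @slot threshold decision threshold (default 0.075).
#' @slot assignment one of `"consistent-with-XY"`, `"not-consistent-with-XY"`,
#'   `"indeterminate"`.
#' @export
setClass("SexResult", representation(
  nChrX = "numeric", nChrY = "numeric", ry = "numeric",
  ciLower = "numeric", ciUpper = "numeric", threshold = "numeric",
  assignment = "character"))

setMethod("show", "SexResult", function(object) {
  cat(sprintf("SexResult: Ry = %.4f [%.4f, %.4f] (chrY %.0f / chrX %.0f) -> %s\n",
              object@ry, object@ciLower, object@ciUpper, object@nChrY,
              object@nChrX, object@assignment))
})
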