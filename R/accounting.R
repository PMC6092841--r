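## Per-library read accounting: deduplication, on/off-target classification,
## down-sampling replicates, Table-style metrics and confidence intervals.

#' Remove PCR duplicates by mapped coordinates
#'
#' Reads are duplicates iff they share (reference, start, end, strand) — both
#' fragment ends plus orientation, so distinct templates are never merged.
#' One representative per duplicate class is kept: the read with the smallest
#' `read_id` (deterministic tie-break).
#'
#' @param reads a `GRanges` read set with a `read_id` metadata column.
#' @return a list with elements `unique` (the representative reads, input
#'   order of coordinates preserved by sorting on the duplicate key) and
#'   `histogram` (a [DuplicateHistogram-class]; `sum(j * n_j)` equals
#'   `length(reads)`).
#' @export
deduplicate <- function(reads) {
  if (!length(reads)) {
    return(list(unique = reads,
                histogram = NULL))
  }
  key <- paste(GenomicRanges::seqnames(reads), GenomicRanges::start(reads),
               GenomicRanges::end(reads), GenomicRanges::strand(reads),
               sep = "\r")
  o <- order(key, reads$read_id, method = "radix")
  first <- !duplicated(key[o])
  classSize <- as.integer(table(key))
  tab <- table(classSize)
  list(unique = reads[o][first],
       histogram = DuplicateHistogram(as.integer(names(tab)),
                                      as.integer(tab)))
}

#' Partition reads by target overlap
#'
#' A read is on-target iff its mapped interval overlaps any target interval
#' by at least one base (half-open file coordinates; touching intervals do
#' not overlap). The partition is exhaustive and disjoint.
#'
#' @param reads a `GRanges` read set.
#' @param regions target regions (`GRanges`).
#' @return list of `GRanges`: `on_target`, `off_target_same_reference`
#'   (same reference as the targets, no overlap), `other`.
#' @export
classifyOnTarget <- function(reads, regions) {
  hit <- IRanges::overlapsAny(reads, regions, ignore.strand = TRUE)
  sameRef <- as.character(GenomicRanges::seqnames(reads)) %in%
    unique(as.character(GenomicRanges::seqnames(regions)))
  list(on_target = reads[hit],
       off_target_same_reference = reads[!hit & sameRef],
       other = reads[!hit & !sameRef])
}

#' Minimum retained read count across experimental conditions
#'
#' The common down-sampling depth for one individual: the smallest number of
#' retained reads across its experimental conditions.
#'
#' @param readCountsByCondition named numeric vector or list,
#'   condition -> retained read count.
#' @return the minimum count.
#' @export
minRetainedReads <- function(readCountsByCondition) {
  x <- unlist(readCountsByCondition)
  if (!length(x)) stop("no conditions supplied")
  min(x)
}

#' Down-sample a read set into replicates
#'
#' Draws `nReplicates` uniform samples without replacement of exactly `n`
#' reads; replicate `r` uses seed `baseSeed + r`, so individual replicates
#' are reproducible in isolation.
#'
#' @param reads a `GRanges` read set.
#' @param n reads per replicate; must not exceed `length(reads)`.
#' @param nReplicates number of replicates (default 10).
#' @param baseSeed integer; replicate `r` is seeded with `baseSeed + r`.
#' @return list of `GRanges` subsets of length `nReplicates`.
#' @export
downsampleReads <- function(reads, n, nReplicates = 10, baseSeed) {
  if (n > length(reads))
    stop("cannot down-sample ", length(reads), " reads to ", n)
  lapply(seq_len(nReplicates), function(r)
    withSeed(baseSeed + r, reads[sample.int(length(reads), n)]))
}

#' Per-library metrics of one read set
#'
#' Computes the per-library condition-table quantities: unique (deduplicated)
#' read counts overall, on the Y and on target, endogenous content, clonality
#' and the two on-target percentages. Mapped reads are those not on the
#' `"unmapped"` pseudo-reference. Zero-denominator ratios are reported as
#' `NA` (the "-" convention). Internal values keep full precision; see
#' [formatMetrics()] for display rounding.
#'
#' @param reads a `GRanges` read set (mapped and unmapped reads together).
#' @param regions target regions (`GRanges`).
#' @param yName Y-chromosome reference name.
#' @return one-row `data.frame` with columns `total_reads`, `mapped_reads`,
#'   `unique_mapped`, `chrY_unique`, `on_target_unique`,
#'   `off_target_chrY_unique`, `endogenous_pct`, `clonality_pct`,
#'   `pct_sequenced_on_target`, `pct_chrY_on_target`, `mean_length`.
#' @export
libraryMetrics <- function(reads, regions, yName = "chrY") {
  mapped <- reads[as.character(GenomicRanges::seqnames(reads)) != UNMAPPED]
  uniq <- deduplicate(mapped)$unique
  yUniq <- uniq[as.character(GenomicRanges::seqnames(uniq)) == yName]
  onT <- sum(IRanges::overlapsAny(yUniq, regions, ignore.strand = TRUE))
  nTot <- length(reads); nMap <- length(mapped); nU <- length(uniq)
  nY <- length(yUniq)
  data.frame(
    total_reads = nTot,
    mapped_reads = nMap,
    unique_mapped = nU,
    chrY_unique = nY,
    on_target_unique = onT,
    off_target_chrY_unique = nY - onT,
    endogenous_pct = if (nTot > 0) 100 * nU / nTot else NA_real_,
    clonality_pct = if (nMap > 0) 100 * (nMap - nU) / nMap else NA_real_,
    pct_sequenced_on_target = if (nTot > 0) 100 * onT / nTot else NA_real_,
    pct_chrY_on_target = if (nY > 0) 100 * onT / nY else NA_real_,
    mean_length = if (nU > 0) mean(GenomicRanges::width(uniq)) else NA_real_)
}

#' Display rounding of per-library metrics
#'
#' Follows the published table conventions: "% of sequenced on-target" with
#' two decimals, "% of chrY on-target" as a whole percent (half-up), missing
#' ratios printed as "-".
#'
#' @param metrics a row (or rows) from [libraryMetrics()].
#' @return `data.frame` of formatted strings.
#' @export
formatMetrics <- function(metrics) {
  pct2 <- function(x) ifelse(is.na(x), "-",
                             sprintf("%.2f%%", roundHalfUp(x, 2)))
  pct0 <- function(x) ifelse(is.na(x), "-",
                             sprintf("%.0f%%", roundHalfUp(x, 0)))
  data.frame(
    pct_sequenced_on_target = pct2(metrics$pct_sequenced_on_target),
    pct_chrY_on_target = pct0(metrics$pct_chrY_on_target),
    clonality_pct = pct2(metrics$clonality_pct),
    endogenous_pct = pct2(metrics$endogenous_pct))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials counts (successes may be a non-integer mean count).
#' @param level confidence level (default 0.95).
#' @return named numeric `c(lower, upper)`, contained in [0,1] and containing
#'   `successes / trials`.
#' @export
binomialCI <- function(successes, trials, level = 0.95) {
  stopifnot(trials > 0, successes >= 0, successes <= trials)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Paired t-test on per-library mean read lengths
#'
#' Two-sided paired t-test on the differences of paired length means, used to
#' test for the fragment-length shift after capture. Constant differences
#' (zero variance) are degenerate for the t statistic and flagged rather than
#' tested; identical lists return `t = 0`, `p = 1`.
#'
#' @param meanLengthsA,meanLengthsB paired numeric vectors (bp), length >= 2.
#' @return list with `statistic`, `p.value`, `df`, `degenerate`.
#' @export
pairedLengthTest <- function(meanLengthsA, meanLengthsB) {
  stopifnot(length(meanLengthsA) == length(meanLengthsB),
            length(meanLengthsA) >= 2)
  d <- meanLengthsA - meanLengthsB
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(statistic = 0, p.value = 1, df = length(d) - 1,
                  degenerate = TRUE))
    return(list(statistic = NA_real_, p.value = NA_real_,
                df = length(d) - 1, degenerate = TRUE))
  }
  tt <- stats::t.test(meanLengthsA, meanLengthsB, paired = TRUE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Summarise down-sampling replicates of one library condition
#'
#' Runs [libraryMetrics()] on each replicate and reports per-metric means
#' plus Wilson 95\% confidence intervals for the proportion metrics (computed
#' from the mean count over the replicate's fixed denominator, on the percent
#' scale).
#'
#' @param replicates list of `GRanges` read sets from [downsampleReads()].
#' @param regions target regions.
#' @param yName Y-chromosome reference name.
#' @param level confidence level.
#' @return an object of class `ReplicateSummary`: list with `metrics`
#'   (per-replicate `data.frame`), `mean` (named numeric), `ci`
#'   (`data.frame` metric/lower/upper, percent scale), `n_replicates`.
#' @export
replicateSummary <- function(replicates, regions, yName = "chrY",
                             level = 0.95) {
  metrics <- do.call(rbind, lapply(replicates, libraryMetrics,
                                   regions = regions, yName = yName))
  means <- colMeans(metrics, na.rm = TRUE)
  n <- metrics$total_reads[1]
  ciOf <- function(successMean, trials) {
    if (is.na(successMean) || trials <= 0 || successMean > trials)
      return(c(lower = NA_real_, upper = NA_real_))
    100 * binomialCI(successMean, trials, level)
  }
  ci <- rbind(
    endogenous_pct = ciOf(means[["unique_mapped"]], n),
    pct_sequenced_on_target = ciOf(means[["on_target_unique"]], n),
    clonality_pct = ciOf(means[["mapped_reads"]] - means[["unique_mapped"]],
                         means[["mapped_reads"]]),
    pct_chrY_on_target = ciOf(means[["on_target_unique"]],
                              means[["chrY_unique"]]))
  ci <- data.frame(metric = rownames(ci), lower = ci[, "lower"],
                   upper = ci[, "upper"], row.names = NULL)
  structure(list(metrics = metrics, mean = means, ci = ci,
                 n_replicates = length(replicates)),
            class = "ReplicateSummary")
}

#' @export
print.ReplicateSummary <- function(x, ...) {
  cat("ReplicateSummary over", x$n_replicates, "replicates of",
      x$metrics$total_reads[1], "reads\n")
  cat(sprintf("  mean on-target unique: %.1f  (%% of sequenced: %.3g%%)\n",
              x$mean[["on_target_unique"]],
              x$mean[["pct_sequenced_on_target"]]))
  invisible(x)
}
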