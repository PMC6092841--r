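## Fold-enrichment between experimental conditions and the condition grid.

#' Fold-enrichment between two conditions
#'
#' Ratio of mean unique on-target read counts at matched sequencing effort.
#' When the denominator is zero the numerator itself is assigned (the
#' published zero-denominator convention for libraries whose baseline
#' replicates had no on-target reads). An alternative convention — dividing
#' by a supplied fallback `baseline`, e.g. the maximum replicate count of the
#' baseline library — is available via `zeroRule = "baseline"`.
#'
#' @param onTargetMean1 numerator condition's mean unique on-target reads.
#' @param onTargetMean2 denominator condition's mean (the baseline).
#' @param zeroRule `"numerator"` (default) or `"baseline"`.
#' @param baseline fallback denominator for `zeroRule = "baseline"`.
#' @return the fold-enrichment at full precision; display with one-decimal
#'   half-up rounding (see [roundHalfUp()]).
#' @export
#' @examples
#' foldEnrichment(16191, 2.3)          # ~7039.6
#' foldEnrichment(12, 0)               # 12: zero-denominator rule
foldEnrichment <- function(onTargetMean1, onTargetMean2,
                           zeroRule = c("numerator", "baseline"),
                           baseline = NULL) {
  zeroRule <- match.arg(zeroRule)
  if (onTargetMean1 < 0 || onTargetMean2 < 0)
    stop("on-target means must be >= 0")
  if (onTargetMean2 > 0) return(onTargetMean1 / onTargetMean2)
  switch(zeroRule,
         numerator = onTargetMean1,
         baseline = {
           if (is.null(baseline) || baseline <= 0)
             stop("zeroRule = 'baseline' needs a positive baseline")
           onTargetMean1 / baseline
         })
}

## The six ordered condition pairs of the enrichment grid.
ENRICHMENT_PAIRS <- list(
  c("YCC", "pre"), c("YCC", "WGC"), c("YCC", "WGC+YCC"),
  c("WGC", "pre"), c("WGC+YCC", "pre"), c("WGC+YCC", "WGC"))

#' Assemble the per-sample condition grid of fold-enrichments
#'
#' Emits the six ordered condition pairs (YCC/pre, YCC/WGC, YCC/WGC+YCC,
#' WGC/pre, WGC+YCC/pre, WGC+YCC/WGC) for every sample present. Pairs whose
#' conditions are missing for a sample are omitted with a warning.
#'
#' @param onTargetMeans `data.frame` with columns `sample`, `condition`
#'   (values among `"pre"`, `"YCC"`, `"WGC"`, `"WGC+YCC"`) and
#'   `on_target_mean` (mean unique on-target reads over the down-sampling
#'   replicates).
#' @param zeroRule,baselines passed to [foldEnrichment()]; `baselines`
#'   optionally maps `sample` to the fallback denominator.
#' @return `data.frame` with columns `sample`, `condition1`, `condition2`,
#'   `fold` (full precision) and `fold_display` (one-decimal half-up).
#' @export
buildEnrichmentTable <- function(onTargetMeans, zeroRule = "numerator",
                                 baselines = NULL) {
  stopifnot(all(c("sample", "condition", "on_target_mean") %in%
                  names(onTargetMeans)))
  rows <- list()
  for (s in unique(onTargetMeans$sample)) {
    sub <- onTargetMeans[onTargetMeans$sample == s, ]
    get <- function(cond) sub$on_target_mean[match(cond, sub$condition)]
    for (pair in ENRICHMENT_PAIRS) {
      m1 <- get(pair[1]); m2 <- get(pair[2])
      if (is.na(m1) || is.na(m2)) {
        warning("sample ", s, ": pair ", pair[1], "/", pair[2],
                " omitted (condition missing)", call. = FALSE)
        next
      }
      f <- foldEnrichment(m1, m2, zeroRule = zeroRule,
                          baseline = baselines[[s]])
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, condition1 = pair[1], condition2 = pair[2],
        fold = f, fold_display = roundHalfUp(f, 1),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(), condition1 = character(),
                      condition2 = character(), fold = numeric(),
                      fold_display = numeric()))
  do.call(rbind, rows)
}
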