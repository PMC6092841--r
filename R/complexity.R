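## Library-complexity extrapolation: zero-truncated negative-binomial model of
## per-template read counts, yield curves vs sequencing effort with bootstrap
## uncertainty, linear fallback for duplicate-free libraries, and enrichment
## curves between conditions.

noDuplicatesError <- function() {
  structure(class = c("ycaptureNoDuplicates", "error", "condition"),
            list(message = paste("histogram contains no duplicates;",
                                 "use linearFallback()"),
                 call = sys.call(-1)))
}

#' Fit a zero-truncated negative-binomial complexity model
#'
#' Models the number of reads per template molecule as negative binomial
#' (dispersion `k`, mean `mu`); templates with zero reads are unobserved, so
#' the duplicate histogram is a zero-truncated sample. The fit is maximum
#' likelihood via EM over the latent zero class: the E-step imputes the
#' expected number of unseen templates `n0 = D p0 / (1 - p0)`, the M-step
#' refits `mu` (closed form) and `k` (one-dimensional likelihood
#' maximisation) on the completed histogram. The estimated library size is
#' `L = D / (1 - p0)`, which makes the expected yield interpolate the
#' observed distinct count exactly at the observed effort.
#'
#' @param hist a [DuplicateHistogram-class] containing at least one class
#'   with multiplicity >= 2.
#' @param maxIter,tol EM iteration cap and relative convergence tolerance.
#' @return a [ZTNBModel-class].
#' @seealso [linearFallback()] for duplicate-free histograms,
#'   [expectedYield()], [extrapolateYield()].
#' @export
fitYieldModel <- function(hist, maxIter = 200, tol = 1e-8) {
  j <- as.numeric(names(hist@counts))
  n <- hist@counts
  if (max(j) < 2) stop(noDuplicatesError())
  D <- sum(n)
  S <- sum(j * n)
  mu <- S / D
  k <- 1
  for (it in seq_len(maxIter)) {
    p0 <- (k / (k + mu))^k
    n0 <- D * p0 / (1 - p0)
    muNew <- S / (D + n0)
    nll <- function(logk) {
      kk <- exp(logk)
      -(n0 * stats::dnbinom(0, size = kk, mu = muNew, log = TRUE) +
          sum(n * stats::dnbinom(j, size = kk, mu = muNew, log = TRUE)))
    }
    kNew <- exp(stats::optimize(nll, c(log(1e-3), log(1e6)))$minimum)
    done <- abs(muNew - mu) < tol * (mu + tol) &&
      abs(kNew - k) < tol * (k + tol)
    mu <- muNew; k <- kNew
    if (done) break
  }
  p0 <- (k / (k + mu))^k
  new("ZTNBModel", size = k, mu = mu, librarySize = D / (1 - p0),
      observedReads = S, observedDistinct = D)
}

#' Linear yield model for duplicate-free libraries
#'
#' Without duplicated reads the saturation of a library cannot be estimated;
#' the expected unique on-target yield is instead taken linear in total
#' sequencing effort with slope equal to the proportion of unique on-target
#' reads in the library: `yield(n) = n * uniqueOnTarget / totalReads`.
#'
#' @param uniqueOnTarget unique on-target reads observed.
#' @param totalReads total sequenced reads of the library.
#' @return a [LinearYieldModel-class].
#' @export
linearFallback <- function(uniqueOnTarget, totalReads) {
  stopifnot(totalReads > 0, uniqueOnTarget >= 0)
  new("LinearYieldModel", slope = uniqueOnTarget / totalReads,
      observedReads = totalReads, observedDistinct = uniqueOnTarget)
}

#' @rdname expectedYield
setMethod("expectedYield", "ZTNBModel", function(model, nReads) {
  stopifnot(all(nReads >= 0))
  t <- nReads / model@observedReads
  p0t <- (model@size / (model@size + model@mu * t))^model@size
  model@librarySize * (1 - p0t)
})

#' @rdname expectedYield
setMethod("expectedYield", "LinearYieldModel", function(model, nReads) {
  stopifnot(all(nReads >= 0))
  model@slope * nReads
})

## Convert a grid of total sequenced reads into the model's own effort unit.
modelEffort <- function(model, totalEffort, onTargetFraction) {
  if (methods::is(model, "ZTNBModel")) totalEffort * onTargetFraction
  else totalEffort
}

#' Extrapolate a yield curve over a sequencing-effort grid
#'
#' Evaluates a fitted yield model over a grid of *total sequenced reads*,
#' correcting the effort by the library's on-target fraction (only an
#' `onTargetFraction` of sequenced reads can hit the targets; the
#' duplicate-histogram model lives in on-target read units). Linear fallback
#' models already express their slope per total sequenced read, so no
#' correction is applied to them.
#'
#' @param model a [ZTNBModel-class] or [LinearYieldModel-class].
#' @param effortGrid total-sequenced-read grid (values >= 0); sorted
#'   internally with a warning if unsorted.
#' @param onTargetFraction proportion of sequenced reads mapping on target,
#'   in (0, 1].
#' @return a [YieldCurve-class] (bootstrap slots `NA`).
#' @export
extrapolateYield <- function(model, effortGrid, onTargetFraction = 1) {
  stopifnot(all(effortGrid >= 0), onTargetFraction > 0, onTargetFraction <= 1)
  if (is.unsorted(effortGrid)) {
    warning("effort grid was not sorted; sorting")
    effortGrid <- sort(effortGrid)
  }
  y <- expectedYield(model, modelEffort(model, effortGrid, onTargetFraction))
  new("YieldCurve", effort = effortGrid, yield = y,
      median = rep(NA_real_, length(effortGrid)),
      variance = rep(NA_real_, length(effortGrid)),
      onTargetFraction = onTargetFraction,
      modelTag = if (methods::is(model, "ZTNBModel")) "ztnb" else "linear")
}

#' Default sequencing-effort grid
#'
#' @param from,to,points log-spaced grid limits (total sequenced reads) and
#'   number of points.
#' @return numeric grid.
#' @export
effortGrid <- function(from = 1e2, to = 1e7, points = 50) {
  exp(seq(log(from), log(to), length.out = points))
}

#' Bootstrap yield-curve uncertainty
#'
#' Each bootstrap replicate resamples the observed reads multinomially over
#' the observed template classes (resampling sequencing effort, not
#' templates), rebuilds the duplicate histogram, refits the model and
#' re-extrapolates. Replicates whose resampled histogram is duplicate-free
#' fall back to the linear model. Per grid point the median and variance
#' across replicates are reported.
#'
#' @param hist a [DuplicateHistogram-class].
#' @param effortGrid total-sequenced-read grid.
#' @param onTargetFraction proportion of sequenced reads on target.
#' @param nBoot bootstrap replicates (default 100).
#' @param seed integer RNG seed.
#' @return a [YieldCurve-class] with `yield` from the full-data model and
#'   `median`/`variance` from the bootstrap.
#' @export
bootstrapYield <- function(hist, effortGrid, onTargetFraction = 1,
                           nBoot = 100, seed) {
  if (is.unsorted(effortGrid)) effortGrid <- sort(effortGrid)
  j <- as.numeric(names(hist@counts))
  classSizes <- rep(j, hist@counts)
  S <- sum(classSizes)
  full <- fitOrFallback(hist, onTargetFraction)
  pointCurve <- extrapolateYield(full, effortGrid, onTargetFraction)
  mat <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      cnt <- as.vector(stats::rmultinom(1, S, classSizes / S))
      cnt <- cnt[cnt > 0]
      tab <- table(cnt)
      h <- DuplicateHistogram(as.integer(names(tab)), as.integer(tab))
      m <- fitOrFallback(h, onTargetFraction)
      expectedYield(m, modelEffort(m, effortGrid, onTargetFraction))
    }, numeric(length(effortGrid)))
  })
  mat <- matrix(mat, nrow = length(effortGrid))
  new("YieldCurve", effort = effortGrid, yield = pointCurve@yield,
      median = apply(mat, 1, stats::median),
      variance = apply(mat, 1, stats::var),
      onTargetFraction = onTargetFraction,
      modelTag = pointCurve@modelTag)
}

## ZTNB fit with automatic linear fallback for duplicate-free histograms.
## The fallback slope is expressed per total sequenced read, so the on-target
## read count is divided back by the on-target fraction.
fitOrFallback <- function(hist, onTargetFraction) {
  tryCatch(fitYieldModel(hist),
           ycaptureNoDuplicates = function(e)
             linearFallback(distinctReads(hist),
                            totalReads(hist) / onTargetFraction))
}

#' Predicted enrichment curve between two conditions
#'
#' Pointwise ratio of the bootstrap medians of two yield curves sharing an
#' effort grid (numerator / denominator); grid points where the denominator
#' median is zero (or missing) are reported as `NA`.
#'
#' @param numerator,denominator [YieldCurve-class] objects on the same grid.
#' @param labels character(2): condition labels for the two curves.
#' @return an [EnrichmentCurve-class].
#' @export
enrichmentCurve <- function(numerator, denominator,
                            labels = c("captured", "pre-capture")) {
  if (!isTRUE(all.equal(numerator@effort, denominator@effort)))
    stop("yield curves must share the same effort grid")
  med <- function(cv) if (all(is.na(cv@median))) cv@yield else cv@median
  num <- med(numerator); den <- med(denominator)
  fold <- ifelse(is.na(den) | den <= 0, NA_real_, num / den)
  new("EnrichmentCurve", effort = numerator@effort, fold = fold,
      numeratorLabel = labels[1], denominatorLabel = labels[2])
}

#' Coerce curve objects to data frames
#'
#' @param x a [YieldCurve-class] or [EnrichmentCurve-class].
#' @param ... ignored.
#' @return `data.frame` representation (one row per effort grid point).
#' @export
#' @name curve-as-data-frame
setMethod("as.data.frame", "YieldCurve", function(x, ...) {
  data.frame(effort = x@effort, yield = x@yield, median = x@median,
             variance = x@variance)
})

#' @rdname curve-as-data-frame
#' @export
setMethod("as.data.frame", "EnrichmentCurve", function(x, ...) {
  data.frame(effort = x@effort, fold = x@fold)
})
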