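#' Accessors for duplicate histograms and yield models
#'
#' `totalReads()` is the number of mapped reads (`sum(j * n_j)`),
#' `distinctReads()` the number of distinct templates (`sum(n_j)`), and
#' `librarySize()` the estimated total number of distinct templates in the
#' library (for a [DuplicateHistogram-class] this is unknown and errors; for a
#' fitted [ZTNBModel-class] it is the model estimate).
#'
#' @param x a [DuplicateHistogram-class] or yield model.
#' @return a single numeric value.
#' @name complexity-accessors
NULL

#' @rdname complexity-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname complexity-accessors
#' @export
setGeneric("distinctReads", function(x) standardGeneric("distinctReads"))

#' @rdname complexity-accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname complexity-accessors
setMethod("totalReads", "DuplicateHistogram", function(x) {
  j <- as.numeric(names(x@counts))
  sum(j * x@counts)
})

#' @rdname complexity-accessors
setMethod("distinctReads", "DuplicateHistogram", function(x) sum(x@counts))

#' @rdname complexity-accessors
setMethod("librarySize", "ZTNBModel", function(x) x@librarySize)

#' @rdname complexity-accessors
setMethod("librarySize", "LinearYieldModel", function(x)
  stop("a duplicate-free library carries no information on its total size"))

#' Expected distinct-template yield at a given sequencing effort
#'
#' For a [ZTNBModel-class], `nReads` counts *on-target mapped reads* (the
#' unit the duplicate histogram was observed in) and the yield is
#' `L * (1 - p0(t))` with `t = nReads / observedReads`. For a
#' [LinearYieldModel-class], `nReads` counts *total sequenced reads* and the
#' yield is `slope * nReads`. [extrapolateYield()] handles the unit
#' conversion between the two.
#'
#' @param model a fitted yield model.
#' @param nReads numeric vector of sequencing efforts (>= 0).
#' @return expected number of distinct on-target reads at each effort.
#' @export
setGeneric("expectedYield", function(model, nReads)
  standardGeneric("expectedYield"))
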