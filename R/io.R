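## Plain-text interchange: read/pool tables as TSV (0-based half-open
## coordinates, BED dialect), target regions as 3-column BED via rtracklayer.

#' Write a read set or molecule pool as a TSV table
#'
#' Coordinates on disk are 0-based half-open (BED dialect). Comment lines
#' (`#key=value`) record the seed and any extra metadata so outputs are
#' self-describing.
#'
#' @param gr a `GRanges` read set or molecule pool.
#' @param path output file.
#' @param seed seed recorded in the header (optional).
#' @param extra named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
writeReadTable <- function(gr, path, seed = NULL, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#ycapture_table=", class(gr)[1]), con)
  if (!is.null(seed)) writeLines(paste0("#seed=", seed), con)
  for (k in names(extra)) writeLines(paste0("#", k, "=", extra[[k]]), con)
  df <- data.frame(reference = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   as.data.frame(S4Vectors::mcols(gr)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV read/pool table written by [writeReadTable()]
#'
#' @param path input file.
#' @return a `GRanges` (header comments exposed via
#'   `metadata()$header`).
#' @export
readReadTable <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = df$reference,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  extraCols <- setdiff(names(df), c("reference", "start", "end", "strand"))
  S4Vectors::mcols(gr) <- df[extraCols]
  S4Vectors::metadata(gr)$header <- header
  gr
}

#' Target-region BED I/O
#'
#' Standard 3-column BED, 0-based half-open, through rtracklayer.
#'
#' @param regions a `GRanges` of target regions.
#' @param path BED file path.
#' @return `writeTargetRegions` returns `path` invisibly;
#'   `readTargetRegions` a sorted `GRanges` without metadata columns.
#' @export
writeTargetRegions <- function(regions, path) {
  rtracklayer::export(regions, path, format = "BED")
  invisible(path)
}

#' @rdname writeTargetRegions
#' @param referenceLength optional named vector to set `seqlengths`.
#' @export
readTargetRegions <- function(path, referenceLength = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr) <- NULL
  if (!is.null(referenceLength))
    GenomeInfoDb::seqlengths(gr)[names(referenceLength)] <- referenceLength
  GenomicRanges::sort(gr)
}
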