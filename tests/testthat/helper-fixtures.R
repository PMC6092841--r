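## Fixture builders and independent oracles shared across the suite.

## Compact GRanges read-set builder. start is 0-based half-open on disk;
## here we take 1-based starts/ends directly to mirror GRanges semantics.
FIXTURE_SEQLEVELS <- c("chrY", "chrX", "unmapped")

readSet <- function(reference, start, end, strand = "+",
                    read_id = sprintf("r%03d", seq_along(start)),
                    template_id = read_id,
                    origin = "endogenous_Y") {
  GenomicRanges::GRanges(
    seqnames = factor(reference, levels = FIXTURE_SEQLEVELS),
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand, read_id = read_id, template_id = template_id,
    origin = origin, mapping_quality = 37L)
}

regionSet <- function(start, end, reference = "chrY") {
  GenomicRanges::GRanges(
    seqnames = factor(reference, levels = FIXTURE_SEQLEVELS),
    ranges = IRanges::IRanges(start = start, end = end))
}

## Occupancy expectation: expected distinct templates after n uniform draws
## with replacement from a pool of size P (closed form).
occupancyExpect <- function(P, n) P * (1 - (1 - 1 / P)^n)

## Simulate one occupancy experiment and return its duplicate histogram.
occupancyHistogram <- function(P, n, seed) {
  withr::with_seed(seed, {
    counts <- tabulate(sample.int(P, n, replace = TRUE), P)
    counts <- counts[counts > 0]
    tab <- table(counts)
    DuplicateHistogram(as.integer(names(tab)), as.integer(tab))
  })
}

## Brute-force per-read interval scan: is read i on target? Quadratic oracle
## kept deliberately naive and independent of findOverlaps.
bruteForceOnTarget <- function(reads, regions) {
  rs <- GenomicRanges::start(reads); re <- GenomicRanges::end(reads)
  rc <- as.character(GenomicRanges::seqnames(reads))
  gs <- GenomicRanges::start(regions); ge <- GenomicRanges::end(regions)
  gc <- as.character(GenomicRanges::seqnames(regions))
  vapply(seq_along(reads), function(i) {
    any(gc == rc[i] & gs <= re[i] & ge >= rs[i])
  }, logical(1))
}

## Deterministic 8-node tree (ROOT + 7 SNP-bearing branches) for the
## exhaustive assignment oracle. Topology:
##   ROOT -> A -> B -> C
##   ROOT -> D -> E
##   A    -> F
##   D    -> G
smallTree <- function() {
  nodes <- data.frame(
    name   = c("ROOT", "A", "B", "C", "D", "E", "F", "G"),
    parent = c(NA, "ROOT", "A", "B", "ROOT", "D", "A", "D"),
    stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = paste0("s", 1:7),
    position = c(10, 20, 30, 40, 50, 60, 70),
    ancestral = c("A", "A", "C", "G", "T", "A", "C"),
    derived = c("G", "T", "T", "A", "C", "G", "A"),
    haplogroup = c("A", "B", "C", "D", "E", "F", "G"),
    stringsAsFactors = FALSE)
  ycapture:::newHaplogroupTree(nodes, snps)
}

## Independent brute-force haplogroup search over an explicit parent map:
## deepest node with a derived call on its own branch; ties broken by derived
## support on the root path; remaining ties unresolved (NA).
bruteForceAssign <- function(derivedNodes, parentOf) {
  if (!length(derivedNodes)) return(NA_character_)
  depthOf <- function(n) {
    d <- 0
    while (!is.na(parentOf[[n]])) { n <- parentOf[[n]]; d <- d + 1 }
    d
  }
  pathOf <- function(n) {
    p <- n
    while (!is.na(parentOf[[n]])) { n <- parentOf[[n]]; p <- c(n, p) }
    p
  }
  depths <- vapply(derivedNodes, depthOf, numeric(1))
  cand <- derivedNodes[depths == max(depths)]
  if (length(cand) > 1) {
    support <- vapply(cand, function(n)
      sum(derivedNodes %in% pathOf(n)), numeric(1))
    cand <- cand[support == max(support)]
  }
  if (length(cand) > 1) NA_character_ else cand
}

## Minimal pipeline configuration used by the orchestration tests.
tinyConfig <- function(outputDir = NULL, seed = 11) {
  list(
    seed = seed,
    output_dir = outputDir,
    replicates = 3,
    n_boot = 5,
    tree_nodes = 12,
    genotype_depth = 8,
    error_rate = 0,
    effort_grid = list(from = 100, to = 1e5, points = 12),
    target = list(n_regions = 5, total_bp = 6000),
    samples = list(list(
      name = "S1",
      true_haplogroup = "H005",
      profile = list(pool_size = 2000, endogenous_fraction = 0.3,
                     y_fraction = 0.2,
                     reference_lengths = list(chrY = 3e4, chrX = 5e4,
                                              auto = 1e5)),
      capture = list(p_on_target = 0.9, p_off_target_y = 0.05,
                     p_background = 0.01),
      reads = list(pre = 3000, YCC = 3000, WGC = 3000, `WGC+YCC` = 3000))))
}
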