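## Genetic sex from sex-chromosome read counts and Y-haplogroup assignment by
## haploid genotype sampling plus a most-derived-SNP tree search.

#' Ry statistic for genetic sex determination
#'
#' `Ry = nChrY / (nChrX + nChrY)`, the fraction of sex-chromosome reads
#' mapping to the Y. Values above 0.075 are consistent with an XY karyotype.
#' The 95\% interval is the normal approximation
#' `Ry +/- z * sqrt(Ry (1 - Ry) / n)` clipped to [0, 1], following the
#' published screening procedure; the assignment is `consistent-with-XY`
#' only when the whole interval exceeds the threshold,
#' `not-consistent-with-XY` when it lies entirely below, and
#' `indeterminate` otherwise.
#'
#' @param nChrX,nChrY reads mapping to chrX and chrY; total must be >= 1.
#' @param threshold decision threshold (default 0.075).
#' @param level confidence level (default 0.95).
#' @return a [SexResult-class].
#' @export
#' @examples
#' ryStatistic(925, 75)   # Ry exactly at the threshold: indeterminate
ryStatistic <- function(nChrX, nChrY, threshold = 0.075, level = 0.95) {
  n <- nChrX + nChrY
  if (n < 1) stop("need at least one sex-chromosome read")
  ry <- nChrY / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(ry * (1 - ry) / n)
  lo <- max(0, ry - half); hi <- min(1, ry + half)
  assignment <- if (lo > threshold) "consistent-with-XY"
    else if (hi < threshold) "not-consistent-with-XY"
    else "indeterminate"
  new("SexResult", nChrX = nChrX, nChrY = nChrY, ry = ry,
      ciLower = lo, ciUpper = hi, threshold = threshold,
      assignment = assignment)
}

#' Haploid genotype calls by random base sampling
#'
#' Per position, discards bases with quality below `minQuality` (Phred 13 by
#' default; the floor is inclusive) and samples one base uniformly from the
#' survivors. Positions with no surviving base are omitted.
#'
#' @param pileup `data.frame` with columns `position`, `base`, `quality`
#'   (one row per sequenced base), e.g. from [simulateGenotypes()].
#' @param minQuality Phred quality floor (inclusive).
#' @param seed integer RNG seed for the random base sampling.
#' @return `data.frame` with columns `position`, `base`, sorted by position.
#' @export
callHaploidGenotypes <- function(pileup, minQuality = 13, seed) {
  keep <- pileup[pileup$quality >= minQuality, , drop = FALSE]
  if (!nrow(keep))
    return(data.frame(position = numeric(), base = character(),
                      stringsAsFactors = FALSE))
  withSeed(seed, {
    picked <- vapply(split(keep$base, keep$position),
                     function(b) b[sample.int(length(b), 1)], character(1))
    data.frame(position = as.numeric(names(picked)), base = unname(picked),
               stringsAsFactors = FALSE)[order(as.numeric(names(picked))), ,
                                         drop = FALSE]
  })
}

## Build a validated HaplogroupTree from node and SNP data frames, computing
## depths and root paths. Internal constructor shared by the loader and the
## tree simulator.
newHaplogroupTree <- function(nodes, snps) {
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1)
    stop("tree must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  if (anyDuplicated(nodes$name))
    stop("duplicate node definitions: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  orphan <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$name)
  if (length(orphan))
    stop("orphan parent(s): ", paste(orphan, collapse = ", "))
  # canonical node and SNP order, so equal trees compare equal regardless of
  # input row order
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  snps <- snps[order(snps$position), , drop = FALSE]
  rownames(snps) <- NULL
  nN <- nrow(nodes)
  depth <- integer(nN)
  rootPaths <- vector("list", nN)
  names(rootPaths) <- nodes$name
  for (i in seq_len(nN)) {
    path <- nodes$name[i]
    cur <- nodes$parent[match(nodes$name[i], nodes$name)]
    steps <- 0L
    while (!is.na(cur)) {
      steps <- steps + 1L
      if (steps > nN) stop("cycle detected at node ", nodes$name[i])
      path <- c(cur, path)
      cur <- nodes$parent[match(cur, nodes$name)]
    }
    depth[i] <- steps
    rootPaths[[i]] <- path
  }
  nodes$depth <- depth
  if (nrow(snps) && anyDuplicated(snps$position))
    stop("duplicate SNP position(s): ",
         paste(unique(snps$position[duplicated(snps$position)]),
               collapse = ", "))
  tree <- new("HaplogroupTree", nodes = nodes, snps = snps,
              rootPaths = rootPaths)
  methods::validObject(tree)
  tree
}

#' Read a haplogroup tree from a 6-column TSV
#'
#' The file has a header and columns `haplogroup`, `parent`, `snp_id`,
#' `position` (0-based chrY coordinate), `ancestral`, `derived`. One row per
#' defining SNP; a node with several defining SNPs spans several rows (its
#' `parent` must agree across rows). The root is the node that appears only
#' in the `parent` column, or a row whose `parent` and SNP fields are `"."`.
#' Multiple roots, cycles, orphan parents and duplicate SNP positions are
#' rejected with specific errors. Row order is irrelevant.
#'
#' @param path file path.
#' @return a [HaplogroupTree-class].
#' @export
loadHaplogroupTree <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("haplogroup", "parent", "snp_id", "position", "ancestral",
            "derived")
  if (!all(need %in% names(raw)))
    stop("tree file must have columns: ", paste(need, collapse = ", "))
  raw$parent[raw$parent %in% c("", ".", "NA")] <- NA_character_
  childParent <- unique(raw[, c("haplogroup", "parent")])
  if (anyDuplicated(childParent$haplogroup))
    stop("node with conflicting parents: ",
         paste(childParent$haplogroup[duplicated(childParent$haplogroup)],
               collapse = ", "))
  # nodes referenced only as parents are created implicitly (the root case)
  implicit <- setdiff(childParent$parent[!is.na(childParent$parent)],
                      childParent$haplogroup)
  nodes <- rbind(childParent,
                 data.frame(haplogroup = implicit,
                            parent = rep(NA_character_, length(implicit))))
  names(nodes) <- c("name", "parent")
  hasSnp <- !(raw$snp_id %in% c("", ".")) & !(raw$position %in% c("", "."))
  snps <- data.frame(snp_id = raw$snp_id[hasSnp],
                     position = as.numeric(raw$position[hasSnp]),
                     ancestral = toupper(raw$ancestral[hasSnp]),
                     derived = toupper(raw$derived[hasSnp]),
                     haplogroup = raw$haplogroup[hasSnp],
                     stringsAsFactors = FALSE)
  newHaplogroupTree(nodes, snps)
}

#' Write a haplogroup tree to the 6-column TSV format
#'
#' @param tree a [HaplogroupTree-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHaplogroupTree <- function(tree, path) {
  sp <- tree@snps
  parentOf <- function(n) {
    p <- tree@nodes$parent[match(n, tree@nodes$name)]
    ifelse(is.na(p), ".", p)
  }
  rows <- data.frame(haplogroup = sp$haplogroup,
                     parent = parentOf(sp$haplogroup),
                     snp_id = sp$snp_id, position = sp$position,
                     ancestral = sp$ancestral, derived = sp$derived)
  # nodes without SNPs of their own (incl. the root) still need a row
  bare <- setdiff(tree@nodes$name, sp$haplogroup)
  if (length(bare))
    rows <- rbind(rows, data.frame(haplogroup = bare,
                                   parent = parentOf(bare), snp_id = ".",
                                   position = ".", ancestral = ".",
                                   derived = "."))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign a Y haplogroup by most-derived-SNP tree search
#'
#' Matches haploid calls to the tree's defining SNPs and scores each as
#' derived, ancestral or other. The assignment is the deepest node whose own
#' branch carries at least one derived call (so the node is directly
#' supported); among equally deep candidates the one with more derived calls
#' on its root path wins, and remaining ties are reported unresolved with
#' the tied candidates listed. Derived calls off the chosen root path are
#' returned as conflicts, never silently resolved. With no derived call
#' anywhere the call is unresolved (`NA`, the "-" convention). Calls at
#' positions absent from the tree are counted and ignored.
#'
#' @param calls `data.frame` with columns `position`, `base` from
#'   [callHaploidGenotypes()].
#' @param tree a [HaplogroupTree-class].
#' @return a [HaplogroupCall-class].
#' @export
assignHaplogroup <- function(calls, tree) {
  methods::validObject(tree)
  sp <- tree@snps
  m <- match(calls$position, sp$position)
  nIgnored <- sum(is.na(m))
  if (nIgnored)
    message(nIgnored, " call(s) at positions absent from the tree ignored")
  hit <- !is.na(m)
  snp <- sp[m[hit], , drop = FALSE]
  base <- calls$base[hit]
  status <- ifelse(base == snp$derived, "derived",
                   ifelse(base == snp$ancestral, "ancestral", "other"))
  unresolved <- function(candidates = character())
    new("HaplogroupCall", haplogroup = NA_character_,
        mostDerivedSnp = NA_character_, nDerivedPath = 0L,
        nAncestralPath = 0L,
        conflicts = snp$snp_id[status == "derived"],
        candidates = candidates, nIgnored = as.integer(nIgnored))
  derivedNodes <- unique(snp$haplogroup[status == "derived"])
  if (!length(derivedNodes)) return(unresolved())
  depth <- tree@nodes$depth[match(derivedNodes, tree@nodes$name)]
  cand <- derivedNodes[depth == max(depth)]
  derivedOnPath <- function(node) {
    path <- tree@rootPaths[[node]]
    sum(status == "derived" & snp$haplogroup %in% path)
  }
  if (length(cand) > 1) {
    support <- vapply(cand, derivedOnPath, numeric(1))
    cand <- cand[support == max(support)]
    if (length(cand) > 1) return(unresolved(sort(cand)))
  }
  node <- cand[1]
  path <- tree@rootPaths[[node]]
  onPath <- snp$haplogroup %in% path
  ownBranch <- which(status == "derived" & snp$haplogroup == node)
  mds <- snp$snp_id[ownBranch[order(snp$position[ownBranch])][1]]
  new("HaplogroupCall", haplogroup = node, mostDerivedSnp = mds,
      nDerivedPath = as.integer(sum(status == "derived" & onPath)),
      nAncestralPath = as.integer(sum(status == "ancestral" & onPath)),
      conflicts = snp$snp_id[status == "derived" & !onPath],
      candidates = character(), nIgnored = as.integer(nIgnored))
}
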