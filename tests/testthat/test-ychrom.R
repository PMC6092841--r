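test_that("Ry statistic and its decision rule", {
  male <- ryStatistic(0, 100)
  expect_equal(male@ry, 1)
  expect_equal(male@assignment, "consistent-with-XY")

  female <- ryStatistic(100, 0)
  expect_equal(female@ry, 0)
  expect_equal(female@assignment, "not-consistent-with-XY")

  # Ry exactly at the 0.075 threshold: the interval straddles it
  edge <- ryStatistic(925, 75)
  expect_equal(edge@ry, 0.075)
  expect_lt(edge@ciLower, 0.075)
  expect_gt(edge@ciUpper, 0.075)
  expect_equal(edge@assignment, "indeterminate")

  expect_error(ryStatistic(0, 0), "at least one")
  expect_true(edge@ciLower >= 0 && edge@ciUpper <= 1)
})

test_that("haploid calling applies the inclusive quality floor", {
  pu <- data.frame(position = c(5, 5, 9, 9), base = c("A", "G", "C", "T"),
                   quality = c(13, 10, 12, 11))
  calls <- callHaploidGenotypes(pu, seed = 1)
  expect_equal(nrow(calls), 1)        # position 9 has no surviving base
  expect_equal(calls$base, "A")       # q = 13 is retained

  none <- callHaploidGenotypes(data.frame(position = 1, base = "A",
                                          quality = 12), seed = 1)
  expect_equal(nrow(none), 0)
})

test_that("random base sampling is uniform over surviving bases", {
  pu <- data.frame(position = rep(1, 100),
                   base = rep(c("A", "G"), c(70, 30)),
                   quality = 30)
  hits <- vapply(1:1000, function(s)
    callHaploidGenotypes(pu, seed = s)$base == "A", logical(1))
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.7)
  expect_gte(sum(hits), bounds[1])
  expect_lte(sum(hits), bounds[2])
})

test_that("tree files are validated and order-invariant", {
  lines <- c("haplogroup\tparent\tsnp_id\tposition\tancestral\tderived",
             "H\tROOT\ts1\t100\tA\tG")
  f <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  tree <- loadHaplogroupTree(f)
  expect_equal(nrow(tree@nodes), 2)
  expect_equal(max(tree@nodes$depth), 1)
  expect_equal(tree@rootPaths[["H"]], c("ROOT", "H"))

  shuffled <- withr::local_tempfile(
    lines = c(lines[1],
              "B\tA\ts2\t200\tC\tT",
              "A\tROOT\ts1\t100\tA\tG"),
    fileext = ".tsv")
  ordered <- withr::local_tempfile(
    lines = c(lines[1],
              "A\tROOT\ts1\t100\tA\tG",
              "B\tA\ts2\t200\tC\tT"),
    fileext = ".tsv")
  expect_equal(loadHaplogroupTree(shuffled)@nodes,
               loadHaplogroupTree(ordered)@nodes)

  twoRoots <- withr::local_tempfile(
    lines = c(lines[1], "A\tR1\ts1\t100\tA\tG", "B\tR2\ts2\t200\tC\tT"),
    fileext = ".tsv")
  expect_error(loadHaplogroupTree(twoRoots), "exactly one root")

  dupPos <- withr::local_tempfile(
    lines = c(lines[1], "A\tROOT\ts1\t100\tA\tG", "B\tA\ts2\t100\tC\tT"),
    fileext = ".tsv")
  expect_error(loadHaplogroupTree(dupPos), "duplicate SNP position")

  cyc <- withr::local_tempfile(
    lines = c(lines[1], "A\tB\ts1\t100\tA\tG", "B\tA\ts2\t200\tC\tT",
              "C\t.\ts3\t300\tA\tC"),
    fileext = ".tsv")
  expect_error(loadHaplogroupTree(cyc), "cycle")
})

test_that("tree round-trips through the 6-column TSV format", {
  tree <- simulateHaplogroupTree(15, seed = 3, snpsPerBranch = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeHaplogroupTree(tree, f)
  back <- loadHaplogroupTree(f)
  expect_setequal(back@nodes$name, tree@nodes$name)
  expect_equal(back@snps[order(back@snps$position), ]$snp_id,
               tree@snps[order(tree@snps$position), ]$snp_id)
})

test_that("assignment picks the most derived supported node", {
  tree <- smallTree()
  sp <- tree@snps
  callFor <- function(derivedOn, ancestralOn = setdiff(sp$haplogroup,
                                                       derivedOn)) {
    rbind(
      data.frame(position = sp$position[sp$haplogroup %in% derivedOn],
                 base = sp$derived[sp$haplogroup %in% derivedOn]),
      data.frame(position = sp$position[sp$haplogroup %in% ancestralOn],
                 base = sp$ancestral[sp$haplogroup %in% ancestralOn]))
  }
  expect_equal(assignHaplogroup(callFor("A"), tree)@haplogroup, "A")
  expect_equal(assignHaplogroup(callFor(c("A", "B")), tree)@haplogroup, "B")

  none <- assignHaplogroup(data.frame(position = numeric(),
                                      base = character()), tree)
  expect_true(is.na(none@haplogroup))

  # off-path derived calls surface as conflicts, never silent resolution
  mixed <- assignHaplogroup(callFor(c("A", "B", "C", "E")), tree)
  expect_equal(mixed@haplogroup, "C")
  expect_equal(mixed@conflicts, "s5")

  # positions outside the tree are counted and ignored
  stray <- rbind(callFor("A"), data.frame(position = 9999, base = "A"))
  res <- suppressMessages(assignHaplogroup(stray, tree))
  expect_equal(res@nIgnored, 1L)
  expect_equal(res@haplogroup, "A")
})

test_that("assignment agrees with exhaustive search over all call patterns", {
  tree <- smallTree()
  sp <- tree@snps
  parentOf <- setNames(tree@nodes$parent, tree@nodes$name)
  for (mask in 0:(2^7 - 1)) {
    derived <- as.logical(bitwAnd(mask, 2^(0:6)))
    calls <- data.frame(position = sp$position,
                        base = ifelse(derived, sp$derived, sp$ancestral))
    got <- assignHaplogroup(calls, tree)@haplogroup
    want <- bruteForceAssign(sp$haplogroup[derived], parentOf)
    expect_identical(got, want,
                     info = paste("pattern", mask))
  }
})

test_that("deeper derived calls never yield a shallower assignment", {
  tree <- simulateHaplogroupTree(25, seed = 5)
  sp <- tree@snps
  target <- tree@nodes$name[which.max(tree@nodes$depth)]
  path <- setdiff(tree@rootPaths[[target]], "ROOT")
  prevDepth <- -1
  for (k in seq_along(path)) {
    onPath <- path[seq_len(k)]
    calls <- data.frame(
      position = sp$position[sp$haplogroup %in% onPath],
      base = sp$derived[sp$haplogroup %in% onPath])
    got <- assignHaplogroup(calls, tree)
    d <- tree@nodes$depth[match(got@haplogroup, tree@nodes$name)]
    expect_gte(d, prevDepth)
    prevDepth <- d
  }
  expect_equal(prevDepth, max(tree@nodes$depth))
})

test_that("error-free simulated genotypes recover every lineage", {
  tree <- simulateHaplogroupTree(20, seed = 6)
  for (hap in setdiff(tree@nodes$name, "ROOT")) {
    pu <- simulateGenotypes(tree, hap, meanDepth = 8, errorRate = 0,
                            seed = 7)
    calls <- callHaploidGenotypes(pu, seed = 8)
    expect_equal(assignHaplogroup(calls, tree)@haplogroup, hap)
  }
})
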