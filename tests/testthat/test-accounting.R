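test_that("coordinate deduplication keeps one representative per class", {
  five <- readSet("chrY", rep(100, 5), rep(160, 5))
  dd <- deduplicate(five)
  expect_length(dd$unique, 1)
  expect_equal(dd$unique$read_id, "r001")  # smallest read_id wins
  expect_equal(unname(dd$histogram@counts), 1)
  expect_equal(names(dd$histogram@counts), "5")

  k <- 8
  distinct <- readSet("chrY", 10 * (1:k), 10 * (1:k) + 50)
  ddk <- deduplicate(distinct)
  expect_length(ddk$unique, k)
  expect_equal(unname(ddk$histogram@counts), k)

  # classes {A,A,B,B,B,C} -> histogram {1:1, 2:1, 3:1}
  mixed <- readSet("chrY", c(1, 1, 50, 50, 50, 90), c(40, 40, 80, 80, 80, 120))
  h <- deduplicate(mixed)$histogram
  expect_equal(unname(h@counts[c("1", "2", "3")]), c(1, 1, 1))
  expect_equal(totalReads(h), 6)

  # opposite strands are distinct templates
  strands <- readSet("chrY", c(1, 1), c(40, 40), strand = c("+", "-"))
  expect_length(deduplicate(strands)$unique, 2)
})

test_that("deduplication is idempotent and conserves read counts", {
  withr::with_seed(42, {
    pool <- simulateMoleculePool(LibraryProfile(poolSize = 300), seed = 1)
    reads <- amplifyAndSequence(pool, 900, seed = 2)
  })
  dd <- deduplicate(reads)
  expect_equal(totalReads(dd$histogram), length(reads))
  twice <- deduplicate(dd$unique)
  expect_equal(sort(twice$unique$read_id), sort(dd$unique$read_id))
  expect_true(all(names(twice$histogram@counts) == "1"))
})

test_that("on-target classification matches half-open overlap semantics", {
  # read [100,150) vs region [140,200): 10 bp overlap -> on target
  r1 <- readSet("chrY", 101, 150)
  expect_length(classifyOnTarget(r1, regionSet(141, 200))$on_target, 1)
  # read [100,150) vs region [150,200): touching, no overlap
  cls <- classifyOnTarget(r1, regionSet(151, 200))
  expect_length(cls$on_target, 0)
  expect_length(cls$off_target_same_reference, 1)
  # different reference -> other
  r2 <- readSet("chrX", 101, 150)
  expect_length(classifyOnTarget(r2, regionSet(1, 1000))$other, 1)
})

test_that("classification agrees with a brute-force interval scan", {
  withr::with_seed(7, {
    n <- 1000
    starts <- sample.int(49000, n)
    reads <- readSet(sample(c("chrY", "chrX"), n, replace = TRUE),
                     starts, starts + sample(30:120, n, replace = TRUE))
  })
  regions <- makeTargetRegions(5e4, 15, 8000, seed = 8)
  cls <- classifyOnTarget(reads, regions)
  oracle <- bruteForceOnTarget(reads, regions)
  expect_equal(length(cls$on_target), sum(oracle))
  expect_setequal(cls$on_target$read_id, reads$read_id[oracle])
  expect_equal(length(cls$on_target) + length(cls$off_target_same_reference) +
                 length(cls$other), n)

  # order invariance of the partition sizes
  perm <- withr::with_seed(9, sample.int(n))
  cls2 <- classifyOnTarget(reads[perm], rev(regions))
  expect_equal(length(cls2$on_target), length(cls$on_target))
})

test_that("minimum retained read count picks the smallest condition", {
  expect_equal(minRetainedReads(c(pre = 68795, YCC = 159728)), 68795)
  expect_equal(minRetainedReads(c(only = 42)), 42)
  expect_equal(minRetainedReads(c(a = 5, b = 5)), 5)
  expect_error(minRetainedReads(list()), "no conditions")
})

test_that("down-sampling replicates are exact, seeded and composition-preserving", {
  pool <- simulateMoleculePool(
    LibraryProfile(poolSize = 1000, endogenousFraction = 0.3), seed = 10)
  reads <- amplifyAndSequence(pool, 1000, seed = 11)

  full <- downsampleReads(reads, length(reads), 3, baseSeed = 1)
  for (rep in full) expect_setequal(rep$read_id, reads$read_id)
  empty <- downsampleReads(reads, 0, 2, baseSeed = 1)
  expect_true(all(lengths(empty) == 0))
  expect_error(downsampleReads(reads, length(reads) + 1, 1, 1),
               "cannot down-sample")

  # replicate r depends only on baseSeed + r
  repA <- downsampleReads(reads, 200, 5, baseSeed = 100)[[3]]
  repB <- downsampleReads(reads, 200, 1, baseSeed = 102)[[1]]
  expect_setequal(repA$read_id, repB$read_id)

  # hypergeometric composition bounds per replicate (99.9% each,
  # ~99% jointly across the 10 replicates)
  nEndo <- sum(reads$origin != "exogenous")
  reps <- downsampleReads(reads, 200, 10, baseSeed = 50)
  for (rep in reps) {
    got <- sum(rep$origin != "exogenous")
    bounds <- qhyper(c(0.0005, 0.9995), nEndo, length(reads) - nEndo, 200)
    expect_gte(got, bounds[1])
    expect_lte(got, bounds[2])
  }
})

test_that("library metrics compute the condition-table quantities", {
  regions <- regionSet(c(101, 501), c(200, 700))
  onY <- readSet("chrY", c(110, 110, 520, 900), c(180, 180, 620, 950),
                 read_id = sprintf("r%03d", 1:4))
  offRef <- readSet("chrX", 10, 80, read_id = "r100")
  unmapped <- GenomicRanges::GRanges(
    "unmapped", IRanges::IRanges(1, 60), strand = "+", read_id = "r200",
    template_id = "t1", origin = "exogenous", mapping_quality = 0L)
  reads <- c(onY, offRef, unmapped)
  m <- libraryMetrics(reads, regions)
  expect_equal(m$total_reads, 6)
  expect_equal(m$mapped_reads, 5)
  expect_equal(m$unique_mapped, 4)   # one duplicate pair on chrY
  expect_equal(m$chrY_unique, 3)
  expect_equal(m$on_target_unique, 2)
  expect_equal(m$off_target_chrY_unique, 1)
  expect_equal(m$on_target_unique + m$off_target_chrY_unique, m$chrY_unique)
  expect_equal(m$clonality_pct, 100 * (5 - 4) / 5)
  expect_equal(m$pct_sequenced_on_target, 100 * 2 / 6)
  expect_equal(m$pct_chrY_on_target, 100 * 2 / 3)

  # zero denominators are reported missing, not infinite
  noY <- libraryMetrics(offRef, regions)
  expect_true(is.na(noY$pct_chrY_on_target))
  expect_equal(formatMetrics(noY)$pct_chrY_on_target, "-")

  # no duplicates -> clonality 0
  expect_equal(libraryMetrics(onY[c(1, 3, 4)], regions)$clonality_pct, 0)
})

test_that("Wilson interval matches a numerical score-test inversion", {
  # independent oracle: solve |p-hat - p| = z sqrt(p(1-p)/n) for p
  wilsonOracle <- function(x, n, level) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- x / n
    g <- function(q) (p - q)^2 - z^2 * q * (1 - q) / n
    lower <- if (p == 0) 0 else uniroot(g, c(1e-12, p), tol = 1e-12)$root
    upper <- if (p == 1) 1 else uniroot(g, c(p, 1 - 1e-12), tol = 1e-12)$root
    c(lower, upper)
  }
  for (case in list(c(5, 10), c(1, 30), c(29, 30), c(154, 10000))) {
    ci <- binomialCI(case[1], case[2], 0.95)
    expect_equal(unname(ci), wilsonOracle(case[1], case[2], 0.95),
                 tolerance = 1e-6)
    expect_true(ci["lower"] <= case[1] / case[2] &&
                  case[1] / case[2] <= ci["upper"])
  }
  expect_equal(unname(binomialCI(0, 20)["lower"]), 0)
  expect_equal(unname(binomialCI(20, 20)["upper"]), 1)
})

test_that("paired length test follows the textbook t formula", {
  a <- c(91.7, 92.1, 63.6, 69.1, 66.0)
  b <- c(87.4, 94.5, 76.3, 102.3, 80.0)
  res <- pairedLengthTest(a, b)
  d <- a - b
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  pOracle <- 2 * pt(-abs(tOracle), length(d) - 1)
  expect_equal(res$statistic, tOracle, tolerance = 1e-12)
  expect_equal(res$p.value, pOracle, tolerance = 1e-12)
  expect_false(res$degenerate)

  same <- pairedLengthTest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_true(same$degenerate)

  shifted <- pairedLengthTest(c(1, 2, 3), c(2, 3, 4))
  expect_true(shifted$degenerate)
  expect_true(is.na(shifted$p.value))
})

test_that("replicate summaries bracket their means with binomial intervals", {
  pool <- simulateMoleculePool(
    LibraryProfile(poolSize = 800, endogenousFraction = 0.4,
                   yFraction = 0.5), seed = 20)
  reads <- amplifyAndSequence(pool, 2000, seed = 21)
  regions <- makeTargetRegions(5e4, 8, 30000, seed = 22)
  summ <- replicateSummary(downsampleReads(reads, 500, 10, baseSeed = 30),
                           regions)
  expect_equal(summ$n_replicates, 10)
  for (i in seq_len(nrow(summ$ci))) {
    metric <- summ$ci$metric[i]
    if (is.na(summ$ci$lower[i])) next
    expect_lte(summ$ci$lower[i], summ$mean[[metric]])
    expect_gte(summ$ci$upper[i], summ$mean[[metric]])
  }
})
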