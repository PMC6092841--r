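## End-to-end orchestration: simulate -> account -> enrich -> complexity ->
## sex/haplogroup, from a structured (YAML) configuration, with reproducible
## per-stage seeds and an output manifest.

CONDITIONS <- c("pre", "YCC", "WGC", "WGC+YCC")

## Build a LibraryProfile / CaptureProfile from a config sub-list, falling
## back to the constructor defaults for unset fields.
profileFromConfig <- function(cfg) {
  cfg <- cfg %||% list()
  LibraryProfile(
    poolSize = cfg$pool_size %||% formals(LibraryProfile)$poolSize,
    endogenousFraction = cfg$endogenous_fraction %||% 0.0154,
    yFraction = cfg$y_fraction %||% 0.01,
    fragmentLengthMean = cfg$fragment_length_mean %||% 91,
    fragmentLengthSd = cfg$fragment_length_sd %||% 15,
    minLength = cfg$min_length %||% 30,
    referenceLengths = if (!is.null(cfg$reference_lengths))
      unlist(cfg$reference_lengths) else c(chrY = 5e4, chrX = 1.5e5,
                                           auto = 3e6),
    yName = cfg$y_name %||% "chrY")
}

captureFromConfig <- function(cfg) {
  cfg <- cfg %||% list()
  CaptureProfile(
    pOnTarget = cfg$p_on_target %||% 0.8,
    pOffTargetY = cfg$p_off_target_y %||% 0.05,
    pBackground = cfg$p_background %||% 0.002,
    lengthBiasMidpoint = cfg$length_bias_midpoint %||% 105,
    lengthBiasScale = cfg$length_bias_scale %||% 15)
}

## Whole-genome capture target: every endogenous reference end to end, so all
## endogenous templates fall in the on-target retention class.
wholeGenomeRegions <- function(profile) {
  refLens <- profile@referenceLengths
  GenomicRanges::GRanges(
    seqnames = names(refLens),
    ranges = IRanges::IRanges(start = 1, width = unname(refLens)),
    seqinfo = GenomeInfoDb::Seqinfo(names(refLens), unname(refLens)))
}

## Duplicate histogram + on-target fraction of one condition's full read set.
onTargetComplexity <- function(reads, regions, yName) {
  mapped <- reads[as.character(GenomicRanges::seqnames(reads)) != UNMAPPED]
  onT <- classifyOnTarget(mapped, regions)$on_target
  dd <- deduplicate(onT)
  list(hist = dd$histogram,
       unique = length(dd$unique),
       onTargetReads = length(onT),
       totalReads = length(reads))
}

conditionYieldCurve <- function(cx, grid, nBoot, seed) {
  if (cx$onTargetReads == 0 || cx$totalReads == 0)
    return(extrapolateYield(linearFallback(0, max(cx$totalReads, 1)), grid, 1))
  frac <- cx$onTargetReads / cx$totalReads
  if (!is.null(cx$hist) && max(as.numeric(names(cx$hist@counts))) >= 2)
    bootstrapYield(cx$hist, grid, frac, nBoot = nBoot, seed = seed)
  else
    extrapolateYield(linearFallback(cx$unique, cx$totalReads), grid, frac)
}

#' Run the full capture-enrichment evaluation pipeline
#'
#' Simulates, for each configured sample, the four experimental conditions
#' (`pre` = no enrichment; `YCC` = one Y-target capture; `WGC` = one
#' whole-genome capture, i.e. all endogenous templates on-target;
#' `WGC+YCC` = whole-genome then Y-target capture, two sequential
#' [simulateCapture()] rounds expressing the complexity loss of consecutive
#' captures), then runs the full analysis: down-sampling to the minimum
#' retained read count, replicate metrics, the six-pair fold-enrichment grid,
#' yield and enrichment curves, sex determination and haplogroup assignment.
#' Every stage derives its seed deterministically from the top-level seed, so
#' a rerun with the same configuration is byte-identical.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Top-level fields: `seed`, `output_dir` (optional; when set, TSV/BED
#'   outputs and a JSON manifest are written), `replicates` (default 10),
#'   `target` (`n_regions`, `total_bp`), `effort_grid` (`from`, `to`,
#'   `points`), `n_boot`, `tree` (path of a tree TSV; omitted = simulate one
#'   with `tree_nodes` nodes), `genotype_depth`, `error_rate`, and `samples`:
#'   a list of `name`, `true_haplogroup`, `profile`, `capture`, `reads` (per
#'   condition read counts).
#' @return a list of class `ycaptureRun`: `summaries` (per sample/condition
#'   [replicateSummary()] objects), `enrichmentTable`, `yieldCurves`,
#'   `enrichmentCurves`, `sex`, `haplogroups`, `tree`, `manifest`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  nRep <- config$replicates %||% 10
  eg <- config$effort_grid %||% list()
  grid <- effortGrid(from = as.numeric(eg$from %||% 1e2),
                     to = as.numeric(eg$to %||% 1e7),
                     points = as.numeric(eg$points %||% 50))
  nBoot <- config$n_boot %||% 100
  tree <- if (!is.null(config[["tree"]])) loadHaplogroupTree(config[["tree"]])
    else simulateHaplogroupTree(config[["tree_nodes"]] %||% 50,
                                seed = seed + 7)
  summaries <- list()
  meanRows <- list()
  yieldCurves <- list()
  enrichCurves <- list()
  sexRows <- list()
  hapRows <- list()
  regionsBySample <- list()
  for (si in seq_along(config$samples)) {
    sc <- config$samples[[si]]
    sName <- sc$name %||% paste0("sample", si)
    sseed <- seed + 1000 * si
    profile <- profileFromConfig(sc$profile)
    capture <- captureFromConfig(sc$capture)
    yName <- profile@yName
    tcfg <- config$target %||% list()
    regions <- makeTargetRegions(
      profile@referenceLengths[[yName]],
      tcfg$n_regions %||% 20,
      tcfg$total_bp %||% round(0.15 * profile@referenceLengths[[yName]]),
      seed = sseed + 1, reference = yName)
    regionsBySample[[sName]] <- regions
    pool <- simulateMoleculePool(profile, seed = sseed + 2)
    wgcPool <- simulateCapture(pool, wholeGenomeRegions(profile), capture,
                               seed = sseed + 4, yName = yName)
    pools <- list(
      "pre" = pool,
      "YCC" = simulateCapture(pool, regions, capture, seed = sseed + 3,
                              yName = yName),
      "WGC" = wgcPool,
      "WGC+YCC" = simulateCapture(wgcPool, regions, capture,
                                  seed = sseed + 5, yName = yName))
    nReads <- vapply(CONDITIONS, function(cond)
      as.numeric((sc$reads %||% list())[[cond]] %||% 2e4), numeric(1))
    reads <- lapply(seq_along(CONDITIONS), function(k)
      tryCatch(
        amplifyAndSequence(pools[[CONDITIONS[k]]], nReads[[k]],
                           seed = sseed + 10 + k),
        error = function(e) stop("stage 'sequence' failed for sample ",
                                 sName, ", condition ", CONDITIONS[k], ": ",
                                 conditionMessage(e), call. = FALSE)))
    names(reads) <- CONDITIONS
    nMin <- minRetainedReads(vapply(reads, length, numeric(1)))
    allUniqueMapped <- NULL
    for (k in seq_along(CONDITIONS)) {
      cond <- CONDITIONS[k]
      reps <- downsampleReads(reads[[cond]], nMin, nRep,
                              baseSeed = sseed + 100 * k)
      summ <- replicateSummary(reps, regions, yName = yName)
      summaries[[paste(sName, cond, sep = ".")]] <- summ
      meanRows[[length(meanRows) + 1]] <- data.frame(
        sample = sName, condition = cond,
        on_target_mean = summ$mean[["on_target_unique"]])
      cx <- onTargetComplexity(reads[[cond]], regions, yName)
      yieldCurves[[paste(sName, cond, sep = ".")]] <-
        conditionYieldCurve(cx, grid, nBoot, seed = sseed + 500 + k)
      mapped <- reads[[cond]][
        as.character(GenomicRanges::seqnames(reads[[cond]])) != UNMAPPED]
      allUniqueMapped <- c(allUniqueMapped, list(mapped))
    }
    for (pair in list(c("YCC", "pre"), c("WGC+YCC", "pre"),
                      c("WGC+YCC", "WGC"))) {
      enrichCurves[[paste(sName, pair[1], "vs", pair[2])]] <- enrichmentCurve(
        yieldCurves[[paste(sName, pair[1], sep = ".")]],
        yieldCurves[[paste(sName, pair[2], sep = ".")]], labels = pair)
    }
    combined <- deduplicate(do.call(c, allUniqueMapped))$unique
    seqn <- as.character(GenomicRanges::seqnames(combined))
    if ("chrX" %in% names(profile@referenceLengths)) {
      sex <- ryStatistic(sum(seqn == "chrX"), sum(seqn == yName))
      sexRows[[length(sexRows) + 1]] <- data.frame(
        sample = sName, n_chrX = sex@nChrX, n_chrY = sex@nChrY,
        ry = sex@ry, ci_lower = sex@ciLower, ci_upper = sex@ciUpper,
        assignment = sex@assignment)
    }
    trueHap <- sc$true_haplogroup %||%
      tree@nodes$name[which.max(tree@nodes$depth)]
    pileup <- simulateGenotypes(tree, trueHap,
                                meanDepth = config$genotype_depth %||% 5,
                                errorRate = config$error_rate %||% 0.001,
                                seed = sseed + 40)
    calls <- callHaploidGenotypes(pileup, seed = sseed + 41)
    hap <- assignHaplogroup(calls, tree)
    hapRows[[length(hapRows) + 1]] <- data.frame(
      sample = sName, true_haplogroup = trueHap,
      called_haplogroup = ifelse(is.na(hap@haplogroup), "-", hap@haplogroup),
      most_derived_snp = ifelse(is.na(hap@mostDerivedSnp), "-",
                                hap@mostDerivedSnp),
      n_derived_path = hap@nDerivedPath,
      n_conflicts = length(hap@conflicts))
  }
  run <- structure(list(
    summaries = summaries,
    enrichmentTable = buildEnrichmentTable(do.call(rbind, meanRows)),
    yieldCurves = yieldCurves,
    enrichmentCurves = enrichCurves,
    sex = do.call(rbind, sexRows),
    haplogroups = do.call(rbind, hapRows),
    tree = tree,
    regions = regionsBySample,
    seed = seed), class = "ycaptureRun")
  if (!is.null(config$output_dir))
    run$manifest <- writeRunOutputs(run, config)
  run
}

## Write all pipeline artifacts plus a manifest (seed, config hash, per-file
## md5) to config$output_dir. Deterministic: no timestamps.
writeRunOutputs <- function(run, config) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <<- c(out, p)
  }
  wtsv(run$enrichmentTable, "enrichment_table.tsv")
  if (!is.null(run$sex)) wtsv(run$sex, "sex.tsv")
  wtsv(run$haplogroups, "haplogroups.tsv")
  for (nm in names(run$yieldCurves))
    wtsv(as.data.frame(run$yieldCurves[[nm]]),
         paste0("yield_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv"))
  for (nm in names(run$enrichmentCurves))
    wtsv(as.data.frame(run$enrichmentCurves[[nm]]),
         paste0("enrichment_curve_", gsub("[^A-Za-z0-9_.-]", "_", nm),
                ".tsv"))
  for (nm in names(run$regions)) {
    p <- file.path(dir, paste0("targets_", nm, ".bed"))
    writeTargetRegions(run$regions[[nm]], p)
    out <- c(out, p)
  }
  treePath <- file.path(dir, "tree.tsv")
  writeHaplogroupTree(run$tree, treePath)
  out <- c(out, treePath)
  cfgFile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfgFile)
  manifest <- list(
    seed = run$seed,
    config_md5 = unname(tools::md5sum(cfgFile)),
    files = lapply(stats::setNames(out, basename(out)),
                   function(p) unname(tools::md5sum(p))))
  unlink(cfgFile)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' @export
print.ycaptureRun <- function(x, ...) {
  cat("ycapture pipeline run (seed", x$seed, ")\n")
  cat("  samples:", paste(unique(x$enrichmentTable$sample), collapse = ", "),
      "\n")
  cat("  fold-enrichment grid:\n")
  print(x$enrichmentTable, row.names = FALSE)
  if (!is.null(x$sex)) {
    cat("  sex assignments:\n")
    print(x$sex[, c("sample", "ry", "assignment")], row.names = FALSE)
  }
  cat("  haplogroups:\n")
  print(x$haplogroups[, c("sample", "true_haplogroup", "called_haplogroup")],
        row.names = FALSE)
  invisible(x)
}
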