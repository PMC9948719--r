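#' Configure an end-to-end run
#'
#' A run is driven either by a [SynthConfig-class] (simulate everything) or
#' by input file paths (`tis`, `genes`, optionally `genomeFasta` or
#' `genomeLength` + `genomeName`, `regions` as a named character vector of
#' BED/narrowPeak paths, `exclusions` as a gene-id list file). Exactly one
#' of the two sources must be given. Defaults mirror the package-wide
#' conventions: 4% end curation, ecIPKM cutoff 2.2 (or `"auto"` to
#' recalibrate), 10,000 bootstrap sets, 0.8 coverage threshold.
#'
#' @param synth A [SynthConfig-class], or `NULL`.
#' @param paths Named list of input paths, or `NULL`.
#' @param endTrim End-curation proportion (default 0.04).
#' @param cutoff Numeric ecIPKM cutoff or `"auto"` (default 2.2).
#' @param cutoffGrid Grid used when `cutoff = "auto"`.
#' @param nSets Bootstrap sets for the protection test (default 10,000).
#' @param seed Global integer seed; per-stage seeds are derived from it.
#' @param coverageThreshold Gene-coverage threshold (default 0.8).
#' @param outDir Output directory, or `NULL` for no file output.
#' @return A validated run-config list (class `TnseqRunConfig`).
#' @export
runConfig <- function(synth = NULL, paths = NULL, endTrim = 0.04,
                      cutoff = 2.2, cutoffGrid = NULL, nSets = 10000,
                      seed = 1L, coverageThreshold = 0.8, outDir = NULL) {
  if (is.null(synth) == is.null(paths))
    stop("validation failure: exactly one of synth or paths must be given")
  if (!is.null(synth) && !methods::is(synth, "SynthConfig"))
    stop("synth must be a SynthConfig")
  if (!identical(cutoff, "auto") &&
      (!is.numeric(cutoff) || cutoff <= 0))
    stop("cutoff must be positive or \"auto\"")
  if (endTrim < 0 || endTrim >= 0.5)
    stop("endTrim must lie in [0, 0.5)")
  cfg <- list(synth = synth, paths = paths, endTrim = endTrim,
              cutoff = cutoff, cutoffGrid = cutoffGrid, nSets = nSets,
              seed = as.integer(seed),
              coverageThreshold = coverageThreshold, outDir = outDir)
  class(cfg) <- "TnseqRunConfig"
  cfg
}

#' Validate loaded inputs
#'
#' Checks coordinate ranges, sortedness, duplicate sites and basic gene /
#' region sanity, distinguishing fatal problems from warnings.
#'
#' @param genome A [GenomeModel-class].
#' @param tis Optional [TisTable-class].
#' @param genes Optional gene data.frame.
#' @param regions Optional list of [BindingRegionSet-class].
#' @return data.frame with columns `severity` (`fatal`/`warning`) and
#'   `message`; zero rows when everything is clean. The number of fatal
#'   rows is also attached as attribute `nFatal`.
#' @export
validateInputs <- function(genome, tis = NULL, genes = NULL,
                           regions = NULL) {
  issues <- list()
  add <- function(severity, msg)
    issues[[length(issues) + 1L]] <<- data.frame(severity = severity,
                                                 message = msg)
  L <- genomeLength(genome)
  if (!is.null(tis)) {
    p <- tisPositions(tis)
    if (length(p) && (min(p) < 0 || max(p) >= L))
      add("fatal", "insertion position outside [0, genome length)")
    if (is.unsorted(p)) add("fatal", "insertion positions not sorted")
    if (anyDuplicated(p))
      add("warning", "duplicate insertion positions (will be merged)")
    if (length(p) && any(tisCounts(tis) < 1))
      add("fatal", "read count below 1")
  }
  if (!is.null(genes) && nrow(genes)) {
    if (any(genes$start >= genes$end))
      add("fatal", "gene with start >= end")
    if (any(genes$start < 0))
      add("fatal", "gene with negative start")
    if (any(genes$end > L) && !isCircular(genome))
      add("fatal", "gene beyond the end of a linear genome")
    if (anyDuplicated(genes$gene_id))
      add("fatal", "duplicate gene ids")
  }
  if (!is.null(regions)) {
    for (rs in regions) {
      r <- regionTable(rs)
      if (nrow(r) && (any(r$start < 0) || any(r$end > L)))
        add("fatal", paste0("region outside genome in set '",
                            proteinName(rs), "'"))
    }
  }
  out <- if (length(issues)) do.call(rbind, issues)
         else data.frame(severity = character(0), message = character(0))
  attr(out, "nFatal") <- sum(out$severity == "fatal")
  out
}

.writeTsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> landscape summaries -> per-gene
#' statistics -> essentiality calling -> protection tests, writes
#' tab-separated outputs and a plain-text report when an output directory is
#' configured, and returns all intermediate objects. Every stochastic stage
#' derives its seed from the config's global seed, so re-running the same
#' config reproduces every output bit for bit.
#'
#' @param config A run config from [runConfig()].
#' @param quiet Suppress progress messages.
#' @return A list: `genome`, `tis`, `genes`, `truth` (synthetic runs only),
#'   `landscape` (distance stats, GC diagnostics), `stats`, `curve` (when
#'   calibrated), `cutoff`, `call`, `distributions`, `protection`
#'   (summary table + per-test results), `coverage`, `validation`, and the
#'   resolved `config`.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "TnseqRunConfig"))
  say <- function(...) if (!quiet) message(...)
  outDir <- config$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  truth <- NULL
  regions <- NULL
  if (!is.null(config$synth)) {
    synth <- config$synth
    synth@seed <- as.numeric(config$seed)
    say("simulating synthetic study (seed ", config$seed, ")")
    genome <- generateGenome(synth)
    ann <- generateAnnotation(synth, genome)
    genes <- ann$genes
    truth <- ann$truth
    tis <- simulateInsertions(synth, genome, truth)
    if (nrow(truthRegions(truth)) >= 2)
      regions <- list(planted = methods::new(
        "BindingRegionSet", proteinName = "planted",
        regions = truthRegions(truth)))
  } else {
    p <- config$paths
    genome <- if (!is.null(p$genomeFasta)) readGenomeFasta(p$genomeFasta)
              else GenomeModel(name = p$genomeName %||% "genome",
                               length = p$genomeLength)
    say("loading inputs")
    tis <- loadTis(p$tis, format = p$tisFormat %||% "bed", genome)
    genes <- if (!is.null(p$genes))
      readGeneAnnotation(p$genes, format = p$genesFormat %||% "gff3", genome)
    if (!is.null(p$exclusions) && !is.null(genes)) {
      excl <- readGeneIdList(p$exclusions)
      genes$excluded <- genes$gene_id %in% excl
    }
    if (!is.null(p$regions)) {
      regions <- lapply(seq_along(p$regions), function(i)
        readBindingRegions(p$regions[[i]],
                           proteinName = names(p$regions)[i] %||% NULL,
                           genome = genome))
      names(regions) <- vapply(regions, proteinName, character(1))
    }
  }

  validation <- validateInputs(genome, tis, genes, regions)
  if (attr(validation, "nFatal") > 0)
    stop("validation failure:\n  ",
         paste(validation$message[validation$severity == "fatal"],
               collapse = "\n  "))

  say("landscape summaries")
  landscape <- list(
    distance = if (totalUnique(tis) >= 2)
      adjacentDistanceStats(tis, thresholds = c(10, 25)),
    gcNearTis = if (!is.null(genomeSequence(genome)))
      gcNearTis(tis, genome, window = 100),
    genomeGc = if (!is.null(genomeSequence(genome))) gcContent(genome),
    meanIpkm = genomeMeanIpkm(tis))
  profile <- normalizeInsertions(tis)
  if (!is.null(outDir))
    writeProfileWig(profile, genome, file.path(outDir, "profile.wig"))

  stats <- curve <- callRes <- distributions <- NULL
  cutoff <- config$cutoff
  if (!is.null(genes) && nrow(genes)) {
    say("per-gene statistics (end trim ", config$endTrim, ")")
    stats <- geneStats(genes, tis, endTrim = config$endTrim)
    evaluated <- stats[!stats$excluded, ]
    reference <- evaluated$gene_id[evaluated$essential]
    if (identical(cutoff, "auto")) {
      grid <- config$cutoffGrid %||%
        10^seq(log10(0.05), log10(5000), length.out = 200)
      curve <- sweepCutoffs(evaluated, reference, grid)
      cutoff <- selectedCutoff(curve)
      say("auto-calibrated ecIPKM cutoff: ", signif(cutoff, 4))
      .writeTsv(cutoffTable(curve), outDir, "cutoff_curve.tsv")
    }
    callRes <- callEssential(stats, cutoff = cutoff)
    groups <- list(all = evaluated$gene_id,
                   reference_essential = reference,
                   pseudogene = evaluated$gene_id[evaluated$pseudo])
    distributions <- suppressWarnings(
      summarizeDistributions(evaluated, groups))
    .writeTsv(callRes$stats, outDir, "gene_stats.tsv")
    .writeTsv(distributions, outDir, "ecipkm_distributions.tsv")
    if (!is.null(callRes$summary)) {
      s <- callRes$summary
      .writeTsv(data.frame(
        n_called_essential = s@nCalledEssential,
        n_reference = s@nReference, true_positives = s@truePositives,
        false_positives = s@falsePositives,
        false_negatives = s@falseNegatives,
        coverage_percent = s@coveragePercent), outDir, "confusion.tsv")
    }
  }

  protection <- coverage <- NULL
  if (!is.null(regions) && length(regions)) {
    say("protection tests (", config$nSets, " bootstrap sets per region set)")
    tests <- lapply(seq_along(regions), function(i)
      bootstrapProtectionTest(regions[[i]], tis, nSets = config$nSets,
                              seed = .stageSeed(config$seed, "bootstrap") + i))
    names(tests) <- names(regions)
    protection <- list(summary = protectionSummaryTable(tests),
                       tests = tests)
    .writeTsv(protection$summary, outDir, "protection.tsv")
    if (!is.null(callRes)) {
      called <- callRes$stats
      fp <- called$gene_id[called$call == "essential" & !called$essential]
      coverage <- geneRegionCoverage(genes, regions,
                                     threshold = config$coverageThreshold,
                                     geneSubset = fp)
      .writeTsv(coverage$perGene, outDir, "gene_region_coverage.tsv")
    }
  }

  resolved <- config
  resolved$cutoff <- cutoff
  if (!is.null(outDir)) {
    rpt <- c(
      "tnseqr run report",
      paste0("seed: ", config$seed),
      paste0("end trim: ", config$endTrim),
      paste0("cutoff: ", signif(cutoff, 6),
             if (identical(config$cutoff, "auto")) " (auto-calibrated)"
             else ""),
      paste0("bootstrap sets: ", config$nSets),
      paste0("coverage threshold: ", config$coverageThreshold),
      paste0("genome: ", genomeName(genome), " (",
             format(genomeLength(genome), big.mark = ","), " bp)"),
      paste0("unique insertion sites: ", totalUnique(tis)),
      if (!is.null(callRes))
        paste0("genes called essential: ",
               sum(callRes$stats$call == "essential"), " / ",
               nrow(callRes$stats)),
      if (!is.null(callRes) && !is.null(callRes$summary))
        paste0("coverage of reference: ",
               sprintf("%.1f%%", callRes$summary@coveragePercent)),
      if (!is.null(protection))
        paste0("protection sets tested: ", nrow(protection$summary)))
    writeLines(rpt, file.path(outDir, "report.txt"))
  }

  invisible(list(genome = genome, tis = tis, genes = genes, truth = truth,
                 landscape = landscape, stats = stats, curve = curve,
                 cutoff = cutoff, call = callRes,
                 distributions = distributions, protection = protection,
                 coverage = coverage, validation = validation,
                 config = resolved))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quick plots of the main results
#'
#' Base-graphics figures: the accuracy/coverage curve along the cutoff grid,
#' and the bootstrap null distribution with the observed mean marked.
#'
#' @param curve A [CutoffCurve-class].
#' @param result A [BootstrapResult-class].
#' @return Invisibly, `NULL`; called for the plot side effect.
#' @name quick-plots
NULL

#' @rdname quick-plots
#' @export
plotCutoffCurve <- function(curve) {
  cv <- cutoffTable(curve)
  graphics::plot(cv$cutoff, cv$accuracy, type = "l", log = "x",
                 xlab = "ecIPKM cutoff", ylab = "accuracy / coverage",
                 ylim = c(0, 1))
  graphics::lines(cv$cutoff, cv$coverage, lty = 2)
  graphics::abline(v = selectedCutoff(curve), col = "grey50")
  graphics::legend("bottomright", legend = c("accuracy", "coverage"),
                   lty = c(1, 2), bty = "n")
  invisible(NULL)
}

#' @rdname quick-plots
#' @export
plotNullDistribution <- function(result) {
  graphics::hist(nullMeans(result), breaks = 50, main = "",
                 xlab = "mean IPKM of random region sets")
  graphics::abline(v = result@observed@mean, col = "red", lwd = 2)
  invisible(NULL)
}
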